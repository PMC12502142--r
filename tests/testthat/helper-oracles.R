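# Independent brute-force oracles. These deliberately avoid the package's
# constancy/percolation/igraph code paths: everything is computed by direct
# enumeration over full states.

oracle_states <- function(net) {
  n <- length(net$variables)
  m <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(m) <- net$variables
  storage.mode(m) <- "integer"
  m
}

# image table: row r holds f(state r)
oracle_image <- function(net, states = oracle_states(net)) {
  res <- apply(states, 1L, function(x) eval_network(net, x))
  if (is.null(dim(res))) {          # single-variable network
    matrix(res, ncol = 1L, dimnames = list(NULL, net$variables))
  } else {
    t(res)
  }
}

oracle_state_strings <- function(states) apply(states, 1L, paste, collapse = "")

# rows of `states` belonging to subspace s (named 0/1 vector)
oracle_in_subspace <- function(states, s) {
  keep <- rep(TRUE, nrow(states))
  for (v in names(s)) keep <- keep & states[, v] == s[[v]]
  which(keep)
}

# all 3^n subspaces as a list of named 0/1 vectors
oracle_all_subspaces <- function(net) {
  n <- length(net$variables)
  grid <- expand.grid(rep(list(c(-1L, 0L, 1L)), n), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    row <- as.integer(grid[r, ])
    fixed <- row >= 0L
    stats::setNames(row[fixed], net$variables[fixed])
  })
}

# trap space test from the definition: f_i(x) = d_i for every state x in S
# and every fixed variable i
oracle_is_trap_space <- function(net, s, img, states) {
  rows <- oracle_in_subspace(states, s)
  for (v in names(s)) {
    if (any(img[rows, v] != s[[v]])) return(FALSE)
  }
  TRUE
}

oracle_trap_spaces <- function(net) {
  states <- oracle_states(net)
  img <- oracle_image(net, states)
  Filter(function(s) oracle_is_trap_space(net, s, img, states),
         oracle_all_subspaces(net))
}

# smallest subspace containing the image of S (one percolation step)
oracle_percolation_step <- function(net, s) {
  states <- oracle_states(net)
  img <- oracle_image(net, states)
  rows <- oracle_in_subspace(states, s)
  sub <- img[rows, , drop = FALSE]
  const <- vapply(net$variables, function(v) length(unique(sub[, v])) == 1L, TRUE)
  stats::setNames(sub[1L, const], net$variables[const])
}

# asynchronous successor indices of each state, by direct evaluation
oracle_async_successors <- function(net, states, img) {
  n <- ncol(states)
  pow <- 2L^(seq_len(n) - 1L)
  lapply(seq_len(nrow(states)), function(r) {
    d <- which(img[r, ] != states[r, ])
    r + (1L - 2L * states[r, d]) * pow[d]
  })
}

# attractors as terminal SCCs via boolean reachability closure (no igraph)
oracle_attractors <- function(net, update = "async") {
  states <- oracle_states(net)
  img <- oracle_image(net, states)
  ns <- nrow(states)
  succ <- if (update == "async") {
    oracle_async_successors(net, states, img)
  } else if (update == "sync") {
    pow <- 2L^(seq_len(ncol(states)) - 1L)
    lapply(seq_len(ns), function(r) {
      to <- as.integer(sum(img[r, ] * pow)) + 1L
      if (to == r) integer(0) else to
    })
  } else {
    pow <- 2L^(seq_len(ncol(states)) - 1L)
    lapply(seq_len(ns), function(r) {
      d <- which(img[r, ] != states[r, ])
      if (length(d) == 0L) return(integer(0))
      subs <- unlist(lapply(seq_along(d), function(sz) {
        if (length(d) == 1L) list(d) else utils::combn(d, sz, simplify = FALSE)
      }), recursive = FALSE)
      vapply(subs, function(cc) {
        as.integer(r + sum((1L - 2L * states[r, cc]) * pow[cc]))
      }, 1L)
    })
  }
  reach <- diag(ns) > 0
  for (r in seq_len(ns)) reach[r, succ[[r]]] <- TRUE
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  strings <- oracle_state_strings(states)
  seen <- rep(FALSE, ns)
  out <- list()
  for (r in seq_len(ns)) {
    if (seen[r]) next
    fwd <- which(reach[r, ])
    if (all(reach[fwd, r])) {     # terminal SCC containing r
      out[[length(out) + 1L]] <- sort(strings[fwd])
      seen[fwd] <- TRUE
    }
  }
  out[order(vapply(out, `[[`, "", 1L))]
}

# interaction graph straight from the definition, over all 2^n states
oracle_interaction_graph <- function(net) {
  states <- oracle_states(net)
  img <- oracle_image(net, states)
  n <- ncol(states)
  pow <- 2L^(seq_len(n) - 1L)
  edges <- character(0)
  for (i in seq_len(n)) {
    low <- which(states[, i] == 0L)
    d <- img[low + pow[i], ] - img[low, ]   # f(x, x_i=1) - f(x, x_i=0)
    for (j in seq_len(n)) {
      if (any(d[, j] > 0L)) {
        edges <- c(edges, paste(net$variables[i], net$variables[j], "+"))
      }
      if (any(d[, j] < 0L)) {
        edges <- c(edges, paste(net$variables[i], net$variables[j], "-"))
      }
    }
  }
  sort(edges)
}

subspace_key <- function(net, s) format_subspace(net, s)
subspace_set_equal <- function(net, a, b) {
  setequal(vapply(a, subspace_key, "", net = net),
           vapply(b, subspace_key, "", net = net))
}
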