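# State transition graphs and attractors.

#' Explicit state transition graph
#'
#' Builds the full dynamics over the `2^n` states for one of the three
#' update schemes: `"sync"` (all updatable components switch at once, at most
#' one successor), `"async"` (one component at a time), or `"general"` (any
#' nonempty set of updatable components). Self-loops are never included.
#'
#' @param net a `boolean_network`
#' @param update `"async"` (default), `"sync"` or `"general"`
#' @param cap refuse construction for networks with more variables than this
#' @return object of class `stg`: list with `update`, `states` (character
#'   vector of 0/1 state strings in enumeration order) and `edges` (tibble of
#'   integer state indices `from`, `to`).
#' @export
state_transition_graph <- function(net, update = c("async", "sync", "general"),
                                   cap = 20L) {
  update <- match.arg(update)
  n <- length(net$variables)
  if (n > cap) {
    stop("state transition graph needs 2^", n, " states (cap n <= ", cap, ")",
         call. = FALSE)
  }
  m <- all_states_matrix(net$variables)
  fm <- vapply(net$variables,
               function(v) eval_dnf_matrix(net$functions[[v]], m),
               integer(nrow(m)))
  if (n == 1L) fm <- matrix(fm, ncol = 1L, dimnames = list(NULL, net$variables))
  states <- apply(m, 1L, paste, collapse = "")
  pow <- as.integer(2^(seq_len(n) - 1L))   # expand.grid: first variable fastest
  diff <- fm != m

  from <- integer(0); to <- integer(0)
  if (update == "sync") {
    idx <- as.integer(fm %*% pow) + 1L
    keep <- idx != seq_len(nrow(m))
    from <- which(keep); to <- idx[keep]
  } else if (update == "async") {
    for (i in seq_len(n)) {
      rows <- which(diff[, i])
      if (length(rows) == 0L) next
      from <- c(from, rows)
      to <- c(to, rows + (1L - 2L * m[rows, i]) * pow[[i]])
    }
  } else {
    for (r in seq_len(nrow(m))) {
      d <- which(diff[r, ])
      if (length(d) == 0L) next
      for (sz in seq_along(d)) {
        combs <- if (length(d) == 1L) list(d) else utils::combn(d, sz, simplify = FALSE)
        for (cc in combs) {
          from <- c(from, r)
          to <- c(to, r + sum((1L - 2L * m[r, cc]) * pow[cc]))
        }
      }
    }
  }
  structure(list(update = update, states = states,
                 edges = tibble::tibble(from = from, to = to)),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat("State transition graph (", x$update, "): ", length(x$states),
      " states, ", nrow(x$edges), " transitions\n", sep = "")
  invisible(x)
}

#' Attractors as terminal strongly connected components
#'
#' An attractor is a minimal trap set: a terminal strongly connected
#' component of the state transition graph. Steady states are the singleton
#' attractors.
#'
#' @inheritParams state_transition_graph
#' @return tibble with columns `states` (list of character state strings),
#'   `kind` (`"steady"` or `"complex"`) and `size`, sorted by the smallest
#'   state string of each attractor.
#' @export
attractors <- function(net, update = c("async", "sync", "general"), cap = 20L) {
  stg <- state_transition_graph(net, update, cap = cap)
  attractors_of_stg(stg)
}

#' Terminal strongly connected components of an `stg`
#' @param stg object returned by [state_transition_graph()]
#' @return same shape as [attractors()]
#' @export
attractors_of_stg <- function(stg) {
  nstate <- length(stg$states)
  g <- igraph::graph_from_edgelist(cbind(stg$edges$from, stg$edges$to))
  g <- igraph::add_vertices(g, max(0L, nstate - igraph::vcount(g)))
  memb <- igraph::components(g, mode = "strong")$membership
  leaving <- memb[stg$edges$from] != memb[stg$edges$to]
  non_terminal <- unique(memb[stg$edges$from][leaving])
  terminal <- setdiff(unique(memb), non_terminal)
  out <- lapply(terminal, function(k) sort(stg$states[memb == k]))
  out <- out[order(vapply(out, `[[`, "", 1L))]
  tibble::tibble(
    states = out,
    kind = ifelse(vapply(out, length, 1L) == 1L, "steady", "complex"),
    size = vapply(out, length, 1L)
  )
}
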