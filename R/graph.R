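# Signed interaction graph.

#' Signed interaction graph of a Boolean network
#'
#' There is an edge from `i` to `j` with sign `s` when some state `x`
#' witnesses `s = sign((f_j(x with i flipped) - f_j(x)) * (flip direction))`,
#' i.e. only essential (functional) dependencies are reported; both signs may
#' coexist for one ordered pair. Computed exactly by enumerating all
#' assignments of the syntactic regulators of each function.
#'
#' @inheritParams constancy
#' @return tibble with columns `source`, `target`, `sign` (`"+"` or `"-"`)
#' @export
interaction_graph <- function(net, max_indegree = 16L) {
  src <- character(0); tgt <- character(0); sgn <- character(0)
  for (j in net$variables) {
    dnf <- net$functions[[j]]
    regs <- dnf_regulators(dnf)
    if (length(regs) == 0L) next
    if (length(regs) > max_indegree) {
      stop("interaction graph for ", j, " needs enumeration over ",
           length(regs), " regulators (cap ", max_indegree, ")", call. = FALSE)
    }
    m <- all_states_matrix(regs)
    vals <- eval_dnf_matrix(dnf, m)
    for (p in seq_along(regs)) {
      offset <- 2L^(p - 1L)
      low <- which(m[, p] == 0L)           # expand.grid: first column fastest
      d <- vals[low + offset] - vals[low]  # f_j(x_i=1) - f_j(x_i=0)
      if (any(d > 0L)) {
        src <- c(src, regs[[p]]); tgt <- c(tgt, j); sgn <- c(sgn, "+")
      }
      if (any(d < 0L)) {
        src <- c(src, regs[[p]]); tgt <- c(tgt, j); sgn <- c(sgn, "-")
      }
    }
  }
  tibble::tibble(source = src, target = tgt, sign = sgn)
}

#' Variables reachable from each node by sign-consistent walks
#'
#' Walks (repeated vertices allowed) in the signed interaction graph; the
#' sign of a walk is the product of its edge signs and the length-0 walk is
#' positive. Used by the candidate reduction for direct-percolation node
#' control.
#'
#' @param ig tibble as returned by [interaction_graph()]
#' @param variables all network variables
#' @return list with logical matrices `pos` and `neg`; `pos[i, v]` is `TRUE`
#'   when a positive walk from `i` to `v` exists.
#' @noRd
signed_reachability <- function(ig, variables) {
  n <- length(variables)
  pos <- diag(n) > 0                       # length-0 walks
  neg <- matrix(FALSE, n, n)
  dimnames(pos) <- dimnames(neg) <- list(variables, variables)
  es <- match(ig$source, variables)
  et <- match(ig$target, variables)
  ep <- ig$sign == "+"
  repeat {
    changed <- FALSE
    for (k in seq_along(es)) {
      i <- es[[k]]; j <- et[[k]]
      if (ep[[k]]) {
        newpos <- pos[, i] & !pos[, j]
        newneg <- neg[, i] & !neg[, j]
      } else {
        newpos <- neg[, i] & !pos[, j]
        newneg <- pos[, i] & !neg[, j]
      }
      if (any(newpos)) { pos[newpos, j] <- TRUE; changed <- TRUE }
      if (any(newneg)) { neg[newneg, j] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  list(pos = pos, neg = neg)
}
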