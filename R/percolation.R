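# Value percolation.
#
# The percolation function F(f) maps a subspace S to the smallest subspace
# containing its image f(S): variable i is fixed in F(f)(S) exactly when f_i
# restricted to S is constant. Constancy is decided exactly, by enumerating
# all assignments of the free syntactic regulators (a purely syntactic
# partial evaluation would miss tautologies such as x1 | !x1 arising after
# rewriting).

#' Syntactic restriction of a DNF by a partial assignment
#'
#' A literal fixed true is dropped from its clause; a clause containing a
#' literal fixed false is removed; an emptied clause makes the function
#' constant 1; an emptied DNF is the constant 0.
#' @noRd
dnf_restrict <- function(dnf, assignment) {
  out <- list()
  for (clause in dnf) {
    keep <- clause
    dead <- FALSE
    hit <- intersect(names(clause), names(assignment))
    for (v in hit) {
      sat <- (clause[[v]] > 0L) == (assignment[[v]] == 1L)
      if (sat) {
        keep <- keep[names(keep) != v]
      } else {
        dead <- TRUE
        break
      }
    }
    if (dead) next
    if (length(keep) == 0L) return(dnf_constant_1())
    out[[length(out) + 1L]] <- keep
  }
  out
}

#' Constancy of a coordinate function on a subspace
#'
#' Decides whether `f_i` restricted to the subspace `s` is constant, by exact
#' enumeration of all assignments of its free syntactic regulators (variables
#' fixed in `s` are substituted first).
#'
#' @param net a `boolean_network`
#' @param var variable whose function is examined
#' @param s a subspace (named 0/1 vector; empty = full state space)
#' @param max_indegree refuse enumeration beyond this many free regulators
#' @return `0L`, `1L`, or `NA` when the restricted function is not constant
#' @export
constancy <- function(net, var, s = character(0), max_indegree = 16L) {
  dnf <- dnf_restrict(net$functions[[var]], s)
  k <- dnf_const(dnf)
  if (!is.na(k)) return(k)
  regs <- dnf_regulators(dnf)
  if (length(regs) > max_indegree) {
    stop("constancy check on ", var, " needs enumeration over ", length(regs),
         " regulators (cap ", max_indegree, ")", call. = FALSE)
  }
  m <- all_states_matrix(regs)
  vals <- eval_dnf_matrix(dnf, m)
  if (all(vals == 1L)) return(1L)
  if (all(vals == 0L)) return(0L)
  NA_integer_
}

#' One application of the percolation function F(f)
#'
#' Maps a subspace to the smallest subspace containing its image under `f`.
#'
#' @inheritParams constancy
#' @param s a subspace
#' @return a subspace: the variables with constant restricted functions,
#'   fixed at their constant values.
#' @export
percolation_step <- function(net, s = character(0), max_indegree = 16L) {
  vals <- vapply(net$variables, constancy, 1L, net = net, s = s,
                 max_indegree = max_indegree)
  subspace(net, vals[!is.na(vals)])
}

#' Percolation fixpoint from a trap space
#'
#' Iterates [percolation_step()] from a trap space until it stabilizes. Each
#' iterate of a trap space is again a trap space contained in its
#' predecessor, so the iteration reaches its fixpoint within `n` steps. Only
#' trap-space starts are accepted (in particular the full state space); for
#' arbitrary subspaces the iteration has no comparable semantics and is
#' refused.
#'
#' @inheritParams constancy
#' @param s a trap space of `net` (default: the full state space)
#' @param check_trap verify the precondition (disable only when the caller
#'   already knows `s` is a trap space)
#' @return the fixpoint subspace
#' @export
percolate <- function(net, s = character(0), check_trap = TRUE,
                      max_indegree = 16L) {
  if (check_trap && !is_trap_space(net, s, max_indegree = max_indegree)) {
    stop("percolate() requires a trap space start, got ",
         format_subspace(net, s), call. = FALSE)
  }
  for (i in seq_len(length(net$variables) + 1L)) {
    s2 <- percolation_step(net, s, max_indegree = max_indegree)
    if (subspace_equal(s2, s)) return(s)
    s <- s2
  }
  s
}

#' Percolate and remove constant functions
#'
#' Repeatedly removes variables whose regulatory function is constant
#' (decided exactly, so hidden tautologies are caught), substituting the
#' constant value into the remaining functions, until the network is
#' constant-free. The attractors of the original network are the attractors
#' of the reduced network extended by the recorded context.
#'
#' @inheritParams constancy
#' @return list with elements `network` (the constant-free reduced network,
#'   or `NULL` when every variable became constant), `context` (subspace of
#'   the original network recording every removed variable's forced value)
#'   and `all_constant` (flag).
#' @export
percolate_constants <- function(net, max_indegree = 16L) {
  context <- setNames(integer(0), character(0))
  repeat {
    if (length(net$variables) == 0L) break
    vals <- vapply(net$variables, constancy, 1L, net = net,
                   max_indegree = max_indegree)
    fixed <- vals[!is.na(vals)]
    if (length(fixed) == 0L) break
    context <- c(context, fixed)
    keep <- setdiff(net$variables, names(fixed))
    if (length(keep) == 0L) {
      net <- structure(list(variables = character(0), functions = list()),
                       class = "boolean_network")
      break
    }
    funs <- lapply(net$functions[keep], function(dnf) {
      normalize_dnf(dnf_restrict(dnf, fixed), keep)
    })
    net <- boolean_network(keep, setNames(funs, keep))
  }
  all_constant <- length(net$variables) == 0L
  list(network = if (all_constant) NULL else net,
       context = context,
       all_constant = all_constant)
}
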