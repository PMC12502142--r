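#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# ---- DNF primitives ---------------------------------------------------------
#
# A regulatory function is held in disjunctive normal form (DNF):
#   * a DNF is a list of clauses,
#   * a clause is a named integer vector, +1L for a positive literal and
#     -1L for a negated one,
#   * list() is the constant 0, and a DNF holding one empty clause is the
#     constant 1.
# Clauses never mention a variable with both polarities and are deduplicated.

empty_clause <- function() setNames(integer(0), character(0))

dnf_constant_0 <- function() list()
dnf_constant_1 <- function() list(empty_clause())

#' Constant value of a DNF, if syntactically constant
#' @return 0L, 1L or NA (not syntactically constant)
#' @noRd
dnf_const <- function(dnf) {
  if (length(dnf) == 0L) return(0L)
  if (any(vapply(dnf, length, 1L) == 0L)) return(1L)
  NA_integer_
}

clause_key <- function(clause) {
  if (length(clause) == 0L) return("")
  ord <- order(names(clause))
  paste(names(clause)[ord], clause[ord], sep = ":", collapse = ",")
}

#' Canonicalize a DNF: order literals by declaration order, drop duplicate and
#' contradictory clauses, collapse to constant 1 when an empty clause appears.
#' @noRd
normalize_dnf <- function(dnf, variables) {
  keep <- list()
  seen <- character(0)
  for (clause in dnf) {
    if (anyDuplicated(names(clause))) {
      # a variable mentioned twice: same sign collapses, opposite sign is a
      # contradiction and the clause is dropped
      agg <- tapply(clause, names(clause), function(v) {
        if (length(unique(v)) > 1L) NA_integer_ else v[[1L]]
      })
      if (anyNA(agg)) next
      clause <- setNames(as.integer(agg), names(agg))
    }
    clause <- clause[order(match(names(clause), variables))]
    if (length(clause) == 0L) return(dnf_constant_1())
    key <- clause_key(clause)
    if (key %in% seen) next
    seen <- c(seen, key)
    keep[[length(keep) + 1L]] <- clause
  }
  keep[order(vapply(keep, clause_key, ""))]
}

dnf_regulators <- function(dnf) {
  unique(unlist(lapply(dnf, names), use.names = FALSE))
}

#' Evaluate a DNF on one total (or sufficient partial) assignment.
#' @param assignment named integer vector of 0/1 values covering regulators
#' @noRd
eval_dnf <- function(dnf, assignment) {
  if (length(dnf) == 0L) return(0L)
  for (clause in dnf) {
    if (length(clause) == 0L) return(1L)
    vals <- assignment[names(clause)]
    if (all(ifelse(clause > 0L, vals == 1L, vals == 0L))) return(1L)
  }
  0L
}

#' Evaluate a DNF on a 0/1 matrix of assignments (rows = states, named cols).
#' @return integer vector of 0/1, one per row
#' @noRd
eval_dnf_matrix <- function(dnf, m) {
  if (length(dnf) == 0L) return(rep(0L, nrow(m)))
  out <- rep(FALSE, nrow(m))
  for (clause in dnf) {
    if (length(clause) == 0L) return(rep(1L, nrow(m)))
    sat <- rep(TRUE, nrow(m))
    for (v in names(clause)) {
      sat <- sat & (if (clause[[v]] > 0L) m[, v] == 1L else m[, v] == 0L)
    }
    out <- out | sat
    if (all(out)) break
  }
  as.integer(out)
}

dnf_equal <- function(a, b) {
  identical(vapply(a, clause_key, ""), vapply(b, clause_key, ""))
}

# ---- boolean_network --------------------------------------------------------

#' Create a Boolean network
#'
#' A Boolean network on `n` variables is a function
#' `f = (f_1, ..., f_n) : {0,1}^n -> {0,1}^n`; each coordinate function is a
#' regulatory rule stored in disjunctive normal form. Variable order is the
#' declaration order and is used for all `0/1/*` subspace renderings.
#'
#' @param variables character vector of unique variable names.
#' @param functions named list, one DNF per variable. A DNF is a list of
#'   clauses; a clause is a named integer vector with values `+1` (plain
#'   literal) and `-1` (negated literal). `list()` is the constant 0 and a
#'   DNF containing an empty clause is the constant 1.
#' @return an object of class `boolean_network`.
#' @export
boolean_network <- function(variables, functions) {
  stopifnot(is.character(variables), length(variables) >= 1L)
  if (anyDuplicated(variables)) stop("duplicate variable names", call. = FALSE)
  if (!setequal(names(functions), variables)) {
    stop("functions must be named exactly by the declared variables", call. = FALSE)
  }
  functions <- functions[variables]
  functions <- lapply(functions, function(dnf) {
    regs <- dnf_regulators(dnf)
    bad <- setdiff(regs, variables)
    if (length(bad) > 0L) {
      stop("undeclared variable(s) in expression: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    normalize_dnf(dnf, variables)
  })
  structure(list(variables = variables, functions = functions),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", length(x$variables), "variables\n")
  for (v in x$variables) {
    cat(" ", v, "<-", format_dnf(x$functions[[v]]), "\n")
  }
  invisible(x)
}

#' Number of variables of a network
#' @param net a `boolean_network`
#' @return integer count
#' @export
n_variables <- function(net) length(net$variables)

#' Evaluate the network function on a state
#'
#' @param net a `boolean_network`
#' @param state named integer vector assigning 0/1 to every variable, or an
#'   unnamed vector in variable order.
#' @return named integer vector `f(state)` in variable order.
#' @export
eval_network <- function(net, state) {
  if (is.null(names(state))) names(state) <- net$variables
  state <- state[net$variables]
  setNames(vapply(net$variables, function(v) eval_dnf(net$functions[[v]], state), 1L),
           net$variables)
}

#' All states of the network as a 0/1 matrix (rows = states)
#' @noRd
all_states_matrix <- function(variables) {
  n <- length(variables)
  m <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(m) <- variables
  storage.mode(m) <- "integer"
  m
}

state_string <- function(state, variables) {
  paste(state[variables], collapse = "")
}

# ---- subspaces --------------------------------------------------------------
#
# A subspace Sigma(I, d) is a partial assignment: a named integer vector of
# 0/1 values over the fixed variables I. The empty vector is the full state
# space. Rendering uses 0/1 for fixed and * for free positions in variable
# order.

#' Construct / validate a subspace
#'
#' @param net a `boolean_network`
#' @param fixed named integer/numeric vector of 0/1 values, or a string:
#'   either a `0/1/*` mask in variable order (e.g. `"**0"`) or a
#'   comma-separated list of `name=value` pairs (e.g. `"x1=1,x3=0"`).
#' @return named integer vector of class-free canonical form (variable order).
#' @export
subspace <- function(net, fixed) {
  if (is.character(fixed) && length(fixed) == 1L) return(parse_subspace(net, fixed))
  if (length(fixed) == 0L) return(setNames(integer(0), character(0)))
  vals <- as.integer(fixed)
  if (is.null(names(fixed)) || any(names(fixed) == "")) {
    stop("subspace values must be named by variables", call. = FALSE)
  }
  bad <- setdiff(names(fixed), net$variables)
  if (length(bad) > 0L) {
    stop("unknown variable(s) in subspace: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(fixed))) stop("variable fixed twice in subspace", call. = FALSE)
  if (!all(vals %in% c(0L, 1L))) stop("subspace values must be 0 or 1", call. = FALSE)
  v <- setNames(vals, names(fixed))
  v[intersect(net$variables, names(v))]
}

#' @rdname subspace
#' @param text subspace string to parse
#' @export
parse_subspace <- function(net, text) {
  text <- trimws(text)
  if (grepl("=", text, fixed = TRUE)) {
    parts <- strsplit(text, ",", fixed = TRUE)[[1L]]
    parts <- trimws(parts[nzchar(trimws(parts))])
    kv <- strsplit(parts, "=", fixed = TRUE)
    if (any(vapply(kv, length, 1L) != 2L)) {
      stop("malformed target string: ", text, call. = FALSE)
    }
    nm <- trimws(vapply(kv, `[[`, "", 1L))
    val <- trimws(vapply(kv, `[[`, "", 2L))
    if (!all(val %in% c("0", "1"))) {
      stop("subspace values must be 0 or 1 in: ", text, call. = FALSE)
    }
    return(subspace(net, setNames(as.integer(val), nm)))
  }
  chars <- strsplit(text, "")[[1L]]
  if (length(chars) != length(net$variables)) {
    stop("subspace mask length ", length(chars), " does not match ",
         length(net$variables), " variables", call. = FALSE)
  }
  if (!all(chars %in% c("0", "1", "*", "-"))) {
    stop("subspace mask may only contain 0, 1, *: ", text, call. = FALSE)
  }
  fixed <- chars %in% c("0", "1")
  setNames(as.integer(chars[fixed]), net$variables[fixed])
}

#' Render a subspace as a 0/1/* mask in variable order
#' @param net a `boolean_network`
#' @param s a subspace (named 0/1 vector)
#' @return character scalar such as `"**0"`
#' @export
format_subspace <- function(net, s) {
  chars <- rep("*", length(net$variables))
  idx <- match(names(s), net$variables)
  chars[idx] <- as.character(s)
  paste(chars, collapse = "")
}

#' Is subspace `a` contained in subspace `b`?
#'
#' Containment of the induced state sets: every variable fixed in `b` is
#' fixed in `a` at the same value.
#' @param a,b subspaces (named 0/1 vectors)
#' @return logical flag
#' @export
subspace_contained <- function(a, b) {
  if (length(b) == 0L) return(TRUE)
  all(names(b) %in% names(a)) && all(a[names(b)] == b)
}

subspace_equal <- function(a, b) {
  setequal(names(a), names(b)) && (length(a) == 0L || all(a[names(b)] == b))
}

#' Size of a subspace: the number of fixed variables
#' @param s a subspace
#' @return integer
#' @export
subspace_size <- function(s) length(s)

#' 0/1 matrix of all states belonging to a subspace
#' @noRd
subspace_states_matrix <- function(net, s) {
  free <- setdiff(net$variables, names(s))
  if (length(free) == 0L) {
    m <- matrix(s[net$variables], nrow = 1L, dimnames = list(NULL, net$variables))
    storage.mode(m) <- "integer"
    return(m)
  }
  m <- all_states_matrix(free)
  full <- matrix(0L, nrow = nrow(m), ncol = length(net$variables),
                 dimnames = list(NULL, net$variables))
  full[, free] <- m
  for (v in names(s)) full[, v] <- s[[v]]
  full
}
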