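# Node and edge interventions, consistency, and the controlled network f^C.

new_nodes_df <- function(var = character(0), value = integer(0)) {
  data.frame(var = as.character(var), value = as.integer(value),
             stringsAsFactors = FALSE)
}
new_edges_df <- function(source = character(0), target = character(0),
                         value = integer(0)) {
  data.frame(source = as.character(source), target = as.character(target),
             value = as.integer(value), stringsAsFactors = FALSE)
}

parse_intervention_text <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^([^=>-]+)->([^=]+)=([01])$", x))[[1L]]
  if (length(m) == 4L) {
    return(list(type = "edge", source = trimws(m[[2L]]),
                target = trimws(m[[3L]]), value = as.integer(m[[4L]])))
  }
  m <- regmatches(x, regexec("^([^=]+)=([01])$", x))[[1L]]
  if (length(m) == 3L) {
    return(list(type = "node", var = trimws(m[[2L]]),
                value = as.integer(m[[3L]])))
  }
  stop("cannot parse intervention '", x,
       "' (expected \"var=v\" or \"src->tgt=v\")", call. = FALSE)
}

#' Create an intervention set
#'
#' A node intervention `(i, c)` clamps component `i` and its regulatory
#' function to the constant `c` (a knockout or sustained activation). An
#' edge intervention `(i, j, c)` fixes the value of `i` only inside the
#' regulatory function of `j`, leaving every other interaction of `i`
#' untouched. The size of the set is the total number of interventions.
#'
#' @param nodes node interventions: a named 0/1 vector (`c(x3 = 0)`), a data
#'   frame with columns `var`, `value`, or a character vector of `"var=v"` /
#'   `"src->tgt=v"` strings (edge strings are routed to `edges`).
#' @param edges edge interventions: a data frame with columns `source`,
#'   `target`, `value`, or a character vector of `"src->tgt=v"` strings.
#' @return an object of class `intervention_set`
#' @export
intervention_set <- function(nodes = NULL, edges = NULL) {
  ndf <- new_nodes_df()
  edf <- new_edges_df()
  take <- function(parsed) {
    if (parsed$type == "node") {
      ndf[nrow(ndf) + 1L, ] <<- list(parsed$var, parsed$value)
    } else {
      edf[nrow(edf) + 1L, ] <<- list(parsed$source, parsed$target, parsed$value)
    }
  }
  if (!is.null(nodes)) {
    if (is.character(nodes) && is.null(names(nodes))) {
      for (x in nodes) take(parse_intervention_text(x))
    } else if (is.data.frame(nodes)) {
      for (r in seq_len(nrow(nodes))) {
        take(list(type = "node", var = nodes$var[[r]],
                  value = as.integer(nodes$value[[r]])))
      }
    } else {
      if (is.null(names(nodes))) stop("node interventions must be named", call. = FALSE)
      for (v in names(nodes)) take(list(type = "node", var = v,
                                        value = as.integer(nodes[[v]])))
    }
  }
  if (!is.null(edges)) {
    if (is.character(edges)) {
      for (x in edges) {
        p <- parse_intervention_text(x)
        if (p$type != "edge") stop("expected an edge intervention: ", x, call. = FALSE)
        take(p)
      }
    } else {
      for (r in seq_len(nrow(edges))) {
        take(list(type = "edge", source = edges$source[[r]],
                  target = edges$target[[r]], value = as.integer(edges$value[[r]])))
      }
    }
  }
  ndf <- unique(ndf)
  edf <- unique(edf)
  if (!all(c(ndf$value, edf$value) %in% c(0L, 1L))) {
    stop("intervention values must be 0 or 1", call. = FALSE)
  }
  structure(list(nodes = ndf, edges = edf), class = "intervention_set")
}

#' @export
format.intervention_set <- function(x, ...) {
  parts <- character(0)
  if (nrow(x$nodes) > 0L) {
    nd <- x$nodes[order(x$nodes$var, x$nodes$value), , drop = FALSE]
    parts <- c(parts, paste0(nd$var, "=", nd$value))
  }
  if (nrow(x$edges) > 0L) {
    ed <- x$edges[order(x$edges$source, x$edges$target, x$edges$value), , drop = FALSE]
    parts <- c(parts, paste0(ed$source, "->", ed$target, "=", ed$value))
  }
  if (length(parts) == 0L) "{}" else paste(parts, collapse = ",")
}

#' @export
print.intervention_set <- function(x, ...) {
  cat("Intervention set of size", intervention_size(x), ":", format(x), "\n")
  invisible(x)
}

#' Number of interventions in a set
#' @param C an `intervention_set`
#' @return integer
#' @export
intervention_size <- function(C) nrow(C$nodes) + nrow(C$edges)

#' Subspace induced by a pure-node intervention set
#' @param net a `boolean_network`
#' @param C an `intervention_set` with no edge interventions
#' @return a subspace fixing each intervened node at its clamped value
#' @export
induced_subspace <- function(net, C) {
  if (nrow(C$edges) > 0L) {
    stop("induced subspace is defined only for pure-node intervention sets",
         call. = FALSE)
  }
  subspace(net, setNames(C$nodes$value, C$nodes$var))
}

#' Consistency of an intervention set
#'
#' A mixed set of node and edge interventions is consistent when (i) no edge
#' intervention targets the function of a node-clamped component, (ii) no
#' component is clamped to both values and a clamped component is never the
#' source of an edge intervention (node control takes priority over edge
#' control), and (iii) no two edge interventions fix the same source in the
#' same target function to opposite values.
#'
#' @param C an `intervention_set`
#' @return logical flag
#' @export
is_consistent <- function(C) {
  nd <- C$nodes; ed <- C$edges
  if (anyDuplicated(nd$var) > 0L) return(FALSE)                        # (ii)
  if (any(ed$target %in% nd$var)) return(FALSE)                        # (i)
  if (any(ed$source %in% nd$var)) return(FALSE)                        # (ii)
  if (anyDuplicated(paste(ed$source, ed$target, sep = "\r")) > 0L) {
    return(FALSE)                                                      # (iii)
  }
  TRUE
}

#' Context assignment h acting on a regulatory function
#'
#' The partial assignment that the interventions impose on the inputs of the
#' regulatory function of `j`: every node-clamped component at its clamped
#' value, plus the sources of edge interventions targeting `j`.
#'
#' @param C a consistent `intervention_set`
#' @param j a variable name
#' @return named 0/1 vector
#' @export
intervention_context <- function(C, j) {
  if (!is_consistent(C)) stop("inconsistent intervention set", call. = FALSE)
  ctx <- setNames(C$nodes$value, C$nodes$var)
  ed <- C$edges[C$edges$target == j, , drop = FALSE]
  c(ctx, setNames(ed$value, ed$source))
}

is_essential_regulator <- function(net, i, j, max_indegree = 16L) {
  dnf <- net$functions[[j]]
  regs <- dnf_regulators(dnf)
  if (!(i %in% regs)) return(FALSE)
  if (length(regs) > max_indegree) return(TRUE)  # assume essential beyond cap
  m <- all_states_matrix(regs)
  vals <- eval_dnf_matrix(dnf, m)
  p <- match(i, regs)
  offset <- 2L^(p - 1L)
  low <- which(m[, p] == 0L)
  any(vals[low + offset] != vals[low])
}

#' Controlled network f^C
#'
#' Applies a consistent set of interventions: node-clamped functions become
#' constants, every other function is composed with its context, realized by
#' DNF rewriting (a literal fixed true is dropped from its clause, a clause
#' with a literal fixed false is removed, an emptied clause yields the
#' constant 1, an emptied DNF the constant 0). Satisfies
#' `f^C_k(x) = f_k(h(x))` for all states `x`.
#'
#' Edge interventions must name a syntactic regulator of the target
#' function; a syntactic but non-essential regulator is accepted with a
#' warning.
#'
#' @param net a `boolean_network`
#' @param C an `intervention_set`
#' @param warn_inessential warn when an edge intervention acts on a
#'   non-essential regulator
#' @return the controlled `boolean_network`
#' @export
apply_interventions <- function(net, C, warn_inessential = TRUE) {
  if (!is_consistent(C)) stop("inconsistent intervention set", call. = FALSE)
  for (r in seq_len(nrow(C$nodes))) {
    if (!(C$nodes$var[[r]] %in% net$variables)) {
      stop("node intervention on undeclared variable ", C$nodes$var[[r]],
           call. = FALSE)
    }
  }
  for (r in seq_len(nrow(C$edges))) {
    i <- C$edges$source[[r]]; j <- C$edges$target[[r]]
    if (!(j %in% net$variables) || !(i %in% net$variables)) {
      stop("edge intervention on undeclared variable(s): ", i, "->", j,
           call. = FALSE)
    }
    if (!(i %in% dnf_regulators(net$functions[[j]]))) {
      stop("edge intervention ", i, "->", j,
           " does not match a regulator of ", j, call. = FALSE)
    }
    if (warn_inessential && !is_essential_regulator(net, i, j)) {
      warning("edge intervention ", i, "->", j,
              " acts on a non-essential regulator", call. = FALSE)
    }
  }
  clamped <- setNames(C$nodes$value, C$nodes$var)
  funs <- lapply(net$variables, function(k) {
    if (k %in% names(clamped)) {
      if (clamped[[k]] == 1L) dnf_constant_1() else dnf_constant_0()
    } else {
      ctx <- intervention_context(C, k)
      if (length(ctx) == 0L) net$functions[[k]] else {
        dnf_restrict(net$functions[[k]], ctx)
      }
    }
  })
  boolean_network(net$variables, setNames(funs, net$variables))
}

#' Long-term equivalence of intervention sets
#'
#' Two intervention sets are equivalent when percolation from the full state
#' space under the two controlled networks reaches the same subspace. By
#' default the full percolation fixpoints are compared (which makes the
#' relation transitive); `mode = "one_step"` compares a single application
#' of the percolation function instead.
#'
#' @param net a `boolean_network`
#' @param C1,C2 consistent `intervention_set`s
#' @param mode `"fixpoint"` (default) or `"one_step"`
#' @return logical flag
#' @export
equivalent_interventions <- function(net, C1, C2,
                                     mode = c("fixpoint", "one_step")) {
  mode <- match.arg(mode)
  f1 <- apply_interventions(net, C1, warn_inessential = FALSE)
  f2 <- apply_interventions(net, C2, warn_inessential = FALSE)
  if (mode == "one_step") {
    return(subspace_equal(percolation_step(f1), percolation_step(f2)))
  }
  subspace_equal(percolate(f1, check_trap = FALSE),
                 percolate(f2, check_trap = FALSE))
}
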