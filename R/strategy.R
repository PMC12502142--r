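# Enumeration of all inclusion-minimal control strategies up to a size limit.

#' Find minimal control strategies for a target subspace
#'
#' A set of interventions is a control strategy for the target `target` when
#' every attractor of the controlled dynamics lies inside `target`. Two
#' sufficient conditions are searched: direct percolation (the full state
#' space percolates into the target under the controlled network) and
#' percolation into a selected trap space — a non-percolating trap space all
#' of whose attractors lie in the target, with the interventions restricted
#' to its fixed variables. Strategies found via trap spaces never introduce
#' new attractors and can be released once the trap space is reached.
#'
#' Constant functions are percolated away first; candidate subsets are
#' enumerated by increasing size, every superset of an accepted strategy is
#' pruned, and the result is the complete inclusion-minimal antichain of
#' accepted intervention sets up to `max_size`, each annotated with one
#' satisfying witness. Identical inputs always yield identical ordered
#' output.
#'
#' @param net a `boolean_network`
#' @param target target subspace (named 0/1 vector, mask string such as
#'   `"1*0"`, or `"name=value"` pairs)
#' @param method `"combined"` (default: both witness families), `"direct"`,
#'   or `"trapspaces"`
#' @param kind intervention kinds searched: `"node"`, `"edge"` or `"both"`
#' @param max_size largest number of interventions per strategy
#' @param avoid_nodes variables that must not be intervened on as nodes
#' @param avoid_edges edges that must not be intervened on (`"src->tgt"`
#'   strings or a data frame with `source`, `target`)
#' @param update update scheme used when attractors are computed from the
#'   state transition graph
#' @param attractor_source attractor knowledge for Type 2 selected trap
#'   spaces; see [selected_trap_spaces()]
#' @param forbid_target_nodes exclude the target-fixed variables from node
#'   intervention
#' @param reduction apply the signed-path candidate reduction for direct
#'   node candidates
#' @param max_indegree enumeration cap for constancy checks
#' @param stg_cap variable cap for state-transition-graph computations
#' @return tibble with one row per minimal strategy: `strategy` (rendered
#'   text), `size`, `method` (`"direct"`/`"via_trap_space"`), `witness` and
#'   `fixpoint` (subspace strings over the original variables) and
#'   `interventions` (list of `intervention_set`), sorted by size then
#'   rendering.
#' @export
control_strategies <- function(net, target,
                               method = c("combined", "direct", "trapspaces"),
                               kind = c("node", "edge", "both"),
                               max_size = 3L,
                               avoid_nodes = character(0),
                               avoid_edges = NULL,
                               update = "async",
                               attractor_source = NULL,
                               forbid_target_nodes = FALSE,
                               reduction = TRUE,
                               max_indegree = 16L,
                               stg_cap = 20L) {
  method <- match.arg(method)
  kind <- match.arg(kind)
  stopifnot(max_size >= 0L)
  target <- subspace(net, target)
  if (forbid_target_nodes) avoid_nodes <- union(avoid_nodes, names(target))

  empty_result <- tibble::tibble(strategy = character(0), size = integer(0),
                                 method = character(0), witness = character(0),
                                 fixpoint = character(0), interventions = list())

  # constant preprocessing; strategies are searched on the reduced network
  pre <- percolate_constants(net, max_indegree = max_indegree)
  context <- pre$context
  clash <- intersect(names(context), names(target))
  if (length(clash) > 0L && any(context[clash] != target[clash])) {
    warning("target conflicts with percolated constant value(s) of: ",
            paste(clash[context[clash] != target[clash]], collapse = ", "),
            call. = FALSE)
    return(empty_result)
  }
  if (pre$all_constant) {
    # the whole network collapses to one forced state
    if (all(target[names(target)] == context[names(target)])) {
      return(tibble::tibble(strategy = "{}", size = 0L, method = "direct",
                            witness = format_subspace(net, target),
                            fixpoint = format_subspace(net, context),
                            interventions = list(intervention_set())))
    }
    return(empty_result)
  }
  rnet <- pre$network
  rtarget <- target[setdiff(names(target), names(context))]
  full_string <- function(s) format_subspace(net, c(s, context))

  # ---- witnesses ----
  witnesses <- list()
  if (method %in% c("direct", "combined")) {
    witnesses[[length(witnesses) + 1L]] <- list(s = rtarget, mode = "direct")
  }
  if (method %in% c("trapspaces", "combined")) {
    sel <- selected_trap_spaces(rnet, rtarget, attractor_source,
                                update = update, max_indegree = max_indegree,
                                stg_cap = stg_cap)
    for (r in seq_len(nrow(sel))) {
      witnesses[[length(witnesses) + 1L]] <- list(s = sel$fixed[[r]],
                                                  mode = "via_trap")
    }
  }
  if (length(witnesses) == 0L) return(empty_result)
  # largest subspace (fewest fixed variables) first, ties by rendering
  ord <- order(vapply(witnesses, function(w) length(w$s), 1L),
               vapply(witnesses, function(w) format_subspace(rnet, w$s), ""))
  witnesses <- witnesses[ord]

  # ---- candidate pool ----
  per_witness <- lapply(witnesses, function(w) {
    candidate_interventions(rnet, w$s, kind = kind, mode = w$mode,
                            avoid_nodes = avoid_nodes,
                            avoid_edges = avoid_edges, reduction = reduction)
  })
  pool <- unique(do.call(rbind, per_witness))
  ordp <- order(match(pool$type, c("node", "edge")),
                match(pool$target, rnet$variables),
                match(pool$source, rnet$variables), pool$value)
  pool <- pool[ordp, , drop = FALSE]
  pool_key <- paste(pool$type, pool$source, pool$target, pool$value)
  member <- lapply(per_witness, function(cw) {
    pool_key %in% paste(cw$type, cw$source, cw$target, cw$value)
  })
  conflict <- candidate_conflicts(pool)

  accepted <- list()   # list of integer row sets (into pool)
  results <- empty_result

  try_subset <- function(rows) {
    if (any(vapply(accepted, function(a) all(a %in% rows), TRUE))) {
      return(invisible(NULL))  # superset of an accepted strategy
    }
    C <- candidate_row_to_set(pool, rows)
    fp <- NULL
    for (wi in seq_along(witnesses)) {
      if (!all(member[[wi]][rows])) next
      w <- witnesses[[wi]]
      if (is.null(fp)) {
        ctrl <- apply_interventions(rnet, C, warn_inessential = FALSE)
        fp <- percolate(ctrl, check_trap = FALSE, max_indegree = max_indegree)
      }
      if (subspace_contained(fp, w$s)) {
        accepted[[length(accepted) + 1L]] <<- rows
        results <<- rbind(results, tibble::tibble(
          strategy = format(C),
          size = intervention_size(C),
          method = if (w$mode == "direct") "direct" else "via_trap_space",
          witness = full_string(w$s),
          fixpoint = full_string(fp),
          interventions = list(C)))
        return(invisible(NULL))
      }
    }
  }

  k <- nrow(pool)
  try_subset(integer(0))
  if (k > 0L) {
    for (size in seq_len(min(max_size, k))) {
      for (rows in utils::combn(k, size, simplify = FALSE)) {
        if (size > 1L) {
          pairs <- utils::combn(rows, 2L)
          if (any(conflict[t(pairs)])) next
        }
        try_subset(rows)
      }
    }
  }
  results[order(results$size, results$strategy), , drop = FALSE]
}

#' Ground-truth check of a control strategy
#'
#' Verifies the defining property directly: all attractors (terminal
#' strongly connected components) of the controlled network's state
#' transition graph lie inside the target subspace. Exponential in the
#' number of variables; meant as the oracle on small networks.
#'
#' @inheritParams control_strategies
#' @param C an `intervention_set`
#' @param cap variable cap for the state transition graph
#' @return logical flag
#' @export
verify_strategy <- function(net, C, target,
                            update = c("async", "sync", "general"),
                            cap = 20L) {
  update <- match.arg(update)
  target <- subspace(net, target)
  ctrl <- apply_interventions(net, C, warn_inessential = FALSE)
  att <- attractors(ctrl, update, cap = cap)
  state_ok <- function(st) {
    x <- setNames(as.integer(strsplit(st, "")[[1L]]), net$variables)
    all(x[names(target)] == target)
  }
  all(vapply(unlist(att$states), state_ok, TRUE))
}
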