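# Control strategy search: candidates, satisfaction tests, and enumeration of
# all inclusion-minimal strategies up to a size limit.

normalize_avoid_edges <- function(avoid_edges) {
  if (is.null(avoid_edges)) return(new_edges_df()[, c("source", "target")])
  if (is.character(avoid_edges)) {
    parts <- regmatches(avoid_edges, regexec("^(.+)->(.+)$", trimws(avoid_edges)))
    bad <- vapply(parts, length, 1L) != 3L
    if (any(bad)) {
      stop("cannot parse avoided edge '", avoid_edges[bad][[1L]],
           "' (expected \"src->tgt\")", call. = FALSE)
    }
    return(data.frame(source = trimws(vapply(parts, `[[`, "", 2L)),
                      target = trimws(vapply(parts, `[[`, "", 3L)),
                      stringsAsFactors = FALSE))
  }
  data.frame(source = as.character(avoid_edges$source),
             target = as.character(avoid_edges$target),
             stringsAsFactors = FALSE)
}

#' Candidate interventions for one control witness
#'
#' For control via a trap space the candidates are restricted by the
#' targeting condition: node candidates are exactly the witness-fixed
#' variables at their witness values, edge candidates fix a syntactic
#' regulator (either value) inside the function of a witness-fixed variable.
#' For direct percolation all nodes (both values) and all syntactic edges
#' (both values) are candidates; node candidates are optionally pruned by
#' the signed-path reduction: `(i, c)` is kept when a positive walk leads
#' from `i` to a witness variable fixed at `c`, or a negative walk to one
#' fixed at `1 - c` (the length-0 walk counts, so witness variables are
#' their own candidates). The reduction only prunes; disabling it never
#' changes the strategies found.
#'
#' @param net a `boolean_network`
#' @param witness the subspace to percolate into (target or selected trap
#'   space)
#' @param kind `"node"`, `"edge"` or `"both"`
#' @param mode `"direct"` or `"via_trap"`
#' @param avoid_nodes variables excluded from node intervention
#' @param avoid_edges edges excluded from edge intervention (data frame with
#'   `source`,`target` or `"src->tgt"` strings)
#' @param reduction apply the signed-path reduction to direct node candidates
#' @return tibble with columns `type` (`"node"`/`"edge"`), `source` (`NA`
#'   for nodes), `target`, `value`
#' @export
candidate_interventions <- function(net, witness,
                                    kind = c("both", "node", "edge"),
                                    mode = c("via_trap", "direct"),
                                    avoid_nodes = character(0),
                                    avoid_edges = NULL,
                                    reduction = TRUE) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  witness <- subspace(net, witness)
  avoid_e <- normalize_avoid_edges(avoid_edges)
  out <- tibble::tibble(type = character(0), source = character(0),
                        target = character(0), value = integer(0))

  if (kind %in% c("node", "both")) {
    if (mode == "via_trap") {
      vars <- setdiff(names(witness), avoid_nodes)
      out <- rbind(out, tibble::tibble(type = "node", source = NA_character_,
                                       target = vars,
                                       value = as.integer(witness[vars])))
    } else {
      vars <- setdiff(net$variables, avoid_nodes)
      grid <- expand.grid(target = vars, value = 0:1, stringsAsFactors = FALSE)
      if (reduction && nrow(grid) > 0L) {
        reach <- signed_reachability(interaction_graph(net), net$variables)
        ok <- vapply(seq_len(nrow(grid)), function(r) {
          i <- grid$target[[r]]; cc <- grid$value[[r]]
          any(vapply(names(witness), function(v) {
            (reach$pos[i, v] && witness[[v]] == cc) ||
              (reach$neg[i, v] && witness[[v]] == 1L - cc)
          }, TRUE))
        }, TRUE)
        grid <- grid[ok, , drop = FALSE]
      }
      out <- rbind(out, tibble::tibble(type = "node", source = NA_character_,
                                       target = grid$target,
                                       value = as.integer(grid$value)))
    }
  }

  if (kind %in% c("edge", "both")) {
    targets <- if (mode == "via_trap") names(witness) else net$variables
    for (j in targets) {
      regs <- dnf_regulators(net$functions[[j]])
      for (i in regs) {
        if (any(avoid_e$source == i & avoid_e$target == j)) next
        out <- rbind(out, tibble::tibble(type = "edge", source = i, target = j,
                                         value = c(0L, 1L)))
      }
    }
  }

  ord <- order(match(out$type, c("node", "edge")),
               match(out$target, net$variables),
               match(out$source, net$variables),
               out$value)
  out[ord, , drop = FALSE]
}

candidate_row_to_set <- function(cands, rows) {
  sel <- cands[rows, , drop = FALSE]
  nd <- sel[sel$type == "node", , drop = FALSE]
  ed <- sel[sel$type == "edge", , drop = FALSE]
  intervention_set(
    nodes = new_nodes_df(nd$target, nd$value),
    edges = new_edges_df(ed$source, ed$target, ed$value)
  )
}

# Pairwise compatibility of candidate rows under conditions (i)-(iii); a
# subset is consistent iff all its pairs are.
candidate_conflicts <- function(cands) {
  k <- nrow(cands)
  conflict <- matrix(FALSE, k, k)
  if (k < 2L) return(conflict)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      ta <- cands$type[[a]]; tb <- cands$type[[b]]
      bad <-
        if (ta == "node" && tb == "node") {
          cands$target[[a]] == cands$target[[b]] &&
            cands$value[[a]] != cands$value[[b]]
        } else if (ta == "edge" && tb == "edge") {
          cands$source[[a]] == cands$source[[b]] &&
            cands$target[[a]] == cands$target[[b]] &&
            cands$value[[a]] != cands$value[[b]]
        } else {
          nd <- if (ta == "node") a else b
          eg <- if (ta == "node") b else a
          cands$target[[nd]] == cands$target[[eg]] ||   # (i)
            cands$target[[nd]] == cands$source[[eg]]    # (ii)
        }
      conflict[a, b] <- conflict[b, a] <- bad
    }
  }
  conflict
}

#' Consistent combinations of candidate interventions
#'
#' All subsets of a candidate list (including the empty one) that form a
#' consistent intervention set under conditions (i)-(iii).
#'
#' @param candidates tibble from [candidate_interventions()]
#' @param max_size largest subset size to enumerate
#' @return list of integer row-index vectors into `candidates`; the first
#'   element is the empty combination.
#' @export
consistent_combinations <- function(candidates, max_size = Inf) {
  k <- nrow(candidates)
  conflict <- candidate_conflicts(candidates)
  out <- list(integer(0))
  grow <- function(chosen, start) {
    if (length(chosen) >= max_size || start > k) return(invisible(NULL))
    for (i in start:k) {
      if (length(chosen) > 0L && any(conflict[chosen, i])) next
      nxt <- c(chosen, i)
      out[[length(out) + 1L]] <<- nxt
      grow(nxt, i + 1L)
    }
  }
  if (max_size >= 1L && k >= 1L) grow(integer(0), 1L)
  out
}

#' Count of consistent candidate combinations
#'
#' The number of consistent subsets of a candidate list, counting the empty
#' combination.
#'
#' @inheritParams consistent_combinations
#' @return integer count
#' @export
count_consistent_combinations <- function(candidates, max_size = Inf) {
  length(consistent_combinations(candidates, max_size))
}

#' Does an intervention set percolate into a witness subspace?
#'
#' Computes the percolation fixpoint of the full state space under the
#' controlled network and checks that every witness-fixed variable is fixed
#' there at the witness value (the fixpoint may fix more). For control via a
#' trap space, the targeting condition is also required: every node
#' intervention and every edge intervention's target function must belong to
#' the witness-fixed variables.
#'
#' @param net a `boolean_network`
#' @param C a consistent `intervention_set`
#' @param witness subspace to percolate into
#' @param mode `"direct"` or `"via_trap"`
#' @param max_indegree enumeration cap for constancy checks
#' @return logical flag; the attribute `"fixpoint"` carries the fixpoint
#'   subspace.
#' @export
percolation_satisfies <- function(net, C, witness,
                                  mode = c("direct", "via_trap"),
                                  max_indegree = 16L) {
  mode <- match.arg(mode)
  witness <- subspace(net, witness)
  if (mode == "via_trap") {
    if (!all(C$nodes$var %in% names(witness)) ||
        !all(C$edges$target %in% names(witness))) {
      return(structure(FALSE, fixpoint = NULL))
    }
  }
  ctrl <- apply_interventions(net, C, warn_inessential = FALSE)
  fp <- percolate(ctrl, check_trap = FALSE, max_indegree = max_indegree)
  ok <- subspace_contained(fp, witness)
  structure(ok, fixpoint = fp)
}
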