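# JSON/CSV serialization of interventions, strategies and attractors.

#' Intervention set as plain lists (for JSON)
#'
#' Shape: `{"node": {"var": "x3", "value": 0}}` and
#' `{"edge": {"source": "x2", "target": "x1", "value": 1}}`.
#' @param C an `intervention_set`
#' @return unnamed list of single-entry lists
#' @export
interventions_to_list <- function(C) {
  out <- list()
  for (r in seq_len(nrow(C$nodes))) {
    out[[length(out) + 1L]] <- list(node = list(var = C$nodes$var[[r]],
                                                value = C$nodes$value[[r]]))
  }
  for (r in seq_len(nrow(C$edges))) {
    out[[length(out) + 1L]] <- list(edge = list(source = C$edges$source[[r]],
                                                target = C$edges$target[[r]],
                                                value = C$edges$value[[r]]))
  }
  out
}

interventions_from_list <- function(lst) {
  nd <- new_nodes_df(); ed <- new_edges_df()
  for (item in lst) {
    if (!is.null(item$node)) {
      nd[nrow(nd) + 1L, ] <- list(item$node$var, as.integer(item$node$value))
    } else if (!is.null(item$edge)) {
      ed[nrow(ed) + 1L, ] <- list(item$edge$source, item$edge$target,
                                  as.integer(item$edge$value))
    } else {
      stop("intervention entry is neither node nor edge", call. = FALSE)
    }
  }
  intervention_set(nodes = nd, edges = ed)
}

#' Write control strategies to JSON
#'
#' @param strategies tibble from [control_strategies()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_strategies_json <- function(strategies, path) {
  lst <- lapply(seq_len(nrow(strategies)), function(r) {
    list(interventions = interventions_to_list(strategies$interventions[[r]]),
         method = strategies$method[[r]],
         witness = strategies$witness[[r]],
         fixpoint = strategies$fixpoint[[r]])
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read control strategies back from JSON
#'
#' @param path file written by [write_strategies_json()] (or hand-written in
#'   the same shape; `method`/`witness`/`fixpoint` are optional there)
#' @return tibble with columns `strategy`, `size`, `method`, `witness`,
#'   `fixpoint`, `interventions`
#' @export
read_strategies_json <- function(path) {
  lst <- jsonlite::read_json(path)
  sets <- lapply(lst, function(item) interventions_from_list(item$interventions))
  tibble::tibble(
    strategy = vapply(sets, format, ""),
    size = vapply(sets, intervention_size, 1L),
    method = vapply(lst, function(x) x$method %||% NA_character_, ""),
    witness = vapply(lst, function(x) x$witness %||% NA_character_, ""),
    fixpoint = vapply(lst, function(x) x$fixpoint %||% NA_character_, ""),
    interventions = sets
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write control strategies to CSV (one intervention set per row)
#'
#' @inheritParams write_strategies_json
#' @return `path`, invisibly
#' @export
write_strategies_csv <- function(strategies, path) {
  df <- data.frame(strategy = strategies$strategy, size = strategies$size,
                   method = strategies$method, witness = strategies$witness,
                   fixpoint = strategies$fixpoint, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an attractor list from JSON
#'
#' Accepts a JSON array of state strings or subspace strings (e.g. `"110"`,
#' `"1*0"`).
#' @param net a `boolean_network`
#' @param path JSON file
#' @return list of subspaces usable as `attractor_source`
#' @export
read_attractors_json <- function(net, path) {
  lst <- jsonlite::read_json(path)
  lapply(lst, function(s) parse_subspace(net, as.character(s)))
}
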