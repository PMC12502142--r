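# Trap spaces: enumeration, minimality, percolation status, and selection of
# trap spaces containing only attractors inside a target.

#' Is a subspace a trap space?
#'
#' A subspace is closed with respect to the dynamics (any of the three update
#' schemes, trap spaces are update-independent) exactly when every fixed
#' variable's function restricted to the subspace is constant at the fixed
#' value.
#'
#' @inheritParams constancy
#' @param s a subspace
#' @return logical flag
#' @export
is_trap_space <- function(net, s = character(0), max_indegree = 16L) {
  for (v in names(s)) {
    cv <- constancy(net, v, s, max_indegree = max_indegree)
    if (is.na(cv) || cv != s[[v]]) return(FALSE)
  }
  TRUE
}

# Exact enumeration by depth-first branching over (free, 0, 1) per variable
# with constancy-based pruning: once a fixed variable's restricted function is
# constant at the wrong value it stays so on every smaller subspace, so the
# branch is dead.
trap_spaces_list <- function(net, max_indegree = 16L, max_count = Inf) {
  n <- length(net$variables)
  found <- list()
  empty <- setNames(integer(0), character(0))
  dfs <- function(idx, fixed) {
    all_constant_right <- TRUE
    for (v in names(fixed)) {
      cv <- constancy(net, v, fixed, max_indegree = max_indegree)
      if (!is.na(cv) && cv != fixed[[v]]) return(invisible(NULL))
      # constant at the wrong value stays wrong on every smaller subspace:
      # prune; a still-free function may yet become constant, so defer
      if (is.na(cv)) all_constant_right <- FALSE
    }
    if (idx > n) {
      if (all_constant_right) {
        found[[length(found) + 1L]] <<- fixed
        if (length(found) > max_count) {
          stop("trap space enumeration exceeded the output cap (more than ",
               max_count, " found)", call. = FALSE)
        }
      }
      return(invisible(NULL))
    }
    v <- net$variables[[idx]]
    dfs(idx + 1L, fixed)
    dfs(idx + 1L, c(fixed, setNames(0L, v)))
    dfs(idx + 1L, c(fixed, setNames(1L, v)))
  }
  dfs(1L, empty)
  found <- lapply(found, function(s) s[intersect(net$variables, names(s))])
  ord <- order(vapply(found, length, 1L),
               vapply(found, format_subspace, "", net = net))
  found[ord]
}

trap_list_to_tibble <- function(net, lst) {
  tibble::tibble(
    subspace = vapply(lst, format_subspace, "", net = net),
    size = vapply(lst, length, 1L),
    fixed = lst
  )
}

#' All trap spaces of a network
#'
#' Complete, exact enumeration (the full state space is itself always a trap
#' space and is included). Uses a depth-first branch-and-propagate search
#' over partial assignments with exact constancy pruning; identical to the
#' `3^n` brute force on small networks.
#'
#' @inheritParams constancy
#' @param max_count abort (with an error reporting the count) when more trap
#'   spaces than this are found
#' @return tibble with columns `subspace` (0/1/* string), `size` (number of
#'   fixed variables) and `fixed` (list of named 0/1 vectors), ordered by
#'   size then rendering.
#' @export
trap_spaces <- function(net, max_indegree = 16L, max_count = Inf) {
  trap_list_to_tibble(net, trap_spaces_list(net, max_indegree, max_count))
}

minimal_of <- function(net, lst) {
  keep <- vapply(seq_along(lst), function(i) {
    !any(vapply(seq_along(lst), function(j) {
      i != j && subspace_contained(lst[[j]], lst[[i]]) &&
        !subspace_equal(lst[[j]], lst[[i]])
    }, TRUE))
  }, TRUE)
  lst[keep]
}

#' Inclusion-minimal trap spaces
#'
#' The minimal trap spaces form an antichain; every trap space contains at
#' least one of them. They are often good approximations of the attractors
#' (see [mts_approximation_check()]).
#'
#' @inheritParams trap_spaces
#' @return tibble in the shape of [trap_spaces()]
#' @export
minimal_trap_spaces <- function(net, max_indegree = 16L, max_count = Inf) {
  lst <- minimal_of(net, trap_spaces_list(net, max_indegree, max_count))
  trap_list_to_tibble(net, lst)
}

#' Non-percolating trap spaces
#'
#' Trap spaces that are fixpoints of the percolation function. Any subspace
#' percolating into a trap space `T` also percolates into `F(f)(T)`, so only
#' these are useful control witnesses. Every minimal trap space is
#' non-percolating.
#'
#' @inheritParams trap_spaces
#' @return tibble in the shape of [trap_spaces()]
#' @export
non_percolating_trap_spaces <- function(net, max_indegree = 16L, max_count = Inf) {
  lst <- trap_spaces_list(net, max_indegree, max_count)
  keep <- vapply(lst, function(s) {
    subspace_equal(percolation_step(net, s, max_indegree), s)
  }, TRUE)
  trap_list_to_tibble(net, lst[keep])
}

# Normalize the many accepted forms of attractor knowledge into one of:
#   list(kind = "none")
#   list(kind = "mts")
#   list(kind = "explicit", attractors = list of subspaces (named 0/1 vectors))
resolve_attractor_source <- function(net, attractor_source, update, stg_cap) {
  if (is.null(attractor_source)) return(list(kind = "none"))
  if (is.character(attractor_source) && length(attractor_source) == 1L &&
      attractor_source %in% c("none", "mts", "stg")) {
    if (attractor_source == "none") return(list(kind = "none"))
    if (attractor_source == "mts") return(list(kind = "mts"))
    att <- attractors(net, update, cap = stg_cap)
    hulls <- lapply(att$states, function(sts) attractor_hull(net, sts))
    return(list(kind = "explicit", attractors = hulls))
  }
  if (is.data.frame(attractor_source) && "states" %in% names(attractor_source)) {
    hulls <- lapply(attractor_source$states, function(sts) attractor_hull(net, sts))
    return(list(kind = "explicit", attractors = hulls))
  }
  if (is.character(attractor_source)) {
    hulls <- lapply(attractor_source, function(s) parse_subspace(net, s))
    return(list(kind = "explicit", attractors = hulls))
  }
  if (is.list(attractor_source)) {
    hulls <- lapply(attractor_source, function(a) {
      if (is.character(a)) attractor_hull(net, a) else subspace(net, a)
    })
    return(list(kind = "explicit", attractors = hulls))
  }
  stop("cannot interpret attractor_source", call. = FALSE)
}

# Smallest subspace containing a set of state strings.
attractor_hull <- function(net, state_strings) {
  m <- do.call(rbind, lapply(state_strings, function(s) {
    as.integer(strsplit(s, "")[[1L]])
  }))
  colnames(m) <- net$variables
  const <- vapply(net$variables, function(v) length(unique(m[, v])) == 1L, TRUE)
  setNames(m[1L, const], net$variables[const])
}

#' Selected trap spaces for a target
#'
#' Among the non-percolating trap spaces, selects those containing only
#' attractors that lie inside the target subspace `target`. Two types are
#' distinguished: Type 1 trap spaces are contained in the target (no
#' attractor knowledge needed); Type 2 trap spaces are not contained in the
#' target but all attractors inside them are. Type 2 selection needs
#' attractor knowledge: an explicit attractor list, the state transition
#' graph, or the declared approximation of attractors by minimal trap spaces
#' (under which "every attractor in `T` lies in `target`" is decided as
#' `m` contained in `target` for every minimal trap space `m` inside `T`).
#' Without it, Type 2 is skipped with a warning.
#'
#' @inheritParams trap_spaces
#' @param target a subspace (named 0/1 vector or string)
#' @param attractor_source one of `NULL`/`"none"` (Type 1 only), `"mts"`
#'   (assume the minimal-trap-space approximation), `"stg"` (compute
#'   attractors from the state transition graph), a tibble from
#'   [attractors()], or a list/character vector of attractors given as state
#'   or subspace strings.
#' @param update update scheme used when `attractor_source = "stg"`
#' @param stg_cap variable cap for the state transition graph
#' @return tibble with columns `subspace`, `size`, `fixed`, `minimal`,
#'   `selected_type` (`"type1"`/`"type2"`), ordered by size descending then
#'   rendering.
#' @export
selected_trap_spaces <- function(net, target, attractor_source = NULL,
                                 update = "async", max_indegree = 16L,
                                 max_count = Inf, stg_cap = 20L) {
  target <- subspace(net, target)
  src <- resolve_attractor_source(net, attractor_source, update, stg_cap)
  lst <- trap_spaces_list(net, max_indegree, max_count)
  nonperc <- lst[vapply(lst, function(s) {
    subspace_equal(percolation_step(net, s, max_indegree), s)
  }, TRUE)]
  minimal <- minimal_of(net, lst)
  is_minimal <- function(s) {
    any(vapply(minimal, subspace_equal, TRUE, s))
  }

  type_of <- function(s) {
    if (subspace_contained(s, target)) return("type1")
    if (src$kind == "none") return(NA_character_)
    if (src$kind == "mts") {
      inside <- Filter(function(m) subspace_contained(m, s), minimal)
      if (length(inside) > 0L &&
          all(vapply(inside, subspace_contained, TRUE, b = target))) {
        return("type2")
      }
      return(NA_character_)
    }
    inside <- Filter(function(a) subspace_contained(a, s), src$attractors)
    if (length(inside) > 0L &&
        all(vapply(inside, subspace_contained, TRUE, b = target))) {
      return("type2")
    }
    NA_character_
  }

  types <- vapply(nonperc, type_of, "")
  if (src$kind == "none" && any(!subspace_contained_all(nonperc, target))) {
    warning("no attractor source: Type 2 selected trap spaces skipped",
            call. = FALSE)
  }
  keep <- !is.na(types)
  sel <- nonperc[keep]
  out <- trap_list_to_tibble(net, sel)
  out$minimal <- vapply(sel, is_minimal, TRUE)
  out$selected_type <- types[keep]
  out[order(-out$size, out$subspace), , drop = FALSE]
}

subspace_contained_all <- function(lst, target) {
  vapply(lst, subspace_contained, TRUE, b = target)
}

#' Can attractors be approximated by the minimal trap spaces?
#'
#' Checks, against the explicit state transition graph, that each minimal
#' trap space contains exactly one attractor and that every attractor lies
#' inside a minimal trap space. When this holds, Type 2 selected trap spaces
#' can be identified without computing attractors on the controlled models.
#'
#' @inheritParams trap_spaces
#' @param update update scheme for the attractor computation
#' @param cap variable cap for the state transition graph
#' @return logical flag
#' @export
mts_approximation_check <- function(net, update = c("async", "sync", "general"),
                                    cap = 20L, max_indegree = 16L) {
  update <- match.arg(update)
  att <- attractors(net, update, cap = cap)
  mts <- trap_spaces_list(net, max_indegree)
  mts <- minimal_of(net, mts)
  state_in <- function(st, s) {
    x <- setNames(as.integer(strsplit(st, "")[[1L]]), net$variables)
    all(x[names(s)] == s)
  }
  att_in_mts <- function(sts, m) all(vapply(sts, state_in, TRUE, s = m))
  counts <- vapply(mts, function(m) {
    sum(vapply(att$states, att_in_mts, TRUE, m = m))
  }, 1L)
  covered <- vapply(att$states, function(sts) {
    any(vapply(mts, function(m) att_in_mts(sts, m), TRUE))
  }, TRUE)
  all(counts == 1L) && all(covered)
}
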