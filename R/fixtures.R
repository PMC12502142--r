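# Built-in example networks and a reproducible random-network generator.

#' Small example networks
#'
#' Four hand-sized networks exercising every feature of the package:
#'
#' * `bistable3` — 3 nodes, two steady states `110` and `101`; its trap
#'   space `**0` is a selected trap space for the target `110`, giving a
#'   one-intervention strategy that direct percolation misses.
#' * `edge_only3` — 3 nodes; with node interventions on the target-fixed
#'   variables forbidden, only the edge pair `x2->x1=1`, `x2->x3=0` controls
#'   the target `1*0`.
#' * `cascade3` — 3 nodes; clamping `x1=1` percolates the whole state space
#'   directly to the steady state `110`.
#' * `trapselect4` — 4 nodes, attractors `0010` and `1101`; for the target
#'   `00**` the selected trap spaces are `**10` and the steady state `0010`.
#'
#' @return named list of `boolean_network` objects
#' @export
example_networks <- function() {
  list(
    bistable3 = read_bnet(c(
      "x1, x2 | x3",
      "x2, x2 & !x3 | !x1 & !x3",
      "x3, x2 & x3 | x1 & x3"
    )),
    edge_only3 = read_bnet(c(
      "x1, x2 | x3",
      "x2, x1 & x2",
      "x3, x1 & x2 & x3"
    )),
    cascade3 = read_bnet(c(
      "x1, x2 | x1 & !x3",
      "x2, x1",
      "x3, !x1 & x3"
    )),
    trapselect4 = read_bnet(c(
      "x1, x2 & !x4 | x1 & x4 | x1 & x2",
      "x2, !x1 & x2 & !x4 | x1 & x4",
      "x3, x3 | !x4 | !x2 | !x1",
      "x4, !x4 & !x3 | !x2 & !x3 | x1 & !x3"
    ))
  )
}

#' Random Boolean network
#'
#' Each variable receives a random set of regulators (in-degree drawn
#' uniformly from `1..max_indegree`) and a random non-constant truth table
#' over them, written as the DNF of its minterms. Every function is
#' non-constant by construction, so the network is constant-free. Fully
#' reproducible for a fixed seed; the caller's RNG state is left untouched.
#'
#' @param n number of variables
#' @param max_indegree largest number of regulators per function (>= 1)
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#' @param clause_bias probability of output 1 in each truth-table row
#' @return a `boolean_network` with variables `x1..xn`
#' @export
random_network <- function(n, max_indegree = 3L, seed = NULL,
                           clause_bias = 0.5) {
  stopifnot(n >= 1L)
  if (max_indegree < 1L || max_indegree > n) {
    stop("max_indegree must be between 1 and n", call. = FALSE)
  }
  if (clause_bias <= 0 || clause_bias >= 1) {
    stop("clause_bias must be strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  vars <- paste0("x", seq_len(n))
  funs <- lapply(vars, function(v) {
    k <- sample.int(max_indegree, 1L)
    regs <- sample(vars, k)
    repeat {
      tt <- stats::rbinom(2L^k, 1L, clause_bias)
      if (length(unique(tt)) > 1L) break
    }
    m <- all_states_matrix(regs)
    lapply(which(tt == 1L), function(r) {
      setNames(ifelse(m[r, ] == 1L, 1L, -1L), regs)
    })
  })
  boolean_network(vars, setNames(funs, vars))
}
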