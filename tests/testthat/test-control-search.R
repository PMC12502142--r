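test_that("candidate generation respects the trap-space targeting condition", {
  f1 <- ex$bistable3
  w <- subspace(f1, "**0")
  cn <- candidate_interventions(f1, w, kind = "node", mode = "via_trap")
  expect_equal(nrow(cn), 1L)
  expect_equal(cn$target, "x3")
  expect_equal(cn$value, 0L)
  expect_equal(count_consistent_combinations(cn), 2L)

  ce <- candidate_interventions(f1, w, kind = "edge", mode = "via_trap")
  expect_equal(nrow(ce), 6L)             # 3 syntactic regulators of x3, 2 values
  expect_true(all(ce$target == "x3"))
  expect_equal(count_consistent_combinations(ce), 27L)

  cb <- candidate_interventions(f1, w, kind = "both", mode = "via_trap")
  expect_equal(count_consistent_combinations(cb), 28L)

  # avoiding every witness-fixed variable empties the candidate set
  c0 <- candidate_interventions(f1, w, kind = "node", mode = "via_trap",
                                avoid_nodes = "x3")
  expect_equal(nrow(c0), 0L)

  # direct mode with the signed-path reduction keeps the published pair
  cd <- candidate_interventions(f1, subspace(f1, "110"), kind = "node",
                                mode = "direct")
  expect_true(all(c("x2 1", "x3 0") %in% paste(cd$target, cd$value)))
})

test_that("percolation satisfaction distinguishes direct and trap witnesses", {
  f1 <- ex$bistable3
  f3 <- ex$cascade3
  N3 <- intervention_set(c(x3 = 0))
  expect_true(percolation_satisfies(f3, intervention_set(c(x1 = 1)),
                                    subspace(f3, "110"), mode = "direct"))
  expect_false(percolation_satisfies(f1, N3, subspace(f1, "110"),
                                     mode = "direct"))
  ok <- percolation_satisfies(f1, N3, subspace(f1, "**0"), mode = "via_trap")
  expect_true(ok)
  expect_equal(format_subspace(f1, attr(ok, "fixpoint")), "**0")
  # targeting condition: intervention outside the witness-fixed variables
  expect_false(percolation_satisfies(f1, intervention_set(c(x1 = 1)),
                                     subspace(f1, "**0"), mode = "via_trap"))
})

test_that("search reproduces the published minimal strategies", {
  f1 <- ex$bistable3
  comb <- control_strategies(f1, "110", method = "combined", kind = "node",
                             max_size = 2, attractor_source = "stg")
  expect_equal(comb$strategy, "x3=0")
  expect_equal(comb$method, "via_trap_space")
  expect_equal(comb$witness, "**0")

  direct <- control_strategies(f1, "110", method = "direct", kind = "node",
                               max_size = 2)
  expect_equal(direct$strategy, "x2=1,x3=0")
  expect_equal(direct$fixpoint, "110")

  # edge-only control of the second example when target nodes are off-limits
  edge <- control_strategies(ex$edge_only3, "1*0", method = "direct",
                             kind = "edge", max_size = 2,
                             forbid_target_nodes = TRUE)
  expect_true("x2->x1=1,x2->x3=0" %in% edge$strategy)

  # trap-space route on the 4-node example: published size-1 strategies
  trap <- control_strategies(ex$trapselect4, "00**", method = "trapspaces",
                             kind = "node", max_size = 1,
                             attractor_source = "stg")
  expect_true(all(c("x4=0", "x3=1") %in% trap$strategy))
  expect_true(all(trap$method == "via_trap_space"))
  for (r in seq_len(nrow(trap))) {
    expect_true(verify_strategy(ex$trapselect4, trap$interventions[[r]], "00**"))
  }
})

test_that("the ground-truth oracle validates and refutes known strategies", {
  expect_true(verify_strategy(ex$bistable3, intervention_set(c(x3 = 0)), "110"))
  expect_false(verify_strategy(ex$edge_only3, intervention_set(c(x2 = 0)), "1*0"))
  expect_true(verify_strategy(ex$bistable3, intervention_set(), character(0)))
})

test_that("every returned strategy is sound, minimal and deterministic", {
  for (net in random_suite(25L, n_min = 4L, n_max = 6L, seed_base = 1000L)) {
    tgt <- stats::setNames(c(1L, 0L), net$variables[1:2])
    res <- control_strategies(net, tgt, method = "combined", kind = "node",
                              max_size = 2, attractor_source = "stg")
    # soundness: the Definition-1 oracle accepts everything returned
    for (r in seq_len(nrow(res))) {
      expect_true(verify_strategy(net, res$interventions[[r]], tgt),
                  info = paste(format_subspace(net, tgt), res$strategy[[r]]))
    }
    # antichain
    sets <- lapply(res$interventions, function(C) {
      stats::setNames(C$nodes$value, C$nodes$var)
    })
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b) {
        expect_false(all(names(sets[[a]]) %in% names(sets[[b]])) &&
                       all(sets[[b]][names(sets[[a]])] == sets[[a]]))
      }
    }
    # determinism
    res2 <- control_strategies(net, tgt, method = "combined", kind = "node",
                               max_size = 2, attractor_source = "stg")
    expect_identical(res$strategy, res2$strategy)
  }
})

test_that("trap-space strategies never introduce new attractors", {
  for (net in random_suite(15L, n_min = 4L, n_max = 6L, seed_base = 1100L)) {
    tgt <- stats::setNames(1L, net$variables[[1L]])
    res <- control_strategies(net, tgt, method = "trapspaces", kind = "node",
                              max_size = 2, attractor_source = "stg")
    orig <- oracle_attractors(net, "async")
    orig_keys <- vapply(orig, paste, "", collapse = ",")
    for (r in seq_len(nrow(res))) {
      ctrl <- apply_interventions(net, res$interventions[[r]])
      got <- vapply(oracle_attractors(ctrl, "async"), paste, "", collapse = ",")
      expect_true(all(got %in% orig_keys), info = res$strategy[[r]])
    }
  }
})

test_that("the signed-path reduction never changes the result", {
  for (net in random_suite(15L, n_min = 4L, n_max = 6L, seed_base = 1200L)) {
    tgt <- stats::setNames(c(1L, 0L), net$variables[1:2])
    with_red <- control_strategies(net, tgt, method = "direct", kind = "node",
                                   max_size = 2, reduction = TRUE)
    without <- control_strategies(net, tgt, method = "direct", kind = "node",
                                  max_size = 2, reduction = FALSE)
    expect_identical(with_red$strategy, without$strategy)
  }
  # and combined output is the minimal antichain of the per-method union
  for (net in random_suite(8L, n_min = 4L, n_max = 5L, seed_base = 1300L)) {
    tgt <- stats::setNames(1L, net$variables[[1L]])
    comb <- control_strategies(net, tgt, method = "combined", kind = "node",
                               max_size = 2, attractor_source = "stg")
    dir <- control_strategies(net, tgt, method = "direct", kind = "node",
                              max_size = 2)
    trap <- control_strategies(net, tgt, method = "trapspaces", kind = "node",
                               max_size = 2, attractor_source = "stg")
    expect_true(all(comb$strategy %in% c(dir$strategy, trap$strategy)))
    # nothing in the union is strictly below a combined result
    union_sets <- lapply(c(dir$interventions, trap$interventions), function(C) {
      stats::setNames(C$nodes$value, C$nodes$var)
    })
    comb_sets <- lapply(comb$interventions, function(C) {
      stats::setNames(C$nodes$value, C$nodes$var)
    })
    for (cs in comb_sets) for (us in union_sets) {
      strictly_below <- length(us) < length(cs) &&
        all(names(us) %in% names(cs)) && all(cs[names(us)] == us)
      expect_false(strictly_below)
    }
  }
})

test_that("degenerate problems behave as specified", {
  f1 <- ex$bistable3
  # k = 0 with a nonempty target: nothing percolates, empty result
  res <- control_strategies(f1, "110", method = "direct", kind = "node",
                            max_size = 0)
  expect_equal(nrow(res), 0L)
  # empty strategy is the unique minimal one when B^n already percolates
  collapsing <- read_bnet(c("a, 1", "b, a"))
  res2 <- control_strategies(collapsing, c(b = 1), method = "direct",
                             kind = "node", max_size = 2)
  expect_equal(res2$strategy, "{}")
  expect_equal(res2$size, 0L)
  # target conflicting with a percolated constant yields a warning and no result
  expect_warning(
    res3 <- control_strategies(collapsing, c(b = 0), method = "direct",
                               kind = "node", max_size = 1),
    "conflict")
  expect_equal(nrow(res3), 0L)
})
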