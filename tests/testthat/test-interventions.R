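test_that("consistency conditions (i)-(iii) are enforced", {
  # (i) edge intervention may not target a node-clamped function
  expect_false(is_consistent(intervention_set(c(x2 = 1), "x1->x2=0")))
  # (ii) no double clamp; clamped component never an edge source
  expect_false(is_consistent(intervention_set(
    nodes = data.frame(var = c("x1", "x1"), value = c(1L, 0L)))))
  expect_false(is_consistent(intervention_set(c(x1 = 1), "x1->x3=0")))
  # (iii) same edge, both values
  expect_false(is_consistent(intervention_set(edges = c("x1->x2=1", "x1->x2=0"))))
  # the published edge pair is consistent
  expect_true(is_consistent(intervention_set(edges = c("x2->x1=1", "x2->x3=0"))))
  expect_true(is_consistent(intervention_set()))
})

test_that("the context fixes exactly the inputs acting on each function", {
  C <- intervention_set(edges = c("x2->x1=1", "x2->x3=0"))
  expect_equal(intervention_context(C, "x1"), c(x2 = 1L))
  expect_equal(intervention_context(C, "x3"), c(x2 = 0L))
  expect_length(intervention_context(C, "x2"), 0L)
  # node interventions act on every function's context
  N <- intervention_set(c(x1 = 1))
  for (j in c("x1", "x2", "x3")) {
    expect_equal(intervention_context(N, j), c(x1 = 1L))
  }
  expect_error(intervention_context(
    intervention_set(edges = c("x1->x2=1", "x1->x2=0")), "x2"), "inconsistent")
})

test_that("controlled networks match the published rewritings", {
  # edge pair on edge_only3: f^E = (1, x1 & x2, 0)
  fE <- apply_interventions(ex$edge_only3,
                            intervention_set(edges = c("x2->x1=1", "x2->x3=0")))
  expect_equal(dnf_of(fE, "x1"), "1")
  expect_equal(dnf_of(fE, "x2"), "x1&x2")
  expect_equal(dnf_of(fE, "x3"), "0")

  # node clamp x3=0 on bistable3: f^N = (x2, !x1 | x2, 0)
  fN <- apply_interventions(ex$bistable3, intervention_set(c(x3 = 0)))
  expect_equal(dnf_of(fN, "x1"), "x2")
  expect_equal(dnf_of(fN, "x2"), "!x1 | x2")
  expect_equal(dnf_of(fN, "x3"), "0")

  # empty set: identity
  expect_identical(apply_interventions(ex$bistable3, intervention_set())$functions,
                   ex$bistable3$functions)

  # node clamp x4=0 on trapselect4: (x2 | x1&x2, !x1&x2, 1, 0)
  f4 <- apply_interventions(ex$trapselect4, intervention_set(c(x4 = 0)))
  expect_equal(dnf_of(f4, "x1"), "x1&x2 | x2")
  expect_equal(dnf_of(f4, "x2"), "!x1&x2")
  expect_equal(dnf_of(f4, "x3"), "1")
  expect_equal(dnf_of(f4, "x4"), "0")

  # edge interventions must name a syntactic regulator
  expect_error(apply_interventions(ex$bistable3,
                                   intervention_set(edges = "x1->x1=1")),
               "regulator")
})

test_that("f^C agrees exhaustively with composition through the context h", {
  check_contract <- function(net, C) {
    ctrl <- suppressWarnings(apply_interventions(net, C))
    states <- oracle_states(net)
    clamped <- stats::setNames(C$nodes$value, C$nodes$var)
    for (r in seq_len(nrow(states))) {
      x <- states[r, ]
      got <- eval_network(ctrl, x)
      for (k in net$variables) {
        want <- if (k %in% names(clamped)) {
          clamped[[k]]
        } else {
          h <- x
          ctx <- intervention_context(C, k)
          h[names(ctx)] <- ctx
          eval_dnf(net$functions[[k]], h)
        }
        expect_equal(got[[k]], want)
      }
    }
  }
  set.seed(42)
  for (net in random_suite(10L, n_min = 4L, n_max = 5L, seed_base = 700L)) {
    ig <- interaction_graph(net)
    # one random mixed consistent set per network
    nd <- sample(net$variables, 1L)
    ed <- ig[ig$source != nd & ig$target != nd, , drop = FALSE]
    C <- intervention_set(
      nodes = stats::setNames(sample(0:1, 1L), nd),
      edges = if (nrow(ed) > 0L) {
        pick <- ed[sample.int(nrow(ed), 1L), ]
        data.frame(source = pick$source, target = pick$target,
                   value = sample(0:1, 1L))
      } else NULL
    )
    if (is_consistent(C)) check_contract(net, C)
  }
})

test_that("pure-node sets agree with the induced-subspace substitution view", {
  set.seed(7)
  for (net in random_suite(8L, seed_base = 800L)) {
    vs <- sample(net$variables, 2L)
    C <- intervention_set(stats::setNames(sample(0:1, 2L, replace = TRUE), vs))
    omega <- induced_subspace(net, C)
    ctrl <- apply_interventions(net, C)
    states <- oracle_states(net)
    for (r in seq_len(nrow(states))) {
      x <- states[r, ]
      sub <- x
      sub[names(omega)] <- omega        # substitute the clamped values
      want <- eval_network(net, sub)
      want[names(omega)] <- omega       # clamped coordinates stay clamped
      expect_equal(eval_network(ctrl, x), want)
    }
  }
})

test_that("intervention equivalence is decided on percolation fixpoints", {
  f1 <- ex$bistable3
  # single-regulator component: node clamp == matching edge intervention
  net <- read_bnet(c("a, b", "b, a | b"))
  expect_true(equivalent_interventions(net, intervention_set(c(a = 1)),
                                       intervention_set(edges = "b->a=1")))
  # reflexivity
  C <- intervention_set(c(x3 = 0))
  expect_true(equivalent_interventions(f1, C, C))
  # {x3=0} vs {x2=1}: fixpoints **0 vs 11* differ
  expect_false(equivalent_interventions(f1, intervention_set(c(x3 = 0)),
                                        intervention_set(c(x2 = 1))))

  # single-essential-regulator components, randomized
  hits <- 0L
  for (net in random_suite(20L, seed_base = 850L)) {
    ig <- interaction_graph(net)
    for (j in net$variables) {
      srcs <- unique(ig$source[ig$target == j])
      if (length(srcs) != 1L || srcs == j) next
      for (v in 0:1) {
        # the clamp value reached when the lone regulator is held at v
        out <- constancy(net, j, stats::setNames(v, srcs))
        if (is.na(out)) next
        eq <- equivalent_interventions(
          net, intervention_set(stats::setNames(out, j)),
          intervention_set(edges = sprintf("%s->%s=%d", srcs, j, v)))
        expect_true(eq, info = paste(net$variables[1], j, v))
        hits <- hits + 1L
      }
    }
    if (hits >= 10L) break
  }
  expect_gte(hits, 5L)
})
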