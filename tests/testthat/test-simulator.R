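test_that("enabled transitions are exactly the rule/value mismatches", {
  tm <- toy_model()
  tr <- enabled_transitions(tm$model, tm$settings, c(A = 1, B = 0, C = 1))
  expect_setequal(tr$node, c("B", "C"))
  expect_equal(tr$direction[tr$node == "B"], "up")
  expect_equal(tr$direction[tr$node == "C"], "down")
  expect_true(all(tr$rate == 1))
  # absorbing state
  tr0 <- enabled_transitions(tm$model, tm$settings, c(A = 1, B = 1, C = 0))
  expect_equal(nrow(tr0), 0L)
  # a zero opposing rate suppresses the transition (strict fixation)
  s <- apply_strict_nv(tm$settings, "B", 0)
  tr1 <- enabled_transitions(tm$model, s, c(A = 1, B = 0, C = 0))
  expect_false("B" %in% tr1$node)
})

test_that("trajectories respect jump structure and absorption", {
  set.seed(3)
  tm <- toy_model()
  for (rep in 1:10) {
    tr <- simulate_trajectory(tm$model, tm$settings)
    expect_true(all(diff(tr$times) > 0))
    if (nrow(tr$states) > 1) {
      flips <- rowSums(abs(diff(tr$states)))
      expect_true(all(flips == 1))
    }
    # the toy model always absorbs: B follows A, C its complement
    expect_true(tr$absorbed)
    final <- tr$states[nrow(tr$states), ]
    expect_equal(final[["B"]], final[["A"]])
    expect_equal(final[["C"]], 1L - final[["A"]])
  }
  # fully constrained model has zero jumps
  s <- apply_strict_nv(apply_strict_nv(apply_strict_nv(
    tm$settings, "A", 1), "B", 1), "C", 0)
  tr <- simulate_trajectory(tm$model, s)
  expect_equal(length(tr$times), 1L)
})

test_that("single-node relaxation matches the closed-form CTMC solution", {
  # A fixed on, B starts off with unit rate: P(B=1 at t) = 1 - exp(-t)
  tm <- toy_model()
  s <- tm$settings
  s$nodes$istate <- c(1, 0, 0)
  s$n_trajectories <- 4000L
  s$max_time <- 10
  s$time_bins <- 100L
  res <- simulate_ensemble(tm$model, s)
  idx <- c(5, 15, 30, 50)
  p_hat <- res$node_prob[idx, "B"]
  # bin-averaged analytic occupancy over each bin
  lo <- res$breaks[idx]; hi <- res$breaks[idx + 1]
  p_exact <- 1 - (exp(-lo) - exp(-hi)) / (hi - lo)
  se <- res$node_se[idx, "B"]
  expect_true(all(abs(p_hat - p_exact) < 4 * se + 5e-4))
})

test_that("ensembles are reproducible and order-independent by seed", {
  tm <- mini_cancer_model()
  s <- tm$settings
  s$n_trajectories <- 300L
  r1 <- simulate_ensemble(tm$model, s)
  r2 <- simulate_ensemble(tm$model, s)
  expect_identical(r1$node_prob, r2$node_prob)
  expect_identical(r1$states, r2$states)
  s$seed <- s$seed + 1L
  r3 <- simulate_ensemble(tm$model, s)
  expect_false(identical(r1$node_prob, r3$node_prob))
})

test_that("Monte-Carlo error shrinks like the square root of the ensemble size", {
  tm <- mini_cancer_model()
  s <- tm$settings
  s$n_trajectories <- 500L
  r1 <- simulate_ensemble(tm$model, s, record_states = FALSE)
  s$n_trajectories <- 2000L
  r4 <- simulate_ensemble(tm$model, s, record_states = FALSE)
  med1 <- median(r1$node_se[r1$node_se > 0])
  med4 <- median(r4$node_se[r4$node_se > 0])
  expect_equal(med1 / med4, 2, tolerance = 0.25)
})

test_that("state probabilities conserve mass and marginalize to node probabilities", {
  tm <- mini_cancer_model()
  s <- tm$settings
  s$n_trajectories <- 300L
  res <- simulate_ensemble(tm$model, s, record_states = TRUE)
  sums <- tapply(res$states$probability, res$states$bin, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # node marginal from states equals the recorded node probability
  for (nm in c("p53", "Proliferation")) {
    i <- match(nm, res$nodes)
    on <- (res$states$state_key %/% 2^(i - 1)) %% 2 >= 1
    marg <- tapply(res$states$probability * on, res$states$bin, sum)
    expect_equal(as.numeric(marg), unname(res$node_prob[, nm]),
                 tolerance = 1e-9)
  }
})

test_that("exact oracle solves the two-state relaxation in closed form", {
  fn <- free_node_model(k_up = 1, k_down = 1, istate = 0)
  for (t in c(0.3, 1, 2.5)) {
    d <- exact_distribution(fn$model, fn$settings, t)
    expect_equal(d$probability[d$state_key == 1], (1 - exp(-2 * t)) / 2,
                 tolerance = 1e-9)
    expect_equal(sum(d$probability), 1, tolerance = 1e-12)
  }
})

test_that("exact oracle reproduces initial distribution and absorbing limits", {
  tm <- toy_model()
  s <- tm$settings
  s$nodes$istate <- c(0.6, 0.2, 0.9)
  d0 <- exact_distribution(tm$model, s, 0)
  # t = 0: product of independent Bernoullis
  key <- function(a, b, c) a + 2 * b + 4 * c
  expect_equal(d0$probability[d0$state_key == key(1, 0, 1)],
               0.6 * 0.8 * 0.9, tolerance = 1e-12)
  # from (1, 0, 1) all mass ends in (1, 1, 0)
  s$nodes$istate <- c(1, 0, 1)
  dT <- exact_distribution(tm$model, s, 60)
  expect_equal(dT$probability[dT$state_key == key(1, 1, 0)], 1,
               tolerance = 1e-6)
  # oracle refuses models beyond its node limit
  expect_error(exact_distribution(tm$model, s, 1, max_nodes = 2), "limited")
})

test_that("asymptotic probabilities follow the input's initial Bernoulli on the toy model", {
  tm <- toy_model()
  s <- tm$settings
  s$nodes$istate <- c(0.6, 0.5, 0.5)
  s$n_trajectories <- 4000L
  ap <- asymptotic_probabilities(simulate_ensemble(tm$model, s))
  # B relaxes to A's initial Bernoulli(0.6), C to its complement
  expect_equal(ap$probability[ap$node == "B"], 0.6, tolerance = 0.03)
  expect_equal(ap$probability[ap$node == "C"], 0.4, tolerance = 0.03)
  # A initial 0: C is certain
  s$nodes$istate <- c(0, 0.5, 0.5)
  ap0 <- asymptotic_probabilities(simulate_ensemble(tm$model, s))
  expect_equal(ap0$probability[ap0$node == "C"], 1)
  # fully fixed model keeps its initial assignment
  sf <- apply_strict_nv(apply_strict_nv(apply_strict_nv(
    tm$settings, "A", 1), "B", 0), "C", 1)
  apf <- asymptotic_probabilities(simulate_ensemble(tm$model, sf))
  expect_equal(apf$probability, c(1, 0, 1))
})

test_that("ensemble agrees with the exact master equation on the free-node model", {
  fn <- free_node_model(k_up = 2, k_down = 0.5, istate = 0.3)
  s <- fn$settings
  s$n_trajectories <- 3000L
  s$max_time <- 5
  s$time_bins <- 50L
  res <- simulate_ensemble(fn$model, s)
  for (idx in c(10, 25, 45)) {
    lo <- res$breaks[idx]; hi <- res$breaks[idx + 1]
    # bin-average the exact solution (Simpson)
    ts <- c(lo, (lo + hi) / 2, hi)
    px <- vapply(ts, function(t) {
      d <- exact_distribution(fn$model, s, t)
      d$probability[d$state_key == 1]
    }, numeric(1))
    p_exact <- sum(px * c(1, 4, 1)) / 6
    expect_lt(abs(res$node_prob[idx, "X"] - p_exact),
              4 * res$node_se[idx, "X"] + 1e-8)
  }
})

test_that("tidy and glance provide well-formed summaries", {
  tm <- toy_model()
  s <- tm$settings
  s$n_trajectories <- 100L
  res <- simulate_ensemble(tm$model, s)
  td <- tidy(res)
  expect_named(td, c("time", "node", "probability", "std_error"))
  expect_equal(nrow(td), s$time_bins * 3)
  expect_true(all(td$probability >= 0 & td$probability <= 1))
  g <- glance(res)
  expect_equal(g$n_trajectories, 100L)
})
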