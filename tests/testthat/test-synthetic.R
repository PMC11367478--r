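membership7 <- triple_network_membership()

test_that("zero-target and equicorrelation matrices come back unchanged and SPD", {
  specs <- list(
    list(state_id = 1L, targets = block_target_matrix(membership7, base = 0)),
    list(state_id = 2L, targets = block_target_matrix(membership7, base = 0.5))
  )
  st <- make_state_covariances(7, membership7, specs)
  expect_equal(st[[1]]$covariance, diag(7),
               ignore_attr = TRUE, tolerance = 1e-12)
  eq <- st[[2]]$covariance
  expect_equal(unname(diag(eq)), rep(1, 7))
  expect_equal(unname(eq[upper.tri(eq)]), rep(0.5, 21))
  expect_gt(min(eigen(eq, symmetric = TRUE)$values), 1e-6)
})

test_that("infeasible block targets are repaired toward the targets by eigenvalue clipping", {
  # DMN-ECN blocks at 0.6 with everything else near zero is not SPD as
  # written; after repair the mean DMN-ECN entry must stay close to 0.6.
  specs <- list(list(state_id = 2L, targets = block_target_matrix(
    membership7, base = 0.05,
    blocks = list(list(a = "DMN", b = "DMN", r = 0.6),
                  list(a = "ECN", b = "ECN", r = 0.6),
                  list(a = "DMN", b = "ECN", r = 0.6)))))
  st <- make_state_covariances(7, membership7, specs)[[1]]
  expect_gt(min(eigen(st$covariance, symmetric = TRUE)$values), 1e-6 - 1e-12)

  # independent oracle: one direct eigenvalue-clipping pass on the raw target
  raw <- specs[[1]]$targets
  e <- eigen(raw, symmetric = TRUE)
  clipped <- e$vectors %*% (pmax(e$values, 1e-6) * t(e$vectors))
  clipped <- stats::cov2cor(clipped)
  dimnames(clipped) <- dimnames(raw)
  dmn <- names(membership7)[membership7 == "DMN"]
  ecn <- names(membership7)[membership7 == "ECN"]
  expect_equal(mean(st$covariance[dmn, ecn]), mean(clipped[dmn, ecn]),
               tolerance = 0.02)
  expect_lt(abs(mean(st$covariance[dmn, ecn]) - 0.6), 0.05)
})

test_that("every default state covariance passes a Cholesky factorization", {
  st <- make_state_covariances(7, membership7, default_state_specs())
  for (s in st) {
    expect_silent(chol(s$covariance))
    expect_equal(unname(diag(s$covariance)), rep(1, 7))
    expect_equal(s$covariance, t(s$covariance))
  }
})

test_that("degenerate and two-state sequences behave as designed", {
  expect_equal(simulate_state_sequence(
    sequence_params(1, mean_dwell = 3, n_windows = 25, seed = 1)),
    rep(1L, 25))
  # mean_dwell = 1 forces a switch at every window; equal occupancies then
  # give an empirical state-1 frequency within the 3-sigma iid band
  s <- simulate_state_sequence(
    sequence_params(c(.5, .5), mean_dwell = 1, n_windows = 1e5, seed = 11))
  expect_true(all(diff(s) != 0))
  f1 <- mean(s == 1L)
  expect_gte(f1, 0.49)
  expect_lte(f1, 0.51)
})

test_that("empirical occupancy converges to the target occupancy", {
  occ <- c(0.42, 0.19, 0.22, 0.17)
  n <- 148L * 100L
  s <- simulate_state_sequence(
    sequence_params(occ, mean_dwell = 2, n_windows = n, seed = 5))
  freq <- tabulate(s, 4L) / n
  tol <- 3 * sqrt(occ * (1 - occ) / n)
  expect_true(all(abs(freq - occ) <= tol))
  # a dwell of 1 is infeasible for skewed occupancies: the rarest state
  # would need a negative self-transition probability
  expect_error(simulate_state_sequence(
    sequence_params(occ, mean_dwell = 1, n_windows = 10, seed = 1)),
    "too small")
})

test_that("the empirical mean run length recovers mean_dwell within 10%", {
  for (dwell in c(2, 8)) {
    s <- simulate_state_sequence(
      sequence_params(rep(0.25, 4), mean_dwell = dwell, n_windows = 2e4,
                      seed = 3 + dwell))
    runs <- rle(s)
    expect_lt(abs(mean(runs$lengths) - dwell) / dwell, 0.10)
  }
})

test_that("generation is deterministic given the seed", {
  p <- sequence_params(c(.3, .7), mean_dwell = 4, n_windows = 200, seed = 99)
  expect_identical(simulate_state_sequence(p), simulate_state_sequence(p))
  st <- make_state_covariances(7, membership7, default_state_specs())
  a <- simulate_timecourses(2, T_len = 50, TR = 2, states = st,
                            seq_params = sequence_params(n_windows = 29), seed = 7)
  b <- simulate_timecourses(2, T_len = 50, TR = 2, states = st,
                            seq_params = sequence_params(n_windows = 29), seed = 7)
  expect_identical(a, b)
})

test_that("noise-free single-state sampling matches the state covariance", {
  ident <- list(list(state_id = 1L, targets = block_target_matrix(membership7, 0)))
  st <- make_state_covariances(7, membership7, ident)
  tc <- simulate_timecourses(1, T_len = 1e4, TR = 2, states = st,
                             seq_params = sequence_params(1, 1, n_windows = 1L, seed = 1),
                             obs_noise_sd = 0, seed = 21)[[1]]
  cm <- stats::cor(tc$data)
  expect_lt(max(abs(cm[upper.tri(cm)])), 3 / sqrt(1e4))
})

test_that("time-course simulation validates its inputs", {
  st <- make_state_covariances(7, membership7, default_state_specs())
  expect_error(simulate_timecourses(1, T_len = 10, TR = 2, states = st,
                                    seq_params = sequence_params(n_windows = 50)),
               "exceeds")
  bad <- st
  bad[[1]]$covariance <- matrix(2, 7, 7)  # rank 1, not PD
  expect_error(simulate_timecourses(1, T_len = 50, TR = 2, states = bad,
                                    seq_params = sequence_params(n_windows = 29)),
               "positive definite")
})

test_that("cohort generation honors effect sizes and behavior links", {
  spec <- cohort_spec(
    group_sizes = c(HC = 200L, PAT = 200L),
    covariates = list(age = list(mean = 55, sd = 8)),
    measures = list(edge = list(mean = 0.3, sd = 0.2),
                    other = list(mean = 0, sd = 1)),
    effect_sizes = data.frame(measure = "edge", group = "PAT", shift = 0.2),
    behavior_links = data.frame(behavior = c("score_linked", "score_null"),
                                measure = c("edge", "other"),
                                intercept = c(10, 5), slope = c(2, 0),
                                noise_sd = c(0.05, 0.5)),
    seed = 31L)
  out <- simulate_cohort(spec)
  ch <- out$cohort
  shift_hat <- mean(ch$edge[ch$group == "PAT"]) - mean(ch$edge[ch$group == "HC"])
  expect_lt(abs(shift_hat - 0.2), 3 * 0.2 * sqrt(2 / 200))
  expect_gt(stats::cor(ch$edge, ch$score_linked), 0.95)
  expect_lt(abs(stats::cor(ch$other, ch$score_null)), 0.15)
  expect_error(cohort_spec(group_sizes = c(A = 1L, B = 5L)), ">= 2")
})

test_that("cohort spec rejects non-positive noise", {
  expect_error(cohort_spec(behavior_links = data.frame(
    behavior = "b", measure = "m", intercept = 0, slope = 1, noise_sd = 0)),
    "noise sd")
})
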