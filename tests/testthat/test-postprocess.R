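test_that("polynomial detrending annihilates basis members and orthogonalizes noise", {
  t_idx <- seq_len(60)
  x <- cbind(const = rep(3, 60), cubic = t_idx^3 - 2 * t_idx,
             noise = local({set.seed(4); rnorm(60)}))
  colnames(x) <- c("PCC", "LECN", "insula")
  tc <- timecourse_set(x, TR = 2,
                       membership = c(PCC = "DMN", LECN = "ECN", insula = "SAN"))
  out0 <- detrend_polynomial(tc, 0L)
  expect_equal(unname(out0$data[, 1]), rep(0, 60), tolerance = 1e-10)
  out3 <- detrend_polynomial(tc, 3L)
  expect_lt(max(abs(out3$data[, 2])), 1e-8 * sqrt(sum(x[, 2]^2)))
  # residual orthogonal to t, t^2, t^3 (normalized inner products)
  for (p in 1:3) {
    basis <- t_idx^p
    ip <- abs(sum(out3$data[, 3] * (basis - mean(basis))))
    expect_lt(ip / (sqrt(sum(out3$data[, 3]^2)) * sqrt(sum((basis - mean(basis))^2))),
              1e-8)
  }
  expect_error(detrend_polynomial(toy_timecourse(4), order = 3), "time points")
})

test_that("nuisance regression projects out the regressors and their derivatives", {
  set.seed(8)
  T_len <- 80
  reg <- matrix(rnorm(T_len * 6), T_len, 6,
                dimnames = list(NULL, paste0("mot", 1:6)))
  tc_eq <- toy_timecourse(T_len, seed = 2)
  tc_eq$data[, 1] <- reg[, 3]
  out <- regress_nuisance(tc_eq, reg, include_derivatives = FALSE)
  expect_lt(max(abs(out$data[, 1])), 1e-10)

  # full 12-regressor projection: residuals orthogonal to the expanded set
  tc <- toy_timecourse(T_len, seed = 3)
  out12 <- regress_nuisance(tc, reg, include_derivatives = TRUE)
  derivs <- apply(reg, 2, function(v) c(0, diff(v)))
  design <- cbind(1, reg, derivs)
  ips <- crossprod(design, out12$data)
  expect_lt(max(abs(ips)) / max(abs(out12$data)), 1e-8)

  # projection oracle via the normal equations
  beta <- solve(crossprod(design), crossprod(design, tc$data))
  expect_equal(out12$data, tc$data - design %*% beta,
               ignore_attr = TRUE, tolerance = 1e-10)

  dup <- cbind(reg, dup_col = reg[, 1])
  expect_error(regress_nuisance(tc, dup, include_derivatives = FALSE),
               "collinear")
})

test_that("the low-pass filter has the designed frequency response", {
  TR <- 2
  t_sec <- (0:799) * TR
  carrier <- function(f) sin(2 * pi * f * t_sec)
  x <- cbind(PCC = carrier(0.01), LECN = carrier(0.24), insula = rep(1, 800))
  tc <- timecourse_set(x, TR = TR,
                       membership = c(PCC = "DMN", LECN = "ECN", insula = "SAN"))
  out <- lowpass_filter(tc, 0.15)
  core <- 100:700  # away from the filtfilt edge transients
  amp_ratio <- function(j) max(abs(out$data[core, j])) / max(abs(x[core, j]))
  expect_gt(amp_ratio(1), 0.9)          # 0.01 Hz passes
  expect_lt(amp_ratio(2), 0.1)          # 0.24 Hz crushed by >= 90%
  expect_equal(out$data[, 3], x[, 3], ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(lowpass_filter(tc, 0.25), "Nyquist")
})

test_that("despiking replaces only flagged samples and is idempotent", {
  # bounded smooth signal: nothing exceeds the robust threshold
  smooth <- timecourse_set(cbind(PCC = sin(seq_len(50) / 5),
                                 LECN = cos(seq_len(50) / 7)),
                           TR = 2, membership = c(PCC = "DMN", LECN = "ECN"))
  expect_identical(despike(smooth)$data, smooth$data)

  # idempotence on arbitrary data: a second pass changes nothing
  tc <- toy_timecourse(50, seed = 5)
  once <- despike(tc)
  expect_identical(despike(once)$data, once$data)

  spiked <- tc
  spiked$data[25, 1] <- 100
  fixed <- despike(spiked)
  expect_lt(fixed$data[25, 1],
            max(spiked$data[24, 1], spiked$data[26, 1]) + 1e-12)
  expect_identical(fixed$data[-25, 1], spiked$data[-25, 1])

  # two adjacent spikes, hand-computed 6-point example: median 1, MAD 1,
  # threshold 3 * 1.4826 -> samples 50 and 60 flagged, bracket (1, 1)
  x6 <- c(0, 1, 50, 60, 1, 0)
  tc6 <- timecourse_set(cbind(PCC = x6, LECN = rnorm(6)), TR = 2,
                        membership = c(PCC = "DMN", LECN = "ECN"))
  out6 <- despike(tc6)
  expect_equal(unname(out6$data[3:4, 1]), c(1, 1))
  expect_equal(unname(out6$data[c(1, 2, 5, 6), 1]), x6[c(1, 2, 5, 6)])

  # more than half the samples flagged -> unusable signal
  wild <- timecourse_set(cbind(PCC = c(0, 0, 1, -1, 2, -2), LECN = rnorm(6)),
                         TR = 2, membership = c(PCC = "DMN", LECN = "ECN"))
  expect_error(despike(wild, z_thresh = 0.1), "unusable")
})

test_that("the post-processing pipeline preserves shape", {
  tc <- toy_timecourse(80, seed = 6)
  set.seed(7)
  nuis <- matrix(rnorm(80 * 6), 80, 6)
  out <- postprocess_timecourses(tc, nuisance = nuis)
  expect_identical(dim(out$data), dim(tc$data))
  expect_identical(out$node_labels, tc$node_labels)
})
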