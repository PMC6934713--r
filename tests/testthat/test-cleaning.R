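test_that("forward fill propagates the last valid value", {
  expect_equal(forward_fill(c(1, NA, NA, 4)), c(1, 1, 1, 4))
  expect_equal(forward_fill(c(1, 2, 3)), c(1, 2, 3))
  # documented leading-gap rule: back-fill from first valid value
  expect_equal(forward_fill(c(NA, 2, NA)), c(2, 2, 2))
  expect_error(forward_fill(c(NA, NA)), "entirely missing")
})

test_that("forward fill is idempotent and works column-wise", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(30)
    x[sample(2:30, 8)] <- NA
    once <- forward_fill(x)
    expect_false(anyNA(once))
    expect_identical(forward_fill(once), once)
  }
  m <- matrix(c(1, NA, 3, NA, 5, 6), 3, 2)
  expect_equal(forward_fill(m), matrix(c(1, 1, 3, 5, 5, 6), 3, 2))
})

test_that("Haar approximation equals dyadic block means", {
  expect_equal(haar_denoise(c(1, 3, 5, 7), 1), c(2, 6))
  expect_equal(haar_denoise(c(1, 3, 5, 7), 2), 4)
  expect_equal(haar_denoise(rep(2.5, 64), 5), rep(2.5, 2))
  # brute-force oracle: block means of a random series
  set.seed(1)
  x <- rnorm(32)
  expect_equal(haar_denoise(x, 3), colMeans(matrix(x, 8, 4)))
  # true coefficients are block means scaled by 2^(L/2)
  expect_equal(haar_denoise(x, 3, amplitude_preserve = FALSE),
               colMeans(matrix(x, 8, 4)) * 2^(3 / 2))
})

test_that("Haar denoising commutes with adding a constant", {
  set.seed(2)
  x <- rnorm(40)
  expect_equal(haar_denoise(x + 7, 2), haar_denoise(x, 2) + 7)
})

test_that("odd lengths use half-sample symmetric padding", {
  # T = 5 -> pad last sample; lengths ceil(T/2) per level
  expect_equal(haar_denoise(c(1, 3, 2, 4, 6), 1), c(2, 3, 6))
  expect_length(haar_denoise(rnorm(11), 1), 6)
  expect_length(haar_denoise(rnorm(11), 2), 3)
})

test_that("wavelet level is reduced for short series", {
  expect_warning(out <- haar_denoise(c(1, 3, 5), 2), "reducing")
  expect_equal(out, c(2, 5))
  expect_error(haar_denoise(1, 1), "too short")
})

test_that("lowpass denoising contracts variance on noisy channels", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(256) # jitter-dominated: white noise
    expect_lt(var(haar_denoise(x, 5)), var(x))
  }
})

test_that("middle trimming keeps the centred window", {
  expect_equal(trim_middle(1:9999, 10000), 1:9999) # shorter: untouched
  expect_equal(trim_middle(1:12, 10), 2:11) # start floor((12-10)/2) = 1
  expect_equal(trim_middle(1:10000, 10000), 1:10000) # boundary
  expect_equal(trim_middle(1:11, 4), 4:7) # floor((11-4)/2) = 3
  m <- matrix(1:24, 12, 2)
  expect_equal(trim_middle(m, 10), m[2:11, ])
})

test_that("variance QC fits exponential tails with closed-form thresholds", {
  # one pose, channel 1 variances {1.0, 1.2, 0.8, 1.0}: mean 1.0 ->
  # threshold ln(1e7) = 16.118; nothing discarded
  recs <- lapply(1:4, function(i)
    recording_with_variances(c(c(1, 1.2, 0.8, 1)[i], rep(0, 61)),
                             sprintf("P%d", i)))
  out <- variance_qc(recs, 1e-7)
  expect_equal(out$report$n_discarded, 0)
  expect_equal(unname(out$report$per_pose[["1"]]$threshold[1]), log(1e7),
               tolerance = 1e-12)
  # adding one file with variance 100: the single-pass fit includes it,
  # mean becomes 20.8, threshold 335.3, so 100 is (correctly) kept
  recs5 <- c(recs, list(recording_with_variances(c(100, rep(0, 61)), "P5")))
  out5 <- variance_qc(recs5, 1e-7)
  expect_equal(unname(out5$report$per_pose[["1"]]$mean_variance[1]), 20.8)
  expect_equal(unname(out5$report$per_pose[["1"]]$threshold[1]),
               20.8 * log(1e7), tolerance = 1e-12)
  expect_equal(out5$report$n_discarded, 0)
})

test_that("variance QC discards genuine extreme outliers", {
  set.seed(9)
  recs <- lapply(1:30, function(i)
    recording_with_variances(runif(62, 0.8, 1.2), sprintf("P%d", i)))
  recs <- c(recs, list(recording_with_variances(c(100, runif(61, 0.8, 1.2)),
                                                "BAD")))
  out <- variance_qc(recs, 1e-7)
  expect_equal(out$report$discarded$participant_id, "BAD")
  expect_equal(out$report$discarded$offending_channels, "head:x")
  expect_equal(out$report$discard_fraction, 1 / 31)
  expect_length(out$kept, 30)
})

test_that("poses with fewer than two files skip QC with a warning", {
  recs <- list(recording_with_variances(rep(1, 62), "P1", pose = 1),
               recording_with_variances(rep(1, 62), "P2", pose = 1),
               recording_with_variances(rep(1, 62), "P3", pose = 2))
  expect_warning(out <- variance_qc(recs), "pose 2")
  expect_length(out$kept, 3)
})

test_that("the cleaning pipeline composes the four stages in order", {
  cfg <- toy_sim_config(p_missing = 0, p_corrupt_file = 0, jitter_sd = 0)
  ds <- simulate_dataset(cfg)
  cl <- clean_dataset(ds$recordings, cleaning_config())
  expect_equal(cl$qc$n_discarded, 0) # clean data: nothing discarded
  lens_raw <- vapply(ds$recordings, function(r) nrow(r$data), integer(1))
  lens_cl <- vapply(cl$recordings, function(r) nrow(r$data), integer(1))
  expect_equal(lens_cl, pmin(ceiling(lens_raw / 2^5), 10000))
  expect_equal(cl$recordings[[1]]$frame_rate_hz, 30 / 2^5)
  # deterministic
  cl2 <- clean_dataset(ds$recordings, cleaning_config())
  expect_identical(cl$recordings[[5]]$data, cl2$recordings[[5]]$data)
})

test_that("trimming caps the post-wavelet length", {
  r <- toy_recording(T = 400, seed = 5)
  cl <- clean_dataset(list(r, toy_recording(T = 400, seed = 6)),
                      cleaning_config(wavelet_level = 2,
                                      trim_max_len = 50))
  expect_equal(nrow(cl$recordings[[1]]$data), 50)
})
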