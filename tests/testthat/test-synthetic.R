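test_that("cohort has the requested shape and is reproducible", {
  cfg <- simulation_config(n_asd = 39, n_td = 23, rng_seed = 1L)
  cohort <- sample_cohort(cfg)
  expect_equal(nrow(cohort), 62)
  expect_equal(sum(cohort$group == "ASD"), 39)
  expect_equal(sum(cohort$group == "TD"), 23)
  expect_true(all(cohort$age_years >= 7 & cohort$age_years <= 18))
  expect_true(all(cohort$bot2_percentile >= 1 &
                    cohort$bot2_percentile <= 99))
  expect_identical(cohort, sample_cohort(cfg))
})

test_that("latent severity separates groups and drives covariates", {
  cfg <- simulation_config(n_asd = 200, n_td = 200, rng_seed = 7L)
  cohort <- sample_cohort(cfg)
  sev_asd <- cohort$latent_severity[cohort$group == "ASD"]
  sev_td <- cohort$latent_severity[cohort$group == "TD"]
  expect_lt(wilcox.test(sev_td, sev_asd, alternative = "less")$p.value,
            1e-6)
  # monotone links: brute-force correlations over the emitted cohort
  expect_lt(cor(cohort$bot2_percentile, cohort$latent_severity), 0)
  expect_gt(cor(cohort$srs2_score, cohort$latent_severity), 0)
  expect_gt(cor(cohort$rbsr_score, cohort$latent_severity), 0)
})

test_that("invalid configuration fields are named in errors", {
  expect_error(simulation_config(n_asd = 0), "n_asd")
  expect_error(simulation_config(p_missing = 2), "p_missing")
  expect_error(simulation_config(affected_channels = c(1, 70)),
               "affected_channels")
  expect_error(simulation_config(ar_phi = 1), "ar_phi")
  expect_error(simulation_config(corrupt_scale = 0), "corrupt_scale")
})

test_that("recordings have the right shape and per-file reproducibility", {
  cfg <- toy_sim_config()
  prof <- toy_profile()
  r1 <- simulate_recording(prof, 1, 2, cfg)
  expect_s3_class(r1, "recording")
  expect_equal(ncol(r1$data), 62)
  expect_true(nrow(r1$data) >= 800 && nrow(r1$data) <= 1200)
  expect_identical(colnames(r1$data), channel_names())
  # independently reproducible from (seed, participant, pose, session)
  expect_identical(r1$data, simulate_recording(prof, 1, 2, cfg)$data)
  r2 <- simulate_recording(prof, 2, 2, cfg)
  expect_false(identical(r1$data, r2$data))
  expect_error(simulate_recording(prof, 99, 2, cfg), "pose_id")
  expect_error(simulate_recording(prof, 1, 9, cfg), "session")
})

test_that("noise SD follows the severity/affected-channel law", {
  # beta = 2, severity = 1 -> affected-channel SD = 3 * sigma_base
  cfg <- simulation_config(n_asd = 1, n_td = 1, sessions = 2L,
                           frames_range = c(2000L, 2000L),
                           drift_amp_range = c(0, 0), jitter_sd = 0,
                           p_missing = 0, age_slope = 0, rng_seed = 3L)
  prof <- toy_profile(severity = 1)
  vars <- sapply(1:30, function(i) {
    cfg2 <- cfg; cfg2$rng_seed <- i
    apply(simulate_recording(prof, 1, 2, cfg2)$data, 2, var)
  })
  aff <- default_affected_channels()
  sd_aff <- sqrt(mean(vars[aff, ]))
  sd_un <- sqrt(mean(vars[-aff, ]))
  expect_equal(sd_aff, 3, tolerance = 0.1)
  expect_equal(sd_un, 1, tolerance = 0.1)
})

test_that("zero-effect configuration equalises the groups", {
  cfg <- simulation_config(n_asd = 1, n_td = 1, sessions = 2L,
                           frames_range = c(500L, 500L),
                           effect_size_beta = 0, age_slope = 0,
                           p_missing = 0, rng_seed = 11L)
  var_of <- function(group, seed) {
    cfg2 <- cfg; cfg2$rng_seed <- seed
    prof <- toy_profile(group = group, severity = if (group == "ASD") 1
                        else 0.1)
    mean(apply(simulate_recording(prof, 1, 2, cfg2)$data, 2, var))
  }
  v_asd <- sapply(1:25, var_of, group = "ASD")
  v_td <- sapply(26:50, var_of, group = "TD")
  expect_gt(t.test(v_asd, v_td)$p.value, 0.01)
})

test_that("missing cells appear at the configured rate", {
  cfg <- simulation_config(n_asd = 1, n_td = 1, sessions = 2L,
                           frames_range = c(10000L, 10000L),
                           p_missing = 0.001, rng_seed = 2L)
  r <- simulate_recording(toy_profile(), 1, 2, cfg)
  n_missing <- sum(is.na(r$data))
  expected <- 10000 * 62 * 0.001 # ~10 per channel
  expect_lt(abs(n_missing - expected), 3 * sqrt(expected))
})

test_that("corruption rescales variance exactly and at the right rate", {
  rec <- toy_recording(T = 50, seed = 4)
  cfg0 <- toy_sim_config(p_corrupt_file = 0)
  out <- corrupt_recording(rec, cfg0)
  expect_identical(out$data, rec$data)
  expect_false(attr(out, "corrupted"))

  cfg1 <- toy_sim_config(p_corrupt_file = 1, corrupt_scale = 100)
  out1 <- corrupt_recording(rec, cfg1)
  expect_true(attr(out1, "corrupted"))
  expect_equal(apply(out1$data, 2, var), 100 * apply(rec$data, 2, var),
               tolerance = 1e-12)

  cfg05 <- toy_sim_config(p_corrupt_file = 0.05)
  set.seed(99)
  flags <- replicate(1000, attr(corrupt_recording(rec, cfg05), "corrupted"))
  expect_lt(abs(sum(flags) - 50), 3 * sqrt(1000 * 0.05 * 0.95))
})

test_that("on-disk datasets are complete and byte-identical across reruns", {
  cfg <- simulation_config(n_asd = 2, n_td = 2, sessions = 2:4,
                           n_poses = 10, frames_range = c(30L, 40L),
                           rng_seed = 13L)
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  expect_equal(nrow(m1), 120)
  expect_equal(sum(m1$group == "ASD") / (3 * 10), 2) # label bookkeeping
  expect_equal(sum(m1$group == "TD") / (3 * 10), 2)
  tsv <- function(d) sort(list.files(d, pattern = "^p", full.names = TRUE))
  expect_identical(unname(tools::md5sum(tsv(d1))),
                   unname(tools::md5sum(tsv(d2))))
  expect_identical(m1[, setdiff(names(m1), "path")],
                   m2[, setdiff(names(m2), "path")])
  unlink(c(d1, d2), recursive = TRUE)
})
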