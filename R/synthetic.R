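#' Configuration for the synthetic balance-study cohort
#'
#' Defines the generative conditions under which the pipeline is exercised:
#' a two-group cohort (ASD and typically developing youth, ages 7-18) whose
#' recordings are slow postural drift plus first-order autoregressive sway
#' noise plus white sensor jitter, with the group effect expressed as a
#' multiplicative inflation of the sway-noise standard deviation on a subset
#' of channels, modulated by age.
#'
#' Per-channel signal model for one recording:
#' \deqn{x_t = drift_t + a_t + jitter_t}
#' where \eqn{drift} is a mixture of \code{drift_components} sinusoids below
#' 0.4 Hz, \eqn{a_t} is AR(1) with coefficient \code{ar_phi} and stationary
#' standard deviation
#' \eqn{\sigma_{base} (1 + \beta s 1[affected]) f(age, group)},
#' \eqn{s} the participant's latent severity, and jitter is i.i.d. Gaussian.
#' The age factor \eqn{f = 1 + age\_slope (18 - age^*)} decreases with age;
#' for the ASD group the effective age \eqn{age^*} is shifted younger by
#' \code{asd_age_delay} years, emulating a developmental motor delay.
#'
#' @param n_asd,n_td Group sizes (default 20 + 20).
#' @param sessions Training sessions to simulate (default \code{2:4}).
#' @param n_poses Number of balance poses (default 10).
#' @param frame_rate_hz Raw sampling rate in Hz (default 30).
#' @param frames_range Length-2 integer range of raw frames per recording
#'   (default 1600-2400).
#' @param affected_channels Indices of the channels carrying the group
#'   effect (default head, shoulders, feet, board sway;
#'   \code{\link{default_affected_channels}}).
#' @param effect_size_beta Noise-SD inflation per unit latent severity on
#'   affected channels (default 2).
#' @param age_slope Noise-SD increase per year below age 18 (default 0.05).
#' @param asd_age_delay Years by which the ASD age curve lags (default 3).
#' @param sigma_base Baseline stationary sway-noise SD (default 1).
#' @param ar_phi AR(1) coefficient of the sway noise at the raw rate
#'   (default 0.98, i.e. a ~1.7 s time constant at 30 Hz).
#' @param drift_components,drift_freq_range,drift_amp_range Sinusoidal drift
#'   mixture: number of components, frequency band in Hz, and per-component
#'   amplitude range.
#' @param jitter_sd SD of the white high-frequency sensor jitter
#'   (default 0.3).
#' @param p_missing Per-cell missingness probability (default 1e-4).
#' @param p_corrupt_file Probability that a whole file is corrupted
#'   (default 0.01).
#' @param corrupt_scale Variance multiplier applied to corrupted files
#'   (default 1e4).
#' @param severity_shape_asd,severity_rate_asd Gamma parameters of latent
#'   severity in the ASD group (mean 1, SD 0.5 by default).
#' @param severity_shape_td,severity_rate_td Gamma parameters in the TD
#'   group (mean 0.15 by default).
#' @param rng_seed Master seed; every randomised quantity is derived from it.
#' @return An object of class \code{"simulation_config"} (a validated list).
#' @export
simulation_config <- function(n_asd = 20, n_td = 20, sessions = 2:4,
                              n_poses = 10, frame_rate_hz = 30,
                              frames_range = c(1600L, 2400L),
                              affected_channels = default_affected_channels(),
                              effect_size_beta = 2, age_slope = 0.05,
                              asd_age_delay = 3, sigma_base = 1,
                              ar_phi = 0.98, drift_components = 3,
                              drift_freq_range = c(0.02, 0.4),
                              drift_amp_range = c(0.2, 0.6),
                              jitter_sd = 0.3, p_missing = 1e-4,
                              p_corrupt_file = 0.01, corrupt_scale = 1e4,
                              severity_shape_asd = 4, severity_rate_asd = 4,
                              severity_shape_td = 1.5, severity_rate_td = 10,
                              rng_seed = 1L) {
  cfg <- list(n_asd = n_asd, n_td = n_td, sessions = as.integer(sessions),
              n_poses = as.integer(n_poses), frame_rate_hz = frame_rate_hz,
              frames_range = as.integer(frames_range),
              affected_channels = as.integer(affected_channels),
              effect_size_beta = effect_size_beta, age_slope = age_slope,
              asd_age_delay = asd_age_delay, sigma_base = sigma_base,
              ar_phi = ar_phi, drift_components = drift_components,
              drift_freq_range = drift_freq_range,
              drift_amp_range = drift_amp_range, jitter_sd = jitter_sd,
              p_missing = p_missing, p_corrupt_file = p_corrupt_file,
              corrupt_scale = corrupt_scale,
              severity_shape_asd = severity_shape_asd,
              severity_rate_asd = severity_rate_asd,
              severity_shape_td = severity_shape_td,
              severity_rate_td = severity_rate_td,
              rng_seed = as.integer(rng_seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    stop("invalid simulation config field '", field, "': ", why,
         call. = FALSE)
  if (!is.numeric(cfg$n_asd) || cfg$n_asd < 1) bad("n_asd", "must be >= 1")
  if (!is.numeric(cfg$n_td) || cfg$n_td < 1) bad("n_td", "must be >= 1")
  if (cfg$n_poses < 1) bad("n_poses", "must be >= 1")
  if (cfg$frame_rate_hz <= 0) bad("frame_rate_hz", "must be > 0")
  if (length(cfg$frames_range) != 2L || any(cfg$frames_range < 2L) ||
      cfg$frames_range[1L] > cfg$frames_range[2L])
    bad("frames_range", "must be an increasing pair of integers >= 2")
  if (length(cfg$affected_channels) &&
      (min(cfg$affected_channels) < 1 || max(cfg$affected_channels) > 62))
    bad("affected_channels", "indices must lie in 1..62")
  for (f in c("p_missing", "p_corrupt_file"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "must be a probability in [0,1]")
  for (f in c("sigma_base", "corrupt_scale"))
    if (cfg[[f]] <= 0) bad(f, "must be > 0")
  if (cfg$jitter_sd < 0) bad("jitter_sd", "must be >= 0")
  if (cfg$effect_size_beta < 0) bad("effect_size_beta", "must be >= 0")
  if (cfg$ar_phi < 0 || cfg$ar_phi >= 1) bad("ar_phi", "must be in [0,1)")
  invisible(cfg)
}

# Age factor of the noise SD: larger for younger participants, with the ASD
# curve shifted toward an effectively younger age (a developmental delay).
.age_factor <- function(age, group, cfg) {
  eff <- ifelse(group == "ASD", age - cfg$asd_age_delay, age)
  1 + cfg$age_slope * (18 - eff)
}

#' Sample a labelled participant cohort
#'
#' Draws participant profiles: diagnostic group, age, a latent motor-severity
#' driver, and clinical covariates linked monotonically to severity
#' (BOT-2 motor percentile decreasing; SRS-2 and RBS-R symptom scores
#' increasing), plus IQ and sex with group-specific distributions.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return Data frame with one row per participant: \code{participant_id},
#'   \code{group} ("ASD"/"TD"), \code{age_years}, \code{latent_severity},
#'   \code{bot2_percentile}, \code{srs2_score}, \code{rbsr_score},
#'   \code{iq}, \code{sex}. Deterministic given \code{config$rng_seed}.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(.hash_seed(config$rng_seed, "cohort"), {
    n <- config$n_asd + config$n_td
    group <- rep(c("ASD", "TD"), c(config$n_asd, config$n_td))
    sev <- numeric(n)
    sev[group == "ASD"] <- stats::rgamma(config$n_asd,
                                         shape = config$severity_shape_asd,
                                         rate = config$severity_rate_asd)
    sev[group == "TD"] <- stats::rgamma(config$n_td,
                                        shape = config$severity_shape_td,
                                        rate = config$severity_rate_td)
    age <- stats::runif(n, 7, 18)
    bot2 <- pmin(99, pmax(1, 45 - 30 * sev + stats::rnorm(n, 0, 10)))
    srs2 <- pmax(0, 40 + 35 * sev + stats::rnorm(n, 0, 8))
    rbsr <- pmax(0, 25 * sev + stats::rnorm(n, 0, 5))
    iq <- ifelse(group == "ASD", stats::rnorm(n, 104, 15),
                 stats::rnorm(n, 112, 10))
    sex <- ifelse(stats::runif(n) < ifelse(group == "ASD", 0.95, 0.74),
                  "M", "F")
    data.frame(participant_id = sprintf("%s%03d", ifelse(group == "ASD",
                                                         "A", "T"),
                                        seq_len(n)),
               group = group, age_years = age, latent_severity = sev,
               bot2_percentile = bot2, srs2_score = srs2, rbsr_score = rbsr,
               iq = iq, sex = sex, stringsAsFactors = FALSE)
  })
}

#' Simulate one pose recording for a participant
#'
#' Generates a T x 62 matrix under the signal model described in
#' \code{\link{simulation_config}}. The recording is reproducible on its
#' own: its RNG stream is seeded by hashing
#' (rng_seed, participant_id, pose_id, session).
#'
#' @param profile One row of the cohort data frame (see
#'   \code{\link{sample_cohort}}).
#' @param pose_id Pose number in \code{1..n_poses}.
#' @param session Session number; must be in \code{config$sessions}.
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{recording}.
#' @export
simulate_recording <- function(profile, pose_id, session, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!(pose_id %in% seq_len(config$n_poses)))
    stop("pose_id ", pose_id, " out of range 1..", config$n_poses)
  if (!(session %in% config$sessions))
    stop("session ", session, " not in configured sessions")
  seed <- .hash_seed(config$rng_seed, profile$participant_id, pose_id,
                     session)
  m <- .with_seed(seed, {
    T <- config$frames_range[1L] +
      sample.int(config$frames_range[2L] - config$frames_range[1L] + 1L,
                 1L) - 1L
    nch <- 62L
    af <- .age_factor(profile$age_years, profile$group, config)
    sd_ch <- rep(config$sigma_base * af, nch)
    sd_ch[config$affected_channels] <-
      sd_ch[config$affected_channels] *
      (1 + config$effect_size_beta * profile$latent_severity)
    # AR(1) sway noise with stationary SD sd_ch; 200-sample burn-in
    burn <- 200L
    innov <- matrix(stats::rnorm((T + burn) * nch), T + burn, nch)
    ar <- stats::filter(innov, config$ar_phi, method = "recursive")
    ar <- ar[(burn + 1L):(burn + T), , drop = FALSE] *
      rep(sd_ch * sqrt(1 - config$ar_phi^2), each = T)
    # slow sinusoidal drift, identical law for both groups
    tt <- (seq_len(T) - 1L) / config$frame_rate_hz
    drift <- matrix(0, T, nch)
    for (k in seq_len(config$drift_components)) {
      f <- stats::runif(nch, config$drift_freq_range[1L],
                        config$drift_freq_range[2L])
      a <- stats::runif(nch, config$drift_amp_range[1L],
                        config$drift_amp_range[2L])
      ph <- stats::runif(nch, 0, 2 * pi)
      phase <- sweep(outer(tt, 2 * pi * f), 2, ph, "+")
      drift <- drift + sweep(sin(phase), 2, a, "*")
    }
    x <- drift + ar
    if (config$jitter_sd > 0)
      x <- x + matrix(stats::rnorm(T * nch, 0, config$jitter_sd), T, nch)
    if (config$p_missing > 0) {
      miss <- stats::runif(T * nch) < config$p_missing
      x[miss] <- NA_real_
    }
    x
  })
  recording(m, participant_id = profile$participant_id, session = session,
            pose_id = pose_id, frame_rate_hz = config$frame_rate_hz)
}

#' Randomly corrupt a recording (whole-file variance blow-up)
#'
#' With probability \code{config$p_corrupt_file}, every channel's deviations
#' from its mean are rescaled by \code{sqrt(corrupt_scale)}, multiplying each
#' channel's variance exactly by \code{corrupt_scale}. This emulates files
#' ruined by equipment malfunction, which the variance QC stage is meant to
#' catch. The draw uses the current RNG stream.
#'
#' @param rec A \code{recording}.
#' @param config A \code{\link{simulation_config}}.
#' @return The (possibly rescaled) recording, with attribute
#'   \code{"corrupted"} giving the ground-truth flag.
#' @export
corrupt_recording <- function(rec, config) {
  stopifnot(inherits(rec, "recording"))
  hit <- config$p_corrupt_file > 0 &&
    stats::runif(1) < config$p_corrupt_file
  if (hit) {
    mu <- colMeans(rec$data, na.rm = TRUE)
    rec$data <- sweep(sweep(rec$data, 2, mu, "-") * sqrt(config$corrupt_scale),
                      2, mu, "+")
  }
  attr(rec, "corrupted") <- hit
  rec
}

#' Simulate a full dataset in memory
#'
#' Samples a cohort and simulates one recording per
#' (participant, session, pose), applying the file-corruption process.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param cohort Optional pre-sampled cohort data frame; defaults to
#'   \code{sample_cohort(config)}.
#' @return List with \code{recordings} (list of \code{recording}),
#'   \code{manifest} (data frame incl. the \code{corrupted} ground truth and
#'   covariates) and \code{cohort}.
#' @export
simulate_dataset <- function(config, cohort = sample_cohort(config)) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- expand.grid(pose_id = seq_len(config$n_poses),
                      session = config$sessions,
                      row = seq_len(nrow(cohort)))
  recs <- vector("list", nrow(grid))
  corrupted <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    prof <- cohort[grid$row[i], ]
    rec <- simulate_recording(prof, grid$pose_id[i], grid$session[i], config)
    rec <- .with_seed(.hash_seed(config$rng_seed, prof$participant_id,
                                 grid$pose_id[i], grid$session[i], "corrupt"),
                      corrupt_recording(rec, config))
    corrupted[i] <- attr(rec, "corrupted")
    recs[[i]] <- rec
  }
  manifest <- data.frame(
    participant_id = cohort$participant_id[grid$row],
    group = cohort$group[grid$row],
    session = grid$session, pose_id = grid$pose_id,
    path = NA_character_, corrupted = corrupted,
    cohort[grid$row, c("age_years", "latent_severity", "bot2_percentile",
                       "srs2_score", "rbsr_score", "iq", "sex")],
    stringsAsFactors = FALSE, row.names = NULL)
  list(recordings = recs, manifest = manifest, cohort = cohort)
}

#' Generate a dataset on disk
#'
#' Like \code{\link{simulate_dataset}} but writes each recording as a
#' tab-delimited file named \code{p<participant>_s<session>_pose<pose>.tsv}
#' under \code{output_dir}, plus a \code{manifest.tsv}. Regeneration with the
#' same config is byte-identical.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param output_dir Writable directory (created if absent).
#' @return The manifest data frame (with resolvable \code{path}s),
#'   invisibly also written to \code{manifest.tsv}.
#' @export
generate_dataset <- function(config, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) stop("cannot create directory: ", output_dir)
  ds <- simulate_dataset(config)
  paths <- file.path(output_dir,
                     sprintf("p%s_s%d_pose%d.tsv",
                             ds$manifest$participant_id,
                             ds$manifest$session, ds$manifest$pose_id))
  for (i in seq_along(ds$recordings))
    write_recording(ds$recordings[[i]], paths[i])
  ds$manifest$path <- paths
  write_manifest(ds$manifest, file.path(output_dir, "manifest.tsv"))
  ds$manifest
}
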