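#' Cleaning configuration
#'
#' Parameters of the four-stage pre-processing pipeline applied to every
#' recording: forward-fill imputation, multilevel Haar wavelet denoising,
#' middle trimming, and exponential-tail variance quality control across the
#' files of each pose.
#'
#' @param wavelet_level Number of Haar decomposition levels whose detail
#'   coefficients are discarded (default 5); the retained series is the
#'   level-L approximation, decimated by \code{2^L}.
#' @param trim_max_len Maximum series length kept, counted in post-wavelet
#'   samples (default 10000); longer series are trimmed to their centred
#'   window.
#' @param qc_tail Tail probability of the fitted exponential distribution
#'   beyond which a file's channel variance counts as an extreme outlier
#'   (default 1e-7).
#' @param amplitude_preserve If \code{TRUE} (default) approximation
#'   coefficients are rescaled by \code{2^(-L/2)} so they equal dyadic block
#'   means and keep the original amplitude scale.
#' @return An object of class \code{"cleaning_config"}.
#' @export
cleaning_config <- function(wavelet_level = 5, trim_max_len = 10000,
                            qc_tail = 1e-7, amplitude_preserve = TRUE) {
  stopifnot(wavelet_level >= 1, trim_max_len >= 1,
            qc_tail > 0, qc_tail < 1)
  structure(list(wavelet_level = as.integer(wavelet_level),
                 trim_max_len = as.integer(trim_max_len),
                 qc_tail = qc_tail,
                 amplitude_preserve = isTRUE(amplitude_preserve)),
            class = "cleaning_config")
}

#' Forward-fill missing samples
#'
#' Each missing value is replaced by the nearest preceding valid value.
#' Leading missing values (no preceding valid sample) are back-filled from
#' the first valid value. A channel with no valid sample at all is an error.
#' Accepts a vector or a matrix (filled column-wise).
#'
#' @param x Numeric vector or matrix with \code{NA} marking missing samples.
#' @return Same shape as \code{x}, with no missing values. Idempotent.
#' @export
#' @examples
#' forward_fill(c(1, NA, NA, 4))  # 1 1 1 4
forward_fill <- function(x) {
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- forward_fill(x[, j])
    return(x)
  }
  ok <- !is.na(x)
  if (!any(ok)) stop("cleaning error: channel is entirely missing")
  idx <- cumsum(ok)
  lead <- idx == 0L
  idx[lead] <- 1L
  x <- x[which(ok)[idx]]
  x
}

#' Multilevel Haar wavelet denoising
#'
#' Applies L levels of the Haar discrete wavelet transform and keeps only
#' the level-L approximation (lowpass) component, discarding the
#' high-frequency detail at every level. With
#' \code{amplitude_preserve = TRUE} the approximation coefficients are
#' rescaled by \code{2^(-L/2)}, making them dyadic block means on the
#' original amplitude scale. Odd lengths are handled by half-sample
#' symmetric padding (the last sample is repeated), so each level maps
#' length T to \code{ceiling(T/2)}.
#'
#' If \code{T < 2^L} the level is reduced to \code{floor(log2(T))} with a
#' warning.
#'
#' @param x Numeric vector or matrix (transformed column-wise), no missing
#'   values, \code{T >= 2}.
#' @param level Decomposition level L (>= 1).
#' @param amplitude_preserve See above; default \code{TRUE}.
#' @return Vector/matrix of length \code{ceiling(T/2^L)} (per column).
#' @export
#' @examples
#' haar_denoise(c(1, 3, 5, 7), 1)  # 2 6
#' haar_denoise(c(1, 3, 5, 7), 2)  # 4
haar_denoise <- function(x, level, amplitude_preserve = TRUE) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  T <- nrow(x)
  if (T < 2L) stop("cleaning error: series too short for wavelet transform")
  stopifnot(level >= 1)
  level <- as.integer(level)
  if (T < 2^level) {
    level <- max(1L, floor(log2(T)))
    warning("series length ", T, " < 2^L; reducing wavelet level to ", level)
  }
  for (l in seq_len(level)) {
    n <- nrow(x)
    if (n %% 2L == 1L) x <- rbind(x, x[n, , drop = FALSE])
    odd <- seq(1L, nrow(x), by = 2L)
    x <- (x[odd, , drop = FALSE] + x[odd + 1L, , drop = FALSE]) / 2
  }
  if (!amplitude_preserve) x <- x * 2^(level / 2)
  if (vec) x[, 1L] else x
}

#' Trim a series to its centred window
#'
#' Series longer than \code{max_len} samples are cut down to the centred
#' window of exactly \code{max_len} samples, starting at 0-based index
#' \code{floor((T - max_len)/2)}; shorter series pass through unchanged.
#' This drops the non-task movement recorded before and after the pose.
#'
#' @param x Numeric vector or matrix (trimmed row-wise).
#' @param max_len Maximum length kept.
#' @return The trimmed series.
#' @export
trim_middle <- function(x, max_len) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  T <- nrow(x)
  if (T > max_len) {
    s <- floor((T - max_len) / 2)
    x <- x[(s + 1L):(s + max_len), , drop = FALSE]
  }
  if (vec) x[, 1L] else x
}

#' Exponential-tail variance quality control
#'
#' For each pose, fits an exponential distribution (by maximum likelihood,
#' i.e. rate = 1/mean) to each channel's variances across that pose's files
#' and discards any file with at least one channel variance beyond the
#' \code{qc_tail} upper tail of its fitted distribution, i.e. beyond
#' \code{mean * log(1/qc_tail)}. The fit uses all files of the pose in a
#' single pass (no re-fit after discards). Poses with fewer than two files
#' are skipped with a warning.
#'
#' Variances are population variances (divide by n), matching the feature
#' stage.
#'
#' @param recordings List of cleaned \code{recording} objects.
#' @param qc_tail Tail probability (default 1e-7).
#' @return List with \code{kept} (the surviving recordings) and \code{report}
#'   (class \code{"qc_report"}): per-pose fitted means and thresholds per
#'   channel, the discarded files with their offending channels, and the
#'   overall discard fraction.
#' @export
variance_qc <- function(recordings, qc_tail = 1e-7) {
  stopifnot(length(recordings) >= 1)
  poses <- vapply(recordings, function(r) r$pose_id, integer(1))
  vars <- t(vapply(recordings, function(r) .col_pop_var(r$data),
                   numeric(ncol(recordings[[1L]]$data))))
  discard <- logical(length(recordings))
  per_pose <- list()
  discarded_rows <- list()
  for (p in sort(unique(poses))) {
    idx <- which(poses == p)
    if (length(idx) < 2L) {
      warning("variance QC skipped for pose ", p, ": fewer than 2 files")
      per_pose[[as.character(p)]] <- list(skipped = TRUE)
      next
    }
    mean_d <- colMeans(vars[idx, , drop = FALSE])
    thr <- mean_d * log(1 / qc_tail)
    for (i in idx) {
      over <- which(vars[i, ] > thr)
      if (length(over)) {
        discard[i] <- TRUE
        r <- recordings[[i]]
        discarded_rows[[length(discarded_rows) + 1L]] <-
          data.frame(participant_id = r$participant_id,
                     session = r$session, pose_id = r$pose_id,
                     offending_channels = paste(
                       colnames(r$data)[over], collapse = ","),
                     stringsAsFactors = FALSE)
      }
    }
    per_pose[[as.character(p)]] <-
      list(skipped = FALSE, mean_variance = mean_d, threshold = thr)
  }
  report <- structure(
    list(per_pose = per_pose,
         discarded = if (length(discarded_rows))
           do.call(rbind, discarded_rows)
         else data.frame(participant_id = character(), session = integer(),
                         pose_id = integer(),
                         offending_channels = character()),
         n_input = length(recordings), n_discarded = sum(discard),
         discard_fraction = sum(discard) / length(recordings)),
    class = "qc_report")
  list(kept = recordings[!discard], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d files discarded (%.1f%%)\n",
              x$n_discarded, x$n_input, 100 * x$discard_fraction))
  if (nrow(x$discarded)) print(utils::head(x$discarded, 10))
  invisible(x)
}

#' Clean a dataset of recordings
#'
#' Applies the full pre-processing pipeline in order: forward-fill
#' imputation, Haar denoising (decimating by \code{2^L} and dividing the
#' effective frame rate accordingly), middle trimming, then
#' pose-wise variance QC across recordings.
#'
#' @param recordings List of \code{recording} objects.
#' @param config A \code{\link{cleaning_config}}.
#' @return List with \code{recordings} (cleaned survivors) and \code{qc}
#'   (the \code{qc_report}).
#' @export
clean_dataset <- function(recordings, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  cleaned <- lapply(recordings, function(r) {
    m <- forward_fill(r$data)
    m <- haar_denoise(m, config$wavelet_level,
                      amplitude_preserve = config$amplitude_preserve)
    m <- trim_middle(m, config$trim_max_len)
    r$data <- m
    r$frame_rate_hz <- r$frame_rate_hz / 2^config$wavelet_level
    r
  })
  qc <- variance_qc(cleaned, config$qc_tail)
  list(recordings = qc$kept, qc = qc$report)
}
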