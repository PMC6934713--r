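#' Feature-extraction configuration
#'
#' @param window_size Sliding-window length W in samples (default 20).
#' @param window_shift Shift S between consecutive windows (default 10).
#' @param entropy_bins Number of equal-width histogram bins B for the
#'   entropy estimate (default 10).
#' @param entropy_base Logarithm base of the entropy: \code{"nat"}
#'   (natural log, default) or \code{"bit"} (log2).
#' @return An object of class \code{"feature_config"}.
#' @export
feature_config <- function(window_size = 20, window_shift = 10,
                           entropy_bins = 10,
                           entropy_base = c("nat", "bit")) {
  entropy_base <- match.arg(entropy_base)
  stopifnot(window_size >= 2, window_shift >= 1, entropy_bins >= 2)
  structure(list(window_size = as.integer(window_size),
                 window_shift = as.integer(window_shift),
                 entropy_bins = as.integer(entropy_bins),
                 entropy_base = entropy_base),
            class = "feature_config")
}

#' Sliding-window bounds
#'
#' Half-open, 0-based intervals \code{[0, W), [S, S+W), ...} while the end
#' does not exceed T. A series shorter than one window yields no intervals.
#'
#' @param T Series length.
#' @param W Window size.
#' @param S Window shift.
#' @return Integer matrix with columns \code{start} and \code{end}
#'   (0 rows if \code{T < W}).
#' @export
#' @examples
#' window_bounds(100, 20, 10)  # 9 windows, last [80, 100)
window_bounds <- function(T, W, S) {
  if (T < W)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  starts <- seq(0L, T - W, by = S)
  cbind(start = starts, end = starts + W)
}

#' Population variance of a window
#'
#' Variance with divisor W (not W - 1); spread of the samples inside one
#' sliding window. Missing values violate the contract (cleaning must
#' precede feature extraction).
#'
#' @param values Numeric vector (one window of one channel).
#' @return Non-negative scalar.
#' @export
#' @examples
#' window_variance(c(1, 2, 3, 4))  # 1.25
window_variance <- function(values) {
  if (anyNA(values))
    stop("window contains missing values; clean the data first")
  mu <- mean(values)
  mean((values - mu)^2)
}

#' Histogram Shannon entropy of a window
#'
#' Shannon entropy of the empirical distribution over \code{bins}
#' equal-width bins spanning the window's own range
#' \code{[min(values), max(values)]}; \code{0 * log 0 := 0}. A constant
#' window (zero range) has entropy 0. Natural log by default.
#'
#' @param values Numeric vector (one window of one channel), no missing
#'   values.
#' @param bins Number of equal-width bins B.
#' @param base \code{"nat"} or \code{"bit"}.
#' @return Entropy in \code{[0, log(B)]}.
#' @export
#' @examples
#' window_entropy(rep(1:10 / 10, each = 2), 10)  # log(10)
window_entropy <- function(values, bins = 10, base = c("nat", "bit")) {
  base <- match.arg(base)
  if (anyNA(values))
    stop("window contains missing values; clean the data first")
  rng <- range(values)
  span <- rng[2L] - rng[1L]
  if (span == 0) return(0)
  idx <- pmin(bins, floor((values - rng[1L]) / span * bins) + 1L)
  p <- tabulate(idx, bins) / length(values)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (base == "bit") h / log(2) else h
}

#' Featurize one cleaned recording
#'
#' Slides a fixed window over the recording and computes, for every window,
#' the entropy and the variance of each channel, yielding one feature vector
#' of length 2 x (number of channels) per window (124 with the full
#' 62-channel schema). Row k corresponds to window k; columns are the
#' entropies of all channels in schema order followed by the variances.
#'
#' @param rec A cleaned \code{recording}.
#' @param config A \code{\link{feature_config}}.
#' @return Numeric matrix \code{n_windows x 2*n_channels} with feature
#'   names as column names (possibly 0 rows if the recording is shorter
#'   than one window, with a warning).
#' @export
featurize_recording <- function(rec, config = feature_config()) {
  stopifnot(inherits(rec, "recording"), inherits(config, "feature_config"))
  m <- rec$data
  if (anyNA(m))
    stop("recording contains missing values; clean the data first")
  wb <- window_bounds(nrow(m), config$window_size, config$window_shift)
  fn <- feature_names(colnames(m))
  out <- matrix(numeric(0), nrow = nrow(wb), ncol = length(fn),
                dimnames = list(NULL, fn))
  if (nrow(wb) == 0L) {
    warning("recording shorter than one window (", nrow(m), " < ",
            config$window_size, "); contributes no feature vectors")
    return(out)
  }
  nch <- ncol(m)
  for (k in seq_len(nrow(wb))) {
    w <- m[(wb[k, "start"] + 1L):wb[k, "end"], , drop = FALSE]
    ent <- vapply(seq_len(nch), function(j)
      window_entropy(w[, j], config$entropy_bins, config$entropy_base),
      numeric(1))
    out[k, ] <- c(ent, .col_pop_var(w))
  }
  out
}

#' Featurize a dataset of recordings
#'
#' Applies \code{\link{featurize_recording}} to every recording and stacks
#' the resulting vectors, tracking which (participant, session, pose) each
#' row belongs to.
#'
#' @param recordings List of cleaned \code{recording} objects.
#' @param participants Optional data frame of participant metadata (must
#'   contain \code{participant_id} and \code{group}); required for training
#'   and evaluation.
#' @param config A \code{\link{feature_config}}.
#' @return An object of class \code{"movement_features"}: list with
#'   \code{features} (n x p matrix), \code{meta} (data frame with one row
#'   per feature vector: participant_id, session, pose_id) and
#'   \code{participants}.
#' @export
featurize_dataset <- function(recordings, participants = NULL,
                              config = feature_config()) {
  mats <- lapply(recordings, featurize_recording, config = config)
  nrows <- vapply(mats, nrow, integer(1))
  keep <- nrows > 0L
  if (!any(keep))
    stop("no recording is long enough to contribute a feature vector")
  meta <- do.call(rbind, lapply(which(keep), function(i) {
    r <- recordings[[i]]
    data.frame(participant_id = r$participant_id, session = r$session,
               pose_id = r$pose_id, stringsAsFactors = FALSE)[
                 rep(1L, nrows[i]), , drop = FALSE]
  }))
  rownames(meta) <- NULL
  structure(list(features = do.call(rbind, mats[keep]), meta = meta,
                 participants = participants),
            class = "movement_features")
}

#' @export
print.movement_features <- function(x, ...) {
  cat(sprintf("<movement_features> %d vectors x %d features, %d participants, %d poses\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$meta$participant_id)),
              length(unique(x$meta$pose_id))))
  invisible(x)
}

#' Subset a feature set to chosen participants
#'
#' @param x A \code{movement_features} object.
#' @param ids Participant ids to keep.
#' @return A \code{movement_features} restricted to those participants.
#' @export
filter_participants <- function(x, ids) {
  stopifnot(inherits(x, "movement_features"))
  keep <- x$meta$participant_id %in% ids
  structure(list(features = x$features[keep, , drop = FALSE],
                 meta = x$meta[keep, , drop = FALSE],
                 participants = if (!is.null(x$participants))
                   x$participants[x$participants$participant_id %in% ids, ,
                                  drop = FALSE]
                 else NULL),
            class = "movement_features")
}
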