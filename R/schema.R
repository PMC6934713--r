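#' Canonical channel schema
#'
#' Each recording carries 62 channels: the 3D positions of 20 markerless
#' skeleton joints followed by the 2D centre-of-pressure position reported by
#' the balance board. The joint order is fixed: head, shoulder_center,
#' shoulder_L, shoulder_R, elbow_L, elbow_R, wrist_L, wrist_R, hand_L,
#' hand_R, spine, hip_center, hip_L, hip_R, knee_L, knee_R, ankle_L,
#' ankle_R, foot_L, foot_R; each joint contributes an x, y and z channel,
#' and the board contributes \code{board:x} and \code{board:y}.
#'
#' @return Character vector of the 62 canonical channel names, in order.
#' @export
#' @examples
#' head(channel_names())
channel_names <- function() {
  joints <- c(
    "head", "shoulder_center", "shoulder_L", "shoulder_R",
    "elbow_L", "elbow_R", "wrist_L", "wrist_R", "hand_L", "hand_R",
    "spine", "hip_center", "hip_L", "hip_R", "knee_L", "knee_R",
    "ankle_L", "ankle_R", "foot_L", "foot_R"
  )
  c(as.vector(t(outer(joints, c("x", "y", "z"), paste, sep = ":"))),
    "board:x", "board:y")
}

#' Canonical feature names for a channel set
#'
#' Features are the window entropy of every channel followed by the window
#' variance of every channel, giving 2 x (number of channels) names. With the
#' full 62-channel schema this is the 124-name vocabulary used in importance
#' reports, e.g. \code{"entropy:foot_L:y"} or \code{"variance:board:x"}.
#'
#' @param channels Character vector of channel names
#'   (default \code{channel_names()}).
#' @return Character vector, entropies first, then variances.
#' @export
feature_names <- function(channels = channel_names()) {
  c(paste0("entropy:", channels), paste0("variance:", channels))
}

#' Channels carrying the simulated group effect by default
#'
#' The default affected set mirrors the body regions most often reported as
#' informative (head, both shoulders, both feet, and the two board sway
#' channels): 17 of the 62 channels.
#'
#' @return Integer indices into \code{channel_names()}.
#' @export
default_affected_channels <- function() {
  ch <- channel_names()
  which(grepl("^(head|shoulder_L|shoulder_R|foot_L|foot_R|board):", ch))
}

# Deterministic 31-bit hash of a character key, for deriving per-recording
# seeds. Plain polynomial rolling hash; all arithmetic kept in doubles well
# below 2^53 so it is exact.
.hash_seed <- function(...) {
  key <- paste(..., sep = "\r")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Column-wise population variance (divide by n) of a numeric matrix.
.col_pop_var <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  colMeans(m * m) - mu * mu
}
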