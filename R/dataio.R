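#' Construct a movement recording
#'
#' A recording is one performance of one balance pose by one participant: a
#' T x 62 numeric matrix (frames x channels) plus identifying metadata.
#' Missing samples are stored as \code{NA}.
#'
#' @param data Numeric matrix with one column per channel; column names are
#'   set to \code{channels}.
#' @param participant_id Participant identifier string.
#' @param session Integer training-session number.
#' @param pose_id Integer pose number (1-based).
#' @param frame_rate_hz Sampling rate of the rows, in Hz.
#' @param channels Channel-name vector; defaults to the canonical 62-name
#'   schema.
#' @return An object of class \code{"recording"}.
#' @export
recording <- function(data, participant_id, session, pose_id,
                      frame_rate_hz = 30, channels = channel_names()) {
  data <- as.matrix(data)
  if (ncol(data) != length(channels))
    stop("recording must have ", length(channels), " columns, got ",
         ncol(data))
  if (nrow(data) < 1) stop("recording must have at least one frame")
  colnames(data) <- channels
  structure(
    list(participant_id = as.character(participant_id),
         session = as.integer(session), pose_id = as.integer(pose_id),
         frame_rate_hz = frame_rate_hz, data = data),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> participant %s, session %d, pose %d: %d frames x %d channels @ %.4g Hz\n",
              x$participant_id, x$session, x$pose_id,
              nrow(x$data), ncol(x$data), x$frame_rate_hz))
  invisible(x)
}

#' Write a recording as a delimited text file
#'
#' Tab-delimited, one header row of channel names, one row per frame.
#' Missing cells are written as the literal token \code{NaN}. Values are
#' written with 17 significant digits so that a write/read round trip is
#' bit-exact.
#'
#' @param rec A \code{recording}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  m <- rec$data
  body <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  body[is.na(m)] <- "NaN"
  lines <- c(paste(colnames(m), collapse = "\t"),
             apply(body, 1L, paste, collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a recording from a delimited text file
#'
#' Validates the header against an expected channel schema and parses all
#' cells as numbers (\code{NaN} marks a missing sample, stored as \code{NA}).
#' Both LF and CRLF line endings are accepted. Metadata defaults are parsed
#' from the filename pattern \code{p<participant>_s<session>_pose<pose>.tsv}
#' when not supplied.
#'
#' @param path Input file path.
#' @param participant_id,session,pose_id Optional metadata overriding the
#'   filename pattern.
#' @param frame_rate_hz Sampling rate to record (default 30).
#' @param channels Expected channel schema (default the canonical 62 names).
#' @return A \code{recording}.
#' @export
read_recording <- function(path, participant_id = NULL, session = NULL,
                           pose_id = NULL, frame_rate_hz = 30,
                           channels = channel_names()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("format error in ", path, ": no data rows (need T >= 1)")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) != length(channels))
    stop("format error in ", path, ": expected ", length(channels),
         " columns, found ", length(header))
  if (!identical(header, channels))
    stop("format error in ", path, ": header does not match channel schema")
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncell <- lengths(cells)
  if (any(ncell != length(channels))) {
    bad <- which(ncell != length(channels))[1L]
    stop("format error in ", path, ": row ", bad, " has ", ncell[bad],
         " cells")
  }
  flat <- unlist(cells, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(flat))
  bad <- which(is.na(vals) & flat != "NaN")
  if (length(bad)) {
    i <- bad[1L] - 1L
    stop("format error in ", path, ": unparseable cell at row ",
         i %/% length(channels) + 1L, ", col ", i %% length(channels) + 1L)
  }
  vals[flat == "NaN"] <- NA_real_
  m <- matrix(vals, ncol = length(channels), byrow = TRUE)
  meta <- .parse_recording_filename(path)
  recording(m,
            participant_id = participant_id %||% meta$participant_id,
            session = session %||% meta$session,
            pose_id = pose_id %||% meta$pose_id,
            frame_rate_hz = frame_rate_hz, channels = channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_recording_filename <- function(path) {
  base <- basename(path)
  m <- regmatches(base,
                  regexec("^p(.+)_s([0-9]+)_pose([0-9]+)\\.", base))[[1L]]
  if (length(m) == 4L)
    list(participant_id = m[2L], session = as.integer(m[3L]),
         pose_id = as.integer(m[4L]))
  else list(participant_id = base, session = NA_integer_,
            pose_id = NA_integer_)
}

#' Write / read a dataset manifest
#'
#' The manifest is a tab-delimited table with one row per recording file:
#' participant_id, group, session, pose_id, path, corrupted flag, and the
#' participant covariates.
#'
#' @param manifest Data frame of records.
#' @param path File path.
#' @return \code{write_manifest}: \code{path} invisibly;
#'   \code{read_manifest}: the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Load recordings listed in a manifest, restricted to chosen sessions
#'
#' @param manifest Manifest data frame (from \code{\link{read_manifest}} or
#'   \code{\link{generate_dataset}}).
#' @param sessions Integer vector of sessions to keep, e.g. \code{2:4}.
#' @param frame_rate_hz Sampling rate recorded on each loaded recording.
#' @return List of \code{recording} objects.
#' @export
load_dataset <- function(manifest, sessions, frame_rate_hz = 30) {
  keep <- manifest[manifest$session %in% sessions, , drop = FALSE]
  if (nrow(keep) == 0L) return(list())
  missing <- keep$path[!file.exists(keep$path)]
  if (length(missing))
    stop("missing recording files: ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(keep)), function(i)
    read_recording(keep$path[i],
                   participant_id = keep$participant_id[i],
                   session = keep$session[i], pose_id = keep$pose_id[i],
                   frame_rate_hz = frame_rate_hz))
}
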