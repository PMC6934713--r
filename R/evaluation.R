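#' Stratified participant-level fold assignment
#'
#' Splits participants into k folds so that each fold's ASD:TD counts
#' differ from exact proportionality by at most one participant per class.
#' All of a participant's recordings stay in the same fold. Deterministic
#' given \code{seed}.
#'
#' @param participants Data frame with \code{participant_id} and
#'   \code{group} columns.
#' @param k Number of folds (default 5); must not exceed the smaller class.
#' @param seed Integer seed.
#' @return Named integer vector: participant_id -> fold (1..k).
#' @export
stratified_folds <- function(participants, k = 5, seed = 1L) {
  stopifnot(all(c("participant_id", "group") %in% names(participants)))
  sizes <- table(participants$group)
  if (k > min(sizes))
    stop("configuration error: k = ", k,
         " exceeds the smaller class size (", min(sizes), ")")
  if (k == 1L) warning("k = 1 gives a single degenerate fold")
  fold <- integer(nrow(participants))
  .with_seed(.hash_seed(seed, "folds"), {
    for (g in unique(participants$group)) {
      idx <- which(participants$group == g)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  stats::setNames(fold, participants$participant_id)
}

#' Confusion counts with ASD as the positive class
#'
#' @param truth Character vector of true labels ("ASD"/"TD").
#' @param predicted Character vector of predicted labels.
#' @return Named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  c(TP = sum(truth == "ASD" & predicted == "ASD"),
    FP = sum(truth == "TD" & predicted == "ASD"),
    TN = sum(truth == "TD" & predicted == "TD"),
    FN = sum(truth == "ASD" & predicted == "TD"))
}

#' Binary classification metrics from confusion counts
#'
#' Standard definitions with ASD as the positive class:
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' specificity = TN/(TN+FP), F1 = 2PR/(P+R), and Matthews correlation
#' coefficient
#' \deqn{MCC = (TP TN - FP FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' Any 0/0 is reported as 0 by convention.
#'
#' @param counts Named vector or list with \code{TP}, \code{FP}, \code{TN},
#'   \code{FN}.
#' @return Named numeric vector: precision, recall, specificity, mcc, f1.
#' @export
#' @examples
#' classification_metrics(c(TP = 8, FP = 2, TN = 3, FN = 0))
classification_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  c(precision = precision, recall = recall, specificity = specificity,
    mcc = mcc, f1 = f1)
}

#' Drop the z-axis joint channels from recordings
#'
#' Keeps only the x and y coordinates of the 20 joints plus the two board
#' sway channels (42 channels, hence 84 downstream features). Used for the
#' differential experiment probing sensitivity to the depth axis.
#'
#' @param recordings A \code{recording} or list of recordings.
#' @return Same shape as the input, with z channels removed.
#' @export
project_xy <- function(recordings) {
  drop_z <- function(r) {
    keep <- !grepl(":z$", colnames(r$data))
    r$data <- r$data[, keep, drop = FALSE]
    r
  }
  if (inherits(recordings, "recording")) drop_z(recordings)
  else lapply(recordings, drop_z)
}

#' Subsample to balanced group sizes
#'
#' Keeps every TD participant and a uniform random subset of
#' \code{n_per_group} ASD participants (seeded). Used for the balanced
#' differential experiment.
#'
#' @param x A \code{movement_features} object with participant labels.
#' @param n_per_group Target participants per group.
#' @param seed Integer seed.
#' @return A \code{movement_features} restricted to the balanced cohort.
#' @export
balance_groups <- function(x, n_per_group, seed = 1L) {
  stopifnot(inherits(x, "movement_features"), !is.null(x$participants))
  asd <- x$participants$participant_id[x$participants$group == "ASD"]
  td <- x$participants$participant_id[x$participants$group == "TD"]
  if (n_per_group > length(asd) || n_per_group > length(td))
    stop("configuration error: n_per_group = ", n_per_group,
         " exceeds a group size")
  keep_asd <- .with_seed(.hash_seed(seed, "balance"),
                         sample(asd, n_per_group))
  filter_participants(x, c(keep_asd, td))
}

#' Stratified k-fold cross-validation of the full classification pipeline
#'
#' Participant-level CV: for each fold the ensemble is trained on the other
#' folds' feature vectors and the held-out participants are classified by
#' two-level majority voting. Reports per-fold confusion counts, metrics and
#' top-k MDI feature lists, unweighted fold-mean metrics, and each
#' participant's out-of-fold boundary distance.
#'
#' @param x A \code{movement_features} object with participant labels.
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment and per-fold model training.
#' @param params \code{\link{forest_params}} template; each fold's models
#'   derive their seed from \code{seed} and the fold number.
#' @param top_k Length of the per-fold importance list (default 20).
#' @param prob_method Passed to \code{\link{predict.movement_ensemble}}.
#' @return Object of class \code{"movement_cv"}: \code{fold_assignments},
#'   \code{per_fold} (counts, metrics, top features), \code{averages},
#'   \code{predictions} (out-of-fold, one row per participant, with truth).
#' @export
run_cv <- function(x, k = 5, seed = 1L, params = forest_params(),
                   top_k = 20, prob_method = "mean_score") {
  stopifnot(inherits(x, "movement_features"), !is.null(x$participants))
  folds <- stratified_folds(x$participants, k, seed)
  per_fold <- list()
  preds <- list()
  for (f in seq_len(k)) {
    test_ids <- names(folds)[folds == f]
    train_ids <- names(folds)[folds != f]
    fp <- params
    fp$rng_seed <- .hash_seed(seed, "fold", f)
    model <- movement_ensemble(filter_participants(x, train_ids), fp)
    pr <- predict(model, filter_participants(x, test_ids),
                  prob_method = prob_method)
    truth <- x$participants$group[match(pr$participant_id,
                                        x$participants$participant_id)]
    counts <- confusion_counts(truth, pr$final_label)
    pr$truth <- truth
    pr$fold <- f
    preds[[f]] <- pr
    per_fold[[f]] <- list(fold = f, counts = counts,
                          metrics = classification_metrics(counts),
                          top_features = top_features(total_mdi(model),
                                                      top_k))
  }
  predictions <- do.call(rbind, lapply(preds, as.data.frame))
  rownames(predictions) <- NULL
  averages <- colMeans(do.call(rbind,
                               lapply(per_fold, `[[`, "metrics")))
  structure(list(k = k, seed = seed, fold_assignments = folds,
                 per_fold = per_fold, averages = averages,
                 predictions = predictions),
            class = "movement_cv")
}

#' @export
print.movement_cv <- function(x, digits = 2, ...) {
  cat(sprintf("<movement_cv> stratified %d-fold cross-validation\n", x$k))
  tab <- do.call(rbind, lapply(x$per_fold, function(pf) {
    m <- pf$metrics; ct <- pf$counts
    data.frame(fold = pf$fold,
               precision = sprintf("%.2f (%d/%d)", m["precision"],
                                   ct["TP"], ct["TP"] + ct["FP"]),
               recall = sprintf("%.2f (%d/%d)", m["recall"], ct["TP"],
                                ct["TP"] + ct["FN"]),
               specificity = sprintf("%.2f (%d/%d)", m["specificity"],
                                     ct["TN"], ct["TN"] + ct["FP"]),
               mcc = sprintf("%.2f", m["mcc"]),
               f1 = sprintf("%.2f", m["f1"]))
  }))
  print(tab, row.names = FALSE)
  cat("Average:",
      paste(sprintf("%s %.2f", names(x$averages), x$averages),
            collapse = ", "), "\n")
  invisible(x)
}
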