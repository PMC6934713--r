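#' Random-forest hyperparameters for the pose-wise ensemble
#'
#' Each pose's classifier is a random forest of bootstrap-trained CART
#' trees with Gini splitting. The original analysis does not publish its
#' tree-training settings, so standard random-forest practice is adopted and
#' every knob is exposed and recorded in the fitted model's metadata.
#'
#' @param n_trees Trees per forest (default 10).
#' @param min_samples_leaf Minimum terminal-node size (default 5).
#' @param features_per_split Candidate features per split; default
#'   \code{floor(sqrt(p))} at fit time (11 for 124 features), signalled by
#'   \code{NULL}.
#' @param max_depth Maximum tree depth; \code{NULL} (default) means
#'   unbounded. (Mapped to a node-count cap \code{2^max_depth} when set.)
#' @param bootstrap Sample with replacement before each tree (default
#'   \code{TRUE}).
#' @param rng_seed Seed from which each pose forest's RNG stream is derived.
#' @return An object of class \code{"forest_params"}.
#' @export
forest_params <- function(n_trees = 10, min_samples_leaf = 5,
                          features_per_split = NULL, max_depth = NULL,
                          bootstrap = TRUE, rng_seed = 1L) {
  stopifnot(n_trees >= 1, min_samples_leaf >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 features_per_split = features_per_split,
                 max_depth = max_depth, bootstrap = isTRUE(bootstrap),
                 rng_seed = as.integer(rng_seed)),
            class = "forest_params")
}

#' Train one pose-specific random forest
#'
#' Fits \code{n_trees} CART trees on bootstrap resamples of the pose's
#' feature vectors with Gini splitting over \code{features_per_split}
#' random candidates per node, retaining per-feature impurity-decrease
#' bookkeeping for MDI ranking. Deterministic given
#' \code{params$rng_seed}.
#'
#' @param vectors Numeric matrix (n vectors x p features).
#' @param labels Character or factor vector of \code{"ASD"}/\code{"TD"}
#'   labels, one per vector; both classes must be present.
#' @param params A \code{\link{forest_params}}.
#' @param pose_id Pose number, used in error messages and seed derivation.
#' @return A fitted \code{randomForest} object.
#' @export
train_pose_forest <- function(vectors, labels, params = forest_params(),
                              pose_id = NA) {
  labels <- factor(as.character(labels), levels = c("TD", "ASD"))
  if (length(unique(labels)) < 2L)
    stop("training error for pose ", pose_id,
         ": only one class present in training data")
  stopifnot(nrow(vectors) == length(labels))
  p <- ncol(vectors)
  mtry <- params$features_per_split %||% max(1L, floor(sqrt(p)))
  maxnodes <- if (is.null(params$max_depth)) NULL else
    2L^as.integer(params$max_depth)
  .with_seed(.hash_seed(params$rng_seed, "pose", pose_id), {
    randomForest::randomForest(
      x = vectors, y = labels, ntree = params$n_trees, mtry = mtry,
      nodesize = params$min_samples_leaf, maxnodes = maxnodes,
      replace = params$bootstrap, importance = FALSE)
  })
}

#' Score feature vectors with a pose forest
#'
#' The forest score of a vector is the average of the individual trees'
#' decisions: the fraction of trees classifying the vector as ASD, in
#' \code{[0, 1]}.
#'
#' @param forest A fitted pose forest (from \code{\link{train_pose_forest}}).
#' @param vectors Numeric matrix of feature vectors (p columns matching the
#'   training features).
#' @return Numeric vector of ASD scores in \code{[0, 1]}.
#' @export
score_vectors <- function(forest, vectors) {
  if (ncol(vectors) != length(forest$forest$ncat))
    stop("feature dimensionality ", ncol(vectors),
         " does not match the trained forest (",
         length(forest$forest$ncat), ")")
  as.numeric(stats::predict(forest, vectors, type = "prob")[, "ASD"])
}

#' Pose-level partial decision from vector scores
#'
#' Each vector votes ASD iff its score is at least 0.5 (a score of exactly
#' 0.5 votes ASD); the pose label is the majority of votes with ties going
#' to ASD, and the pose probability is the mean vector score.
#'
#' @param scores Numeric vector of per-vector ASD scores (length >= 1).
#' @return List with \code{label} ("ASD"/"TD") and \code{probability}.
#' @export
#' @examples
#' pose_decision(c(0.9, 0.8, 0.2))  # ASD, 0.6333
pose_decision <- function(scores) {
  stopifnot(length(scores) >= 1)
  votes_asd <- sum(scores >= 0.5)
  list(label = if (votes_asd >= length(scores) / 2) "ASD" else "TD",
       probability = mean(scores))
}

#' Final participant decision from pose-level decisions
#'
#' Majority vote over the available poses' partial decisions, ties going to
#' ASD. The participant's ASD probability is, by default, the unweighted
#' mean of the pose probabilities (\code{prob_method = "mean_score"});
#' alternatively the fraction of poses voting ASD
#' (\code{prob_method = "vote_fraction"}). The boundary distance is the
#' probability rescaled to \code{[-1, +1]}: \code{2p - 1}.
#'
#' @param pose_labels Character vector of pose decisions.
#' @param pose_probs Numeric vector of pose probabilities (same length).
#' @param prob_method \code{"mean_score"} (default) or
#'   \code{"vote_fraction"}.
#' @return List with \code{label}, \code{asd_probability} and
#'   \code{boundary_distance}.
#' @export
participant_decision <- function(pose_labels, pose_probs,
                                 prob_method = c("mean_score",
                                                 "vote_fraction")) {
  prob_method <- match.arg(prob_method)
  stopifnot(length(pose_labels) >= 1,
            length(pose_labels) == length(pose_probs))
  votes_asd <- sum(pose_labels == "ASD")
  p <- if (prob_method == "mean_score") mean(pose_probs)
       else votes_asd / length(pose_labels)
  list(label = if (votes_asd >= length(pose_labels) / 2) "ASD" else "TD",
       asd_probability = p, boundary_distance = 2 * p - 1)
}

#' Fit the pose-indexed random-forest ensemble
#'
#' The core classification model: one random forest per balance pose, each
#' trained only on the feature vectors extracted from that pose's
#' recordings. Participants are later classified by two-level majority
#' voting (vectors within a pose, then poses within a participant; see
#' \code{\link{predict.movement_ensemble}}).
#'
#' @param x A \code{movement_features} object whose \code{participants}
#'   data frame carries the training labels (\code{group} column with
#'   values "ASD"/"TD").
#' @param params A \code{\link{forest_params}}.
#' @return An object of class \code{"movement_ensemble"}: the pose-indexed
#'   forests, the feature schema, and training metadata.
#' @export
#' @seealso \code{\link{predict.movement_ensemble}}, \code{\link{total_mdi}},
#'   \code{\link{run_cv}}
movement_ensemble <- function(x, params = forest_params()) {
  stopifnot(inherits(x, "movement_features"))
  if (is.null(x$participants) || !"group" %in% names(x$participants))
    stop("training requires participant labels: supply a participants ",
         "data frame with a 'group' column")
  lab <- x$participants$group[match(x$meta$participant_id,
                                    x$participants$participant_id)]
  if (anyNA(lab))
    stop("some feature vectors belong to participants absent from the ",
         "participants table")
  poses <- sort(unique(x$meta$pose_id))
  forests <- lapply(poses, function(p) {
    sel <- x$meta$pose_id == p
    train_pose_forest(x$features[sel, , drop = FALSE], lab[sel], params,
                      pose_id = p)
  })
  names(forests) <- as.character(poses)
  structure(list(forests = forests, feature_names = colnames(x$features),
                 params = params,
                 training_participants = unique(x$meta$participant_id)),
            class = "movement_ensemble")
}

#' @export
print.movement_ensemble <- function(x, ...) {
  cat(sprintf("<movement_ensemble> %d pose forests x %d trees, %d features, %d training participants\n",
              length(x$forests), x$params$n_trees,
              length(x$feature_names),
              length(x$training_participants)))
  invisible(x)
}

#' @export
summary.movement_ensemble <- function(object, ...) {
  print(object)
  rk <- total_mdi(object)
  cat("Top features by total normalized MDI:\n")
  print(utils::head(rk, 10), row.names = FALSE)
  invisible(rk)
}

#' Importance plot for a fitted ensemble
#'
#' Horizontal bar chart of the top-k features by total normalized
#' mean-decrease-impurity across the pose forests.
#'
#' @param x A \code{movement_ensemble}.
#' @param k Number of features to show (default 20).
#' @param ... Passed to \code{\link[graphics]{barplot}}.
#' @export
plot.movement_ensemble <- function(x, k = 20, ...) {
  rk <- utils::head(total_mdi(x), k)
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(rk$total_mdi), names.arg = rev(rk$feature),
                    horiz = TRUE, las = 1, cex.names = 0.6,
                    xlab = "total normalized MDI", ...)
  invisible(rk)
}

#' Classify participants with a fitted ensemble
#'
#' For every participant in \code{newdata}: each pose's vectors are scored
#' by that pose's forest and combined by majority vote into a partial
#' decision; the partial decisions are combined by a second majority vote
#' into the final label (ties to ASD at both levels). The continuous ASD
#' probability is the mean pose probability, and the boundary distance is
#' its rescaling to \code{[-1, +1]}. Poses absent from the participant's
#' data (e.g. discarded by QC) are omitted from both votes.
#'
#' @param object A fitted \code{movement_ensemble}.
#' @param newdata A \code{movement_features} object.
#' @param prob_method How the participant probability is computed; see
#'   \code{\link{participant_decision}}.
#' @param ... Unused.
#' @return Data frame of class \code{"movement_prediction"}, one row per
#'   participant: \code{participant_id}, \code{final_label},
#'   \code{asd_probability}, \code{boundary_distance}, \code{n_poses}.
#'   Per-pose decisions are attached as attribute \code{"pose_detail"}.
#' @export
predict.movement_ensemble <- function(object, newdata,
                                      prob_method = c("mean_score",
                                                      "vote_fraction"),
                                      ...) {
  prob_method <- match.arg(prob_method)
  stopifnot(inherits(newdata, "movement_features"))
  if (!identical(colnames(newdata$features), object$feature_names))
    stop("feature schema of newdata does not match the trained model")
  ids <- unique(newdata$meta$participant_id)
  pose_detail <- list()
  rows <- lapply(ids, function(id) {
    sel <- newdata$meta$participant_id == id
    poses <- sort(unique(newdata$meta$pose_id[sel]))
    poses <- poses[as.character(poses) %in% names(object$forests)]
    if (length(poses) == 0L)
      stop("classification error: participant ", id,
           " has no usable pose data")
    dec <- lapply(poses, function(p) {
      vsel <- sel & newdata$meta$pose_id == p
      sc <- score_vectors(object$forests[[as.character(p)]],
                          newdata$features[vsel, , drop = FALSE])
      c(pose_decision(sc), list(n_vectors = sum(vsel)))
    })
    labs <- vapply(dec, `[[`, character(1), "label")
    probs <- vapply(dec, `[[`, numeric(1), "probability")
    pose_detail[[id]] <<- data.frame(
      pose_id = poses, label = labs, probability = probs,
      n_vectors = vapply(dec, `[[`, numeric(1), "n_vectors"),
      stringsAsFactors = FALSE)
    fin <- participant_decision(labs, probs, prob_method)
    data.frame(participant_id = id, final_label = fin$label,
               asd_probability = fin$asd_probability,
               boundary_distance = fin$boundary_distance,
               n_poses = length(poses), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pose_detail") <- pose_detail
  class(out) <- c("movement_prediction", "data.frame")
  out
}
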