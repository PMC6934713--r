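#' Per-forest normalized mean-decrease-impurity
#'
#' A feature's MDI in one forest is the total Gini impurity decrease at the
#' nodes splitting on it, accumulated over the forest's trees, normalized so
#' the forest's values sum to 1.
#'
#' @param forest A fitted pose forest.
#' @return Named numeric vector summing to 1 (all zeros if the forest never
#'   splits).
#' @export
forest_mdi <- function(forest) {
  imp <- randomForest::importance(forest, type = 2)[, 1L]
  s <- sum(imp)
  if (s > 0) imp / s else imp
}

#' Total MDI feature ranking across the pose ensemble
#'
#' Sums each feature's per-forest normalized MDI over all pose forests and
#' ranks features in descending order of the total (range 0 to the number
#' of forests). Ties are broken by canonical feature-name order.
#'
#' @param model A fitted \code{\link{movement_ensemble}}.
#' @return Data frame with columns \code{feature} and \code{total_mdi},
#'   sorted by decreasing \code{total_mdi}.
#' @export
total_mdi <- function(model) {
  stopifnot(inherits(model, "movement_ensemble"))
  total <- Reduce(`+`, lapply(model$forests, forest_mdi))
  ord <- order(-total, match(names(total), model$feature_names))
  data.frame(feature = names(total)[ord], total_mdi = unname(total[ord]),
             stringsAsFactors = FALSE)
}

#' Top-k feature names from an importance ranking
#'
#' @param ranking Data frame from \code{\link{total_mdi}}.
#' @param k Number of features (1 <= k <= number of features).
#' @return Character vector of the first k feature names.
#' @export
top_features <- function(ranking, k) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(ranking)) stop("k exceeds the number of features")
  ranking$feature[seq_len(k)]
}

#' Overlap fraction between two equal-length feature lists
#'
#' @param list_a,list_b Character vectors of equal length k.
#' @return \code{|A intersect B| / k}, in \code{[0, 1]}.
#' @export
list_overlap <- function(list_a, list_b) {
  if (length(list_a) != length(list_b))
    stop("lists must have equal length")
  length(intersect(list_a, list_b)) / length(list_a)
}

#' Fold-to-fold consistency of the importance ranking
#'
#' Mean over CV folds of the overlap between the fold model's top-k list
#' and the full-data model's top-k list.
#'
#' @param cv A \code{\link{run_cv}} result.
#' @param full_ranking \code{\link{total_mdi}} of the model trained on all
#'   participants.
#' @param k List length (default the length stored per fold).
#' @return Mean overlap in \code{[0, 1]}.
#' @export
fold_consistency <- function(cv, full_ranking, k = NULL) {
  stopifnot(inherits(cv, "movement_cv"))
  k <- k %||% length(cv$per_fold[[1L]]$top_features)
  ref <- top_features(full_ranking, k)
  mean(vapply(cv$per_fold, function(pf)
    list_overlap(pf$top_features[seq_len(k)], ref), numeric(1)))
}

#' Cohen's d between two groups
#'
#' Standardized mean difference \code{(mean_a - mean_b) / s_pooled} with
#' \code{(n-1)}-weighted pooled standard deviation. By convention the first
#' argument is the ASD group, so positive d means ASD > TD.
#'
#' @param values_asd,values_td Numeric vectors of per-participant values
#'   (>= 2 each).
#' @return Cohen's d, or \code{NA} if the pooled SD is zero.
#' @export
#' @examples
#' cohens_d(c(2, 4), c(1, 3))  # 1/sqrt(2)
cohens_d <- function(values_asd, values_td) {
  na <- length(values_asd); nb <- length(values_td)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(values_asd) +
            (nb - 1) * stats::var(values_td)) / (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(values_asd) - mean(values_td)) / sqrt(sp2)
}

#' Per-participant mean feature values
#'
#' Aggregates a feature matrix to one row per participant (mean over all of
#' the participant's windows), the unit at which group effect sizes are
#' computed to avoid pseudo-replication across windows.
#'
#' @param x A \code{movement_features} object.
#' @return Data frame: \code{participant_id}, then one column per feature.
#' @export
participant_feature_means <- function(x) {
  stopifnot(inherits(x, "movement_features"))
  ids <- unique(x$meta$participant_id)
  m <- t(vapply(ids, function(id)
    colMeans(x$features[x$meta$participant_id == id, , drop = FALSE]),
    numeric(ncol(x$features))))
  out <- data.frame(participant_id = ids, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Group effect sizes for chosen features
#'
#' Per-participant aggregated feature values are compared between groups:
#' group means and SDs plus Cohen's d (positive = ASD > TD).
#'
#' @param x A \code{movement_features} with participant labels.
#' @param features Character vector of feature names (default: all).
#' @return Data frame with one row per feature: group means/SDs and
#'   \code{cohens_d}.
#' @export
effect_size_report <- function(x, features = NULL) {
  stopifnot(inherits(x, "movement_features"), !is.null(x$participants))
  pm <- participant_feature_means(x)
  grp <- x$participants$group[match(pm$participant_id,
                                    x$participants$participant_id)]
  features <- features %||% setdiff(names(pm), "participant_id")
  rows <- lapply(features, function(f) {
    a <- pm[[f]][grp == "ASD"]; b <- pm[[f]][grp == "TD"]
    data.frame(feature = f, mean_asd = mean(a), sd_asd = stats::sd(a),
               mean_td = mean(b), sd_td = stats::sd(b),
               cohens_d = cohens_d(a, b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate boundary distance with a covariate
#'
#' Pearson and Spearman correlations (two-sided) between participants'
#' boundary distances and a covariate; pairs with a missing covariate are
#' dropped. A constant input yields NA correlations.
#'
#' @param distances Numeric vector of boundary distances in \code{[-1, 1]}.
#' @param covariate Numeric vector, same length (NAs allowed).
#' @return One-row data frame: \code{pearson_r}, \code{pearson_p},
#'   \code{spearman_rho}, \code{spearman_p}, \code{n}.
#' @export
correlate_distance <- function(distances, covariate) {
  stopifnot(length(distances) == length(covariate))
  ok <- !is.na(distances) & !is.na(covariate)
  d <- distances[ok]; v <- covariate[ok]
  n <- length(d)
  if (n < 3 || stats::sd(d) == 0 || stats::sd(v) == 0)
    return(data.frame(pearson_r = NA_real_, pearson_p = NA_real_,
                      spearman_rho = NA_real_, spearman_p = NA_real_,
                      n = n))
  pe <- stats::cor.test(d, v, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(d, v, method = "spearman"))
  data.frame(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
             spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
             n = n)
}
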