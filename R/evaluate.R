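# Accuracy metrics and cross-validation for presence / pseudo-absence
# models: rank-based AUC, point-biserial correlation, sensitivity and
# specificity, stratified 10-fold cross-validation of the full
# stepwise-GLM(+kriging) pipeline, best-group selection and the stability
# of prediction maps across pseudo-absence replicates.

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("both classes (0 and 1) must be present")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' presence outscores a randomly chosen absence, with half credit for ties.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  check_two_classes(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Point-biserial correlation
#'
#' Pearson correlation between the 0/1 observation vector and the predicted
#' probabilities; unlike AUC it is sensitive to how far predictions sit
#' from the observations, not just their ranking.
#'
#' @inheritParams auc
#' @return correlation in `[-1, 1]`.
#' @export
pbc <- function(labels, scores) {
  check_two_classes(labels)
  if (stats::sd(scores) == 0)
    stop("scores are constant; the correlation is undefined")
  stats::cor(labels, scores)
}

#' Sensitivity and specificity at a threshold
#'
#' Presence is predicted when `score >= threshold`.
#'
#' @inheritParams auc
#' @param threshold classification threshold.
#' @return named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(labels, scores, threshold) {
  check_two_classes(labels)
  pred <- scores >= threshold
  c(sensitivity = sum(pred & labels == 1) / sum(labels == 1),
    specificity = sum(!pred & labels == 0) / sum(labels == 0))
}

stratified_folds <- function(labels, k, seed) {
  with_seed(derive_seed(seed, "folds"), {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop(sprintf("class %s has %d rows, fewer than k = %d folds; use a smaller k",
                     cl, length(idx), k))
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' Cross-validate the stepwise-GLM(+kriging) pipeline
#'
#' Stratified k-fold split (prevalence preserved per fold); for each fold
#' the full pipeline — stepwise AIC logistic model, residual variogram and,
#' when structure is present, ordinary kriging of the training-fold
#' residuals only — is refit on the training folds and scored on the
#' held-out fold. Sensitivity and specificity use the 0.5 threshold, the
#' natural cut for training data balanced at prevalence 0.5.
#'
#' @param data training table with columns `x`, `y`, `label` and predictor
#'   columns.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param krige krige held-out residual predictions (default TRUE).
#' @param stepwise use stepwise AIC inside each fold (default TRUE).
#' @return object of class `evaluation_report`: per-fold metrics, their
#'   mean and sd.
#' @export
cross_validate <- function(data, k = 10, seed = 1, krige = TRUE,
                           stepwise = TRUE) {
  check_two_classes(data$label)
  fold <- stratified_folds(data$label, k, seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    fit <- suppressWarnings(fit_rk(tr, stepwise = stepwise))
    p <- if (krige) predict(fit, te) else predict_logistic(fit$glm, te)
    ss <- sens_spec(te$label, p, 0.5)
    rows[[f]] <- data.frame(
      fold = f, auc = auc(te$label, p),
      pbc = if (stats::sd(p) > 0) pbc(te$label, p) else NA_real_,
      sensitivity = ss[[1]], specificity = ss[[2]])
  }
  per_fold <- do.call(rbind, rows)
  mets <- c("auc", "pbc", "sensitivity", "specificity")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[mets], na.rm = TRUE),
                 sd = vapply(per_fold[mets], stats::sd, 0, na.rm = TRUE),
                 k = k, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold cross-validation\n", x$k))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Select the most accurate pseudo-absence group
#'
#' Highest mean cross-validated AUC wins; ties go to the higher mean PBC,
#' then to the lowest group id.
#'
#' @param reports named or unnamed list of `evaluation_report`s, in group
#'   order.
#' @return integer index of the winning group.
#' @export
select_best_group <- function(reports) {
  if (!length(reports)) stop("no reports supplied")
  a <- vapply(reports, function(r) r$mean[["auc"]], 0)
  p <- vapply(reports, function(r) r$mean[["pbc"]], 0)
  best <- which(a == max(a))
  if (length(best) > 1) best <- best[p[best] == max(p[best])]
  best[1]
}

#' Stability of prediction maps across pseudo-absence replicates
#'
#' Pearson correlation over jointly valid cells for every unordered pair of
#' maps (45 pairs for 10 maps).
#'
#' @param maps list of co-registered probability `sdm_grid`s.
#' @return object of class `stability_report` with the vector of pairwise
#'   correlations and their min/mean/max.
#' @export
prediction_stability <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 maps")
  ref <- maps[[1]]
  for (m in maps[-1])
    if (!same_geometry(ref, m)) stop("maps are not co-registered")
  pairs <- utils::combn(length(maps), 2)
  cors <- apply(pairs, 2, function(ij) {
    a <- maps[[ij[1]]]$values; b <- maps[[ij[2]]]$values
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) stop("a map pair shares no valid cells")
    stats::cor(a[ok], b[ok])
  })
  structure(list(correlations = cors, pairs = t(pairs),
                 min = min(cors), mean = mean(cors), max = max(cors)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d pairwise correlations: min %.3f, mean %.3f, max %.3f\n",
              length(x$correlations), x$min, x$mean, x$max))
  invisible(x)
}
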