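# Threshold-ensemble fuzzification and fuzzy-AND conservation overlay.
# Instead of committing to one probability threshold, four standard
# optimisation criteria are computed and the probability map is ramped
# linearly between the smallest and the largest of them, yielding a degree
# of membership in the fuzzy set of favourable areas.

confusion_counts <- function(labels, scores, thresholds) {
  # cumulative counts over candidate thresholds (ascending)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tp <- fp <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- scores >= thresholds[i]
    tp[i] <- sum(pred & labels == 1)
    fp[i] <- sum(pred & labels == 0)
  }
  list(tp = tp, fp = fp, fn = n1 - tp, tn = n0 - fp, n1 = n1, n0 = n0)
}

cohen_kappa_counts <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  ifelse(abs(1 - pe) < 1e-12, 0, (po - pe) / (1 - pe))
}

#' Optimal presence/absence thresholds under four criteria
#'
#' Candidate thresholds are the midpoints of consecutive sorted unique
#' scores plus 0 and 1, so every achievable confusion table is visited.
#' Returns the thresholds where (i) sensitivity is closest to specificity,
#' (ii) sensitivity + specificity is maximal, (iii) Cohen's kappa is
#' maximal, and (iv) the percent of correctly classified observations is
#' maximal. Ties go to the lowest threshold.
#'
#' @param labels 0/1 vector.
#' @param scores predicted probabilities.
#' @return object of class `threshold_set` with the four thresholds plus
#'   `t_min` and `t_max`.
#' @export
find_thresholds <- function(labels, scores) {
  check_two_classes(labels)
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)))
  cc <- confusion_counts(labels, scores, cand)
  sens <- cc$tp / cc$n1
  spec <- cc$tn / cc$n0
  kappa <- cohen_kappa_counts(cc$tp, cc$fp, cc$fn, cc$tn)
  pcc <- (cc$tp + cc$tn) / (cc$n1 + cc$n0)
  ts <- list(
    t_sens_eq_spec = cand[which.min(abs(sens - spec))],
    t_max_sens_plus_spec = cand[which.max(sens + spec)],
    t_max_kappa = cand[which.max(kappa)],
    t_max_pcc = cand[which.max(pcc)])
  ts$t_min <- min(unlist(ts))
  ts$t_max <- max(unlist(ts[1:4]))
  structure(ts, class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> sens=spec %.3f | max(sens+spec) %.3f | max kappa %.3f | max PCC %.3f\n",
    x$t_sens_eq_spec, x$t_max_sens_plus_spec, x$t_max_kappa, x$t_max_pcc))
  invisible(x)
}

fuzzy_ramp <- function(v, lo, hi) {
  if (hi > lo) pmin(pmax((v - lo) / (hi - lo), 0), 1)
  else as.numeric(v >= lo)   # degenerate: crisp step at the common value
}

#' Fuzzify a probability map between its threshold extremes
#'
#' Linear membership ramp: 0 at or below the smallest of the four
#' optimised thresholds, 1 at or above the largest, linear between. When
#' all four thresholds coincide the ramp degenerates to a crisp step.
#'
#' @param p probability `sdm_grid` in `[0, 1]`.
#' @param ts a `threshold_set`.
#' @return membership `sdm_grid` in `[0, 1]`.
#' @export
fuzzify_linear <- function(p, ts) {
  grid_check(p, "p")
  if (!inherits(ts, "threshold_set")) stop("`ts` must be a threshold_set")
  new_grid(matrix(fuzzy_ramp(p$values, ts$t_min, ts$t_max),
                  nrow(p$values), ncol(p$values)),
           p$x_origin, p$y_origin, p$cell_size)
}

#' Fuzzify a continuous layer between two breakpoints
#'
#' Linear ramp with membership 0 at or below `lo` and 1 at or above `hi` —
#' e.g. seagrass recovery rate with the (30, 60) percent anchors.
#'
#' @param layer quantitative `sdm_grid`.
#' @param lo,hi ramp anchors, `lo < hi`.
#' @return membership `sdm_grid` in `[0, 1]`.
#' @export
fuzzify_breakpoints <- function(layer, lo, hi) {
  grid_check(layer, "layer")
  if (lo >= hi) stop("`lo` must be strictly less than `hi`")
  new_grid(matrix(fuzzy_ramp(layer$values, lo, hi),
                  nrow(layer$values), ncol(layer$values)),
           layer$x_origin, layer$y_origin, layer$cell_size)
}

#' Fuzzy AND overlay of membership maps
#'
#' Cell-wise minimum of the memberships; a cell that is nodata in any input
#' is nodata in the result.
#'
#' @param memberships list of co-registered membership `sdm_grid`s.
#' @return membership `sdm_grid`.
#' @export
fuzzy_and <- function(memberships) {
  if (!length(memberships)) stop("need at least one membership map")
  ref <- memberships[[1]]
  grid_check(ref)
  for (m in memberships[-1])
    if (!same_geometry(ref, m)) stop("membership maps are not co-registered")
  v <- Reduce(function(a, b) pmin(a, b),
              lapply(memberships, function(g) g$values))
  new_grid(v, ref$x_origin, ref$y_origin, ref$cell_size)
}

#' Multi-species conservation-priority overlay
#'
#' Filters species by cross-validated accuracy (mean AUC at least
#' `min_auc`), fuzzifies each species' probability map between its own
#' threshold extremes, fuzzifies the seagrass recovery layer between the
#' `seagrass_breaks` anchors, and combines everything with the fuzzy AND.
#' The area with nonzero favourability is reported in map units squared.
#'
#' @param species named list; each element needs `prob` (probability
#'   `sdm_grid`), `thresholds` (`threshold_set`) and `auc` (mean
#'   cross-validated AUC).
#' @param seagrass quantitative `sdm_grid` of recovery rates in `[0, 100]`,
#'   or `NULL` to overlay species only.
#' @param min_auc accuracy filter (default 0.8, the conventional lower
#'   bound of "high" accuracy; 0.9 and above is "excellent").
#' @param seagrass_breaks ramp anchors for the seagrass layer (default
#'   `c(30, 60)` percent).
#' @return list with `map` (membership `sdm_grid`), `area_nonzero`
#'   (map-unit^2), `species_used`, and per-species memberships.
#' @export
conservation_overlay <- function(species, seagrass = NULL, min_auc = 0.8,
                                 seagrass_breaks = c(30, 60)) {
  aucs <- vapply(species, function(s) s$auc, 0)
  keep <- names(species)[aucs >= min_auc]
  if (!length(keep))
    stop(sprintf("no species reaches the accuracy filter (mean AUC >= %.2f)", min_auc))
  mem <- lapply(species[keep], function(s) fuzzify_linear(s$prob, s$thresholds))
  if (!is.null(seagrass))
    mem$seagrass <- fuzzify_breakpoints(seagrass, seagrass_breaks[1],
                                        seagrass_breaks[2])
  out <- fuzzy_and(mem)
  cs <- out$cell_size
  list(map = out,
       area_nonzero = sum(out$values > 0, na.rm = TRUE) * cs * cs,
       species_used = keep, memberships = mem)
}
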