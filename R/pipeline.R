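# End-to-end orchestration: simulate (or accept) a seascape, then per
# species run ordination -> ENFA -> HSI -> pseudo-absence groups ->
# regression kriging -> cross-validated evaluation -> best-group selection
# -> thresholds, and finally the multi-species fuzzy conservation overlay.

#' Assemble a pipeline run configuration
#'
#' Defaults mirror the standard survey-modelling settings: 10 weighted
#' pseudo-absence groups plus 1 random, 10-fold cross-validation, and a
#' 100-permutation marginality test.
#'
#' @param stack an `sdm_stack` of predictor layers.
#' @param occurrences data.frame with columns `x`, `y`, `species`
#'   (presence-only records).
#' @param n_hauls number of hauls behind the occurrence records (used by
#'   the commonness filter).
#' @param seagrass optional recovery-rate `sdm_grid` for the overlay.
#' @param species optional subset of species codes to model.
#' @param n_weighted_groups weighted pseudo-absence groups (default 10).
#' @param k_folds cross-validation folds (default 10).
#' @param n_perm marginality-test permutations (default 100).
#' @param min_frac commonness filter (default 0.10, strict).
#' @param min_auc overlay accuracy filter (default 0.8).
#' @param seed master seed; all per-species, per-group seeds derive from it.
#' @param krige use regression kriging (default TRUE).
#' @return a `run_config` list.
#' @export
run_config <- function(stack, occurrences, n_hauls, seagrass = NULL,
                       species = NULL, n_weighted_groups = 10, k_folds = 10,
                       n_perm = 100, min_frac = 0.10, min_auc = 0.8,
                       seed = 1, krige = TRUE) {
  stopifnot(inherits(stack, "sdm_stack"),
            all(c("x", "y", "species") %in% names(occurrences)),
            n_hauls > 0)
  structure(list(stack = stack, occurrences = occurrences,
                 n_hauls = n_hauls, seagrass = seagrass, species = species,
                 n_weighted_groups = n_weighted_groups, k_folds = k_folds,
                 n_perm = n_perm, min_frac = min_frac, min_auc = min_auc,
                 seed = seed, krige = krige),
            class = "run_config")
}

model_one_species <- function(cfg, sp, tab, hs, bg_scores) {
  occ <- cfg$occurrences[cfg$occurrences$species == sp, , drop = FALSE]
  occ_tab <- extract_at_points(cfg$stack, occ, quiet = TRUE)
  pres_scores <- predict(hs, occ_tab[names(cfg$stack$layers)])
  en <- fit_enfa(bg_scores, pres_scores)
  mt <- marginality_test(bg_scores, pres_scores, n_perm = cfg$n_perm,
                         seed = derive_seed(cfg$seed, sp, "margtest"))
  hsi <- hsi_grid(en, cfg$stack, bg_scores)
  groups <- make_groups(hsi, occ_tab, n_weighted = cfg$n_weighted_groups,
                        seed = derive_seed(cfg$seed, sp, "groups"))
  comp_names <- colnames(bg_scores)
  cell_tab <- cbind(tab[c("x", "y")], as.data.frame(bg_scores))
  score_rows <- function(pts) {
    ptab <- extract_at_points(cfg$stack, pts[c("x", "y")], quiet = TRUE)
    s <- predict(hs, ptab[names(cfg$stack$layers)])
    cbind(ptab[c("x", "y")], as.data.frame(s))
  }
  pres_rows <- score_rows(occ_tab)
  pres_rows$label <- 1
  reports <- list(); fits <- list(); maps <- list()
  for (gi in seq_along(groups)) {
    pa_rows <- score_rows(groups[[gi]])
    pa_rows$label <- 0
    train <- rbind(pres_rows, pa_rows)
    reports[[gi]] <- cross_validate(
      train, k = cfg$k_folds, krige = cfg$krige,
      seed = derive_seed(cfg$seed, sp, "cv", gi))
    fits[[gi]] <- suppressWarnings(fit_rk(train, stepwise = TRUE))
    maps[[gi]] <- probability_grid(fits[[gi]], cfg$stack, cell_tab)
  }
  best <- select_best_group(reports)
  best_train <- rbind(pres_rows,
                      { pr <- score_rows(groups[[best]]); pr$label <- 0; pr })
  thresholds <- find_thresholds(best_train$label,
                                predict(fits[[best]], best_train))
  weighted_idx <- which(vapply(groups, function(g) g$method[1], "") == "weighted")
  stability <- if (length(weighted_idx) >= 2)
    prediction_stability(maps[weighted_idx]) else NULL
  list(species = sp, n_presences = nrow(occ_tab), enfa = en,
       marginality_p = mt$p_value, hsi = hsi, groups = groups,
       reports = reports, fits = fits, maps = maps, best_group = best,
       auc = reports[[best]]$mean[["auc"]], thresholds = thresholds,
       prob = maps[[best]], stability = stability)
}

#' Run the full modelling and conservation-planning pipeline
#'
#' Applies the commonness filter, models every retained species, selects
#' each species' best pseudo-absence group, and (when a seagrass layer is
#' supplied) builds the fuzzy conservation overlay. Species whose model
#' fails are recorded and skipped; the rest continue.
#'
#' @param cfg a [run_config()].
#' @return object of class `pipeline_result` with per-species results, the
#'   overlay (or `NULL`), and a manifest of settings, seeds and metrics.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  sp_all <- filter_common_species(cfg$occurrences, cfg$n_hauls, cfg$min_frac)
  if (!is.null(cfg$species)) sp_all <- intersect(sp_all, cfg$species)
  if (!length(sp_all)) stop("no species passes the commonness filter")
  tab <- stack_table(cfg$stack)
  # degenerate ordination axes (tiny eigenvalues) destabilise the niche
  # analysis without adding usable environmental signal
  hs <- hill_smith(tab[names(cfg$stack$layers)], min_eigenvalue = 0.02)
  bg_scores <- hs$scores
  results <- list(); failures <- list()
  for (sp in sp_all) {
    res <- tryCatch(model_one_species(cfg, sp, tab, hs, bg_scores),
                    error = function(e) e)
    if (inherits(res, "error")) failures[[sp]] <- conditionMessage(res)
    else results[[sp]] <- res
  }
  overlay <- NULL; overlay_note <- NULL
  if (length(results)) {
    sp_in <- lapply(results, function(r)
      list(prob = r$prob, thresholds = r$thresholds, auc = r$auc))
    if (is.null(cfg$seagrass))
      overlay_note <- "no seagrass layer supplied; overlay limited to species maps"
    overlay <- tryCatch(
      conservation_overlay(sp_in, cfg$seagrass, min_auc = cfg$min_auc),
      error = function(e) { overlay_note <<- conditionMessage(e); NULL })
  }
  manifest <- list(
    seed = cfg$seed,
    settings = list(n_weighted_groups = cfg$n_weighted_groups,
                    k_folds = cfg$k_folds, n_perm = cfg$n_perm,
                    min_frac = cfg$min_frac, min_auc = cfg$min_auc),
    species = lapply(results, function(r) list(
      n_presences = r$n_presences,
      marginality = r$enfa$marginality_coefficient,
      marginality_p = r$marginality_p,
      best_group = r$best_group,
      best_method = r$groups[[r$best_group]]$method[1],
      cv_mean = as.list(r$reports[[r$best_group]]$mean),
      thresholds = unclass(r$thresholds)[1:4],
      stability_mean = if (is.null(r$stability)) NA else r$stability$mean)),
    failures = failures,
    overlay = if (is.null(overlay)) overlay_note
      else list(area_nonzero = overlay$area_nonzero,
                species_used = overlay$species_used))
  if (!is.null(overlay_note)) message("overlay: ", overlay_note)
  structure(list(species = results, overlay = overlay, manifest = manifest,
                 config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d species modelled, %d failed\n",
              length(x$species), length(x$manifest$failures)))
  for (sp in names(x$species)) {
    r <- x$species[[sp]]
    cat(sprintf("  %-10s n=%3d  M=%.2f (p=%.3g)  best group %d (%s)  AUC %.3f\n",
                sp, r$n_presences, r$enfa$marginality_coefficient,
                r$marginality_p, r$best_group,
                r$groups[[r$best_group]]$method[1], r$auc))
  }
  if (!is.null(x$overlay))
    cat(sprintf("  overlay: %d species, nonzero-favourability area %.4g\n",
                length(x$overlay$species_used), x$overlay$area_nonzero))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Serialises the probability and HSI maps (ESRI ASCII), the pseudo-absence
#' groups (CSV) and the manifest (JSON) so any stage can be re-run or
#' inspected from disk.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(result$species)) {
    r <- result$species[[sp]]
    write_ascii_grid(r$hsi, file.path(dir, paste0(sp, "_hsi.asc")))
    write_ascii_grid(r$prob, file.path(dir, paste0(sp, "_prob.asc")))
    pa <- do.call(rbind, r$groups)
    utils::write.csv(pa, file.path(dir, paste0(sp, "_pseudoabs.csv")),
                     row.names = FALSE)
  }
  if (!is.null(result$overlay))
    write_ascii_grid(result$overlay$map, file.path(dir, "favourability.asc"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
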