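# Pseudo-absence samplers. The weighted sampler places artificial absences
# preferentially in unsuitable habitat (low HSI) far from the occurrence
# records; the random sampler is the uniform baseline it is compared with.

#' Normalised distance from the occurrence records
#'
#' Per-cell distance to the nearest presence point, divided by the maximum
#' such distance over valid cells and scaled to `[0, 100]`. Cells containing
#' a presence are exactly 0.
#'
#' @param domain an `sdm_grid` defining geometry and validity (nodata cells
#'   stay nodata).
#' @param presences data.frame with columns `x`, `y`.
#' @return quantitative `sdm_grid` in `[0, 100]`.
#' @export
normalized_distance <- function(domain, presences) {
  grid_check(domain, "domain")
  if (!nrow(presences)) stop("at least one presence is required")
  valid <- which(!is.na(domain$values))
  ctr <- cell_centers(domain)
  d <- rep(NA_real_, length(domain$values))
  d[valid] <- min_dist_to_points(ctr[valid, , drop = FALSE],
                                 cbind(presences$x, presences$y))
  loc <- locate_cells(domain, presences$x, presences$y)
  inb <- loc$inside
  d[loc$row[inb] + (loc$col[inb] - 1L) * nrow(domain$values)] <- 0
  mx <- max(d, na.rm = TRUE)
  if (mx <= 0) stop("all valid cells contain presences; no distance signal")
  new_grid(matrix(100 * d / mx, nrow(domain$values), ncol(domain$values)),
           domain$x_origin, domain$y_origin, domain$cell_size)
}

#' Pseudo-absence sampling weight map
#'
#' The weight of a cell combines its unsuitability and its remoteness from
#' the occurrence records, squared:
#' `tau = (((100 - HSI)/100) * (d_R/100))^2 * 100`, so `tau` is 0 at fully
#' suitable cells and at presence cells, and maximal (100) where HSI = 0
#' and `d_R = 100`. The squaring pushes pseudo-absences towards the edge of
#' low suitability and large distance. The exact algebra is isolated here
#' so an alternative reading of the weighting is a one-line change.
#'
#' @param hsi `sdm_grid` of habitat suitability in `[0, 100]`.
#' @param d_r `sdm_grid` of normalised distances in `[0, 100]`
#'   (see [normalized_distance()]).
#' @return `sdm_grid` of weights in `[0, 100]` with attribute `total`
#'   (the sum over valid cells, used to normalise to sampling
#'   probabilities).
#' @export
weight_map <- function(hsi, d_r) {
  grid_check(hsi, "hsi"); grid_check(d_r, "d_r")
  if (!same_geometry(hsi, d_r)) stop("hsi and d_r are not co-registered")
  rng_ok <- function(v) all(is.na(v) | (v >= -1e-9 & v <= 100 + 1e-9))
  if (!rng_ok(hsi$values)) stop("HSI values must lie in [0, 100]")
  if (!rng_ok(d_r$values)) stop("d_R values must lie in [0, 100]")
  tau <- (((100 - hsi$values) / 100) * (d_r$values / 100))^2 * 100
  g <- new_grid(tau, hsi$x_origin, hsi$y_origin, hsi$cell_size)
  attr(g, "total") <- sum(tau, na.rm = TRUE)
  if (attr(g, "total") <= 0)
    stop("all sampling weights are zero; cannot place pseudo-absences")
  g
}

#' Draw pseudo-absences proportional to a weight map
#'
#' Cells are drawn without replacement with probability proportional to
#' `tau`; points are emitted at cell centres.
#'
#' @param weights `sdm_grid` of non-negative weights (see [weight_map()]).
#' @param n number of pseudo-absences.
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y`, `cell`, `label` (0).
#' @export
sample_weighted <- function(weights, n, seed = 1) {
  grid_check(weights, "weights")
  if (n < 1) stop("n must be at least 1")
  tau <- weights$values
  pos <- which(!is.na(tau) & tau > 0)
  if (n > length(pos))
    stop(sprintf("requested %d pseudo-absences but only %d cells have positive weight",
                 n, length(pos)))
  pick <- with_seed(derive_seed(seed, "weighted"), {
    if (length(pos) == 1) pos else sample(pos, n, prob = tau[pos])
  })
  ctr <- cell_centers(weights)
  data.frame(x = ctr[pick, 1], y = ctr[pick, 2], cell = pick, label = 0)
}

#' Draw pseudo-absences uniformly at random
#'
#' Uniform draw without replacement from valid cells that do not contain a
#' presence.
#'
#' @param domain an `sdm_grid` defining geometry and validity.
#' @param presences data.frame with columns `x`, `y` (their cells are
#'   excluded).
#' @param n number of pseudo-absences.
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y`, `cell`, `label` (0).
#' @export
sample_random <- function(domain, presences, n, seed = 1) {
  grid_check(domain, "domain")
  if (n < 1) stop("n must be at least 1")
  loc <- locate_cells(domain, presences$x, presences$y)
  inb <- loc$inside
  pres_cells <- unique(loc$row[inb] + (loc$col[inb] - 1L) * nrow(domain$values))
  avail <- setdiff(which(!is.na(domain$values)), pres_cells)
  if (n > length(avail))
    stop(sprintf("requested %d pseudo-absences but only %d cells are available",
                 n, length(avail)))
  pick <- with_seed(derive_seed(seed, "random"), {
    if (length(avail) == 1) avail else sample(avail, n)
  })
  ctr <- cell_centers(domain)
  data.frame(x = ctr[pick, 1], y = ctr[pick, 2], cell = pick, label = 0)
}

#' Build the replicate pseudo-absence groups
#'
#' The standard design: `n_weighted` (default 10) groups drawn from the
#' suitability/distance weight map plus one uniform-random group, each of
#' size equal to the number of presences, so every merged training set has
#' prevalence exactly 0.5.
#'
#' @param hsi `sdm_grid` of habitat suitability in `[0, 100]`.
#' @param presences data.frame with columns `x`, `y`.
#' @param n_weighted number of weighted groups (default 10).
#' @param seed master seed; per-group seeds are derived from it.
#' @return object of class `pa_groups`: list of data.frames with columns
#'   `x`, `y`, `cell`, `label`, `group`, `method` (the random group last),
#'   plus the `tau` map as an attribute.
#' @export
make_groups <- function(hsi, presences, n_weighted = 10, seed = 1) {
  n <- nrow(presences)
  if (!n) stop("no presences supplied")
  d_r <- normalized_distance(hsi, presences)
  tau <- weight_map(hsi, d_r)
  groups <- vector("list", n_weighted + 1)
  for (g in seq_len(n_weighted)) {
    pa <- sample_weighted(tau, n, seed = derive_seed(seed, "group", g))
    pa$group <- g; pa$method <- "weighted"
    groups[[g]] <- pa
  }
  pa <- sample_random(hsi, presences, n,
                      seed = derive_seed(seed, "group", "random"))
  pa$group <- n_weighted + 1; pa$method <- "random"
  groups[[n_weighted + 1]] <- pa
  structure(groups, class = "pa_groups", tau = tau)
}

#' Merge presences with one pseudo-absence group into a training set
#'
#' @param presences data.frame with columns `x`, `y` (label 1 is added).
#' @param group one element of [make_groups()] output (label 0).
#' @return data.frame with columns `x`, `y`, `label`.
#' @export
training_set <- function(presences, group) {
  rbind(data.frame(x = presences$x, y = presences$y, label = 1),
        data.frame(x = group$x, y = group$y, label = 0))
}
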