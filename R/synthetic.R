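# Virtual seascapes, virtual species and trawl-like surveys. Everything here
# is a pure function of (parameters, seed): the RNG state is saved and
# restored around every stochastic block.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Deterministic per-stage seed derivation: every stochastic stage traces to
# the master seed through this one function. Result always < 2^31.
derive_seed <- function(master, ...) {
  tokens <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tokens)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

# Repeated 3x3 mean filter with edge replication: cheap smooth random field
# used for the terrain, seafloor and seagrass surfaces.
smooth_field <- function(m, passes = 4L) {
  for (k in seq_len(passes)) {
    p <- rbind(m[1, ], m, m[nrow(m), ])
    p <- cbind(p[, 1], p, p[, ncol(p)])
    nr <- nrow(m); nc <- ncol(m)
    acc <- matrix(0, nr, nc)
    for (dr in 0:2) for (dc in 0:2)
      acc <- acc + p[dr + seq_len(nr), dc + seq_len(nc)]
    m <- acc / 9
  }
  m
}

#' Generate a synthetic coastal environment stack
#'
#' Emulates a gridded shelf seascape: a shoreline along the western edge,
#' depth increasing smoothly offshore (0 to about 200 m) with a smooth noise
#' component, a categorical seafloor-type layer with `n_seafloor` occupied
#' classes, and the derived terrain layers (slope, eastness, northness,
#' distance to shore) computed with the package's own raster operators.
#'
#' @param nx,ny grid size in cells (each at least 20).
#' @param cell_size cell edge in map units (default 90, a typical coastal
#'   DEM resolution).
#' @param seed integer seed; same seed, same stack, bit for bit.
#' @param max_depth deepest water on the offshore edge (m).
#' @param noise_sd standard deviation (m) of the smooth bathymetric noise;
#'   0 gives the pure monotone profile.
#' @param n_seafloor number of seafloor categories (2 to 26, default 8).
#' @return an `sdm_stack` with layers `depth`, `slope`, `eastness`,
#'   `northness`, `dshore`, `seafloor`, plus attribute `shore_mask`.
#' @export
generate_environment <- function(nx = 60, ny = 40, cell_size = 90,
                                 seed = 1, max_depth = 200,
                                 noise_sd = 6, n_seafloor = 8) {
  if (nx < 20 || ny < 20) stop("nx and ny must both be at least 20")
  if (n_seafloor < 2 || n_seafloor > 26)
    stop("n_seafloor must be between 2 and 26")
  with_seed(derive_seed(seed, "environment"), {
    # shoreline: full western column
    shore <- matrix(0, ny, nx); shore[, 1] <- 1
    shore_g <- new_grid(shore, 0, ny * cell_size, cell_size)
    dsh <- distance_to_shore(shore_g)
    # monotone offshore profile + smooth noise, clamped at >= 0
    prof <- max_depth * (dsh$values / max(dsh$values))^1.2
    if (noise_sd > 0) {
      z <- smooth_field(matrix(stats::rnorm(ny * nx), ny, nx), 5L)
      z <- z / stats::sd(z)
      depth <- pmax(prof + noise_sd * z, 0)
    } else depth <- prof
    depth_g <- new_grid(depth, 0, ny * cell_size, cell_size)
    slope_g <- derive_slope(depth_g)
    asp <- derive_aspect_components(depth_g)
    # categorical seafloor: quantile-sliced smooth field, all classes occupied
    sf <- smooth_field(matrix(stats::rnorm(ny * nx), ny, nx), 3L)
    br <- stats::quantile(sf, probs = seq(0, 1, length.out = n_seafloor + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    sfc <- matrix(as.numeric(cut(sf, br, labels = FALSE)), ny, nx)
    sf_g <- new_grid(sfc, 0, ny * cell_size, cell_size,
                     kind = "categorical", levels = seq_len(n_seafloor))
    st <- new_stack(list(depth = depth_g, slope = slope_g,
                         eastness = asp$eastness, northness = asp$northness,
                         dshore = dsh, seafloor = sf_g))
    attr(st, "shore_mask") <- shore_g
    st
  })
}

#' Define a virtual species
#'
#' The species' true suitability is a logistic response on standardised
#' quantitative predictors, optionally plus a spatially autocorrelated
#' Gaussian field on the logit scale (the "real factors" a pure habitat
#' model cannot capture, which gives kriging a recoverable signal).
#'
#' @param niche named numeric vector of coefficients on standardised
#'   quantitative layers (names must match stack layers).
#' @param intercept logit-scale intercept.
#' @param detection_prob probability in (0, 1] that a present individual is
#'   recorded by a haul (false absences arise when < 1).
#' @param spatial_sd standard deviation of the logit-scale spatial field
#'   (0 disables it).
#' @param spatial_range range parameter (map units) of the exponential
#'   covariance of that field.
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(niche, intercept = 0, detection_prob = 1,
                            spatial_sd = 0, spatial_range = 500) {
  stopifnot(is.numeric(niche), !is.null(names(niche)),
            detection_prob > 0, detection_prob <= 1,
            spatial_sd >= 0, spatial_range > 0)
  structure(list(niche = niche, intercept = intercept,
                 detection_prob = detection_prob,
                 spatial_sd = spatial_sd, spatial_range = spatial_range),
            class = "virtual_species")
}

#' Simulate a Gaussian random field with exponential covariance
#'
#' Dense Cholesky factorisation of `sd^2 * exp(-d / range)` evaluated at the
#' supplied coordinates; intended for the few thousand locations of a
#' desk-scale seascape.
#'
#' @param coords matrix of (x, y) locations.
#' @param sd marginal standard deviation.
#' @param range exponential range parameter (map units).
#' @param seed integer seed.
#' @return numeric vector of field values.
#' @export
simulate_gaussian_field <- function(coords, sd, range, seed = 1) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  cov <- sd^2 * exp(-d / range)
  L <- chol(cov + diag(1e-8, n))
  with_seed(seed, as.vector(crossprod(L, stats::rnorm(n))))
}

#' True suitability grid of a virtual species
#'
#' @param stack an `sdm_stack`.
#' @param vs a `virtual_species`.
#' @param seed seed for the spatial field component.
#' @return quantitative `sdm_grid` with values in `[0, 1]`.
#' @export
species_truth <- function(stack, vs, seed = 1) {
  tab <- stack_table(stack)
  miss <- setdiff(names(vs$niche), names(tab))
  if (length(miss))
    stop("niche names missing from stack: ", paste(miss, collapse = ", "))
  logit <- rep(vs$intercept, nrow(tab))
  for (nm in names(vs$niche)) {
    v <- tab[[nm]]
    if (!is.numeric(v)) stop(sprintf("niche layer '%s' is not quantitative", nm))
    logit <- logit + vs$niche[[nm]] * as.vector(scale(v))
  }
  if (vs$spatial_sd > 0)
    logit <- logit + simulate_gaussian_field(
      cbind(tab$x, tab$y), vs$spatial_sd, vs$spatial_range,
      derive_seed(seed, "field"))
  ref <- stack$layers[[1]]
  m <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  m[tab$cell] <- stats::plogis(logit)
  new_grid(m, ref$x_origin, ref$y_origin, ref$cell_size)
}

#' Define a stratified-random trawl survey
#'
#' @param n_hauls total number of hauls.
#' @param strata data.frame with columns `depth_min`, `depth_max`,
#'   `fraction`; fractions must sum to 1 and strata must not overlap.
#'   The default mirrors a three-stratum shelf survey (0-25, 25-65,
#'   65-200 m).
#' @param seed integer seed.
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(n_hauls = 360,
                          strata = data.frame(
                            depth_min = c(0, 25, 65),
                            depth_max = c(25, 65, 200),
                            fraction = c(0.4, 0.35, 0.25)),
                          seed = 1) {
  stopifnot(n_hauls > 0, nrow(strata) >= 1)
  if (abs(sum(strata$fraction) - 1) > 1e-9)
    stop("stratum fractions must sum to 1")
  o <- order(strata$depth_min)
  strata <- strata[o, ]
  if (any(strata$depth_max[-nrow(strata)] > strata$depth_min[-1] + 1e-9))
    stop("strata must not overlap")
  structure(list(n_hauls = as.integer(n_hauls), strata = strata,
                 seed = seed), class = "survey_design")
}

# Largest-remainder apportionment of n into fractions.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Place stratified-random haul locations
#'
#' Haul counts per depth stratum follow the design fractions exactly
#' (largest-remainder rounding); cells are drawn without replacement within
#' each stratum and hauls sit at cell centres.
#'
#' @param stack an `sdm_stack` with a `depth` layer.
#' @param design a `survey_design`.
#' @param seed overrides the design seed when given.
#' @return data.frame with columns `x`, `y`, `cell`, `stratum`.
#' @export
generate_hauls <- function(stack, design, seed = NULL) {
  if (is.null(seed)) seed <- design$seed
  depth <- stack$layers$depth
  if (is.null(depth)) stop("stack has no 'depth' layer")
  valid <- stack_valid_mask(stack)
  counts <- largest_remainder(design$n_hauls, design$strata$fraction)
  ctr <- cell_centers(depth)
  with_seed(derive_seed(seed, "hauls"), {
    rows <- vector("list", nrow(design$strata))
    for (s in seq_len(nrow(design$strata))) {
      lo <- design$strata$depth_min[s]; hi <- design$strata$depth_max[s]
      last <- s == nrow(design$strata)
      elig <- which(valid & !is.na(depth$values) & depth$values >= lo &
                      (if (last) depth$values <= hi else depth$values < hi))
      if (length(elig) < counts[s])
        stop(sprintf("stratum %d (%g-%g m) has %d eligible cells for %d hauls",
                     s, lo, hi, length(elig), counts[s]))
      pick <- if (length(elig) == 1) elig else sample(elig, counts[s])
      rows[[s]] <- data.frame(x = ctr[pick, 1], y = ctr[pick, 2],
                              cell = pick, stratum = s)
    }
    do.call(rbind, rows)
  })
}

#' Simulate a presence-only trawl record for a virtual species
#'
#' At each haul the species is recorded with probability
#' `truth_suitability * detection_prob`; only the presences are returned
#' (the presence-only situation of bottom-trawl occurrence data), together
#' with the hidden truth grid for validation.
#'
#' @param stack an `sdm_stack`.
#' @param vs a `virtual_species`.
#' @param design a `survey_design`.
#' @param seed master seed for hauls, field and detection.
#' @param species code attached to the occurrence records.
#' @param hauls optional pre-generated haul table (to share hauls across
#'   species, as one survey does).
#' @return list with `hauls`, `occurrences` (presences only), and `truth`.
#' @export
generate_species <- function(stack, vs, design, seed = 1,
                             species = "SP1", hauls = NULL) {
  if (is.null(hauls)) hauls <- generate_hauls(stack, design, seed)
  truth <- species_truth(stack, vs, seed)
  p <- truth$values[hauls$cell] * vs$detection_prob
  caught <- with_seed(derive_seed(seed, "detect", species),
                      stats::runif(nrow(hauls)) < p)
  occ <- hauls[caught, c("x", "y", "cell")]
  occ$species <- rep(species, nrow(occ))
  rownames(occ) <- NULL
  list(hauls = hauls, occurrences = occ, truth = truth)
}

#' Filter to relatively common species
#'
#' Keeps the species recorded in strictly more than `min_frac` of hauls —
#' the commonness rule used to avoid fitting models on tiny samples.
#'
#' @param occurrences data.frame with a `species` column (one row per
#'   presence record).
#' @param n_hauls total hauls in the survey.
#' @param min_frac strict lower bound on occurrence frequency (default 0.10).
#' @return character vector of retained species codes.
#' @export
filter_common_species <- function(occurrences, n_hauls, min_frac = 0.10) {
  if (n_hauls <= 0) stop("n_hauls must be positive")
  if (!nrow(occurrences)) return(character(0))
  counts <- table(occurrences$species)
  names(counts)[counts / n_hauls > min_frac]
}

#' Generate a synthetic seagrass recovery-rate layer
#'
#' A smooth 0-100% surface concentrated inshore, standing in for a mapped
#' seagrass recovery-rate product.
#'
#' @param stack an `sdm_stack` with a `dshore` layer.
#' @param seed integer seed.
#' @return quantitative `sdm_grid` in `[0, 100]`.
#' @export
generate_seagrass <- function(stack, seed = 1) {
  dsh <- stack$layers$dshore
  if (is.null(dsh)) stop("stack has no 'dshore' layer")
  with_seed(derive_seed(seed, "seagrass"), {
    z <- smooth_field(matrix(stats::rnorm(length(dsh$values)),
                             nrow(dsh$values)), 4L)
    z <- (z - min(z)) / (max(z) - min(z))
    inshore <- 1 - dsh$values / max(dsh$values)
    v <- 100 * pmin(1, pmax(0, 0.65 * inshore + 0.55 * z))
    new_grid(matrix(v, nrow(dsh$values), ncol(dsh$values)),
             dsh$x_origin, dsh$y_origin, dsh$cell_size)
  })
}
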