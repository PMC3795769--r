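# Ecological Niche Factor Analysis: contrasts the environmental space
# occupied by a species (presence rows) with the whole study area
# (background rows). The first factor, marginality, is the standardised
# shift of the niche centroid from the background centroid; the remaining
# factors, specialisation, maximise the ratio of background to niche
# variance in the subspace orthogonal to marginality (in the niche
# covariance metric), so large eigenvalues flag a narrow niche.

as_num_matrix <- function(x, arg) {
  if (is.data.frame(x)) {
    if (!all(vapply(x, is.numeric, TRUE)))
      stop(sprintf("`%s` must be all-quantitative; ordinate mixed tables first", arg))
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

#' Fit an ecological niche factor analysis
#'
#' Predictors are standardised over the background (mean 0, variance 1);
#' the marginality vector `m` is the mean of the standardised presence
#' rows and the global marginality coefficient is `M = ||m|| / 1.96`, so
#' `M` near 1 places the niche centroid near the background's 95% bound.
#' Specialisation eigenvalues are ratios of background to presence variance
#' along each factor; factor 1 always spans `m`.
#'
#' @param background matrix/data.frame of predictor rows describing the
#'   study area (typically all valid cells, or Hill-Smith scores of them).
#' @param presences matrix/data.frame of predictor rows at the occurrence
#'   locations, in the same column space.
#' @param keep_threshold retained specialisation factors are the smallest
#'   set explaining at least this share of total specialisation
#'   (default 0.9), capped at `max_factors`.
#' @param max_factors cap on retained factors (default 5).
#' @return object of class `enfa` with `marginality_vector`,
#'   `marginality_coefficient`, `factors` (columns, factor 1 first),
#'   `eigenvalues`, `n_factors_kept`, presence factor scores and the
#'   background transform.
#' @export
fit_enfa <- function(background, presences, keep_threshold = 0.9,
                     max_factors = 5) {
  B <- as_num_matrix(background, "background")
  P <- as_num_matrix(presences, "presences")
  p <- ncol(B)
  if (ncol(P) != p) stop("background and presences must share columns")
  if (nrow(P) < p + 2)
    stop(sprintf("need at least %d presences for %d predictors", p + 2, p))
  mu <- colMeans(B)
  sg <- sqrt(colMeans(sweep(B, 2, mu)^2))
  if (any(sg < 1e-12)) stop("constant background predictor")
  Zb <- sweep(sweep(B, 2, mu), 2, sg, `/`)
  Zp <- sweep(sweep(P, 2, mu), 2, sg, `/`)
  m <- colMeans(Zp)
  M <- sqrt(sum(m^2)) / 1.96
  Sg <- stats::cov(Zb)
  Se <- stats::cov(Zp)
  eg <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
  if (min(eg) < 1e-10 * max(eg))
    stop("background covariance is singular; ordinate the predictors first")
  ee <- eigen((Se + t(Se)) / 2, symmetric = TRUE)
  if (max(ee$values) < 1e-12)
    stop("presence covariance is singular (too few distinct presences)")
  floor_ev <- max(ee$values) * 1e-8
  if (min(ee$values) < floor_ev) {
    warning("near-singular presence covariance; specialisation along ",
            "degenerate directions is capped")
    ee$values <- pmax(ee$values, floor_ev)
  }
  A <- ee$vectors %*% (sqrt(ee$values) * t(ee$vectors))      # Se^{1/2}
  Ainv <- ee$vectors %*% ((1 / sqrt(ee$values)) * t(ee$vectors))
  W <- Ainv %*% Sg %*% Ainv
  W <- (W + t(W)) / 2
  y <- as.vector(A %*% m)
  if (sqrt(sum(y^2)) < 1e-12) y <- c(1, rep(0, p - 1)) else y <- y / sqrt(sum(y^2))
  lambda1 <- as.numeric(t(y) %*% W %*% y)
  if (p > 1) {
    Q <- qr.Q(qr(cbind(y)), complete = TRUE)[, -1, drop = FALSE]
    H <- t(Q) %*% W %*% Q
    eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
    U <- cbind(Ainv %*% y, Ainv %*% Q %*% eh$vectors)
    lambdas <- c(lambda1, pmax(eh$values, 0))
  } else {
    U <- matrix(Ainv %*% y, ncol = 1)
    lambdas <- lambda1
  }
  colnames(U) <- paste0("F", seq_len(ncol(U)))
  share <- cumsum(lambdas / sum(lambdas))
  n_keep <- min(max_factors, which(share >= keep_threshold)[1], length(lambdas))
  structure(
    list(marginality_vector = m, marginality_coefficient = M,
         factors = U, eigenvalues = lambdas, n_factors_kept = n_keep,
         presence_scores = Zp %*% U, mu = mu, sg = sg,
         n_background = nrow(B), n_presence = nrow(P)),
    class = "enfa")
}

#' @export
print.enfa <- function(x, ...) {
  cat(sprintf("<enfa> %d predictors, %d presences / %d background rows\n",
              length(x$marginality_vector), x$n_presence, x$n_background))
  cat(sprintf("  marginality M = %.3f; specialisation eigenvalues: %s\n",
              x$marginality_coefficient,
              paste(sprintf("%.2f", x$eigenvalues), collapse = ", ")))
  cat(sprintf("  %d factor(s) retained\n", x$n_factors_kept))
  invisible(x)
}

enfa_scores <- function(object, X) {
  X <- as_num_matrix(X, "X")
  Z <- sweep(sweep(X, 2, object$mu), 2, object$sg, `/`)
  Z %*% object$factors
}

#' Habitat suitability index from a fitted ENFA
#'
#' For each retained factor, the suitability of a location is the share of
#' presence observations lying at least as far from the presence median
#' (two-sided) as the location's factor score — 1 at the niche centre, 0
#' beyond the outermost presence. Per-factor suitabilities are combined as
#' a weighted mean (weights proportional to the specialisation eigenvalues,
#' with the marginality factor given the largest eigenvalue) and scaled to
#' 0-100.
#'
#' @param object a fitted `enfa`.
#' @param X matrix/data.frame of locations in the original predictor space.
#' @return numeric vector of HSI values in `[0, 100]`.
#' @export
habitat_suitability <- function(object, X) {
  if (!inherits(object, "enfa")) stop("`object` must be a fitted enfa")
  S <- enfa_scores(object, X)
  nk <- object$n_factors_kept
  lam <- object$eigenvalues[seq_len(nk)]
  w <- lam
  w[1] <- max(object$eigenvalues)   # marginality factor carries max weight
  w <- w / sum(w)
  n_pres <- nrow(object$presence_scores)
  hsi <- numeric(nrow(S))
  for (f in seq_len(nk)) {
    ps <- object$presence_scores[, f]
    med <- stats::median(ps)
    pd <- abs(ps - med)
    d <- abs(S[, f] - med)
    # share of presences at least as extreme as the cell (ties count)
    cnt <- vapply(d, function(di) sum(pd >= di - 1e-12), 0)
    hsi <- hsi + w[f] * cnt / n_pres
  }
  unname(pmin(pmax(100 * hsi, 0), 100))
}

#' Map the habitat suitability index over a stack
#'
#' @param object a fitted `enfa` whose predictor space matches `scores` of
#'   the stack table (see `predict.hill_smith`).
#' @param stack an `sdm_stack` (geometry template).
#' @param cell_scores matrix of per-valid-cell rows in the ENFA predictor
#'   space, aligned with `stack_table(stack)`.
#' @return quantitative `sdm_grid` with HSI in `[0, 100]`.
#' @export
hsi_grid <- function(object, stack, cell_scores) {
  tab_cells <- stack_table(stack)$cell
  if (nrow(as_num_matrix(cell_scores, "cell_scores")) != length(tab_cells))
    stop("cell_scores rows must match the stack's valid cells")
  ref <- stack$layers[[1]]
  m <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  m[tab_cells] <- habitat_suitability(object, cell_scores)
  new_grid(m, ref$x_origin, ref$y_origin, ref$cell_size)
}

#' Monte-Carlo randomisation test of the marginality coefficient
#'
#' Repeatedly relocates the presences to random background rows (uniform,
#' without replacement), recomputes the marginality coefficient `M`, and
#' returns the one-sided permutation p-value
#' `(1 + #\{M_perm >= M_obs\}) / (1 + n_perm)`.
#'
#' @param background matrix/data.frame of background predictor rows.
#' @param presences matrix/data.frame of presence predictor rows.
#' @param n_perm number of permutations (at least 19; default 100, giving
#'   a p-value floor of 1/101).
#' @param seed integer seed; same seed, same p-value.
#' @return list with `p_value`, `M_obs`, `M_perm`.
#' @export
marginality_test <- function(background, presences, n_perm = 100, seed = 1) {
  if (n_perm < 19) stop("n_perm must be at least 19")
  B <- as_num_matrix(background, "background")
  P <- as_num_matrix(presences, "presences")
  n_pres <- nrow(P)
  if (nrow(B) < n_pres) stop("too few background rows to relocate presences")
  mu <- colMeans(B)
  sg <- sqrt(colMeans(sweep(B, 2, mu)^2))
  if (any(sg < 1e-12)) stop("constant background predictor")
  Zb <- sweep(sweep(B, 2, mu), 2, sg, `/`)
  Zp <- sweep(sweep(P, 2, mu), 2, sg, `/`)
  M_obs <- sqrt(sum(colMeans(Zp)^2)) / 1.96
  M_perm <- with_seed(derive_seed(seed, "margtest"), {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nrow(Zb), n_pres)
      sqrt(sum(colMeans(Zb[idx, , drop = FALSE])^2)) / 1.96
    }, 0)
  })
  list(p_value = (1 + sum(M_perm >= M_obs)) / (1 + n_perm),
       M_obs = M_obs, M_perm = M_perm)
}
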