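# Logistic regression-kriging: a binomial GLM on ordination components
# selected by stepwise AIC, plus ordinary kriging of the response-scale
# residuals when they carry spatial structure. Residuals are kriged on the
# probability scale (r = y - p_hat) because binary labels make link-scale
# residuals unbounded; the combined prediction is clamped to [0, 1].

## ---- logistic regression -------------------------------------------------

ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100, tol = 1e-8) {
  X1 <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X))), ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X1 %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- crossprod(X1, y - p) - pen %*% beta
    Hm <- crossprod(X1 * w, X1) + pen
    step <- solve(Hm, grad)
    beta <- beta + step
    if (max(abs(grad)) < tol) break
  }
  as.vector(beta)
}

new_logistic_model <- function(coefficients, aic, fitted, terms_kept,
                               ridge = FALSE, glm_fit = NULL) {
  structure(list(coefficients = coefficients, aic = aic, fitted = fitted,
                 terms_kept = terms_kept, ridge = ridge, glm_fit = glm_fit),
            class = "logistic_model")
}

#' Fit a binomial GLM on presence/pseudo-absence data
#'
#' Maximum-likelihood logistic regression of a 0/1 label on predictor
#' columns. Perfect separation is flagged with a warning and handled by a
#' lightly ridge-penalised refit so coefficients stay finite.
#'
#' @param data data.frame with a 0/1 `label` column; every other numeric
#'   column is a predictor (columns `x`, `y`, `cell` are ignored as
#'   coordinates/bookkeeping).
#' @return object of class `logistic_model` with `coefficients`, `aic`,
#'   `fitted` (training probabilities) and `terms_kept`.
#' @export
fit_logistic <- function(data) {
  preds <- setdiff(names(data), c("label", "x", "y", "cell"))
  if (length(unique(data$label)) < 2)
    stop("both classes must be present")
  if (anyNA(data[c("label", preds)])) stop("missing values are not allowed")
  fml <- stats::as.formula(paste("label ~",
                                 if (length(preds)) paste(preds, collapse = " + ")
                                 else "1"))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || any(abs(stats::coef(fit)[-1]) > 50, na.rm = TRUE)) {
    warning("possible complete separation; refitting with a small ridge penalty")
    X <- as.matrix(data[preds])
    beta <- ridge_logistic(X, data$label)
    p <- stats::plogis(as.vector(cbind(1, X) %*% beta))
    ll <- sum(data$label * log(p) + (1 - data$label) * log(1 - p))
    names(beta) <- c("(Intercept)", preds)
    return(new_logistic_model(beta, -2 * ll + 2 * length(beta), p, preds,
                              ridge = TRUE))
  }
  new_logistic_model(stats::coef(fit), stats::AIC(fit), stats::fitted(fit),
                     preds, glm_fit = fit)
}

#' Bidirectional stepwise AIC selection for the logistic model
#'
#' Starts from the full model and adds/drops single predictors until no
#' move lowers the AIC (ties resolved towards the smaller model, then the
#' earlier term, which makes the search deterministic).
#'
#' @inheritParams fit_logistic
#' @return a `logistic_model` for the selected predictor subset.
#' @export
stepwise_aic <- function(data) {
  full <- fit_logistic(data)
  if (full$ridge) return(full)   # separation: selection is meaningless
  sel <- stats::step(full$glm_fit, direction = "both", trace = 0)
  kept <- setdiff(attr(stats::terms(sel), "term.labels"), character(0))
  new_logistic_model(stats::coef(sel), stats::AIC(sel), stats::fitted(sel),
                     kept, glm_fit = sel)
}

predict_logistic <- function(model, newdata) {
  co <- model$coefficients
  eta <- rep(co[["(Intercept)"]], nrow(newdata))
  for (nm in model$terms_kept)
    if (nm %in% names(co)) eta <- eta + co[[nm]] * newdata[[nm]]
  stats::plogis(eta)
}

## ---- variograms ----------------------------------------------------------

coerce_xy <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  else if (is.matrix(x)) x <- x[, 1:2, drop = FALSE]
  else x <- matrix(x, ncol = 2)
  storage.mode(x) <- "double"
  x
}

#' Empirical semivariogram of residuals
#'
#' Classical (Matheron) estimator: half the mean squared difference of all
#' point pairs, binned by separation distance.
#'
#' @param locations matrix or data.frame of (x, y) coordinates.
#' @param residuals numeric vector, one per location.
#' @param n_lags number of equal-width distance bins (default 12).
#' @param max_dist largest pair separation used; default half the maximum
#'   pairwise distance.
#' @return data.frame of class `empirical_variogram` with columns `lag`
#'   (bin centre), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(locations, residuals, n_lags = 12,
                                max_dist = NULL) {
  locs <- coerce_xy(locations)
  n <- nrow(locs)
  if (n < 2) stop("need at least 2 points")
  if (n < 30) warning("fewer than 30 points; the variogram will be unstable")
  d <- stats::dist(locs)
  if (max(d) <= 0) stop("all points are coincident")
  if (is.null(max_dist)) max_dist <- max(d) / 2
  dv <- as.vector(d)
  rr <- as.vector(stats::dist(matrix(residuals, ncol = 1)))^2 / 2
  keep <- dv <= max_dist
  br <- seq(0, max_dist, length.out = n_lags + 1)
  bin <- pmin(pmax(findInterval(dv[keep], br, rightmost.closed = TRUE), 1), n_lags)
  gamma <- tapply(rr[keep], bin, mean)
  cnt <- tapply(rr[keep], bin, length)
  idx <- as.integer(names(gamma))
  out <- data.frame(lag = (br[idx] + br[idx + 1]) / 2,
                    gamma = as.numeric(gamma), n_pairs = as.integer(cnt))
  class(out) <- c("empirical_variogram", "data.frame")
  attr(out, "max_dist") <- max_dist
  out
}

vgm_curve <- function(family, nugget, psill, range, h) {
  s <- switch(family,
    spherical = ifelse(h >= range, 1, 1.5 * h / range - 0.5 * (h / range)^3),
    exponential = 1 - exp(-h / range),
    stop("unknown variogram family"))
  ifelse(h <= 0, 0, nugget + psill * s)
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares (weights `n_pairs / lag^2`) over the spherical
#' and exponential families; the better-fitting family wins. Spatial
#' structure is declared absent when the structured share of the sill is
#' under 5%, when the fitted range is shorter than the first lag, or when
#' the structured model barely improves on a flat (pure-nugget) variogram
#' (under 5% WLS loss reduction) — in any of these cases downstream
#' prediction falls back to the plain GLM surface.
#'
#' @param emp an `empirical_variogram`.
#' @param min_nugget lower bound on the nugget. For residuals of a binomial
#'   model the micro-scale variance is known — the Bernoulli variance
#'   `mean(p*(1-p))` — and passing it here stops the fit from disguising
#'   that noise as short-range spatial structure.
#' @return object of class `variogram_model` with `family`, `nugget`,
#'   `partial_sill`, `range`, `has_structure` and the empirical lags.
#' @export
fit_variogram_model <- function(emp, min_nugget = 0) {
  if (nrow(emp) < 4) stop("need at least 4 non-empty lags")
  h <- emp$lag; g <- emp$gamma; w <- emp$n_pairs / pmax(h, 1e-9)^2
  sill0 <- mean(g[(length(g) - min(2, length(g) - 1)):length(g)])
  mx <- max(g); md <- max(h)
  # box bounds keep the search away from the degenerate near-linear limit
  # (huge partial sill with huge range) where parameters are unidentifiable
  lower <- log(c(max(min_nugget, 1e-8), 1e-8, md / 50))
  upper <- log(c(2 * mx + max(min_nugget, 1e-8), 10 * mx + 1e-8, 4 * md))
  best <- NULL
  for (fam in c("spherical", "exponential")) {
    loss <- function(par) {
      nug <- exp(par[1]); ps <- exp(par[2]); rg <- exp(par[3])
      sum(w * (g - vgm_curve(fam, nug, ps, rg, h))^2)
    }
    inits <- list(
      log(c(max(min(g), sill0 * 0.1, 1e-6),
            max(sill0 - min(g), sill0 * 0.5, 1e-6), md / 3)),
      log(c(max(sill0 * 0.5, 1e-6), max(sill0 * 0.5, 1e-6), md)),
      log(c(1e-4, max(sill0, 1e-6), md / 6)))
    for (init in inits) {
      init <- pmin(pmax(init, lower), upper)
      opt <- try(stats::optim(init, loss, method = "L-BFGS-B",
                              lower = lower, upper = upper,
                              control = list(maxit = 500)),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value < best$value)
        best <- list(value = opt$value, family = fam,
                     nugget = exp(opt$par[1]), psill = exp(opt$par[2]),
                     range = exp(opt$par[3]),
                     converged = opt$convergence %in% c(0, 52))
    }
  }
  if (is.null(best) || !best$converged) {
    warning("variogram fit did not converge; treating residuals as spatially independent")
    return(structure(list(family = "none", nugget = if (is.null(best)) mean(g) else best$nugget,
                          partial_sill = 0, range = NA_real_,
                          has_structure = FALSE, empirical = emp),
                     class = "variogram_model"))
  }
  flat_loss <- sum(w * (g - stats::weighted.mean(g, w))^2)
  has_structure <- best$psill / (best$nugget + best$psill) >= 0.05 &&
    best$range >= min(h) &&
    best$value < 0.95 * flat_loss
  structure(list(family = best$family, nugget = best$nugget,
                 partial_sill = best$psill, range = best$range,
                 has_structure = has_structure, empirical = emp,
                 wls_loss = best$value),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g\n",
              x$family, x$nugget, x$partial_sill, x$range))
  cat(sprintf("  spatial structure: %s\n",
              if (x$has_structure) "present" else "absent"))
  invisible(x)
}

#' Moran's I permutation test for residual spatial autocorrelation
#'
#' Inverse-distance weighted Moran's I restricted to local pairs (the
#' closest `neighbour_q` share of pairwise distances), with a one-sided
#' permutation null: residual values are shuffled across locations, which
#' destroys any spatial arrangement while keeping the value distribution.
#' Restricting to local pairs concentrates power at the separations where
#' residual autocorrelation lives instead of diluting it over the whole
#' domain.
#'
#' @param locations matrix/data.frame of (x, y).
#' @param values numeric vector (residuals).
#' @param n_perm number of permutations (default 199).
#' @param seed integer seed; the test is deterministic given the seed.
#' @param neighbour_q distance-quantile defining the local neighbourhood
#'   (default 0.1).
#' @return list with `I_obs`, `p_value`.
#' @export
moran_test <- function(locations, values, n_perm = 199, seed = 1,
                       neighbour_q = 0.1) {
  locs <- coerce_xy(locations)
  n <- nrow(locs)
  if (n < 10) stop("need at least 10 locations")
  d <- as.matrix(stats::dist(locs))
  thr <- stats::quantile(d[upper.tri(d)], neighbour_q)
  W <- ifelse(d <= thr, 1 / pmax(d, 1e-9), 0)
  diag(W) <- 0
  z <- values - mean(values)
  s0 <- sum(W)
  denom <- sum(z^2)
  I_of <- function(zz) (n / s0) * as.numeric(t(zz) %*% W %*% zz) / denom
  I_obs <- I_of(z)
  I_perm <- with_seed(derive_seed(seed, "moran"), {
    vapply(seq_len(n_perm), function(i) I_of(z[sample.int(n)]), 0)
  })
  list(I_obs = I_obs,
       p_value = (1 + sum(I_perm >= I_obs)) / (1 + n_perm))
}

## ---- ordinary kriging ----------------------------------------------------

#' Ordinary kriging of point values
#'
#' Solves the ordinary-kriging system (semivariance form, with a Lagrange
#' multiplier enforcing that weights sum to 1 per target). The semivariance
#' at zero separation is 0, so prediction at a data point returns that
#' point's value exactly even with a nonzero nugget. Duplicate locations
#' are deduplicated by averaging their values.
#'
#' @param vgm a fitted `variogram_model` with `has_structure = TRUE`.
#' @param locations matrix/data.frame of training (x, y).
#' @param values numeric vector of training values.
#' @param targets matrix/data.frame of prediction (x, y).
#' @param return_weights also return the weight matrix (targets x points).
#' @param filter_nugget predict the spatially structured signal only: a
#'   target coinciding with a data point takes the nugget semivariance
#'   instead of 0 in the right-hand side, so the micro-scale noise is
#'   smoothed out rather than reproduced. The default (`FALSE`) is the
#'   exact interpolator.
#' @return numeric vector of predictions, or a list with `predictions` and
#'   `weights` when `return_weights = TRUE`.
#' @export
krige_points <- function(vgm, locations, values, targets,
                         return_weights = FALSE, filter_nugget = FALSE) {
  if (!inherits(vgm, "variogram_model") || !isTRUE(vgm$has_structure))
    stop("kriging requires a variogram model with spatial structure")
  locs <- coerce_xy(locations)
  key <- paste(locs[, 1], locs[, 2])
  if (anyDuplicated(key)) {
    warning("duplicate locations; averaging their values before kriging")
    values <- as.numeric(tapply(values, key, mean)[unique(key)])
    locs <- locs[!duplicated(key), , drop = FALSE]
  }
  n <- nrow(locs)
  tg <- coerce_xy(targets)
  gam <- function(h) vgm_curve(vgm$family, vgm$nugget, vgm$partial_sill,
                               vgm$range, h)
  if (n == 1) {
    pred <- rep(values, nrow(tg))
    if (return_weights)
      return(list(predictions = pred, weights = matrix(1, nrow(tg), 1)))
    return(pred)
  }
  D <- as.matrix(stats::dist(locs))
  K <- rbind(cbind(gam(D), 1), c(rep(1, n), 0))
  dx <- outer(tg[, 1], locs[, 1], "-")
  dy <- outer(tg[, 2], locs[, 2], "-")
  H0 <- sqrt(dx * dx + dy * dy)
  G0 <- gam(H0)
  if (filter_nugget) G0[H0 <= 0] <- vgm$nugget
  rhs <- rbind(t(G0), 1)
  sol <- solve(K, rhs)                    # (n+1) x n_targets
  Wt <- t(sol[seq_len(n), , drop = FALSE])
  pred <- as.vector(Wt %*% values)
  if (return_weights) list(predictions = pred, weights = Wt) else pred
}

## ---- regression kriging --------------------------------------------------

#' Fit a logistic regression-kriging model
#'
#' Stepwise-AIC binomial GLM on the predictor columns, then a variogram of
#' the response-scale residuals; kriging is armed only when the variogram
#' shows spatial structure.
#'
#' @param data data.frame with columns `x`, `y`, 0/1 `label` and predictor
#'   columns.
#' @param stepwise run stepwise AIC selection (default TRUE).
#' @param n_lags,max_dist passed to [empirical_variogram()].
#' @return object of class `rk_model`.
#' @export
fit_rk <- function(data, stepwise = TRUE, n_lags = 12, max_dist = NULL) {
  glm_part <- if (stepwise) stepwise_aic(data) else fit_logistic(data)
  resid <- data$label - glm_part$fitted
  emp <- suppressWarnings(
    empirical_variogram(cbind(data$x, data$y), resid, n_lags, max_dist))
  vgm <- fit_variogram_model(emp)
  # gate the variogram's verdict with a calibrated permutation test:
  # a 3-parameter curve can always improve a little on a flat variogram,
  # but only genuinely autocorrelated residuals pass Moran's I
  moran <- moran_test(cbind(data$x, data$y), resid, n_perm = 199, seed = 1)
  if (vgm$has_structure && moran$p_value > 0.05) vgm$has_structure <- FALSE
  structure(list(glm = glm_part, variogram = vgm, moran = moran,
                 locations = cbind(x = data$x, y = data$y),
                 residuals = resid),
            class = "rk_model")
}

#' Predict probability of presence with regression kriging
#'
#' Trend (inverse-logit GLM surface) plus ordinary-kriged residual, clamped
#' to `[0, 1]`. The residual surface is kriged with nugget filtering:
#' binary-label residuals carry a large micro-scale (binomial) component
#' that must not be reproduced at the sampled cells, so only the spatially
#' structured part of the residual is added back. Without residual spatial
#' structure the prediction is the plain GLM surface.
#'
#' @param object an `rk_model`.
#' @param newdata data.frame with columns `x`, `y` and the predictor
#'   columns.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.rk_model <- function(object, newdata, ...) {
  trend <- predict_logistic(object$glm, newdata)
  if (isTRUE(object$variogram$has_structure)) {
    kr <- krige_points(object$variogram, object$locations,
                       object$residuals, cbind(newdata$x, newdata$y),
                       filter_nugget = TRUE)
    pmin(pmax(trend + kr, 0), 1)
  } else trend
}

#' Map regression-kriging predictions over a stack
#'
#' @param object an `rk_model`.
#' @param stack an `sdm_stack` (geometry template).
#' @param cell_table data.frame aligned with `stack_table(stack)` holding
#'   `x`, `y` and the predictor columns for every valid cell.
#' @return quantitative `sdm_grid` of probabilities in `[0, 1]`.
#' @export
probability_grid <- function(object, stack, cell_table) {
  p <- predict(object, cell_table)
  ref <- stack$layers[[1]]
  m <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  m[stack_table(stack)$cell] <- p
  new_grid(m, ref$x_origin, ref$y_origin, ref$cell_size)
}
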