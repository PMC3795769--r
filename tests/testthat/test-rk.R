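# Logistic regression, stepwise AIC, variograms and ordinary kriging.

sim_logit <- function(n, beta0 = -1, beta1 = 2, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  p <- plogis(beta0 + beta1 * x1)
  data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100),
             label = rbinom(n, 1, p), PC1 = x1)
}

test_that("the GLM recovers known coefficients within 3 SE", {
  d <- sim_logit(2000, seed = 41)
  fit <- fit_logistic(d)
  se <- sqrt(diag(vcov(fit$glm_fit)))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - (-1)), 3 * se[1])
  expect_lt(abs(fit$coefficients[["PC1"]] - 2), 3 * se[2])
  # GLM score identity: mean fitted probability = prevalence
  expect_equal(mean(fit$fitted), mean(d$label), tolerance = 1e-8)
})

test_that("labels independent of the predictors give near-zero slopes", {
  set.seed(42)
  d <- data.frame(x = runif(1000), y = runif(1000),
                  label = rbinom(1000, 1, 0.5), PC1 = rnorm(1000))
  fit <- fit_logistic(d)
  z <- coef(summary(fit$glm_fit))["PC1", "z value"]
  expect_lt(abs(z), 4)
  expect_error(fit_logistic(data.frame(label = rep(1, 10), PC1 = rnorm(10))),
               "both classes")
})

test_that("perfect separation is flagged and handled with finite coefficients", {
  d <- data.frame(x = 1:20, y = 1:20,
                  label = rep(c(0, 1), each = 10),
                  PC1 = c(rnorm(10, -5, 0.1), rnorm(10, 5, 0.1)))
  expect_warning(fit <- fit_logistic(d), "separation")
  expect_true(fit$ridge)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("stepwise AIC keeps the signal, drops noise, and never exceeds
           the full model's AIC", {
  keep_signal <- 0; null_when_noise <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    d <- sim_logit(600, seed = 400 + r)
    for (j in 2:6) d[[paste0("PC", j)]] <- rnorm(600)   # 5 noise components
    sel <- stepwise_aic(d)
    full <- fit_logistic(d)
    expect_lte(sel$aic, full$aic + 1e-9)
    if ("PC1" %in% sel$terms_kept) keep_signal <- keep_signal + 1
    # all-noise candidates (3 of them: with more, the ~16% per-variable
    # false-inclusion rate of AIC makes a null selection a coin flip)
    d0 <- data.frame(x = d$x, y = d$y, label = rbinom(600, 1, 0.5),
                     PC1 = rnorm(600), PC2 = rnorm(600), PC3 = rnorm(600))
    sel0 <- stepwise_aic(d0)
    if (!length(sel0$terms_kept)) null_when_noise <- null_when_noise + 1
  }
  expect_gte(keep_signal, ceiling(0.95 * n_rep))
  expect_gt(null_when_noise / n_rep, 0.5)
})

test_that("the empirical variogram matches an exhaustive 4-point oracle", {
  locs <- cbind(c(0, 1, 0, 3), c(0, 0, 2, 0))
  r <- c(1, 2, 4, 0)
  emp <- suppressWarnings(
    empirical_variogram(locs, r, n_lags = 3, max_dist = 3.7))
  # all 6 pairs: d = 1, 2, sqrt(5), 2, 3, sqrt(13), binned over
  # (0, 1.233], (1.233, 2.467], (2.467, 3.7]
  # bin1: pair (1,2) d=1: 0.5*(1-2)^2 = 0.5
  # bin2: pairs (1,3) d=2: 4.5; (2,3) d=sqrt5: 2; (2,4) d=2: 2 -> mean 17/6
  # bin3: pairs (1,4) d=3: 0.5; (3,4) d=sqrt13: 8 -> mean 4.25
  expect_equal(emp$gamma, c(0.5, mean(c(4.5, 2, 2)), mean(c(0.5, 8))),
               tolerance = 1e-12)
  expect_equal(emp$n_pairs, c(1L, 3L, 2L))
  expect_error(suppressWarnings(
    empirical_variogram(cbind(c(1, 1), c(2, 2)), c(1, 2))), "coincident")
})

test_that("white-noise residuals give a flat variogram near sigma^2 and no
           detected structure", {
  set.seed(43)
  locs <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  r <- rnorm(300, sd = 0.4)
  emp <- empirical_variogram(locs, r)
  expect_true(all(abs(emp$gamma - 0.16) < 0.06))
  vg <- fit_variogram_model(emp)
  expect_false(vg$has_structure)
})

test_that("duplicated points at zero offset put zero semivariance in the
           first bin", {
  base <- as.matrix(expand.grid(x = seq(0, 30, 10), y = seq(0, 30, 10)))
  locs <- rbind(base, base + 1e-9)   # co-located duplicates
  set.seed(47)
  r <- rnorm(16); r <- c(r, r)       # identical residuals at zero offset
  # first bin is narrower than the closest distinct-pair distance (10),
  # so it holds only the duplicate pairs
  emp <- empirical_variogram(locs, r, n_lags = 6)
  expect_equal(emp$gamma[1], 0)
  expect_equal(emp$n_pairs[1], 16L)
})

test_that("exponential variogram parameters are recovered from simulated
           spatial data", {
  set.seed(44)
  n <- 500
  locs <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  d <- as.matrix(dist(locs))
  psill <- 0.04; nugget <- 0.01; rng <- 15
  cv <- psill * exp(-d / rng) + diag(nugget, n)
  r <- as.vector(crossprod(chol(cv), rnorm(n)))
  vg <- fit_variogram_model(empirical_variogram(locs, r))
  expect_true(vg$has_structure)
  sill_hat <- vg$nugget + vg$partial_sill
  expect_lt(abs(sill_hat - 0.05) / 0.05, 0.5)
  expect_lt(abs(vg$partial_sill - psill) / psill, 0.6)
  # model curve is non-decreasing in h
  h <- seq(0, 100, by = 0.5)
  curve <- fuzzsdm:::vgm_curve(vg$family, vg$nugget, vg$partial_sill,
                               vg$range, h)
  expect_true(all(diff(curve) >= -1e-12))
})

test_that("ordinary kriging is exact at data points with weights summing
           to one, and matches a hand-solved 5-point system", {
  locs <- cbind(c(0, 4, 1, 3, 2), c(0, 0, 3, 3, 1.5))
  r <- c(0.2, -0.1, 0.05, 0.15, -0.2)
  vg <- structure(list(family = "exponential", nugget = 0.02,
                       partial_sill = 0.05, range = 3,
                       has_structure = TRUE),
                  class = "variogram_model")
  # exactness at every training location
  at_data <- krige_points(vg, locs, r, locs)
  expect_equal(at_data, r, tolerance = 1e-6)
  # hand-solved system at a fresh target
  tg <- cbind(1.7, 1.2)
  gam <- function(h) ifelse(h <= 0, 0, 0.02 + 0.05 * (1 - exp(-h / 3)))
  D <- as.matrix(dist(locs))
  K <- rbind(cbind(gam(D), 1), c(1, 1, 1, 1, 1, 0))
  g0 <- c(gam(sqrt((locs[, 1] - 1.7)^2 + (locs[, 2] - 1.2)^2)), 1)
  sol <- solve(K, g0)
  out <- krige_points(vg, locs, r, tg, return_weights = TRUE)
  expect_equal(as.vector(out$weights), unname(sol[1:5]), tolerance = 1e-10)
  expect_equal(sum(out$weights), 1, tolerance = 1e-10)
  expect_equal(out$predictions, sum(sol[1:5] * r), tolerance = 1e-10)
  # single training point: its value everywhere
  one <- krige_points(vg, locs[1, , drop = FALSE], r[1],
                      rbind(c(9, 9), c(0, 0)))
  expect_equal(one, c(0.2, 0.2))
  # weights sum to 1 for a batch of random targets
  tg2 <- cbind(runif(20, 0, 4), runif(20, 0, 3))
  w <- krige_points(vg, locs, r, tg2, return_weights = TRUE)$weights
  expect_equal(rowSums(w), rep(1, 20), tolerance = 1e-10)
})

test_that("duplicate kriging locations are averaged with a warning", {
  locs <- rbind(c(0, 0), c(0, 0), c(2, 2))
  vg <- structure(list(family = "spherical", nugget = 0.01,
                       partial_sill = 0.04, range = 2, has_structure = TRUE),
                  class = "variogram_model")
  expect_warning(p <- krige_points(vg, locs, c(1, 3, 0), cbind(0, 0)),
                 "duplicate")
  expect_equal(p, 2, tolerance = 1e-8)  # average of 1 and 3
})

test_that("without residual structure the RK prediction reduces exactly to
           the GLM surface", {
  set.seed(45)
  d <- sim_logit(400, seed = 46)
  fit <- suppressWarnings(fit_rk(d, stepwise = FALSE))
  fit$variogram$has_structure <- FALSE
  newd <- sim_logit(100, seed = 47)
  expect_identical(predict(fit, newd), predict_logistic(fit$glm, newd))
  # and with zero residuals kriging adds nothing
  fit2 <- fit
  fit2$variogram$has_structure <- TRUE
  fit2$variogram$family <- "exponential"
  fit2$variogram$nugget <- 0.01; fit2$variogram$partial_sill <- 0.05
  fit2$variogram$range <- 10
  fit2$residuals <- rep(0, nrow(d))
  p2 <- predict(fit2, newd)
  expect_equal(p2, predict_logistic(fit$glm, newd), tolerance = 1e-10)
  expect_true(all(p2 >= 0 & p2 <= 1))
})
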