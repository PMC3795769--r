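# Threshold optimisation, fuzzification and the fuzzy AND overlay.

mk_grid <- function(m, cs = 1) new_grid(m, cell_size = cs, y_origin = nrow(m) * cs)

test_that("perfectly separated classes put all four thresholds at the
           midpoint", {
  ts <- find_thresholds(c(0, 0, 1, 1), c(0.2, 0.2, 0.8, 0.8))
  expect_equal(ts$t_sens_eq_spec, 0.5)
  expect_equal(ts$t_max_sens_plus_spec, 0.5)
  expect_equal(ts$t_max_kappa, 0.5)
  expect_equal(ts$t_max_pcc, 0.5)
  expect_equal(ts$t_min, ts$t_max)
})

test_that("thresholds match an exhaustive search on a 10-point dataset", {
  lab <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  sc <- c(0.95, 0.8, 0.7, 0.45, 0.3, 0.65, 0.5, 0.35, 0.2, 0.05)
  ts <- find_thresholds(lab, sc)
  u <- sort(unique(sc))
  cand <- sort(unique(c(0, (u[-1] + u[-length(u)]) / 2, 1)))
  stats_at <- function(t) {
    pred <- sc >= t
    tp <- sum(pred & lab == 1); fp <- sum(pred & lab == 0)
    fn <- 5 - tp; tn <- 5 - fp
    po <- (tp + tn) / 10
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / 100
    c(sens = tp / 5, spec = tn / 5,
      kappa = if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe),
      pcc = po)
  }
  m <- sapply(cand, stats_at)
  expect_equal(ts$t_sens_eq_spec, cand[which.min(abs(m["sens", ] - m["spec", ]))])
  expect_equal(ts$t_max_sens_plus_spec,
               cand[which.max(m["sens", ] + m["spec", ])])
  expect_equal(ts$t_max_kappa, cand[which.max(m["kappa", ])])
  expect_equal(ts$t_max_pcc, cand[which.max(m["pcc", ])])
  # all four thresholds live in [min score, max score] union {0, 1}
  expect_true(all(unlist(ts)[1:4] >= 0 & unlist(ts)[1:4] <= 1))
})

test_that("max(sens+spec) equals the independently computed Youden optimum", {
  set.seed(61)
  lab <- rbinom(300, 1, 0.5)
  sc <- plogis(rnorm(300) + 1.2 * lab)
  ts <- find_thresholds(lab, sc)
  u <- sort(unique(sc))
  cand <- sort(unique(c(0, (u[-1] + u[-length(u)]) / 2, 1)))
  youden <- vapply(cand, function(t) {
    s <- sens_spec(lab, sc, t); s[[1]] + s[[2]] - 1
  }, 0)
  expect_equal(ts$t_max_sens_plus_spec, cand[which.max(youden)])
})

test_that("kappa at its optimum is near zero when labels are random", {
  set.seed(62)
  lab <- rbinom(1000, 1, 0.5)
  sc <- runif(1000)
  ts <- find_thresholds(lab, sc)
  pred <- sc >= ts$t_max_kappa
  tp <- sum(pred & lab == 1); fp <- sum(pred & lab == 0)
  fn <- sum(!pred & lab == 1); tn <- sum(!pred & lab == 0)
  k <- fuzzsdm:::cohen_kappa_counts(tp, fp, fn, tn)
  expect_lt(abs(k), 3 * sqrt(1 / 1000) + 0.05)
})

test_that("linear fuzzification anchors at the threshold extremes and is
           monotone", {
  ts <- structure(list(t_sens_eq_spec = 0.3, t_max_sens_plus_spec = 0.5,
                       t_max_kappa = 0.4, t_max_pcc = 0.7,
                       t_min = 0.3, t_max = 0.7), class = "threshold_set")
  p <- mk_grid(matrix(c(0.1, 0.3, 0.5, 0.7, 0.9, NA), 2, 3))
  mu <- fuzzify_linear(p, ts)
  expect_equal(mu$values[1, 1], 0)     # below t_min
  expect_equal(mu$values[2, 1], 0)     # at t_min
  expect_equal(mu$values[1, 2], 0.5)   # midpoint
  expect_equal(mu$values[2, 2], 1)     # at t_max
  expect_equal(mu$values[1, 3], 1)     # above t_max
  expect_true(is.na(mu$values[2, 3]))  # nodata propagates
  # degenerate equal thresholds: crisp step
  ts0 <- ts; ts0[1:4] <- 0.6; ts0$t_min <- 0.6; ts0$t_max <- 0.6
  class(ts0) <- "threshold_set"
  p2 <- mk_grid(matrix(c(0.59, 0.6, 0.61, 0.2), 2, 2))
  mu2 <- fuzzify_linear(p2, ts0)
  expect_equal(as.vector(mu2$values), c(0, 1, 1, 0))
})

test_that("breakpoint fuzzification ramps between its anchors", {
  g <- mk_grid(matrix(c(10, 30, 45, 60, 75, 100), 2, 3))
  mu <- fuzzify_breakpoints(g, 30, 60)
  expect_equal(as.vector(mu$values), c(0, 0, 0.5, 1, 1, 1))
  expect_error(fuzzify_breakpoints(g, 60, 30), "strictly less")
})

test_that("the fuzzy AND is the cell-wise minimum: absorbing, idempotent,
           order-invariant and bounded by every input", {
  set.seed(63)
  a <- mk_grid(matrix(runif(20), 4, 5))
  b <- mk_grid(matrix(runif(20), 4, 5))
  c3 <- mk_grid(matrix(runif(20), 4, 5))
  out <- fuzzy_and(list(a, b, c3))
  expect_equal(out$values, pmin(a$values, pmin(b$values, c3$values)))
  expect_true(all(out$values <= a$values & out$values <= b$values &
                    out$values <= c3$values))
  expect_equal(fuzzy_and(list(a, a))$values, a$values)           # idempotent
  expect_equal(fuzzy_and(list(c3, b, a))$values, out$values)     # order-free
  expect_equal(fuzzy_and(list(a))$values, a$values)              # identity
  z <- mk_grid(matrix(0, 4, 5))
  expect_true(all(fuzzy_and(list(a, z))$values == 0))            # absorbing
  a_na <- a; a_na$values[1, 1] <- NA
  expect_true(is.na(fuzzy_and(list(a_na, b))$values[1, 1]))
  expect_error(fuzzy_and(list(a, mk_grid(matrix(0, 3, 3)))),
               "co-registered")
})

test_that("the conservation overlay filters by accuracy, vetoes on a zero
           layer, and reduces to the seagrass ramp under full membership", {
  ts1 <- find_thresholds(c(0, 0, 1, 1), c(0.2, 0.2, 0.8, 0.8))
  ones <- mk_grid(matrix(1, 5, 5))
  sg <- mk_grid(matrix(seq(0, 100, length.out = 25), 5, 5))
  sp <- list(A = list(prob = ones, thresholds = ts1, auc = 0.95),
             B = list(prob = ones, thresholds = ts1, auc = 0.92),
             low = list(prob = ones, thresholds = ts1, auc = 0.55))
  ov <- conservation_overlay(sp, sg)
  expect_setequal(ov$species_used, c("A", "B"))   # low-accuracy species out
  ramp <- fuzzify_breakpoints(sg, 30, 60)
  expect_equal(ov$map$values, ramp$values)
  expect_equal(ov$area_nonzero, sum(ramp$values > 0))
  # a fully unsuitable species vetoes everything
  sp$B$prob <- mk_grid(matrix(0, 5, 5))
  ov0 <- conservation_overlay(sp, sg)
  expect_true(all(ov0$map$values == 0))
  expect_error(conservation_overlay(sp["low"], sg), "accuracy filter")
  # brute-force cell-wise check with three varying species maps
  set.seed(64)
  sp3 <- lapply(1:3, function(i)
    list(prob = mk_grid(matrix(runif(25), 5, 5)), thresholds = ts1,
         auc = 0.9))
  names(sp3) <- c("s1", "s2", "s3")
  ov3 <- conservation_overlay(sp3, seagrass = NULL)
  mems <- sapply(sp3, function(s)
    as.vector(fuzzify_linear(s$prob, ts1)$values))
  expect_equal(as.vector(ov3$map$values), apply(mems, 1, min))
  expect_equal(which(as.vector(ov3$map$values) > 0),
               which(apply(mems, 1, min) > 0))
})
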