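# Hill-Smith ordination: principal components of a mixed table of
# quantitative and categorical predictors. Quantitative columns are
# standardised (population sd); each factor level becomes the indicator
# contrast x/p - 1 carrying column weight p (its relative frequency), so a
# k-level factor contributes k - 1 units of inertia, exactly as in
# multiple correspondence analysis. With only quantitative columns the
# analysis reduces to correlation-matrix PCA.

hs_build <- function(df, means = NULL, sds = NULL, levels_tab = NULL,
                     freqs = NULL) {
  fit <- is.null(means)
  n <- nrow(df)
  cols <- list(); w <- c(); src <- c()
  if (fit) { means <- list(); sds <- list(); levels_tab <- list(); freqs <- list() }
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      if (fit) {
        mu <- mean(v); sg <- sqrt(mean((v - mu)^2))
        if (sg < 1e-12)
          stop(sprintf("quantitative column '%s' is constant", nm))
        means[[nm]] <- mu; sds[[nm]] <- sg
      }
      cols[[nm]] <- (v - means[[nm]]) / sds[[nm]]
      w <- c(w, 1); src <- c(src, nm)
    } else {
      v <- as.factor(v)
      if (fit) {
        lev <- levels(droplevels(v))
        if (length(lev) < 2)
          stop(sprintf("factor column '%s' has fewer than 2 observed levels", nm))
        levels_tab[[nm]] <- lev
        freqs[[nm]] <- vapply(lev, function(l) mean(v == l), 0)
      }
      lev <- levels_tab[[nm]]; p <- freqs[[nm]]
      for (j in seq_along(lev)) {
        ind <- as.numeric(v == lev[j])
        cols[[paste0(nm, ".", lev[j])]] <- ind / p[j] - 1
        w <- c(w, p[j]); src <- c(src, nm)
      }
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, w = w, src = src, means = means, sds = sds,
       levels_tab = levels_tab, freqs = freqs)
}

#' Hill-Smith ordination of a mixed predictor table
#'
#' @param df data.frame of quantitative (numeric) and categorical
#'   (factor/character) columns; no missing values.
#' @param n_keep number of components to keep (default: all with eigenvalue
#'   above `min_eigenvalue`).
#' @param min_eigenvalue smallest eigenvalue worth keeping when `n_keep` is
#'   not given; raise it to shed numerically degenerate axes.
#' @return object of class `hill_smith` with elements `scores` (row
#'   scores, variance of component k equals `eigenvalues[k]`), `loadings`,
#'   `eigenvalues`, `column_weights`, and the fitted transform so new data
#'   can be projected with [predict.hill_smith()].
#' @export
hill_smith <- function(df, n_keep = NULL, min_eigenvalue = 1e-9) {
  if (nrow(df) < 2) stop("need at least 2 rows")
  if (anyNA(df)) stop("missing values are not allowed")
  b <- hs_build(df)
  n <- nrow(b$X)
  sw <- sqrt(b$w)
  # weighted covariance C = D_c^{1/2} (X' D_r X) D_c^{1/2}, D_r = I/n
  A <- crossprod(b$X) / n
  C <- sweep(sweep(A, 1, sw, `*`), 2, sw, `*`)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- if (is.null(n_keep)) which(ev > min_eigenvalue) else seq_len(n_keep)
  V <- e$vectors[, keep, drop = FALSE]
  # row scores l = X D_c^{1/2} v  (variance of column k = lambda_k)
  proj <- sweep(V, 1, sw, `*`)
  scores <- b$X %*% proj
  colnames(scores) <- paste0("PC", seq_along(keep))
  structure(
    list(scores = scores, loadings = V, eigenvalues = ev[keep],
         all_eigenvalues = ev, column_weights = b$w, column_source = b$src,
         proj = proj, means = b$means, sds = b$sds,
         levels_tab = b$levels_tab, freqs = b$freqs,
         colnames = colnames(b$X), var_names = names(df)),
    class = "hill_smith")
}

#' Project new observations onto fitted Hill-Smith components
#'
#' @param object a `hill_smith` fit.
#' @param newdata data.frame with the same columns as the fitted table.
#' @param ... unused.
#' @return matrix of component scores.
#' @export
predict.hill_smith <- function(object, newdata, ...) {
  miss <- setdiff(object$var_names, names(newdata))
  if (length(miss))
    stop("newdata lacks columns: ", paste(miss, collapse = ", "))
  b <- hs_build(newdata[, object$var_names, drop = FALSE],
                means = object$means, sds = object$sds,
                levels_tab = object$levels_tab, freqs = object$freqs)
  scores <- b$X %*% object$proj
  colnames(scores) <- colnames(object$scores)
  scores
}
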