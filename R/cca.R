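#' Canonical correlation analysis between two variable sets
#'
#' Correlation-matrix CCA: both sets are standardized column-wise, the
#' canonical correlations r_1 >= ... >= r_m (m = min(p, q)) are the singular
#' values of the whitened cross-correlation matrix
#' Rxx^{-1/2} Rxy Ryy^{-1/2}, and the canonical variates are standardized to
#' unit variance. Working on correlations makes every loading and cross
#' loading a plain correlation coefficient.
#'
#' The result carries the sequential Wilks' lambda statistics, Bartlett
#' chi-square tests for the null that the k-th and later correlations
#' vanish, structure loadings (correlations of each raw variable with its
#' own set's variates) and cross loadings (with the other set's variates).
#' Variate signs follow a deterministic convention: the first nonzero raw
#' coefficient of each x-variate is positive, and the paired y-variate is
#' oriented so the canonical correlation is non-negative.
#'
#' @param x Numeric matrix or data frame, n rows by p columns (set 1).
#' @param y Numeric matrix or data frame, n rows by q columns (set 2).
#' @return Object of class `pes_cca`: list with `correlations`, `wilks`,
#'   `chi_square`, `df`, `p_value` (each length m), coefficient matrices
#'   `x_coef` (p x m) and `y_coef` (q x m) on the standardized scale,
#'   `x_loadings`, `y_loadings`, `x_cross_loadings` (p x m),
#'   `y_cross_loadings` (q x m), `x_scores`, `y_scores` (n x m canonical
#'   variates) and `n`, `p`, `q`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' y <- x %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(300), 100, 3)
#' cc <- canonical_correlations(x, y)
#' cc$correlations
#' @export
canonical_correlations <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  storage.mode(x) <- "double"
  storage.mode(y) <- "double"
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (n <= max(p, q)) {
    stop("need more observations than variables in either set (n = ", n,
         ", p = ", p, ", q = ", q, ")")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("all columns must be finite")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(q))
  zx <- .standardize(x, "x")
  zy <- .standardize(y, "y")
  R <- stats::cor(cbind(zx, zy))
  Rxx <- R[1:p, 1:p, drop = FALSE]
  Ryy <- R[p + 1:q, p + 1:q, drop = FALSE]
  Rxy <- R[1:p, p + 1:q, drop = FALSE]
  Wx <- .inv_sqrt(Rxx, colnames(x), "set 1")
  Wy <- .inv_sqrt(Ryy, colnames(y), "set 2")
  sv <- svd(Wx %*% Rxy %*% Wy)
  m <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(m)], 0), 1)
  a <- Wx %*% sv$u[, seq_len(m), drop = FALSE]   # x coefficients (std scale)
  b <- Wy %*% sv$v[, seq_len(m), drop = FALSE]
  # sign convention: first nonzero x coefficient positive per variate
  for (k in seq_len(m)) {
    nz <- which(abs(a[, k]) > 1e-12)
    s <- if (length(nz)) sign(a[nz[1L], k]) else 1
    a[, k] <- s * a[, k]
    b[, k] <- s * b[, k]
  }
  u <- zx %*% a   # unit-variance canonical variates (up to sampling scale)
  v <- zy %*% b
  wilks <- wilks_sequence(r)
  bt <- bartlett_tests(wilks, n, p, q)
  x_load <- stats::cor(zx, u)
  y_load <- stats::cor(zy, v)
  x_cross <- stats::cor(zx, v)
  y_cross <- stats::cor(zy, u)
  dn <- list(NULL, paste0("variate_", seq_len(m)))
  dimnames(a) <- dimnames(x_load) <- dimnames(x_cross) <-
    list(colnames(x), dn[[2]])
  dimnames(b) <- dimnames(y_load) <- dimnames(y_cross) <-
    list(colnames(y), dn[[2]])
  structure(list(correlations = r, wilks = wilks,
                 chi_square = bt$chi_square, df = bt$df,
                 p_value = bt$p_value,
                 x_coef = a, y_coef = b,
                 x_loadings = x_load, y_loadings = y_load,
                 x_cross_loadings = x_cross, y_cross_loadings = y_cross,
                 x_scores = u, y_scores = v,
                 n = n, p = p, q = q),
            class = "pes_cca")
}

.standardize <- function(m, what) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  zero <- which(sd == 0 | !is.finite(sd))
  if (length(zero)) {
    stop(what, " column '", colnames(m)[zero[1L]], "' has zero variance")
  }
  sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
}

.inv_sqrt <- function(S, vars, what) {
  e <- eigen(S, symmetric = TRUE)
  tol <- max(dim(S)) * .Machine$double.eps * max(e$values)
  if (any(e$values < tol)) {
    # point at the most collinear direction
    w <- e$vectors[, which.min(e$values)]
    culprit <- vars[order(-abs(w))[1:2]]
    stop("within-", what, " correlation matrix is singular; collinear ",
         "columns involve '", culprit[1L], "' and '", culprit[2L], "'")
  }
  e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
}

#' @export
print.pes_cca <- function(x, ...) {
  cat("Canonical correlation analysis: n =", x$n, ", p =", x$p,
      ", q =", x$q, "\n")
  print(data.frame(correlation = round(x$correlations, 3),
                   wilks_lambda = round(x$wilks, 3),
                   chi_square = round(x$chi_square, 3),
                   df = x$df,
                   p_value = signif(x$p_value, 3)), row.names = TRUE)
  invisible(x)
}

#' Sequential Wilks' lambda from canonical correlations
#'
#' Lambda_k = prod over i >= k of (1 - r_i^2): the unexplained-variance
#' statistic for the test that canonical correlations k, k+1, ..., m are all
#' zero.
#'
#' @param correlations Canonical correlations, each in \[0, 1\].
#' @return Numeric vector Lambda_1..Lambda_m.
#' @export
wilks_sequence <- function(correlations) {
  if (any(correlations < 0 | correlations > 1)) {
    stop("canonical correlations must lie in [0, 1]")
  }
  rev(cumprod(rev(1 - correlations^2)))
}

#' Bartlett chi-square tests for a Wilks' lambda sequence
#'
#' chi^2_k = -(n - 1 - (p + q + 1)/2) * log(Lambda_k) on
#' df_k = (p - k + 1)(q - k + 1) degrees of freedom, the classic
#' large-sample test that the k-th and all later canonical correlations are
#' zero.
#'
#' @param wilks Wilks' lambda sequence (from [wilks_sequence()]).
#' @param n Number of observations; must exceed (p + q + 3)/2.
#' @param p,q Number of variables in each set.
#' @return List with `chi_square`, `df` and `p_value` vectors; a zero
#'   lambda yields an infinite statistic with p-value 0.
#' @export
bartlett_tests <- function(wilks, n, p, q) {
  if (n <= (p + q + 3) / 2) stop("n too small for the Bartlett test")
  if (any(wilks < 0 | wilks > 1)) stop("wilks values must lie in [0, 1]")
  m <- length(wilks)
  k <- seq_len(m)
  mult <- n - 1 - (p + q + 1) / 2
  chi2 <- ifelse(wilks == 0, Inf, -mult * log(wilks))
  df <- (p - k + 1) * (q - k + 1)
  pv <- ifelse(is.infinite(chi2), 0,
               stats::pchisq(chi2, df = df, lower.tail = FALSE))
  list(chi_square = chi2, df = df, p_value = pv)
}

#' Cross loadings of raw variables on the other set's canonical variates
#'
#' x_cross\[j, k\] is the correlation of set-1 variable j with the k-th
#' canonical variate of set 2 (and symmetrically for y_cross). Cross
#' loadings factor as (within-set structure loading) * r_k, which is also
#' returned as an identity the caller can verify.
#'
#' @param x,y The data matrices the result was fitted on.
#' @param result A `pes_cca` object from [canonical_correlations()].
#' @return List with `x_cross` (p x m) and `y_cross` (q x m).
#' @export
cross_loadings <- function(x, y, result) {
  stopifnot(inherits(result, "pes_cca"))
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  list(x_cross = stats::cor(x, result$y_scores),
       y_cross = stats::cor(y, result$x_scores))
}

#' Bundled published canonical correlations
#'
#' The six canonical correlations printed for the subscale-by-cognition
#' analysis (0.507, 0.327, 0.267, 0.152, 0.123, 0.028), usable with
#' [wilks_sequence()] and [bartlett_tests()].
#'
#' @return Numeric vector of length 6.
#' @export
pes_published_correlations <- function() {
  path <- system.file("extdata", "published_correlations.csv",
                      package = "pesval")
  utils::read.csv(path)$canonical_correlation
}
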