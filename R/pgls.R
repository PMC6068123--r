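#' Phylogenetic generalized least squares
#'
#' Closed-form GLS estimation under a given error covariance (normally the
#' Brownian-motion matrix from [vcv_phylo()]): beta = (X' V^-1 X)^-1 X' V^-1 y.
#' Residuals are raw, `y - X beta`, and satisfy the weighted orthogonality
#' X' V^-1 r = 0.
#'
#' @param y numeric response vector.
#' @param X design matrix (with intercept column if wanted); a plain vector
#'   is promoted to a one-column matrix.
#' @param V positive-definite error covariance, dimension `length(y)`.
#' @return list of class `pgls_fit`: `coefficients` (data frame with
#'   estimate, std. error, t, p), `residuals`, `fitted`, `sigma2`,
#'   `df.residual`, `n`.
#' @export
pgls_fit <- function(y, X, V) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n, all(dim(V) == n))
  L <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite"))
  Xt <- backsolve(L, X, transpose = TRUE)
  yt <- backsolve(L, y, transpose = TRUE)
  q <- qr(Xt)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(q$rank)]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(q, yt)
  fitted <- as.numeric(X %*% beta)
  res <- y - fitted
  rt <- yt - Xt %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(rt^2) / df
  XtXinv <- chol2inv(qr.R(q))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = beta,
                              std_error = se, t = tval, p = pval,
                              row.names = NULL),
    residuals = res, fitted = fitted, sigma2 = sigma2,
    df.residual = df, n = n
  ), class = "pgls_fit")
}

#' @method print pgls_fit
#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit, N =", x$n, "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
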