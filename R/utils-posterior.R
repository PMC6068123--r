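#' Z-transform a numeric vector
#'
#' Centres to mean 0 and scales to unit standard deviation over non-missing
#' values, the standardization applied to every continuous predictor before
#' model fitting so that coefficients are comparable across paths.
#'
#' @param x numeric vector.
#' @return numeric vector with mean 0 and sd 1 over complete cases.
#' @export
z_transform <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("z_transform: zero or undefined variance")
  (x - m) / s
}

#' Posterior mode via kernel density
#'
#' Mode of a sample estimated as the argmax of a Gaussian kernel density with
#' Silverman's rule-of-thumb bandwidth, the convention used for reporting
#' posterior point estimates throughout the package.
#'
#' @param x numeric vector of posterior draws.
#' @return scalar mode estimate.
#' @export
posterior_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(x[1L])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given posterior mass, computed from the
#' empirical draws (sort the sample, slide a window of the required mass,
#' keep the narrowest).
#'
#' @param x numeric vector of draws.
#' @param prob interval mass, default 0.95.
#' @return length-2 numeric vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3L) return(range(x))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(range(x))
  widths <- x[(k + 1L):n] - x[1L:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' MCMC significance (pMCMC)
#'
#' Proportion of posterior draws on the minority side of zero. The default is
#' two-tailed, 2 x min(fraction > 0, fraction < 0), floored at 2/N so that a
#' sample with no sign changes still reports a resolvable value; a one-tailed
#' variant (min tail, floored at 1/N) is available.
#'
#' @param x numeric vector of draws.
#' @param tails "two" (default) or "one".
#' @return scalar in (0, 1].
#' @export
pmcmc <- function(x, tails = c("two", "one")) {
  tails <- match.arg(tails)
  x <- x[is.finite(x)]
  n <- length(x)
  gt <- mean(x > 0)
  lt <- mean(x < 0)
  if (tails == "two") {
    p <- 2 * min(gt, lt)
    p <- max(p, 2 / n)
  } else {
    p <- max(min(gt, lt), 1 / n)
  }
  min(p, 1)
}

#' Lag-1 autocorrelation of a chain
#' @param x numeric vector of sequential draws.
#' @return scalar autocorrelation at lag 1.
#' @export
lag1_autocorr <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(0)
  stats::cor(x[-n], x[-1L])
}

#' Effective sample size of a chain
#'
#' Initial-positive-sequence estimator: N / (1 + 2 * sum of consecutive
#' positive autocorrelation pairs).
#'
#' @param x numeric vector of sequential draws.
#' @return scalar effective sample size (capped at N).
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE)$acf[-1L]
  s <- 0
  i <- 1L
  while (i < length(ac)) {
    pair <- ac[i] + ac[i + 1L]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    i <- i + 2L
  }
  min(n, n / (1 + 2 * s))
}
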