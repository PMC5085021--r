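#' Empirical cumulative distribution function
#'
#' The right-continuous step estimator F_n(t) = #(sample elements <= t) / n.
#' Ties share a value and the sample maximum maps to exactly 1 (which is why
#' downstream use Winsorizes before applying the normal quantile function).
#'
#' @param sample numeric vector of observations (n >= 1, finite).
#' @param t numeric vector of evaluation points.
#' @return numeric vector of the same length as \code{t}, values in [0, 1].
#' @examples
#' empiricalCdf(c(3, 1, 2), c(3, 1, 2))  # 1, 1/3, 2/3
#' @export
empiricalCdf <- function(sample, t) {
  if (length(sample) < 1L) stop("empty sample: no data to form an empirical CDF")
  if (any(!is.finite(sample))) stop("sample must be finite")
  n <- length(sample)
  vapply(t, function(ti) sum(sample <= ti) / n, numeric(1))
}

#' Winsorization bound for the empirical CDF
#'
#' delta_n = 1 / (4 n^{1/4} sqrt(pi log n)): the truncation level used for
#' the Winsorized (nonparanormal) CDF estimator. Strictly decreasing in n and
#' inside (0, 0.5) for every n >= 2.
#'
#' @param n integer sample size, n >= 2.
#' @return the bound delta_n.
#' @examples
#' winsorizationBound(100)  # ~0.0208
#' @export
winsorizationBound <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 2) stop("n must be a single integer >= 2")
  1 / (4 * n^(1 / 4) * sqrt(pi * log(n)))
}

#' Winsorize an empirical CDF value
#'
#' Clamps u into [delta_n, 1 - delta_n], preventing infinite normal quantiles
#' at u = 0 and u = 1. Idempotent and order-preserving.
#'
#' @param u numeric vector of CDF values in [0, 1].
#' @param deltaN single value in (0, 0.5).
#' @return clamped values in [deltaN, 1 - deltaN].
#' @examples
#' winsorizeCdf(c(0.001, 0.5, 1), 0.02)  # 0.02, 0.5, 0.98
#' @export
winsorizeCdf <- function(u, deltaN) {
  if (length(deltaN) != 1L || !is.finite(deltaN) || deltaN <= 0 || deltaN >= 0.5)
    stop("deltaN must be a single value in (0, 0.5)")
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("u must be in [0, 1]")
  pmin(pmax(u, deltaN), 1 - deltaN)
}

#' Gaussian copula transform of a time-series matrix
#'
#' Maps each column through its Winsorized empirical CDF and the
#' standard-normal quantile function, then rescales to the column's sample
#' mean and sample standard deviation:
#' z = mean(x) + sd(x) * qnorm(winsorize(Fhat(x))).
#' The transform is a pointwise function of within-column ranks, so it maps
#' ties to ties and is invariant to any strictly increasing remapping of a
#' column's marginal — which is what lets downstream linear Granger fits
#' absorb monotone-nonlinear marginals. It is strictly monotone on distinct
#' values away from the Winsorized extremes; once delta_n exceeds 1/T
#' (around T = 96 and above) the few most extreme order statistics on each
#' side share a clamped CDF value and are mapped to ties.
#'
#' @param X a \linkS4class{TimeSeriesMatrix} (or a plain numeric matrix,
#'   which is coerced).
#' @param delta optional override of the Winsorization bound; defaults to
#'   \code{winsorizationBound(T)} for T time points.
#' @return a \linkS4class{CopulaSeries}.
#' @examples
#' x <- TimeSeriesMatrix(matrix(rexp(40), 20, 2))
#' z <- copulaTransform(x)
#' all(order(tsValues(z)[, 1]) == order(tsValues(x)[, 1]))  # rank-preserving
#' @export
copulaTransform <- function(X, delta = NULL) {
  if (!is(X, "TimeSeriesMatrix")) X <- TimeSeriesMatrix(X)
  v <- tsValues(X)
  Tn <- nrow(v)
  dn <- if (is.null(delta)) winsorizationBound(Tn) else delta
  if (length(dn) != 1L || dn <= 0 || dn >= 0.5)
    stop("delta must be a single value in (0, 0.5)")
  out <- v
  for (i in seq_len(ncol(v))) {
    x <- v[, i]
    # rank with ties.method = "max" equals T * Fhat(x_t) = #(x <= x_t)
    u <- rank(x, ties.method = "max") / Tn
    z <- stats::qnorm(winsorizeCdf(u, dn))
    s <- stats::sd(x)
    if (s == 0) {
      warning(sprintf("column %d ('%s') is constant; normal scores not rescaled by sd",
                      i, colnames(v)[i]))
      out[, i] <- mean(x) + z
    } else {
      out[, i] <- mean(x) + s * z
    }
  }
  new("CopulaSeries", values = out, deltaN = dn, sourceNames = colnames(v))
}
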