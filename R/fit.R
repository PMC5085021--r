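#' Elastic-net penalized least squares by cyclic coordinate descent
#'
#' Minimizes (1/(2n)) ||y - X b||^2 + lambda (alpha ||b||_1 +
#' (1-alpha)/2 ||b||_2^2) with the soft-thresholding update
#' b_j <- S(z_j, lambda alpha) / (x_j'x_j/n + lambda (1-alpha)),
#' z_j = (1/n) x_j'(y - X_{-j} b_{-j}), cycled until the maximal absolute
#' coefficient change drops below \code{tol}. The caller is expected to pass
#' standardized predictor columns and a centered response (as
#' \code{\link{fitPath}} does); the solver itself works on the inputs as
#' given. alpha = 1 is the LASSO; as alpha decreases the ridge component
#' grows and the fit densifies.
#'
#' @param predictors numeric n x m matrix.
#' @param response numeric vector of length n.
#' @param lambda overall penalty, >= 0.
#' @param alpha elastic-net mixing in (0, 1].
#' @param maxIter,tol convergence controls (full cycles / max coefficient
#'   change).
#' @return numeric coefficient vector of length m.
#' @examples
#' X <- scale(matrix(rnorm(200), 50, 4)); y <- X[, 1] * 2 + rnorm(50)
#' elasticNetFit(X, y - mean(y), lambda = 0.1, alpha = 0.9)
#' @export
elasticNetFit <- function(predictors, response, lambda, alpha,
                          maxIter = 100000L, tol = 1e-7) {
  X <- as.matrix(predictors)
  y <- as.numeric(response)
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  if (length(lambda) != 1L || lambda < 0) stop("lambda must be a single value >= 0")
  if (length(alpha) != 1L || alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (nrow(X) != length(y)) stop("predictors and response dimensions differ")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 observations")
  fit <- enet_path_cpp(crossprod(X) / n, crossprod(X, y)[, 1] / n,
                       sum(y^2) / n, n, lambda, alpha,
                       as.integer(maxIter), tol)
  if (!fit$converged[1])
    warning("coordinate descent did not converge within maxIter cycles; returning current iterate")
  b <- fit$beta[, 1]
  names(b) <- colnames(X)
  b
}

#' Gaussian-likelihood AIC for a penalized fit
#'
#' n * log(max(RSS, 1e-12) / n) + 2 * df, with df the number of structurally
#' nonzero coefficients (the standard degrees-of-freedom estimator for
#' LASSO-type fits). Lower is better; at fixed RSS the score is strictly
#' increasing in df, so sparser fits win ties in fit quality.
#'
#' @param rss residual sum of squares, >= 0.
#' @param df integer count of nonzero coefficients, >= 0.
#' @param n number of observations, >= 1.
#' @return the AIC value.
#' @examples
#' aicScore(rss = 50, df = 0, n = 50)  # 50 * log(1) = 0
#' @export
aicScore <- function(rss, df, n) {
  if (n < 1) stop("n must be >= 1")
  if (rss < 0) stop("rss must be >= 0")
  n * log(max(rss, 1e-12) / n) + 2 * df
}

#' Fit the full (alpha, lambda) path for one lagged design and select by AIC
#'
#' Standardizes predictor columns (zero mean, unit variance; zero-variance
#' columns are dropped with a warning and reported as exact-zero
#' coefficients) and centers the response. For each alpha in the grid a
#' log-spaced lambda path of \code{lambdaCount} values runs from
#' lambda_max(alpha) = max_j |x_j'y| / (n alpha) down to
#' \code{lambdaMinRatio} * lambda_max, warm-starting each solution from the
#' previous one. Every (alpha, lambda) fit is scored by
#' \code{\link{aicScore}} and the minimum-AIC fit is returned; exact AIC ties
#' break toward larger lambda, then larger alpha (sparser fits first).
#'
#' @param design a \linkS4class{LaggedDesign}.
#' @param config a \linkS4class{PenaltyConfig}.
#' @return the selected \linkS4class{FitResult} (coefficients on the
#'   standardized scale, in design column order).
#' @examples
#' z <- copulaTransform(simulateDataset1(200, seed = 1)[["series"]])
#' fitPath(buildLaggedDesign(z, target = 1, L = 2), penaltyConfig())
#' @export
fitPath <- function(design, config = penaltyConfig()) {
  stopifnot(is(design, "LaggedDesign"), is(config, "PenaltyConfig"))
  X <- design@predictors
  y <- design@response
  n <- length(y)
  m <- ncol(X)

  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sdn <- sqrt(colMeans(Xc^2))          # population scaling: x_j'x_j / n = 1
  keep <- sdn > 0
  if (!all(keep))
    warning(sprintf("%d zero-variance predictor column(s) dropped from fitting",
                    sum(!keep)))
  Xs <- sweep(Xc[, keep, drop = FALSE], 2L, sdn[keep], "/")
  yc <- y - mean(y)

  mk <- ncol(Xs)
  if (mk == 0L) {
    rss <- sum(yc^2)
    return(new("FitResult", coefficients = numeric(m), lambda = Inf,
               alpha = config@alphaGrid[length(config@alphaGrid)],
               rss = rss, df = 0L, aic = aicScore(rss, 0L, n),
               converged = TRUE))
  }

  XtXn <- crossprod(Xs) / n
  Xtyn <- crossprod(Xs, yc)[, 1] / n
  ytyn <- sum(yc^2) / n
  absCor <- max(abs(Xtyn))

  alphas <- sort(config@alphaGrid)
  best <- NULL
  for (alpha in alphas) {
    lamMax <- max(absCor / alpha, 1e-10)
    lambdas <- exp(seq(log(lamMax), log(lamMax * config@lambdaMinRatio),
                       length.out = config@lambdaCount))
    fit <- enet_path_cpp(XtXn, Xtyn, ytyn, n, lambdas, alpha,
                         config@maxIter, config@tol)
    if (!all(fit$converged))
      warning(sprintf("coordinate descent did not converge for %d path point(s) at alpha = %.2f",
                      sum(!fit$converged), alpha))
    dfv <- colSums(abs(fit$beta) > config@zeroTol)
    aicv <- n * log(pmax(fit$rss, 1e-12) / n) + 2 * dfv
    # best candidate within this alpha: min AIC, ties toward larger lambda
    k <- order(round(aicv, 9), -lambdas)[1]
    # across alphas: min AIC, ties toward larger lambda, then larger alpha;
    # alphas are visited in increasing order, so '>= within tolerance with
    # larger lambda' and 'ties at equal lambda prefer the later alpha'
    aic <- aicv[k]
    better <- is.null(best) ||
      aic < best$aic - 1e-9 ||
      (abs(aic - best$aic) <= 1e-9 &&
         (lambdas[k] > best$lambda + 1e-12 ||
            abs(lambdas[k] - best$lambda) <= 1e-12))
    if (better)
      best <- list(beta = fit$beta[, k], lambda = lambdas[k], alpha = alpha,
                   rss = fit$rss[k], df = dfv[k], aic = aic,
                   converged = fit$converged[k])
  }

  coefs <- numeric(m)
  coefs[keep] <- best$beta
  coefs[abs(coefs) <= config@zeroTol] <- 0
  names(coefs) <- colnames(X)
  new("FitResult", coefficients = coefs, lambda = best$lambda,
      alpha = best$alpha, rss = best$rss, df = as.integer(best$df),
      aic = best$aic, converged = as.logical(best$converged))
}
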