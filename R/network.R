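#' Infer a directed Granger-causal network from a multivariate time series
#'
#' The full pipeline: (optionally) map every column into Gaussian copula
#' space via the Winsorized empirical CDF, build the lagged design for each
#' target variable, fit the elastic-net path over the (alpha, lambda) grid,
#' select each target's model by minimum AIC, and declare an edge j -> i
#' when at least one selected lag coefficient of source j in target i's
#' regression is structurally nonzero. With \code{alphaGrid = 1} this is the
#' LASSO-copula baseline. Deterministic given the inputs.
#'
#' @param X a \linkS4class{TimeSeriesMatrix} (or coercible matrix), T x p.
#' @param L lag order, 1 <= L <= T - 2.
#' @param config a \linkS4class{PenaltyConfig}.
#' @param useCopula logical; if FALSE the raw series are used (the "plain"
#'   variants).
#' @param delta optional Winsorization bound override passed to
#'   \code{\link{copulaTransform}}.
#' @return a \linkS4class{NetworkEstimate}. Its adjacency has source rows and
#'   target columns; the diagonal holds self-dependencies, which are reported
#'   but excluded from cross-edge scoring by default (see
#'   \code{\link{scoreNetwork}}).
#' @examples
#' sim <- simulateDataset1(200, seed = 1)
#' net <- inferNetwork(sim$series, L = 2)
#' adjacency(net)
#' @export
inferNetwork <- function(X, L, config = penaltyConfig(), useCopula = TRUE,
                         delta = NULL) {
  if (!is(X, "TimeSeriesMatrix")) X <- TimeSeriesMatrix(X)
  p <- nVars(X)
  nm <- varNames(X)
  L <- as.integer(L)
  Z <- if (useCopula) copulaTransform(X, delta = delta) else X

  lasso <- length(config@alphaGrid) == 1L && config@alphaGrid[1] == 1
  method <- if (useCopula) {
    if (lasso) "lasso_copula" else "elastic_net_copula"
  } else {
    if (lasso) "lasso_plain" else "elastic_net_plain"
  }

  adj <- matrix(FALSE, p, p, dimnames = list(source = nm, target = nm))
  fits <- vector("list", p)
  names(fits) <- nm
  # the lagged predictor matrix is the same for every target; build it once
  d <- buildLaggedDesign(Z, target = 1L, L = L)
  cmap <- d@columnMap
  v <- tsValues(Z)
  Tn <- nrow(v)
  for (i in seq_len(p)) {
    d@target <- i
    d@response <- v[(L + 1L):Tn, i]
    fit <- fitPath(d, config)
    fits[[i]] <- fit
    nz <- abs(fit@coefficients) > config@zeroTol
    for (j in seq_len(p))
      adj[j, i] <- any(nz[cmap$source == j])
  }
  new("NetworkEstimate", adjacency = adj, fits = fits, columnMap = cmap,
      L = L, method = method, zeroTol = config@zeroTol)
}
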