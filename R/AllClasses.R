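#' @import methods
NULL

#' Multivariate time series container
#'
#' Holds a T x p numeric matrix of observations: rows are time points in
#' temporal order, columns are variables (genes, brain regions, ...).
#' Validity requires at least two time points, finite entries throughout and
#' unique variable names.
#'
#' @slot values numeric matrix, T rows (time) by p columns (variables), with
#'   unique column names.
#' @export
setClass("TimeSeriesMatrix", slots = c(values = "matrix"))

setValidity("TimeSeriesMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (nrow(v) < 2L) return("need at least 2 time points (rows)")
  if (ncol(v) < 1L) return("need at least 1 variable (column)")
  if (any(!is.finite(v))) return("all entries must be finite (no NA/NaN/Inf)")
  nm <- colnames(v)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    return("variables must be named (non-empty column names)")
  if (anyDuplicated(nm)) return("variable names must be unique")
  TRUE
})

#' Construct a TimeSeriesMatrix
#'
#' @param values numeric matrix (rows = time points, columns = variables) or
#'   a data.frame of numeric columns.
#' @param names optional character vector of variable names; defaults to the
#'   column names of \code{values} or \code{V1..Vp}.
#' @return A validated \linkS4class{TimeSeriesMatrix}.
#' @examples
#' x <- TimeSeriesMatrix(matrix(rnorm(20), 10, 2), names = c("g1", "g2"))
#' nTimes(x); nVars(x); varNames(x)
#' @export
TimeSeriesMatrix <- function(values, names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  storage.mode(values) <- "double"
  if (!is.null(names)) {
    colnames(values) <- names
  } else if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  }
  new("TimeSeriesMatrix", values = values)
}

#' Copula-space representation of a time series
#'
#' The result of the Winsorized empirical-CDF Gaussian copula transform:
#' same shape as the source series, each column a rank-preserving monotone
#' remapping of the source column to (rescaled) normal scores.
#'
#' @slot values numeric matrix of transformed observations.
#' @slot deltaN Winsorization bound used, in (0, 0.5).
#' @slot sourceNames variable names of the source series.
#' @export
setClass("CopulaSeries",
         slots = c(values = "matrix", deltaN = "numeric",
                   sourceNames = "character"))

setValidity("CopulaSeries", function(object) {
  if (any(!is.finite(object@values))) return("transformed values must be finite")
  if (length(object@deltaN) != 1L || object@deltaN <= 0 || object@deltaN >= 0.5)
    return("deltaN must be a single value in (0, 0.5)")
  if (length(object@sourceNames) != ncol(object@values))
    return("sourceNames length must match the number of columns")
  TRUE
})

#' Lagged regression design for one target variable
#'
#' Response vector and lagged predictor matrix for regressing one variable on
#' the lag-1..L history of all variables. Predictor columns are ordered
#' source-major, lag-minor, so the L coefficients of one source are
#' contiguous; that block is the unit over which an edge is declared.
#'
#' @slot target integer index (1-based) of the response variable.
#' @slot response numeric vector of length T - L.
#' @slot predictors numeric matrix, (T - L) rows by p*L columns.
#' @slot columnMap data.frame with columns \code{source} and \code{lag}
#'   describing each predictor column.
#' @slot L integer, maximal time delay.
#' @export
setClass("LaggedDesign",
         slots = c(target = "integer", response = "numeric",
                   predictors = "matrix", columnMap = "data.frame",
                   L = "integer"))

setValidity("LaggedDesign", function(object) {
  if (length(object@response) != nrow(object@predictors))
    return("response length must equal the number of predictor rows")
  if (nrow(object@columnMap) != ncol(object@predictors))
    return("columnMap must describe every predictor column")
  if (anyDuplicated(object@columnMap[, c("source", "lag")]))
    return("duplicate (source, lag) pairs in columnMap")
  if (object@L < 1L) return("L must be >= 1")
  TRUE
})

#' Penalty and path configuration for the sparse fits
#'
#' @slot alphaGrid numeric vector of elastic-net mixing values in (0, 1];
#'   alpha = 1 is the pure-LASSO baseline.
#' @slot lambdaCount integer, number of lambda values per alpha.
#' @slot lambdaMinRatio smallest lambda as a fraction of lambda_max.
#' @slot zeroTol coefficients with absolute value at or below this are
#'   treated as structurally zero.
#' @slot maxIter maximal number of full coordinate-descent cycles.
#' @slot tol convergence tolerance on the maximal absolute coefficient
#'   change per cycle.
#' @export
setClass("PenaltyConfig",
         slots = c(alphaGrid = "numeric", lambdaCount = "integer",
                   lambdaMinRatio = "numeric", zeroTol = "numeric",
                   maxIter = "integer", tol = "numeric"))

setValidity("PenaltyConfig", function(object) {
  a <- object@alphaGrid
  if (length(a) < 1L || any(a <= 0) || any(a > 1))
    return("alphaGrid must be nonempty with values in (0, 1]")
  if (object@lambdaCount < 1L) return("lambdaCount must be >= 1")
  if (object@lambdaMinRatio <= 0 || object@lambdaMinRatio >= 1)
    return("lambdaMinRatio must be in (0, 1)")
  if (object@zeroTol <= 0) return("zeroTol must be positive")
  TRUE
})

#' Construct a PenaltyConfig
#'
#' Defaults: mixing grid alpha = 0.1, 0.2, ..., 1.0; 50 lambda values per
#' alpha, log-spaced down to 0.01 * lambda_max; zero tolerance 1e-8;
#' convergence at max coefficient change < 1e-7 within 1e5 cycles.
#'
#' @param alphaGrid,lambdaCount,lambdaMinRatio,zeroTol,maxIter,tol see slots
#'   of \linkS4class{PenaltyConfig}.
#' @return A validated \linkS4class{PenaltyConfig}.
#' @examples
#' lassoCfg <- penaltyConfig(alphaGrid = 1)   # pure-LASSO baseline
#' @export
penaltyConfig <- function(alphaGrid = seq(0.1, 1, by = 0.1),
                          lambdaCount = 50L, lambdaMinRatio = 0.01,
                          zeroTol = 1e-8, maxIter = 100000L, tol = 1e-7) {
  new("PenaltyConfig", alphaGrid = as.numeric(alphaGrid),
      lambdaCount = as.integer(lambdaCount),
      lambdaMinRatio = as.numeric(lambdaMinRatio),
      zeroTol = as.numeric(zeroTol), maxIter = as.integer(maxIter),
      tol = as.numeric(tol))
}

#' One selected penalized fit
#'
#' @slot coefficients numeric vector (standardized scale), one entry per
#'   predictor column.
#' @slot lambda,alpha the penalty at which the fit was selected.
#' @slot rss residual sum of squares of the fit.
#' @slot df integer, number of structurally nonzero coefficients.
#' @slot aic the Gaussian-likelihood AIC, n*log(RSS/n) + 2*df.
#' @slot converged logical, coordinate descent reached tolerance.
#' @export
setClass("FitResult",
         slots = c(coefficients = "numeric", lambda = "numeric",
                   alpha = "numeric", rss = "numeric", df = "integer",
                   aic = "numeric", converged = "logical"))

#' Directed network estimate
#'
#' @slot adjacency logical p x p matrix; entry (j, i) TRUE means variable j
#'   Granger-causes variable i (source rows, target columns). The diagonal
#'   holds self-dependencies.
#' @slot fits list of \linkS4class{FitResult}, one per target.
#' @slot columnMap data.frame mapping predictor columns to (source, lag).
#' @slot L lag order used.
#' @slot method one of \code{"elastic_net_copula"}, \code{"lasso_copula"},
#'   \code{"elastic_net_plain"}, \code{"lasso_plain"}.
#' @slot zeroTol the threshold used to call coefficients nonzero.
#' @export
setClass("NetworkEstimate",
         slots = c(adjacency = "matrix", fits = "list",
                   columnMap = "data.frame", L = "integer",
                   method = "character", zeroTol = "numeric"))

setValidity("NetworkEstimate", function(object) {
  a <- object@adjacency
  if (!is.logical(a) || nrow(a) != ncol(a))
    return("adjacency must be a square logical matrix")
  if (length(object@fits) != ncol(a))
    return("one fit per target is required")
  ok <- c("elastic_net_copula", "lasso_copula",
          "elastic_net_plain", "lasso_plain")
  if (!object@method %in% ok)
    return(paste("method must be one of:", paste(ok, collapse = ", ")))
  TRUE
})

#' Ground-truth influence graph of a simulated system
#'
#' @slot adjacency logical p x p matrix of generating cross edges
#'   (source rows, target columns; diagonal FALSE).
#' @slot selfEdges logical vector: which variables depend on their own past.
#' @slot lagAnnotations data.frame with columns \code{source},
#'   \code{target}, \code{lag}, \code{coefficient}: every nonzero generating
#'   term, self terms included.
#' @export
setClass("GroundTruthGraph",
         slots = c(adjacency = "matrix", selfEdges = "logical",
                   lagAnnotations = "data.frame"))

setValidity("GroundTruthGraph", function(object) {
  a <- object@adjacency
  if (!is.logical(a) || nrow(a) != ncol(a))
    return("adjacency must be a square logical matrix")
  if (any(diag(a))) return("diagonal must be FALSE; self edges live in selfEdges")
  if (length(object@selfEdges) != nrow(a))
    return("selfEdges length must equal p")
  TRUE
})
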