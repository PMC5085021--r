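#' Build the lagged regression design for one target variable
#'
#' For a series of T time points and p variables, the response is the target
#' column at times t = L+1..T and the predictor matrix holds, for every
#' source j and lag l in 1..L, the column Z_j(t - l). Columns are ordered
#' source-major, lag-minor, so the L lag coefficients of each source are
#' contiguous; an edge j -> target is later declared when that block is not
#' all zero. No intercept column is included: predictors are centered and the
#' response is de-meaned inside the fitting step.
#'
#' @param Z a \linkS4class{CopulaSeries}, \linkS4class{TimeSeriesMatrix} or
#'   plain numeric matrix (rows = time).
#' @param target integer in 1..p, the response variable.
#' @param L maximal time delay, 1 <= L <= T - 2.
#' @return a \linkS4class{LaggedDesign}.
#' @examples
#' d <- buildLaggedDesign(matrix(1:8, 4, 2), target = 1, L = 1)
#' d@response    # rows 2..4 of column 1
#' @export
buildLaggedDesign <- function(Z, target, L) {
  v <- if (is(Z, "CopulaSeries") || is(Z, "TimeSeriesMatrix")) tsValues(Z) else as.matrix(Z)
  Tn <- nrow(v)
  p <- ncol(v)
  L <- as.integer(L)
  target <- as.integer(target)
  if (target < 1L || target > p) stop("target must be in 1..p")
  if (L < 1L) stop("L must be >= 1")
  if (L >= Tn - 1L)
    stop(sprintf("insufficient time points: need T >= L + 2 (T = %d, L = %d)", Tn, L))
  nr <- Tn - L
  preds <- matrix(0, nr, p * L)
  src <- integer(p * L)
  lag <- integer(p * L)
  nm <- colnames(v)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  cn <- character(p * L)
  k <- 0L
  for (j in seq_len(p)) {
    for (l in seq_len(L)) {
      k <- k + 1L
      preds[, k] <- v[(L + 1L - l):(Tn - l), j]
      src[k] <- j
      lag[k] <- l
      cn[k] <- sprintf("%s_lag%d", nm[j], l)
    }
  }
  colnames(preds) <- cn
  new("LaggedDesign", target = target,
      response = v[(L + 1L):Tn, target], predictors = preds,
      columnMap = data.frame(source = src, lag = lag), L = L)
}
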