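# Simulated benchmark systems with known ground-truth influence graphs.

# Run expr under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Iterate x(t) = sum_l A[[l]] x(t-l) + e(t), e ~ N(0, I), the first L values
# i.i.d. N(0, 1), then discard `burnin` steps.
simulateVARCore <- function(A, T, burnin) {
  p <- nrow(A[[1]])
  L <- length(A)
  n <- T + burnin
  if (n <= L) stop("T + burnin must exceed the lag order")
  x <- matrix(0, n, p)
  x[seq_len(L), ] <- stats::rnorm(L * p)
  e <- matrix(stats::rnorm((n - L) * p), n - L, p)
  for (t in (L + 1L):n) {
    acc <- e[t - L, ]
    for (l in seq_len(L)) acc <- acc + A[[l]] %*% x[t - l, ]
    x[t, ] <- acc
  }
  x[(burnin + 1L):n, , drop = FALSE]
}

truthFromCoefficients <- function(A, names) {
  p <- nrow(A[[1]])
  adj <- matrix(FALSE, p, p, dimnames = list(source = names, target = names))
  self <- logical(p)
  ann <- list()
  for (l in seq_along(A)) {
    nz <- which(A[[l]] != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      i <- nz[r, 1]; j <- nz[r, 2]   # target i, source j
      if (i == j) self[i] <- TRUE else adj[j, i] <- TRUE
      ann[[length(ann) + 1L]] <- data.frame(source = j, target = i, lag = l,
                                            coefficient = A[[l]][i, j])
    }
  }
  ann <- do.call(rbind, ann)
  ann <- ann[order(ann$target, ann$source, ann$lag), ]
  rownames(ann) <- NULL
  new("GroundTruthGraph", adjacency = adj, selfEdges = self,
      lagAnnotations = ann)
}

#' Companion matrix and spectral radius of a VAR coefficient set
#'
#' Stacks the lag coefficient matrices A_1..A_L (target rows, source columns)
#' into the (p L) x (p L) companion form and returns its largest eigenvalue
#' modulus. A value below 1 means the system is stationary; the farther below
#' 1, the faster transients decay.
#'
#' @param A list of L numeric p x p matrices: \code{A[[l]][i, j]} is the
#'   coefficient of variable j at lag l in variable i's equation.
#' @return the spectral radius (non-negative numeric).
#' @examples
#' companionSpectralRadius(list(diag(0.5, 2)))  # 0.5
#' @export
companionSpectralRadius <- function(A) {
  p <- nrow(A[[1]])
  L <- length(A)
  top <- do.call(cbind, A)
  C <- rbind(top, cbind(diag(p * (L - 1L)), matrix(0, p * (L - 1L), p)))
  if (L == 1L) C <- top
  max(Mod(eigen(C, only.values = TRUE)$values))
}

dataset1Coefficients <- function() {
  A1 <- matrix(0, 3, 3); A2 <- matrix(0, 3, 3)
  A1[1, 1] <- 0.8;  A2[1, 1] <- -0.5; A1[1, 3] <- 0.4
  A1[2, 2] <- 0.9;  A2[2, 3] <- -0.8
  A1[3, 3] <- 0.5;  A2[3, 3] <- -0.2; A1[3, 2] <- 0.5
  list(A1, A2)
}

dataset2Coefficients <- function() {
  A <- replicate(4, matrix(0, 5, 5), simplify = FALSE)
  A[[1]][1, 1] <- 0.6;  A[[2]][1, 2] <- 0.65
  A[[1]][2, 2] <- 0.5;  A[[2]][2, 2] <- -0.3
  A[[4]][2, 3] <- -0.3; A[[1]][2, 4] <- 0.6
  A[[1]][3, 3] <- 0.8;  A[[2]][3, 3] <- -0.7; A[[3]][3, 5] <- -0.1
  A[[1]][4, 4] <- 0.5;  A[[2]][4, 3] <- 0.9;  A[[2]][4, 5] <- 0.4
  A[[1]][5, 5] <- 0.7;  A[[2]][5, 5] <- -0.5; A[[1]][5, 3] <- -0.2
  A
}

#' Simulated benchmark system 1: three coupled variables
#'
#' Iterates the three-variable lag-2 autoregression
#' \preformatted{
#'   x1(t) = 0.8 x1(t-1) - 0.5 x1(t-2) + 0.4 x3(t-1) + e1(t)
#'   x2(t) = 0.9 x2(t-1) - 0.8 x3(t-2)               + e2(t)
#'   x3(t) = 0.5 x3(t-1) - 0.2 x3(t-2) + 0.5 x2(t-1) + e3(t)
#' }
#' with mutually independent standard-normal innovations and the first two
#' values of each series drawn N(0, 1). By default no burn-in is discarded:
#' the series starts at the noise initialization, which is this benchmark's
#' generation protocol. The ground-truth graph has exactly three cross
#' edges: 3 -> 1 (lag 1), 3 -> 2 (lag 2), 2 -> 3 (lag 1); every variable
#' has a self edge.
#'
#' Note: the companion matrix of these coefficients has spectral radius
#' 1.00228, so the system is marginally explosive — series magnitudes grow
#' slowly (about a factor 10 per 1000 steps). At the benchmark horizons
#' (T <= 1000) values stay modest, and the rank-based copula transform is
#' unaffected by the drift in scale, but long simulations (or a long
#' burn-in) let the deterministic growing mode dominate the innovations,
#' making the lagged columns of x2 and x3 nearly collinear; large-sample
#' moment-based checks do not apply to this system.
#'
#' @param T number of retained time points, >= 15.
#' @param seed RNG seed; identical (T, seed, burnin) give identical output.
#' @param burnin number of initial steps discarded before the retained
#'   window (default 0, the benchmark protocol).
#' @return list with elements \code{series} (a
#'   \linkS4class{TimeSeriesMatrix}, T x 3) and \code{truth} (a
#'   \linkS4class{GroundTruthGraph}).
#' @examples
#' sim <- simulateDataset1(100, seed = 1)
#' sum(adjacency(sim$truth))  # 3 cross edges
#' @export
simulateDataset1 <- function(T, seed, burnin = 0L) {
  if (T < 15) stop("T must be >= 15")
  A <- dataset1Coefficients()
  x <- withSeed(seed, simulateVARCore(A, T, burnin))
  nm <- paste0("x", 1:3)
  colnames(x) <- nm
  list(series = TimeSeriesMatrix(x), truth = truthFromCoefficients(A, nm))
}

#' Simulated benchmark system 2: five variables, maximal lag 4
#'
#' Iterates the five-variable autoregression
#' \preformatted{
#'   x1(t) = 0.6 x1(t-1) + 0.65 x2(t-2)                               + e1(t)
#'   x2(t) = 0.5 x2(t-1) - 0.3 x2(t-2) - 0.3 x3(t-4) + 0.6 x4(t-1)    + e2(t)
#'   x3(t) = 0.8 x3(t-1) - 0.7 x3(t-2) - 0.1 x5(t-3)                  + e3(t)
#'   x4(t) = 0.5 x4(t-1) + 0.9 x3(t-2) + 0.4 x5(t-2)                  + e4(t)
#'   x5(t) = 0.7 x5(t-1) - 0.5 x5(t-2) - 0.2 x3(t-1)                  + e5(t)
#' }
#' under the same innovation and burn-in protocol as
#' \code{\link{simulateDataset1}}. The system is stationary (companion
#' spectral radius 0.877). Ground truth: seven cross edges (2 -> 1, 3 -> 2,
#' 4 -> 2, 5 -> 3, 3 -> 4, 5 -> 4, 3 -> 5) and self edges on all five
#' variables. The x3 -> x2 dependency acts at lag 4, so inference must use
#' L >= 4 to reach it.
#'
#' @inheritParams simulateDataset1
#' @return list with \code{series} (T x 5) and \code{truth}.
#' @examples
#' sim <- simulateDataset2(100, seed = 1)
#' sum(adjacency(sim$truth))  # 7 cross edges
#' @export
simulateDataset2 <- function(T, seed, burnin = 0L) {
  if (T < 15) stop("T must be >= 15")
  A <- dataset2Coefficients()
  x <- withSeed(seed, simulateVARCore(A, T, burnin))
  nm <- paste0("x", 1:5)
  colnames(x) <- nm
  list(series = TimeSeriesMatrix(x), truth = truthFromCoefficients(A, nm))
}

#' Random sparse stable VAR generator
#'
#' Draws a random sparse VAR(L): every variable gets a lag-1 self term
#' (uniform on [0.2, 0.6]); each ordered cross pair (j, i) is included with
#' probability \code{density}, at a single uniformly chosen lag, with
#' coefficient drawn uniformly from [-0.8, -0.3] or [0.3, 0.8]. All
#' coefficients are then shrunk geometrically until the companion spectral
#' radius is at most 0.9, and the system is simulated like the benchmark
#' systems. Intended as a property-test generator.
#'
#' @param p number of variables, >= 2.
#' @param L lag order, >= 1.
#' @param density probability of each cross edge, in (0, 1].
#' @param T retained time points.
#' @param seed RNG seed.
#' @param burnin discarded initial steps.
#' @param maxTries maximal shrink iterations before giving up.
#' @return list with \code{series}, \code{truth} and \code{coefficients}
#'   (the list of lag matrices actually used).
#' @examples
#' sim <- simulateRandomVAR(p = 4, L = 2, density = 0.3, T = 100, seed = 1)
#' @export
simulateRandomVAR <- function(p, L, density, T, seed, burnin = 1000L,
                              maxTries = 200L) {
  if (p < 2) stop("p must be >= 2")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  withSeed(seed, {
    A <- replicate(L, matrix(0, p, p), simplify = FALSE)
    for (i in seq_len(p)) A[[1]][i, i] <- stats::runif(1, 0.2, 0.6)
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      if (stats::runif(1) < density) {
        l <- sample.int(L, 1)
        A[[l]][i, j] <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.8)
      }
    }
    tries <- 0L
    while (companionSpectralRadius(A) > 0.9) {
      tries <- tries + 1L
      if (tries > maxTries) stop("could not stabilize the random VAR")
      A <- lapply(A, function(M) M * 0.93)
    }
    x <- simulateVARCore(A, T, burnin)
    nm <- paste0("V", seq_len(p))
    colnames(x) <- nm
    list(series = TimeSeriesMatrix(x),
         truth = truthFromCoefficients(A, nm), coefficients = A)
  })
}
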