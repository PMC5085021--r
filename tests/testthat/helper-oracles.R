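# Independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Elastic-net objective on the (1/(2n)) RSS scale.
enetObjective <- function(X, y, b, lambda, alpha) {
  sum((y - X %*% b)^2) / (2 * nrow(X)) +
    lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
}

# Accelerated proximal-gradient (FISTA) solver for the same objective:
# a generic convex-optimization oracle entirely independent of the
# coordinate-descent implementation under test.
fistaEnet <- function(X, y, lambda, alpha, iters = 50000L) {
  n <- nrow(X)
  G <- crossprod(X) / n
  xty <- crossprod(X, y) / n
  lip <- max(eigen(G, only.values = TRUE, symmetric = TRUE)$values) +
    lambda * (1 - alpha)
  b <- numeric(ncol(X))
  v <- b
  th <- 1
  for (k in seq_len(iters)) {
    g <- G %*% v - xty + lambda * (1 - alpha) * v
    bn <- as.numeric(v - g / lip)
    bn <- sign(bn) * pmax(abs(bn) - lambda * alpha / lip, 0)
    thn <- (1 + sqrt(1 + 4 * th^2)) / 2
    v <- bn + ((th - 1) / thn) * (bn - b)
    b <- bn
    th <- thn
  }
  b
}

# Standardize columns to mean 0 and population variance 1.
standardizeCols <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sweep(Xc, 2, sqrt(colMeans(Xc^2)), "/")
}

# Minimal NetworkEstimate wrapper around a bare logical adjacency matrix,
# for exercising the scorer without running the pipeline.
fakeEstimate <- function(adj) {
  p <- ncol(adj)
  dimnames(adj) <- list(source = paste0("x", 1:p), target = paste0("x", 1:p))
  dummy <- new("FitResult", coefficients = numeric(0), lambda = 0,
               alpha = 1, rss = 0, df = 0L, aic = 0, converged = TRUE)
  new("NetworkEstimate", adjacency = adj,
      fits = rep(list(dummy), p),
      columnMap = data.frame(source = integer(), lag = integer()),
      L = 1L, method = "elastic_net_copula", zeroTol = 1e-8)
}

# Ground truth with a given cross-edge adjacency and self-edge vector.
fakeTruth <- function(adj, self = rep(TRUE, ncol(adj))) {
  p <- ncol(adj)
  dimnames(adj) <- list(source = paste0("x", 1:p), target = paste0("x", 1:p))
  new("GroundTruthGraph", adjacency = adj, selfEdges = self,
      lagAnnotations = data.frame(source = integer(), target = integer(),
                                  lag = integer(), coefficient = numeric()))
}
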