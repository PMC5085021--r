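#' Score an estimated network against ground truth
#'
#' Compares the estimated adjacency with the generating graph over the
#' p(p-1) ordered off-diagonal pairs (self edges excluded by default).
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), FDR = FP/(TP+FP) = 1 -
#' precision, F1 = 2PR/(P+R). Empty-denominator conventions: when nothing is
#' predicted (TP+FP = 0) precision and FDR are 0; recall is 0 when there are
#' no true edges; F1 is 0 when P + R = 0.
#'
#' @param estimate a \linkS4class{NetworkEstimate}.
#' @param truth a \linkS4class{GroundTruthGraph} with the same p.
#' @param includeSelf logical; if TRUE the diagonal (self-dependency) entries
#'   are scored too, against \code{selfEdges(truth)}.
#' @return one-row data.frame: tp, fp, fn, tn, precision, recall, fdr, f1.
#' @examples
#' sim <- simulateDataset1(300, seed = 2)
#' scoreNetwork(inferNetwork(sim$series, L = 2), sim$truth)
#' @export
scoreNetwork <- function(estimate, truth, includeSelf = FALSE) {
  est <- adjacency(estimate)
  tru <- adjacency(truth)
  p <- ncol(tru)
  if (!all(dim(est) == dim(tru)))
    stop("estimate and truth have different numbers of variables")
  if (includeSelf) diag(tru) <- selfEdges(truth)
  mask <- matrix(TRUE, p, p)
  if (!includeSelf) diag(mask) <- FALSE
  e <- est[mask]
  g <- tru[mask]
  tp <- sum(e & g); fp <- sum(e & !g); fn <- sum(!e & g); tn <- sum(!e & !g)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  fdr <- if (tp + fp > 0) fp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
             recall = recall, fdr = fdr, f1 = f1)
}

benchmarkMethods <- c("elastic_net_copula", "lasso_copula",
                      "elastic_net_plain", "lasso_plain")

methodConfig <- function(method, config) {
  if (method %in% c("lasso_copula", "lasso_plain")) {
    config@alphaGrid <- 1
  }
  config
}

#' Monte-Carlo benchmark of network recovery on simulated systems
#'
#' For each replicate r, simulates the chosen system with seed
#' \code{baseSeed + r}, runs every requested method on the same realization,
#' scores it against the generating graph, and reports the arithmetic mean
#' of each metric per (method, T). F1 is averaged per replicate (mean of
#' per-replicate F1, not the harmonic mean of the averaged precision and
#' recall). A replicate whose fit fails is recorded and excluded.
#'
#' @param system one of \code{"dataset1"}, \code{"dataset2"},
#'   \code{"random"}.
#' @param TGrid integer vector of series lengths (default the benchmark grid
#'   15, 20, 35, 75, 150, 500, 1000).
#' @param replicates Monte-Carlo replicates per cell (default 500).
#' @param L lag order; defaults to the maximal generating lag of the chosen
#'   system (2 for dataset1, 4 for dataset2, the generator's L for random).
#' @param methods subset of \code{"elastic_net_copula"},
#'   \code{"lasso_copula"}, \code{"elastic_net_plain"},
#'   \code{"lasso_plain"}.
#' @param baseSeed integer; replicate r uses seed baseSeed + r.
#' @param config a \linkS4class{PenaltyConfig} (the LASSO methods override
#'   the alpha grid to 1).
#' @param includeSelf score self edges too (default FALSE: cross edges are
#'   the benchmark quantity).
#' @param p,density random-system parameters (ignored otherwise).
#' @param verbose print one line per finished cell.
#' @return data.frame with columns method, T, precision, fdr, recall, f1,
#'   replicates (successful count), failures.
#' @examples
#' runBenchmark("dataset1", TGrid = 75, replicates = 3, baseSeed = 1)
#' @export
runBenchmark <- function(system = c("dataset1", "dataset2", "random"),
                         TGrid = c(15L, 20L, 35L, 75L, 150L, 500L, 1000L),
                         replicates = 500L, L = NULL,
                         methods = c("elastic_net_copula", "lasso_copula"),
                         baseSeed = 1L, config = penaltyConfig(),
                         includeSelf = FALSE, p = 10L, density = 0.2,
                         verbose = FALSE) {
  system <- match.arg(system)
  methods <- match.arg(methods, benchmarkMethods, several.ok = TRUE)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (length(TGrid) < 1L) stop("TGrid must be nonempty")
  if (is.null(L))
    L <- switch(system, dataset1 = 2L, dataset2 = 4L, random = 2L)
  L <- as.integer(L)

  simulateOne <- function(T, seed) {
    switch(system,
           dataset1 = simulateDataset1(T, seed),
           dataset2 = simulateDataset2(T, seed),
           random = simulateRandomVAR(p = p, L = L, density = density,
                                      T = T, seed = seed))
  }

  metricCols <- c("precision", "fdr", "recall", "f1")
  rows <- list()
  for (T in TGrid) {
    acc <- lapply(methods, function(m)
      matrix(NA_real_, replicates, length(metricCols),
             dimnames = list(NULL, metricCols)))
    names(acc) <- methods
    failures <- stats::setNames(integer(length(methods)), methods)
    for (r in seq_len(replicates)) {
      sim <- simulateOne(T, baseSeed + r)
      for (m in methods) {
        res <- tryCatch({
          net <- suppressWarnings(inferNetwork(
            sim$series, L = L, config = methodConfig(m, config),
            useCopula = !endsWith(m, "_plain")))
          scoreNetwork(net, sim$truth, includeSelf = includeSelf)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[m] <- failures[m] + 1L
        } else {
          acc[[m]][r, ] <- unlist(res[metricCols])
        }
      }
    }
    for (m in methods) {
      means <- colMeans(acc[[m]], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, T = T, precision = means["precision"],
        fdr = means["fdr"], recall = means["recall"], f1 = means["f1"],
        replicates = replicates - failures[m], failures = failures[m],
        row.names = NULL)
      if (verbose)
        message(sprintf("%s T=%d: precision %.3f fdr %.3f recall %.3f f1 %.3f (%d ok, %d failed)",
                        m, T, means["precision"], means["fdr"],
                        means["recall"], means["f1"],
                        replicates - failures[m], failures[m]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
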