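# Reading and writing time-series tables and network estimates.

#' Read a multivariate time series from CSV or TSV
#'
#' First row = variable names, subsequent rows = time points in temporal
#' order. The delimiter is taken from the file extension (.tsv/.tab = tab,
#' otherwise comma) unless given. Missing or non-numeric cells are reported
#' with their 1-based time-point row and column name.
#'
#' @param path file path.
#' @param sep optional field separator ("," or "\t").
#' @return a \linkS4class{TimeSeriesMatrix}.
#' @export
readTimeSeries <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  nm <- colnames(df)
  if (anyDuplicated(nm))
    stop("duplicate variable names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  v <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, nm))
  for (j in seq_along(df)) {
    cell <- df[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | cell == "")
    if (length(bad) > 0)
      stop(sprintf("missing or non-numeric value at time point %d, column '%s'",
                   bad[1], nm[j]))
    v[, j] <- num
  }
  TimeSeriesMatrix(v)
}

#' Write a time series to CSV or TSV
#'
#' @param x a \linkS4class{TimeSeriesMatrix} or \linkS4class{CopulaSeries}.
#' @param path output path; extension .tsv/.tab selects tab separation.
#' @param sep optional separator override.
#' @export
writeTimeSeries <- function(x, path, sep = NULL) {
  v <- tsValues(x)
  if (is(x, "CopulaSeries")) colnames(v) <- varNames(x)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(v, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Edge list of a network estimate
#'
#' One row per declared edge: source and target names, the largest absolute
#' selected coefficient over the source's lags, the nonzero lags
#' (semicolon-separated) and whether the edge is a self-dependency.
#'
#' @param estimate a \linkS4class{NetworkEstimate}.
#' @return data.frame with columns source, target, max_abs_coefficient,
#'   lags_nonzero, is_self (zero rows for an empty network).
#' @export
edgeList <- function(estimate) {
  adj <- adjacency(estimate)
  nm <- colnames(adj)
  cmap <- estimate@columnMap
  rows <- list()
  for (i in seq_len(ncol(adj))) {
    b <- estimate@fits[[i]]@coefficients
    for (j in seq_len(nrow(adj))) {
      if (!adj[j, i]) next
      sel <- cmap$source == j & abs(b) > estimate@zeroTol
      rows[[length(rows) + 1L]] <- data.frame(
        source = nm[j], target = nm[i],
        max_abs_coefficient = max(abs(b[sel])),
        lags_nonzero = paste(sort(cmap$lag[sel]), collapse = ";"),
        is_self = j == i)
    }
  }
  if (length(rows) == 0)
    return(data.frame(source = character(), target = character(),
                      max_abs_coefficient = numeric(),
                      lags_nonzero = character(), is_self = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a network estimate to disk
#'
#' Writes the edge list as CSV and, optionally, the dense 0/1 adjacency
#' matrix (source rows, target columns, with variable names).
#'
#' @param estimate a \linkS4class{NetworkEstimate}.
#' @param path edge-list CSV path.
#' @param adjacencyPath optional path for the dense adjacency CSV.
#' @export
writeNetwork <- function(estimate, path, adjacencyPath = NULL) {
  utils::write.csv(edgeList(estimate), path, row.names = FALSE, quote = FALSE)
  if (!is.null(adjacencyPath)) {
    adj <- adjacency(estimate) * 1L
    utils::write.csv(data.frame(source = rownames(adj), adj,
                                check.names = FALSE),
                     adjacencyPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Rebuild an adjacency matrix from a written edge list
#'
#' @param path edge-list CSV as written by \code{\link{writeNetwork}}.
#' @param names character vector of all variable names (needed because
#'   isolated variables do not appear in the edge list).
#' @return logical adjacency matrix (source rows, target columns).
#' @export
readNetworkEdges <- function(path, names) {
  df <- utils::read.csv(path, colClasses = c(source = "character",
                                             target = "character"))
  adj <- matrix(FALSE, length(names), length(names),
                dimnames = list(source = names, target = names))
  for (r in seq_len(nrow(df))) adj[df$source[r], df$target[r]] <- TRUE
  adj
}
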