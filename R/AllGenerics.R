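#' @rdname TimeSeriesMatrix-class
#' @param x a \linkS4class{TimeSeriesMatrix} or \linkS4class{CopulaSeries}.
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))

#' @rdname TimeSeriesMatrix-class
#' @export
setGeneric("varNames", function(x) standardGeneric("varNames"))

#' @rdname TimeSeriesMatrix-class
#' @export
setGeneric("nTimes", function(x) standardGeneric("nTimes"))

#' @rdname TimeSeriesMatrix-class
#' @export
setGeneric("nVars", function(x) standardGeneric("nVars"))

#' @rdname CopulaSeries-class
#' @param x a \linkS4class{CopulaSeries}.
#' @export
setGeneric("winsorBound", function(x) standardGeneric("winsorBound"))

#' Adjacency matrix of a network estimate or ground-truth graph
#'
#' Logical p x p matrix with source rows and target columns: entry (j, i)
#' TRUE means j -> i.
#'
#' @param x a \linkS4class{NetworkEstimate} or \linkS4class{GroundTruthGraph}.
#' @return logical matrix.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname GroundTruthGraph-class
#' @param x a \linkS4class{GroundTruthGraph}.
#' @export
setGeneric("selfEdges", function(x) standardGeneric("selfEdges"))

#' @rdname GroundTruthGraph-class
#' @export
setGeneric("lagAnnotations", function(x) standardGeneric("lagAnnotations"))

setMethod("tsValues", "TimeSeriesMatrix", function(x) x@values)
setMethod("varNames", "TimeSeriesMatrix", function(x) colnames(x@values))
setMethod("nTimes", "TimeSeriesMatrix", function(x) nrow(x@values))
setMethod("nVars", "TimeSeriesMatrix", function(x) ncol(x@values))

setMethod("tsValues", "CopulaSeries", function(x) x@values)
setMethod("varNames", "CopulaSeries", function(x) x@sourceNames)
setMethod("nTimes", "CopulaSeries", function(x) nrow(x@values))
setMethod("nVars", "CopulaSeries", function(x) ncol(x@values))
setMethod("winsorBound", "CopulaSeries", function(x) x@deltaN)

setMethod("adjacency", "NetworkEstimate", function(x) x@adjacency)
setMethod("adjacency", "GroundTruthGraph", function(x) x@adjacency)
setMethod("selfEdges", "GroundTruthGraph", function(x) x@selfEdges)
setMethod("lagAnnotations", "GroundTruthGraph", function(x) x@lagAnnotations)

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat("TimeSeriesMatrix:", nrow(object@values), "time points x",
      ncol(object@values), "variables\n")
  cat("  variables:", paste(utils::head(colnames(object@values), 8),
                            collapse = ", "),
      if (ncol(object@values) > 8) "...\n" else "\n")
})

setMethod("show", "CopulaSeries", function(object) {
  cat("CopulaSeries:", nrow(object@values), "time points x",
      ncol(object@values), "variables (Winsorization bound",
      format(object@deltaN, digits = 4), ")\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: alpha = %.2f, lambda = %.4g, df = %d, AIC = %.3f%s\n",
              object@alpha, object@lambda, object@df, object@aic,
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "NetworkEstimate", function(object) {
  p <- ncol(object@adjacency)
  cross <- sum(object@adjacency) - sum(diag(object@adjacency))
  cat("NetworkEstimate (", object@method, "): ", p, " variables, L = ",
      object@L, "\n  ", cross, " cross edges, ",
      sum(diag(object@adjacency)), " self edges\n", sep = "")
})

setMethod("show", "GroundTruthGraph", function(object) {
  cat("GroundTruthGraph:", ncol(object@adjacency), "variables,",
      sum(object@adjacency), "cross edges,",
      sum(object@selfEdges), "self edges\n")
})
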