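#' Accessors for coralAcclim classes
#'
#' \code{clusterLabels} returns the cluster labels of a \code{ClusterSet}
#' ordered by decreasing size; \code{membership} the gene -> cluster map;
#' \code{eigengenes} the clusters-by-samples eigengene matrix;
#' \code{varianceExplained} the per-cluster fraction of variance the
#' eigengene captures; \code{designTable} the sample design of an
#' \code{AcclimExperiment} as a data.frame with a \code{sample_id} column;
#' \code{nullSamples} and \code{pValue} the resampled null and empirical
#' p-value of a \code{ResamplingTest}.
#'
#' @param x a coralAcclim object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))

#' @rdname accessors
#' @export
setGeneric("varianceExplained",
           function(x) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname accessors
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterSet", function(x) {
  labs <- setdiff(unique(x@membership), "unassigned")
  sizes <- vapply(labs, function(l) sum(x@membership == l), integer(1))
  labs[order(-sizes, labs)]
})

#' @rdname accessors
#' @export
setMethod("membership", "ClusterSet", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("eigengenes", "ClusterSet", function(x) x@eigengenes)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "ClusterSet", function(x) x@varianceExplained)

#' @rdname accessors
#' @export
setMethod("designTable", "AcclimExperiment", function(x) {
  cd <- as.data.frame(colData(x))
  data.frame(sample_id = colnames(x),
             cd[, setdiff(DESIGN_COLUMNS, "sample_id"), drop = FALSE],
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("nullSamples", "ResamplingTest", function(x) x@nullSamples)

#' @rdname accessors
#' @export
setMethod("pValue", "ResamplingTest", function(x) x@p)
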