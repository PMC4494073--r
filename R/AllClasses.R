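#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<- colData<-
NULL

## Factor levels of the acclimation design. Treatments follow the three tank
## regimes (ambient 29 C control, stable 31 C, diel-variable 29-33 C); days
## are acclimation durations at which branches were assayed.
ACCLIM_TREATMENTS <- c("control29", "stable31", "variable29_33")
ACCLIM_DAYS <- c(0L, 2L, 7L, 11L)
ACCLIM_CONDITIONS <- c("nonstressed", "stressed")

DESIGN_COLUMNS <- c("sample_id", "colony_id", "tank_id", "batch",
                    "treatment", "day", "condition")

#' Container for a coral acclimation experiment
#'
#' An \code{AcclimExperiment} couples a gene-by-sample read-count matrix with
#' the factorial sample design of a thermal-acclimation experiment: each
#' sample (a coral branch) carries an acclimation treatment, an acclimation
#' duration in days, an acute-stress condition, and the colony, tank and
#' collection batch it came from. The class extends
#' \linkS4class{SummarizedExperiment}; the \code{"counts"} assay holds raw
#' counts and a \code{"normalized"} assay is added by
#' \code{\link{normalizeCounts}}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; design factors live in
#'   \code{colData}.
#' @seealso \code{\link{AcclimExperiment}} (constructor),
#'   \code{\link{canonicalDesign}}, \code{\link{readCounts}}
#' @exportClass AcclimExperiment
.AcclimExperiment <- setClass("AcclimExperiment",
                              contains = "SummarizedExperiment")

setValidity("AcclimExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(abs(cts - round(cts)) > 1e-8))
      msg <- c(msg, "counts must be integers")
  }
  cd <- colData(object)
  missing <- setdiff(setdiff(DESIGN_COLUMNS, "sample_id"), colnames(cd))
  if (length(missing))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing, collapse = ", ")))
  if (!length(msg)) {
    if (!all(cd$treatment %in% ACCLIM_TREATMENTS))
      msg <- c(msg, paste0("treatment must be one of: ",
                           paste(ACCLIM_TREATMENTS, collapse = ", ")))
    if (!all(cd$condition %in% ACCLIM_CONDITIONS))
      msg <- c(msg, paste0("condition must be one of: ",
                           paste(ACCLIM_CONDITIONS, collapse = ", ")))
    if (!all(cd$day %in% ACCLIM_DAYS))
      msg <- c(msg, paste0("day must be one of: ",
                           paste(ACCLIM_DAYS, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "sample ids (colnames) must be unique")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "gene ids (rownames) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Co-expression cluster set with eigengenes
#'
#' Result of \code{\link{clusterGenes}} plus \code{\link{addEigengenes}}:
#' a disjoint assignment of genes to clusters (genes in groups smaller than
#' \code{minSize} are labelled \code{"unassigned"}), and per cluster the
#' eigengene -- the centred first principal component of the cluster's
#' standardized expression -- with the fraction of cluster variance it
#' explains.
#'
#' @slot membership named character vector, gene id -> cluster label or
#'   \code{"unassigned"}.
#' @slot eigengenes numeric matrix, clusters x samples (centred rows); may
#'   have zero rows before \code{\link{addEigengenes}} is called.
#' @slot varianceExplained named numeric in (0, 1], one entry per cluster.
#' @slot parameters list of the clustering parameters used.
#' @exportClass ClusterSet
.ClusterSet <- setClass("ClusterSet",
  slots = c(membership = "character",
            eigengenes = "matrix",
            varianceExplained = "numeric",
            parameters = "list"))

setValidity("ClusterSet", function(object) {
  msg <- character()
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by gene id")
  labs <- setdiff(unique(object@membership), "unassigned")
  if (nrow(object@eigengenes)) {
    if (!setequal(rownames(object@eigengenes), labs))
      msg <- c(msg, "eigengene rows must match cluster labels")
    if (any(abs(rowMeans(object@eigengenes)) > 1e-6))
      msg <- c(msg, "eigengenes must be centred across samples")
    ve <- object@varianceExplained[rownames(object@eigengenes)]
    if (any(is.na(ve)) || any(ve <= 0) || any(ve > 1 + 1e-12))
      msg <- c(msg, "varianceExplained must lie in (0, 1] per cluster")
  }
  if (length(msg)) msg else TRUE
})

#' Resampling-null test for a gene-set summary
#'
#' Holds the observed summary statistic of a gene set (here, the mean log2
#' heat-stress response of a co-expression cluster), the null distribution of
#' the same summary over randomly drawn gene sets of equal size, the central
#' 95\% envelope of that null, and the two-sided empirical p-value.
#'
#' @slot observed observed summary statistic.
#' @slot nullSamples numeric vector of resampled summaries.
#' @slot p empirical p-value, in [1/(B+1), 1].
#' @slot envelope length-2 numeric, 2.5\% and 97.5\% null quantiles.
#' @slot nDraws number of resampled gene sets.
#' @slot setSize gene-set size drawn.
#' @exportClass ResamplingTest
.ResamplingTest <- setClass("ResamplingTest",
  slots = c(observed = "numeric", nullSamples = "numeric", p = "numeric",
            envelope = "numeric", nDraws = "integer", setSize = "integer"))

setValidity("ResamplingTest", function(object) {
  msg <- character()
  B <- object@nDraws
  if (length(object@nullSamples) != B)
    msg <- c(msg, "nullSamples must have length nDraws")
  if (object@p < 1 / (B + 1) - 1e-12 || object@p > 1)
    msg <- c(msg, "p must lie in [1/(B+1), 1]")
  if (length(object@envelope) != 2 || object@envelope[1] > object@envelope[2])
    msg <- c(msg, "envelope must be an ordered pair")
  if (length(msg)) msg else TRUE
})

#' Wax-dip surface-area standard curve
#'
#' Ordinary least-squares calibration of branch surface area (cm^2) against
#' wax weight gain (g) from standards of known area, used to convert the
#' second-dip weight gain of a coral branch into surface area.
#'
#' @slot slope,intercept fit coefficients (area = slope * gain + intercept).
#' @slot r.squared coefficient of determination of the fit.
#' @slot standards data.frame with columns \code{weight_gain}, \code{area}.
#' @exportClass AreaStandardCurve
.AreaStandardCurve <- setClass("AreaStandardCurve",
  slots = c(slope = "numeric", intercept = "numeric", r.squared = "numeric",
            standards = "data.frame"))

setValidity("AreaStandardCurve", function(object) {
  msg <- character()
  if (nrow(object@standards) < 3)
    msg <- c(msg, "at least 3 standards are required")
  if (!(object@slope > 0))
    msg <- c(msg, "slope must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AcclimExperiment", function(object) {
  callNextMethod()
  cd <- colData(object)
  cat(sprintf("design: %d treatment(s), day(s) %s, %d stressed / %d nonstressed\n",
              length(unique(cd$treatment)),
              paste(sort(unique(cd$day)), collapse = ","),
              sum(cd$condition == "stressed"),
              sum(cd$condition == "nonstressed")))
})

setMethod("show", "ClusterSet", function(object) {
  labs <- clusterLabels(object)
  cat(sprintf("ClusterSet: %d gene(s), %d cluster(s), %d unassigned\n",
              length(object@membership), length(labs),
              sum(object@membership == "unassigned")))
  for (l in labs) {
    n <- sum(object@membership == l)
    ve <- object@varianceExplained[l]
    if (is.na(ve))
      cat(sprintf("  %s: %d genes\n", l, n))
    else
      cat(sprintf("  %s: %d genes, eigengene explains %.1f%% of variance\n",
                  l, n, 100 * ve))
  }
})

setMethod("show", "ResamplingTest", function(object) {
  cat(sprintf(
    "ResamplingTest: observed %.4f, null 95%% envelope [%.4f, %.4f], p = %.4g (%d draws of %d genes)\n",
    object@observed, object@envelope[1], object@envelope[2], object@p,
    object@nDraws, object@setSize))
})

setMethod("show", "AreaStandardCurve", function(object) {
  cat(sprintf(
    "AreaStandardCurve: area = %.4f * gain %+.4f (R^2 = %.4f, %d standards)\n",
    object@slope, object@intercept, object@r.squared, nrow(object@standards)))
})
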