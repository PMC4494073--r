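#' Abundance filter for contigs
#'
#' Keeps a contig (gene) when its mean raw count across all samples is
#' strictly greater than \code{minMean} and its sample standard deviation is
#' strictly less than its mean. The SD criterion drops contigs whose counts
#' are dominated by one or a few samples (typically mapping artifacts).
#'
#' @param x an \linkS4class{AcclimExperiment} or a counts matrix.
#' @param minMean mean-count threshold (strict; default 5).
#' @return for a matrix, a list with the row-subset \code{counts} and a
#'   per-gene \code{report} data.frame (mean, sd, both criteria, kept flag);
#'   for an \code{AcclimExperiment}, the row-subsetted object with the report
#'   in \code{metadata(x)$filter_report}.
#' @examples
#' m <- rbind(keep = c(6L, 6L, 6L, 6L), drop = c(0L, 0L, 0L, 100L))
#' colnames(m) <- paste0("s", 1:4)
#' filterContigs(m)$report
#' @export
filterContigs <- function(x, minMean = 5) {
  if (is(x, "AcclimExperiment")) {
    res <- filterContigs(assay(x, "counts"), minMean = minMean)
    out <- x[rownames(res$counts), ]
    metadata(out)$filter_report <- res$report
    return(out)
  }
  counts <- x
  if (ncol(counts) < 2)
    stop("filtering needs >= 2 samples (sample SD undefined for n = 1)")
  mu <- rowMeans(counts)
  sdev <- apply(counts, 1, stats::sd)
  meanOK <- mu > minMean
  sdOK <- sdev < mu
  keep <- meanOK & sdOK
  report <- data.frame(gene_id = rownames(counts), mean = mu, sd = sdev,
                       mean_gt_threshold = meanOK, sd_lt_mean = sdOK,
                       kept = keep, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(counts = counts[keep, , drop = FALSE], report = report)
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: for each gene positive in every
#' sample, the ratio of its count in sample j to its geometric mean across
#' samples; the size factor of sample j is the median of those ratios.
#'
#' @param counts counts matrix (genes x samples) or
#'   \linkS4class{AcclimExperiment}.
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- rbind(g1 = c(2L, 4L), g2 = c(10L, 20L))
#' colnames(m) <- c("a", "b")
#' medianOfRatios(m)  # 1/sqrt(2), sqrt(2)
#' @export
medianOfRatios <- function(counts) {
  if (is(counts, "AcclimExperiment")) counts <- assay(counts, "counts")
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos))
    stop("no gene has strictly positive counts in all samples; ",
         "size factors are undefined -- consider filtering low-count genes")
  logc <- log(counts[pos, , drop = FALSE])
  logratio <- logc - rowMeans(logc)  # log count minus log geometric mean
  sf <- exp(apply(logratio, 2, stats::median))
  names(sf) <- colnames(counts)
  sf
}

#' Divide counts by size factors
#'
#' @param x counts matrix or \linkS4class{AcclimExperiment}.
#' @param sizeFactors named per-sample factors; computed with
#'   \code{\link{medianOfRatios}} when missing.
#' @return normalized matrix, or the \code{AcclimExperiment} with a
#'   \code{"normalized"} assay and \code{colData(x)$size_factor} filled in.
#' @export
normalizeCounts <- function(x, sizeFactors = NULL) {
  if (is(x, "AcclimExperiment")) {
    cts <- assay(x, "counts")
    if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(cts)
    assay(x, "normalized") <- normalizeCounts(cts, sizeFactors)
    colData(x)$size_factor <- sizeFactors[colnames(x)]
    return(x)
  }
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(x)
  missing <- setdiff(colnames(x), names(sizeFactors))
  if (length(missing))
    stop("no size factor for sample(s): ", paste(missing, collapse = ", "))
  sf <- sizeFactors[colnames(x)]
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factors must be finite and positive")
  sweep(x, 2, sf, "/")
}

#' Log2 transform with pseudocount
#'
#' @param x normalized matrix or \linkS4class{AcclimExperiment} (uses the
#'   \code{"normalized"} assay, computing it first if absent).
#' @param pseudocount positive offset added before taking log2 (default 1).
#' @return matrix of log2(value + pseudocount); for an
#'   \code{AcclimExperiment}, the object with a \code{"log2"} assay.
#' @export
logTransform <- function(x, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (is(x, "AcclimExperiment")) {
    if (!"normalized" %in% assayNames(x)) x <- normalizeCounts(x)
    assay(x, "log2") <- log2(assay(x, "normalized") + pseudocount)
    return(x)
  }
  log2(x + pseudocount)
}

#' Flag outlier samples on the first two principal components
#'
#' Runs a PCA over samples of the gene-centred log2 normalized matrix and
#' flags samples whose robust z-score, |score - median| / (1.4826 * MAD),
#' exceeds \code{zThreshold} on PC1 or PC2. Flagging only: removal is the
#' caller's explicit decision (subset the experiment by the report).
#'
#' @param x \linkS4class{AcclimExperiment} or normalized matrix (genes x
#'   samples; log2 is taken internally).
#' @param zThreshold robust z cut-off (default 3).
#' @param pseudocount offset for the internal log transform.
#' @return data.frame with per-sample PC1/PC2 scores, robust z-scores and a
#'   \code{flagged} logical; the threshold used is kept in
#'   \code{attr(, "parameters")}.
#' @export
flagOutlierSamples <- function(x, zThreshold = 3, pseudocount = 1) {
  if (is(x, "AcclimExperiment")) {
    if (!"normalized" %in% assayNames(x)) x <- normalizeCounts(x)
    m <- assay(x, "normalized")
  } else m <- x
  if (ncol(m) < 3) stop("outlier flagging needs >= 3 samples")
  lg <- log2(m + pseudocount)
  centred <- lg - rowMeans(lg)
  if (all(abs(centred) < 1e-12)) stop("matrix has zero variance")
  pc <- stats::prcomp(t(centred), center = TRUE, scale. = FALSE, rank. = 2)
  scores <- pc$x[, 1:2, drop = FALSE]
  robustZ <- function(s) {
    scale <- stats::mad(s)   # 1.4826 * MAD
    if (scale == 0) return(ifelse(s == stats::median(s), 0, Inf))
    abs(s - stats::median(s)) / scale
  }
  z1 <- robustZ(scores[, 1])
  z2 <- robustZ(scores[, 2])
  report <- data.frame(sample_id = colnames(m),
                       PC1 = scores[, 1], PC2 = scores[, 2],
                       z_PC1 = z1, z_PC2 = z2,
                       flagged = z1 > zThreshold | z2 > zThreshold,
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "parameters") <- list(z_threshold = zThreshold,
                                     pseudocount = pseudocount)
  report
}
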