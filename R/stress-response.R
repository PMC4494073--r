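#' Per-gene heat-stress response (log2 fold change)
#'
#' For each gene, log2 of the ratio of mean normalized expression in
#' heat-stressed samples to mean normalized expression in nonstressed
#' samples, within an optional design stratum:
#' log2((mean_stressed + pc) / (mean_nonstressed + pc)). The pseudocount
#' guards zero means; the statistic is exactly antisymmetric under swapping
#' the stressed/nonstressed labels.
#'
#' @param x \linkS4class{AcclimExperiment} with a \code{"normalized"} assay
#'   (computed if absent), or a normalized matrix plus \code{design}.
#' @param design design data.frame (when \code{x} is a matrix).
#' @param stratum optional predicate on the design, either a function
#'   (design -> logical) or a one-sided formula / expression evaluated in the
#'   design (e.g. \code{~ day == 11 & treatment == "control29"}). Default:
#'   all samples.
#' @param pseudocount offset inside the ratio (default 1).
#' @return named numeric vector of log2 fold changes, one per gene.
#' @export
geneLog2fc <- function(x, design = NULL, stratum = NULL, pseudocount = 1) {
  if (is(x, "AcclimExperiment")) {
    if (!"normalized" %in% assayNames(x)) x <- normalizeCounts(x)
    design <- designTable(x)
    x <- assay(x, "normalized")
  }
  keep <- .evalStratum(stratum, design)
  d <- design[keep, , drop = FALSE]
  m <- x[, d$sample_id, drop = FALSE]
  isStr <- d$condition == "stressed"
  if (sum(isStr) < 1 || sum(!isStr) < 1)
    stop("stratum must contain >= 1 stressed and >= 1 nonstressed sample")
  ms <- rowMeans(m[, isStr, drop = FALSE])
  mn <- rowMeans(m[, !isStr, drop = FALSE])
  log2((ms + pseudocount) / (mn + pseudocount))
}

.evalStratum <- function(stratum, design) {
  if (is.null(stratum)) return(rep(TRUE, nrow(design)))
  if (is.function(stratum)) keep <- stratum(design)
  else if (inherits(stratum, "formula"))
    keep <- eval(stratum[[2]], design, environment(stratum))
  else keep <- eval(stratum, design)
  if (!is.logical(keep) || length(keep) != nrow(design))
    stop("stratum must evaluate to one logical per design row")
  keep & !is.na(keep)
}

#' Resampling null test for a cluster's mean stress response
#'
#' Compares the mean log2 heat-stress response of a gene cluster with the
#' same summary for randomly drawn gene sets of equal size from a background
#' (all filtered contigs). The two-sided empirical p-value measures the
#' displacement of the observed mean from the null mean relative to the null
#' spread: p = (1 + #\{|null_b - null mean| >= |observed - null mean|\}) /
#' (nDraws + 1). The reported envelope is the central 95\% of the null.
#'
#' @param log2fc named per-gene log2 fold changes over the background (from
#'   \code{\link{geneLog2fc}}).
#' @param clusterGenes character vector of cluster member gene ids (must be
#'   a subset of the background).
#' @param backgroundGenes background gene ids (default: all names of
#'   \code{log2fc}).
#' @param nDraws number of random gene sets (>= 999; default 1000).
#' @param seed RNG seed.
#' @return a \linkS4class{ResamplingTest}.
#' @export
clusterNullTest <- function(log2fc, clusterGenes,
                            backgroundGenes = names(log2fc),
                            nDraws = 1000L, seed = 1L) {
  if (nDraws < 999) stop("nDraws must be >= 999")
  missing <- setdiff(backgroundGenes, names(log2fc))
  if (length(missing))
    stop("log2fc lacks background gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (!all(clusterGenes %in% backgroundGenes))
    stop("cluster genes must be a subset of the background")
  k <- length(clusterGenes)
  bg <- log2fc[backgroundGenes]
  if (k > length(bg)) stop("cluster larger than background")
  observed <- mean(log2fc[clusterGenes])
  set.seed(seed)
  nulls <- vapply(seq_len(nDraws),
                  function(b) mean(bg[sample.int(length(bg), k)]),
                  numeric(1))
  centre <- mean(nulls)
  p <- (1 + sum(abs(nulls - centre) >= abs(observed - centre))) / (nDraws + 1)
  .ResamplingTest(observed = observed, nullSamples = nulls, p = p,
                  envelope = unname(stats::quantile(nulls, c(0.025, 0.975))),
                  nDraws = as.integer(nDraws), setSize = as.integer(k))
}

#' Transcriptional dampening index
#'
#' Quantifies how much smaller the heat-stress response is under an
#' acclimated treatment than under the control: the through-origin
#' least-squares slope of acclimated per-gene log2 responses on control
#' responses, plus the ratio of mean absolute responses. Dampening is
#' declared when the slope is below 1 with a gene-resampling bootstrap 95\%
#' confidence interval excluding 1.
#'
#' @param log2fcControl,log2fcAcclimated per-gene log2 fold changes for the
#'   same gene set under the control and an acclimated treatment (same
#'   stratum conventions, typically day 11).
#' @param nBoot bootstrap draws over genes (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{slope}, \code{ci} (bootstrap 2.5/97.5
#'   percentiles), \code{ratio} (mean|acclimated| / mean|control|) and
#'   logical \code{dampening}.
#' @export
dampeningIndex <- function(log2fcControl, log2fcAcclimated, nBoot = 1000L,
                           seed = 1L) {
  stopifnot(length(log2fcControl) == length(log2fcAcclimated))
  x <- as.numeric(log2fcControl)
  y <- as.numeric(log2fcAcclimated)
  if (all(x == 0)) stop("all control responses are zero; slope undefined")
  slope <- sum(x * y) / sum(x * x)
  ratio <- mean(abs(y)) / mean(abs(x))
  n <- length(x)
  set.seed(seed)
  boots <- vapply(seq_len(nBoot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    sxx <- sum(x[i]^2)
    if (sxx == 0) return(NA_real_)
    sum(x[i] * y[i]) / sxx
  }, numeric(1))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  list(slope = slope, ci = ci, ratio = ratio,
       dampening = slope < 1 && ci[2] < 1)
}

#' Classify dampening versus frontloading per gene
#'
#' Distinguishes two acclimation mechanisms from four per-gene stratum
#' means on the normalized scale: \emph{frontloading} (baseline expression
#' already shifted in acclimated colonies before acute stress, with a
#' reduced further response) versus \emph{dampening} (unchanged baseline but
#' a smaller reaction to acute stress). Responses are measured in log2
#' units: response = log2(stressed + pc) - log2(baseline + pc) per arm;
#' baseline shift = |log2(baseline_acclimated + pc) - log2(baseline_control
#' + pc)|.
#'
#' @param baselineControl,baselineAcclimated per-gene mean nonstressed
#'   expression under control / acclimated treatment.
#' @param stressedControl,stressedAcclimated per-gene mean stressed
#'   expression per arm.
#' @param tauBaseline log2 baseline-shift threshold separating frontloading
#'   from dampening (default 0.5).
#' @param tauResponse minimum log2 reduction in response magnitude to call
#'   dampening (default 0.25).
#' @param pseudocount offset before logs (default 1).
#' @return character vector of labels in \{"dampening", "frontloading",
#'   "none"\}.
#' @export
classifyMechanism <- function(baselineControl, baselineAcclimated,
                              stressedControl, stressedAcclimated,
                              tauBaseline = 0.5, tauResponse = 0.25,
                              pseudocount = 1) {
  lg <- function(v) log2(v + pseudocount)
  dBase <- abs(lg(baselineAcclimated) - lg(baselineControl))
  respC <- lg(stressedControl) - lg(baselineControl)
  respA <- lg(stressedAcclimated) - lg(baselineAcclimated)
  reduced <- abs(respA) < abs(respC)
  label <- rep("none", length(dBase))
  label[dBase > tauBaseline & reduced] <- "frontloading"
  label[dBase <= tauBaseline &
          abs(respA) < abs(respC) - tauResponse] <- "dampening"
  if (!is.null(names(baselineControl))) names(label) <- names(baselineControl)
  label
}
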