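#' Spearman correlation matrix between genes
#'
#' Rank (midrank for ties) correlation between all pairs of gene expression
#' profiles across samples.
#'
#' @param expr matrix (genes x samples), typically log2 normalized
#'   expression of the acclimation-significant genes.
#' @return symmetric genes x genes correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(expr) {
  if (nrow(expr) < 2) stop("need >= 2 genes")
  if (ncol(expr) < 3) stop("need >= 3 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s), correlation undefined: ",
         paste(rownames(expr)[sds == 0], collapse = ", "))
  stats::cor(t(expr), method = "spearman")
}

#' Cluster genes by co-expression
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - rho
#' (Spearman), with the tree cut at height 1 - \code{rhoThreshold}, so genes
#' in one cluster are linked at average correlation above the threshold.
#' Clusters smaller than \code{minSize} are dissolved into
#' \code{"unassigned"}. Cluster labels are \code{"cluster1"},
#' \code{"cluster2"}, ... in decreasing size order.
#'
#' @param corr correlation matrix from \code{\link{spearmanMatrix}}.
#' @param rhoThreshold correlation threshold (default 0.6).
#' @param minSize smallest reportable cluster (default 10; must be >= 2).
#' @param linkage linkage method for \code{\link[stats]{hclust}} (default
#'   \code{"average"}; \code{"complete"} gives the stricter guarantee that
#'   every within-cluster pair exceeds the threshold).
#' @return a \linkS4class{ClusterSet} with membership only; call
#'   \code{\link{addEigengenes}} to fill in eigengenes.
#' @export
clusterGenes <- function(corr, rhoThreshold = 0.6, minSize = 10L,
                         linkage = "average") {
  if (minSize < 2) stop("minSize must be >= 2")
  if (nrow(corr) != ncol(corr)) stop("corr must be square")
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = linkage)
  grp <- stats::cutree(hc, h = 1 - rhoThreshold)
  sizes <- table(grp)
  keep <- as.integer(names(sizes)[sizes >= minSize])
  keep <- keep[order(-sizes[as.character(keep)])]
  membership <- rep("unassigned", length(grp))
  names(membership) <- rownames(corr)
  for (i in seq_along(keep))
    membership[grp == keep[i]] <- paste0("cluster", i)
  .ClusterSet(membership = membership,
              eigengenes = matrix(numeric(), 0, 0),
              varianceExplained = stats::setNames(numeric(), character()),
              parameters = list(rho_threshold = rhoThreshold,
                                min_size = as.integer(minSize),
                                linkage = linkage))
}

#' Eigengene of one gene set
#'
#' Standardizes each gene (centred, unit variance across samples) and takes
#' the first principal component over samples as the cluster summary. The
#' eigengene is centred, and its sign is oriented so that it correlates
#' positively with the mean standardized profile of the cluster, removing
#' the eigenvector sign ambiguity.
#'
#' @param expr matrix (cluster genes x samples).
#' @return list with \code{eigengene} (named per-sample vector, mean 0),
#'   \code{varianceExplained} (leading eigenvalue over total) and
#'   \code{sign} (orientation applied to the raw component).
#' @export
eigengene <- function(expr) {
  if (nrow(expr) < 2) stop("a cluster needs >= 2 genes")
  mu <- rowMeans(expr)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s) in cluster: ",
         paste(rownames(expr)[sds == 0], collapse = ", "))
  z <- (expr - mu) / sds
  sv <- svd(t(z))                     # samples x genes; columns centred
  scores <- sv$u[, 1] * sv$d[1]
  scores <- scores - mean(scores)
  meanProfile <- colMeans(z)
  s <- sign(sum(scores * (meanProfile - mean(meanProfile))))
  if (s == 0) s <- 1
  ev <- sv$d^2
  list(eigengene = stats::setNames(s * scores, colnames(expr)),
       varianceExplained = ev[1] / sum(ev),
       sign = s)
}

#' Attach eigengenes to a ClusterSet
#'
#' @param clusters a \linkS4class{ClusterSet} (membership filled).
#' @param expr expression matrix covering at least the assigned genes
#'   (genes x samples).
#' @return the \code{ClusterSet} with \code{eigengenes} and
#'   \code{varianceExplained} populated.
#' @export
addEigengenes <- function(clusters, expr) {
  labs <- clusterLabels(clusters)
  if (!length(labs)) return(clusters)
  memb <- membership(clusters)
  eg <- matrix(NA_real_, length(labs), ncol(expr),
               dimnames = list(labs, colnames(expr)))
  ve <- stats::setNames(numeric(length(labs)), labs)
  for (l in labs) {
    genes <- names(memb)[memb == l]
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
      stop("expression matrix lacks cluster gene(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    fit <- eigengene(expr[genes, , drop = FALSE])
    eg[l, ] <- fit$eigengene
    ve[l] <- fit$varianceExplained
  }
  clusters@eigengenes <- eg
  clusters@varianceExplained <- ve
  validObject(clusters)
  clusters
}

#' Permutational ANOVA on an eigengene
#'
#' Tests acclimation treatment, day and their interaction on a cluster
#' eigengene with the same permutation engine used for per-gene tests.
#'
#' @param eig named per-sample eigengene vector (or one row of
#'   \code{eigengenes(clusters)}).
#' @param design design data.frame aligned to \code{eig} by sample id.
#' @param B permutations (default 999).
#' @param seed RNG seed.
#' @param permutations optional explicit permutation matrix (see
#'   \code{\link{permAnova}}).
#' @return one-row \link[S4Vectors]{DataFrame} with F/p/q for treatment, day
#'   and interaction.
#' @export
eigengeneAnova <- function(eig, design, B = 999L, seed = 1L,
                           permutations = NULL) {
  if (!is.null(names(eig))) {
    idx <- match(design$sample_id, names(eig))
    if (any(is.na(idx)))
      stop("eigengene lacks sample(s): ",
           paste(utils::head(design$sample_id[is.na(idx)], 5), collapse = ", "))
    eig <- eig[idx]
  }
  permAnova(matrix(eig, nrow = 1, dimnames = list("eigengene", NULL)),
            design, B = B, seed = seed, interaction = TRUE,
            permutations = permutations)
}
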