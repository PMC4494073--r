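## Orthonormal bases for the nested linear models used by the two-factor
## permutational ANOVA. RSS under model M for every gene at once is
## rowSums(Y^2) - rowSums((Y %*% Q_M)^2), with Q_M an orthonormal basis of
## M's column space (intercept included), so a permutation costs one skinny
## matrix product per model rather than a per-gene lm() fit.
.orthobasis <- function(X) {
  qrX <- qr(X)
  qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
}

.twoFactorBases <- function(design, interaction = FALSE) {
  trt <- factor(design$treatment)
  day <- factor(design$day)
  if (nlevels(trt) < 2) stop("treatment factor has fewer than 2 levels")
  if (nlevels(day) < 2) stop("day factor has fewer than 2 levels")
  n <- length(trt)
  Qt <- .orthobasis(stats::model.matrix(~trt))
  Qd <- .orthobasis(stats::model.matrix(~day))
  Qa <- .orthobasis(stats::model.matrix(~ trt + day))
  out <- list(treatment = Qt, day = Qd, additive = Qa,
              df_treatment = nlevels(trt) - 1L,
              df_day = nlevels(day) - 1L, n = n)
  if (interaction) {
    Qf <- .orthobasis(stats::model.matrix(~ trt * day))
    out$full <- Qf
    out$df_interaction <- ncol(Qf) - ncol(Qa)
    if (out$df_interaction < 1)
      stop("interaction term is not estimable in this design")
    out$df_resid <- n - ncol(Qf)
  } else {
    out$full <- Qa
    out$df_resid <- n - ncol(Qa)
  }
  if (out$df_resid < 1) stop("no residual degrees of freedom")
  out
}

## Type-II F statistics for a genes-x-samples matrix Y given precomputed
## bases; `perm` permutes the response (columns of Y). Returns a matrix with
## one row per gene and columns F_treatment, F_day (and F_interaction when
## the bases include it). SS below `tol` relative to the response's total
## sum of squares count as zero, so a constant response yields F = 0 and a
## perfectly fitted term with zero residual yields Inf.
.typeIIF <- function(Y, bases, perm = NULL, tol = 1e-10) {
  if (!is.null(perm)) {
    ## F of y[perm] against the fixed design == F of y against rows
    ## order(perm) of each basis
    reord <- order(perm)
    project <- function(Q) rowSums((Y %*% Q[reord, , drop = FALSE])^2)
  } else {
    project <- function(Q) rowSums((Y %*% Q)^2)
  }
  tss <- rowSums(Y^2)
  fitT <- project(bases$treatment)
  fitD <- project(bases$day)
  fitA <- project(bases$additive)
  rssT <- tss - fitT       # model with treatment only
  rssD <- tss - fitD
  rssA <- tss - fitA
  scale <- pmax(tss - project(.interceptBasis(bases)), 1)
  ssTrt <- pmax(rssD - rssA, 0)
  ssDay <- pmax(rssT - rssA, 0)
  if (!is.null(bases$df_interaction)) {
    rssF <- tss - project(bases$full)
    ssInt <- pmax(rssA - rssF, 0)
    rssResid <- rssF
  } else {
    rssResid <- rssA
  }
  mse <- rssResid / bases$df_resid
  fstat <- function(ss, df) {
    f <- (ss / df) / mse
    f[ss <= tol * scale] <- 0
    f[rssResid <= tol * scale & ss > tol * scale] <- Inf
    f[!is.finite(f) & !(rssResid <= tol * scale & ss > tol * scale)] <- 0
    f
  }
  out <- cbind(F_treatment = fstat(ssTrt, bases$df_treatment),
               F_day = fstat(ssDay, bases$df_day))
  if (!is.null(bases$df_interaction))
    out <- cbind(out, F_interaction = fstat(ssInt, bases$df_interaction))
  out
}

.interceptBasis <- function(bases) {
  matrix(1 / sqrt(bases$n), bases$n, 1)
}

#' Two-factor F statistics for one response vector
#'
#' Fits the additive model \code{y ~ treatment + day} (both categorical, no
#' interaction) and returns the Type-II F statistic for each term: each
#' term's sum of squares is adjusted for the other term, so the tests do not
#' depend on factor order even in unbalanced designs. A constant response
#' gives (0, 0); a term that fits the data exactly with nonzero sum of
#' squares gives \code{Inf}.
#'
#' @param y numeric response, one value per design row.
#' @param design design data.frame with \code{treatment} and \code{day}.
#' @return named numeric \code{c(F_treatment, F_day)}.
#' @export
fitTwoFactorF <- function(y, design) {
  stopifnot(length(y) == nrow(design))
  bases <- .twoFactorBases(design)
  f <- .typeIIF(matrix(y, nrow = 1), bases)
  c(F_treatment = unname(f[1, "F_treatment"]),
    F_day = unname(f[1, "F_day"]))
}

## Draw B column permutations of n samples as an n x B integer matrix, or
## validate a user-supplied matrix (e.g. the exhaustive set on a toy).
.permMatrix <- function(n, B, seed, permutations = NULL) {
  if (!is.null(permutations)) {
    stopifnot(nrow(permutations) == n)
    return(permutations)
  }
  set.seed(seed)
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

#' Per-gene permutational two-factor ANOVA
#'
#' For every gene (row of \code{y}), computes the observed Type-II F of the
#' additive treatment + day model and an empirical p-value from B random
#' reshuffles of the response against the fixed design. The same B
#' permutations are applied to every gene (one shared permutation stream per
#' seed), so the genome-wide null is exchangeable and runs are reproducible.
#' p = (1 + #\{permuted F >= observed F\}) / (B + 1); Benjamini-Hochberg
#' q-values are appended per term.
#'
#' @param y matrix of responses (genes x samples), usually the \code{"log2"}
#'   assay restricted to filtered genes, or an \linkS4class{AcclimExperiment}
#'   (its \code{"log2"} assay is used, computed if absent).
#' @param design design data.frame aligned to the columns of \code{y}
#'   (taken from the object when \code{y} is an \code{AcclimExperiment}).
#' @param B number of permutations (>= 99; default 999).
#' @param seed RNG seed for the permutation stream.
#' @param interaction include the treatment:day interaction term (used for
#'   eigengene and phenotype tests; default FALSE, matching the per-gene
#'   screen).
#' @param permutations optional explicit n x B matrix of permutation
#'   indices; overrides \code{B}/\code{seed} (used to run the exhaustive set
#'   on small designs).
#' @return \link[S4Vectors]{DataFrame} with one row per gene: F, p and q per
#'   term, plus \code{n_permutations}; permutation count also in
#'   \code{metadata()}.
#' @export
permAnova <- function(y, design = NULL, B = 999L, seed = 1L,
                      interaction = FALSE, permutations = NULL) {
  if (is(y, "AcclimExperiment")) {
    if (!"log2" %in% assayNames(y)) y <- logTransform(y)
    design <- designTable(y)
    y <- assay(y, "log2")
  }
  if (is.null(dim(y))) y <- matrix(y, nrow = 1, dimnames = list("y", NULL))
  stopifnot(ncol(y) == nrow(design))
  if (is.null(permutations) && B < 99)
    stop("B must be >= 99 (permutation p-values too coarse below that)")
  bases <- .twoFactorBases(design, interaction = interaction)
  obs <- .typeIIF(y, bases)
  perms <- .permMatrix(ncol(y), B, seed, permutations)
  B <- ncol(perms)
  exceed <- matrix(0L, nrow(y), ncol(obs))
  eps <- 1e-12
  for (b in seq_len(B)) {
    fp <- .typeIIF(y, bases, perm = perms[, b])
    exceed <- exceed + (fp >= obs - eps * pmax(abs(obs), 1))
  }
  p <- (1 + exceed) / (B + 1)
  cols <- list()
  for (j in seq_len(ncol(obs))) {
    term <- sub("^F_", "", colnames(obs)[j])
    cols[[paste0("F_", term)]] <- unname(obs[, j])
    cols[[paste0("p_", term)]] <- unname(p[, j])
    cols[[paste0("q_", term)]] <- bhAdjust(unname(p[, j]))
  }
  cols$n_permutations <- rep(B, nrow(y))
  res <- S4Vectors::DataFrame(cols, row.names = rownames(y))
  metadata(res) <- list(B = B, seed = seed, interaction = interaction)
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via \code{\link[stats]{p.adjust}}), with input
#' validation: permutation p-values must lie in (0, 1].
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select genes significant for one model term
#'
#' @param table result of \code{\link{permAnova}}.
#' @param term \code{"treatment"}, \code{"day"} or \code{"interaction"}.
#' @param alpha FDR level; selection is inclusive (q <= alpha).
#' @return character vector of gene ids.
#' @export
selectSignificant <- function(table, term = "treatment", alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  col <- paste0("q_", term)
  if (!col %in% colnames(table))
    stop("no q-values for term '", term, "' in table")
  rownames(table)[table[[col]] <= alpha]
}

#' Two-group permutation test per gene
#'
#' Tests each gene for a difference in mean log2 expression between two
#' disjoint sample groups (e.g. stable 31 C versus variable 29-33 C samples
#' at days 7 and 11). Statistic: |difference of group means|; null: random
#' reassignment of group labels; p = (1 + exceedances) / (B + 1), with BH
#' q-values.
#'
#' @param y matrix (genes x samples) of log2 expression.
#' @param groupA,groupB disjoint character vectors of sample ids (columns of
#'   \code{y}).
#' @param B permutations (default 999).
#' @param seed RNG seed.
#' @param splits optional explicit matrix whose columns are index vectors
#'   (into the pooled samples) assigned to group A; overrides \code{B}/
#'   \code{seed} for exhaustive enumeration.
#' @return \link[S4Vectors]{DataFrame} with columns \code{delta} (meanA -
#'   meanB), \code{p}, \code{q}.
#' @export
twoGroupTest <- function(y, groupA, groupB, B = 999L, seed = 1L,
                         splits = NULL) {
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs >= 2 samples")
  missing <- setdiff(c(groupA, groupB), colnames(y))
  if (length(missing))
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  pool <- y[, c(groupA, groupB), drop = FALSE]
  nA <- length(groupA)
  n <- ncol(pool)
  delta <- rowMeans(pool[, seq_len(nA), drop = FALSE]) -
    rowMeans(pool[, nA + seq_len(n - nA), drop = FALSE])
  obs <- abs(delta)
  tot <- rowSums(pool)
  statFor <- function(idxA) {
    mA <- rowMeans(pool[, idxA, drop = FALSE])
    mB <- (tot - mA * nA) / (n - nA)
    abs(mA - mB)
  }
  if (is.null(splits)) {
    if (B < 99) stop("B must be >= 99")
    set.seed(seed)
    splits <- vapply(seq_len(B), function(b) sample.int(n, nA), integer(nA))
  }
  B <- ncol(splits)
  eps <- 1e-12
  exceed <- integer(nrow(pool))
  for (b in seq_len(B))
    exceed <- exceed + (statFor(splits[, b]) >= obs - eps * pmax(obs, 1))
  p <- unname((1 + exceed) / (B + 1))
  res <- S4Vectors::DataFrame(delta = unname(delta), p = p, q = bhAdjust(p),
                              row.names = rownames(y))
  metadata(res) <- list(B = B, seed = seed, nA = nA, nB = n - nA)
  res
}
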