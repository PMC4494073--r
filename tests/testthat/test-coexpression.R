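test_that("Spearman matrix uses midranks and is rank-invariant", {
  x <- c(1, 2, 3, 4, 5)
  expr <- rbind(g1 = x, g2 = 2 * x + 1, g3 = -x)
  colnames(expr) <- paste0("s", 1:5)
  rho <- spearmanMatrix(expr)
  expect_equal(rho["g1", "g2"], 1)
  expect_equal(rho["g1", "g3"], -1)
  expect_equal(diag(rho), c(g1 = 1, g2 = 1, g3 = 1))
  ## ties handled by midranks: compare against rank-then-Pearson
  tied <- rbind(a = c(1, 1, 2, 3, 3), b = c(2, 1, 1, 3, 2),
                c = c(5, 4, 4, 1, 2))
  colnames(tied) <- paste0("s", 1:5)
  rhoT <- spearmanMatrix(tied)
  oracle <- cor(apply(tied, 1, rank))   # columns are genes after apply
  expect_equal(unname(rhoT), unname(oracle), tolerance = 1e-12)
  expect_error(spearmanMatrix(rbind(a = rep(1, 5), b = 1:5)), "constant")
})

test_that("hierarchical clustering recovers planted blocks and applies the size rule", {
  pb <- plantedBlocks(nPerBlock = 20, rho = 0.9, seed = 2)
  cs <- clusterGenes(spearmanMatrix(pb$expr))
  expect_length(clusterLabels(cs), 2)
  expect_equal(adjustedRand(membership(cs), pb$truth), 1)
  ## uncorrelated genes: everything unassigned
  set.seed(6)
  noise <- matrix(rnorm(15 * 40), 15,
                  dimnames = list(paste0("g", 1:15), paste0("s", 1:40)))
  csN <- clusterGenes(spearmanMatrix(noise))
  expect_length(clusterLabels(csN), 0)
  expect_true(all(membership(csN) == "unassigned"))
  ## a coherent block below minSize is dissolved
  small <- plantedBlocks(nPerBlock = 5, rho = 0.95, seed = 3)
  csS <- clusterGenes(spearmanMatrix(small$expr[1:5, ]), minSize = 10)
  expect_true(all(membership(csS) == "unassigned"))
  expect_error(clusterGenes(spearmanMatrix(noise), minSize = 1), ">= 2")
})

test_that("clustering is invariant to gene order and monotone transforms", {
  pb <- plantedBlocks(nPerBlock = 12, rho = 0.85, seed = 4)
  ref <- membership(clusterGenes(spearmanMatrix(pb$expr)))
  perm <- sample(nrow(pb$expr))
  shuf <- membership(clusterGenes(spearmanMatrix(pb$expr[perm, ])))
  expect_equal(adjustedRand(shuf[names(ref)], ref), 1)
  mono <- membership(clusterGenes(spearmanMatrix(exp(pb$expr / 2))))
  expect_equal(adjustedRand(mono, ref), 1)
})

test_that("eigengene matches an explicit eigendecomposition and orientation rule", {
  ## identical profiles: the eigengene is the centred common profile
  set.seed(10)
  prof <- rnorm(30)
  expr <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(expr) <- paste0("s", 1:30)
  eg <- eigengene(expr)
  expect_equal(eg$varianceExplained, 1)
  ctr <- scale(prof, scale = sd(prof))[, 1]
  expect_gt(cor(eg$eigengene, ctr), 0.999999)
  ## two genes: variance explained from the 2x2 eigendecomposition
  g1 <- rnorm(40)
  g2 <- g1 + rnorm(40, sd = 1)
  two <- rbind(a = g1, b = g2)
  colnames(two) <- paste0("s", 1:40)
  got <- eigengene(two)$varianceExplained
  r <- cor(g1, g2)
  lam <- eigen(matrix(c(1, r, r, 1), 2))$values
  expect_equal(got, lam[1] / sum(lam), tolerance = 1e-8)
  ## sign ambiguity resolved: negating the input flips the eigengene but
  ## the orientation to the cluster mean profile holds either way
  egNeg <- eigengene(-two)
  expect_equal(unname(egNeg$eigengene), unname(-eigengene(two)$eigengene),
               tolerance = 1e-8)
  z <- (two - rowMeans(two)) / apply(two, 1, sd)
  expect_gt(cor(eigengene(two)$eigengene, colMeans(z)), 0)
  ## variance explained never below 1/k
  pb <- plantedBlocks(nPerBlock = 8, rho = 0.5, seed = 5)
  ve <- eigengene(pb$expr[1:8, ])$varianceExplained
  expect_gte(ve, 1 / 8)
  expect_error(eigengene(two[1, , drop = FALSE]), ">= 2 genes")
  expect_error(eigengene(rbind(a = rep(1, 5), b = rnorm(5))), "constant")
})

test_that("eigengene variance explained tracks the equicorrelation closed form", {
  ## for k equicorrelated genes the leading eigenvalue fraction is
  ## (1 + (k-1) rho) / k
  k <- 10
  rho <- 0.7
  ves <- vapply(1:10, function(s) {
    pb <- plantedBlocks(nPerBlock = k, nSamples = 400, rho = rho, seed = s)
    eigengene(pb$expr[1:k, ])$varianceExplained
  }, numeric(1))
  expect_equal(mean(ves), (1 + (k - 1) * rho) / k, tolerance = 0.03)
})

test_that("eigengene ANOVA detects a planted treatment divergence", {
  d <- canonicalDesign()
  d <- d[d$condition == "stressed", ]
  set.seed(19)
  ## treatments diverge at days 7/11 by 2 SD of noise
  eig <- rnorm(nrow(d)) +
    2 * (d$treatment != "control29") * (d$day %in% c(7, 11))
  names(eig) <- d$sample_id
  res <- eigengeneAnova(eig, d, B = 999, seed = 3)
  expect_lte(res$p_treatment, 0.01)
  ## constant eigengene: everything null
  const <- eigengeneAnova(setNames(rep(1, nrow(d)), d$sample_id), d,
                          B = 199, seed = 1)
  expect_equal(const$p_treatment, 1)
  expect_equal(const$p_interaction, 1)
})
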