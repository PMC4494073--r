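test_that("abundance filter applies both printed criteria strictly", {
  m <- rbind(steady = c(6L, 6L, 6L, 6L),      # mean 6 > 5, SD 0 < 6: kept
             border = c(5L, 5L, 5L, 5L),      # mean not > 5: dropped
             spiky  = c(0L, 0L, 0L, 100L))    # mean 25, SD 50 >= 25: dropped
  colnames(m) <- paste0("s", 1:4)
  res <- filterContigs(m)
  expect_identical(rownames(res$counts), "steady")
  rep <- res$report
  ## hand computation: sample variance of spiky = (3*625 + 5625)/3 = 2500
  expect_equal(rep$sd[rep$gene_id == "spiky"], 50)
  expect_false(rep$sd_lt_mean[rep$gene_id == "spiky"])
  expect_false(rep$mean_gt_threshold[rep$gene_id == "border"])
  ## idempotence
  again <- filterContigs(res$counts)
  expect_identical(again$counts, res$counts)
  expect_error(filterContigs(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("median-of-ratios matches hand-derived and reference values", {
  ## identical columns: every ratio is 1
  m <- matrix(rep(c(3L, 9L, 27L), 2), 3)
  colnames(m) <- c("a", "b")
  expect_equal(unname(medianOfRatios(m)), c(1, 1))
  ## worked example: geometric means sqrt(8), sqrt(200); all per-sample
  ## ratios equal, so the median is the ratio itself
  m <- rbind(g1 = c(2L, 4L), g2 = c(10L, 20L))
  colnames(m) <- c("a", "b")
  sf <- medianOfRatios(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-14)
  ## scale-equivariance on a random matrix: scaling one column by 3
  ## multiplies its factor by 3 up to common rescaling
  set.seed(11)
  m <- matrix(rpois(50 * 4, 40) + 1L, 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  sf0 <- medianOfRatios(m)
  m3 <- m
  m3[, 2] <- m3[, 2] * 3L
  sf3 <- medianOfRatios(m3)
  rel <- (sf3 / sf0)
  expect_equal(unname(rel[2] / rel[1]), 3, tolerance = 1e-10)
  expect_equal(unname(rel[3] / rel[1]), 1, tolerance = 1e-10)
  ## invariant to gene order
  expect_equal(medianOfRatios(m[sample(50), ]), sf0)
  ## agreement with the reference implementation
  expect_equal(medianOfRatios(m),
               DESeq2::estimateSizeFactorsForMatrix(m), tolerance = 1e-12)
  ## no all-positive gene
  z <- rbind(a = c(0L, 5L), b = c(5L, 0L))
  colnames(z) <- c("x", "y")
  expect_error(medianOfRatios(z), "no gene has strictly positive")
})

test_that("normalization divides by size factors and inverts column scaling", {
  m <- rbind(g1 = c(10L, 10L), g2 = c(4L, 4L))
  colnames(m) <- c("a", "b")
  expect_equal(normalizeCounts(m, c(a = 1, b = 1)), m)
  expect_equal(normalizeCounts(m, c(a = 2, b = 1))["g1", "a"], 5)
  expect_error(normalizeCounts(m, c(a = 2)), "no size factor")
  ## normalize o medianOfRatios recovers a column-scaled matrix up to a
  ## global constant (base pre-normalized so its own factors are uniform)
  set.seed(4)
  raw <- matrix(rpois(200, 60) + 1, 50, 4,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  base <- normalizeCounts(raw, medianOfRatios(raw))
  scaled <- sweep(base, 2, c(0.5, 1, 2, 4), "*")
  rec <- normalizeCounts(scaled, medianOfRatios(scaled))
  ratio <- rec / base
  expect_lt(diff(range(ratio)), 1e-8)
})

test_that("log transform is a monotone shifted log2", {
  expect_equal(logTransform(matrix(0)), matrix(0))
  expect_equal(logTransform(matrix(3)), matrix(2))
  expect_error(logTransform(matrix(1), pseudocount = 0), "pseudocount")
  x <- sort(runif(20, 0, 100))
  expect_true(all(diff(logTransform(matrix(x, 1))[1, ]) > 0))
})

test_that("PCA outlier flagging recovers a planted artifact tank run", {
  d <- canonicalDesign()
  cfg <- simulationConfig(nGenes = 300, moduleSizes = c(background_DE = 100))
  sim <- simulateCounts(d, cfg, seed = 9)
  ## the nine stressed day-2 samples of one tank per treatment, inflated
  ## 10x on 30% of genes
  out9 <- d$sample_id[d$condition == "stressed" & d$day == 2 &
                        grepl("_t1$", d$tank_id)]
  expect_length(out9, 9)
  cts <- injectOutliers(sim$counts, out9, scale = 10, fractionGenes = 0.3,
                        seed = 2)
  qc <- flagOutlierSamples(normalizeCounts(AcclimExperiment(cts, d)))
  expect_setequal(qc$sample_id[qc$flagged], out9)
  ## no flags at infinite threshold, and invariance to sample order
  expect_false(any(flagOutlierSamples(
    normalizeCounts(AcclimExperiment(cts, d)), zThreshold = Inf)$flagged))
  perm <- sample(ncol(cts))
  qcPerm <- flagOutlierSamples(
    normalizeCounts(AcclimExperiment(cts[, perm], d)))
  expect_setequal(qcPerm$sample_id[qcPerm$flagged], out9)
})

test_that("spurious flags on homogeneous data stay at the nominal tail level", {
  ## a robust-z > 3 rule on two PCs has a ~0.5% two-sided normal tail per
  ## sample, so a handful of spurious flags per 144-sample run is expected
  ## behaviour; the fraction flagged must stay at that order, far below any
  ## planted-artifact separation
  d <- canonicalDesign()
  flags <- vapply(1:20, function(s) {
    cfg <- simulationConfig(nGenes = 150, moduleSizes = c(background_DE = 0),
                            sigmaColony = 0)
    sim <- simulateCounts(d, cfg, seed = 100 + s)
    sum(flagOutlierSamples(normalizeCounts(
      AcclimExperiment(sim$counts, d)))$flagged)
  }, numeric(1))
  expect_lte(mean(flags) / nrow(d), 0.03)
})
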