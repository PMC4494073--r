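test_that("simulated designs count out correctly", {
  expect_equal(nrow(simulateDesign()), 144)
  cfg <- simulationConfig(coloniesPerTreatment = 1, tanksPerTreatment = 1,
                          days = c(0, 2))
  d <- simulateDesign(cfg)
  expect_equal(nrow(d), 3 * 1 * 2 * 2)
  cells <- table(d$treatment, d$day, d$condition)
  expect_true(all(cells == 1))
})

test_that("generation is bit-reproducible from (config, seed)", {
  cfg <- simulationConfig(nGenes = 40, moduleSizes = c(background_DE = 10))
  a <- simulateExperiment(cfg, seed = 7)
  b <- simulateExperiment(cfg, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$truth$genes, b$truth$genes)
  c2 <- simulateExperiment(cfg, seed = 8)
  expect_false(identical(a$counts, c2$counts))
})

test_that("config validation rejects inconsistent module layouts", {
  expect_error(simulationConfig(nGenes = 10,
                                moduleSizes = c(background_DE = 50)),
               "exceed")
  expect_error(simulationConfig(moduleSizes = c(bogus = 5)), "unknown")
  expect_error(simulateCounts(canonicalDesign(), simulationConfig()),
               "seed is mandatory")
})

test_that("counts follow the planted mean model as dispersion vanishes", {
  d <- canonicalDesign()
  cfg <- simulationConfig(nGenes = 1000,
                          moduleSizes = c(background_DE = 0),
                          dispersionRange = c(1e-6, 1e-6),
                          sigmaColony = 0,
                          baselineLog2Range = c(8, 10),
                          sizeFactorRange = c(1, 1))
  sim <- simulateCounts(d, cfg, seed = 12)
  ## with no effects, unit size factors and negligible dispersion every
  ## sample mean estimates 2^baseline to Poisson accuracy
  est <- rowMeans(sim$counts)
  expected <- 2^sim$truth$genes$baseline_log2
  expect_lt(max(abs(est / expected - 1)), 0.02)
})

test_that("undampened acclimated treatments are a null for treatment contrasts", {
  d <- canonicalDesign()
  cfg <- simulationConfig(nGenes = 300,
                          moduleSizes = c(down_dampened = 100),
                          dampening = 1)
  sim <- simulateCounts(d, cfg, seed = 21)
  ae <- logTransform(normalizeCounts(AcclimExperiment(sim$counts, d)))
  fcC <- geneLog2fc(ae, stratum = ~ day == 11 & treatment == "control29")
  fcA <- geneLog2fc(ae, stratum = ~ day == 11 & treatment == "stable31")
  dif <- (fcA - fcC)[sim$truth$genes$gene_id[sim$truth$genes$module ==
                                               "down_dampened"]]
  expect_lt(abs(mean(dif)), 0.1)
})

test_that("outlier injection is a targeted multiplicative corruption", {
  cfg <- simulationConfig(nGenes = 50, moduleSizes = c(background_DE = 0))
  d <- canonicalDesign(coloniesPerTreatment = 1, tanksPerTreatment = 1)
  sim <- simulateCounts(d, cfg, seed = 2)
  expect_identical(injectOutliers(sim$counts, d$sample_id[1:3], scale = 1),
                   sim$counts)
  expect_identical(injectOutliers(sim$counts, character(0)), sim$counts)
  expect_error(injectOutliers(sim$counts, d$sample_id[1], scale = 0),
               "> 0")
  corrupted <- injectOutliers(sim$counts, d$sample_id[1:2], scale = 10,
                              fractionGenes = 0.4, seed = 5)
  changed <- corrupted[, 1] != sim$counts[, 1]
  expect_equal(sum(changed), 20, tolerance = 2)
  expect_identical(corrupted[, -(1:2)], sim$counts[, -(1:2)])
})

test_that("default baselines survive the abundance filter", {
  cfg <- simulationConfig(nGenes = 500,
                          moduleSizes = c(background_DE = 250))
  sim <- simulateCounts(canonicalDesign(), cfg, seed = 31)
  kept <- filterContigs(sim$counts)
  expect_gte(nrow(kept$counts) / 500, 0.95)
})

test_that("zero-noise phenotype generation inverts exactly through the pipeline", {
  cfg <- simulationConfig(sigmaPhenotype = 0, sigmaWax = 0)
  d <- canonicalDesign()
  ph <- simulatePhenotype(d, cfg, seed = 3)
  curve <- fitAreaCurve(ph$standards)
  chl <- chlorophyllA(as.matrix(ph$phenotype[, 2:5]),
                      volume = cfg$extractVolume)
  areas <- branchArea(ph$phenotype$w1, ph$phenotype$w2, curve)
  dens <- chl / areas
  expect_equal(unname(dens), unname(ph$truth$density), tolerance = 1e-8)
  expect_equal(unname(areas), unname(ph$truth$area), tolerance = 1e-8)
  ## planted retained fractions come back exactly for stressed branches
  stressedIdx <- d$condition == "stressed"
  pair <- match(sub("stressed$", "nonstressed", d$sample_id[stressedIdx]),
                d$sample_id)
  rf <- retainedFraction(
    setNames(dens[stressedIdx], d$colony_id[stressedIdx]),
    setNames(dens[pair], d$colony_id[stressedIdx]))
  expect_equal(unname(rf), unname(ph$truth$retained[stressedIdx]),
               tolerance = 1e-8)
})
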