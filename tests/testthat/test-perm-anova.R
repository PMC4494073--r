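test_that("two-factor F matches an independent least-squares oracle", {
  d <- toyDesign6()
  set.seed(21)
  for (i in 1:5) {
    y <- rnorm(6, sd = 2)
    expect_equal(unname(fitTwoFactorF(y, d)), oracleF(y, d),
                 tolerance = 1e-8)
  }
  ## an extra unbalanced row keeps the design estimable but unbalanced
  d7 <- rbind(d, data.frame(treatment = "control29", day = 2))
  y <- c(1.2, 3.4, 2.2, 0.5, 4.4, 1.1, 2.9)
  expect_equal(unname(fitTwoFactorF(y, d7)), oracleF(y, d7),
               tolerance = 1e-8)
})

test_that("degenerate responses give the documented F sentinels", {
  d <- toyDesign6()
  expect_equal(unname(fitTwoFactorF(rep(2, 6), d)), c(0, 0))
  ## response perfectly separated by treatment
  y <- ifelse(d$treatment == "stable31", 1, 0)
  f <- fitTwoFactorF(y, d)
  expect_identical(unname(f[1]), Inf)
  expect_equal(unname(f[2]), 0)
  expect_error(fitTwoFactorF(rnorm(6),
                             data.frame(treatment = rep("control29", 6),
                                        day = d$day)),
               "fewer than 2 levels")
})

test_that("permutation p-values equal exhaustive enumeration on a toy", {
  d <- toyDesign6()
  set.seed(33)
  y <- rnorm(6)
  perms <- allPermutations(6)
  mine <- permAnova(matrix(y, 1), d, permutations = perms)
  expect_equal(mine$p_treatment, oraclePermP(y, d, perms)[1])
  expect_equal(mine$p_day, oraclePermP(y, d, perms)[2])
  ## constant gene: every permuted F ties the observed one
  const <- permAnova(matrix(1, 1, 6), d, permutations = perms)
  expect_equal(const$p_treatment, 1)
  expect_equal(const$p_day, 1)
})

test_that("permutation ANOVA is seed-deterministic and gene-order invariant", {
  d <- canonicalDesign(coloniesPerTreatment = 1, tanksPerTreatment = 1)
  set.seed(5)
  Y <- matrix(rnorm(10 * nrow(d)), 10,
              dimnames = list(paste0("g", 1:10), d$sample_id))
  a <- permAnova(Y, d, B = 199, seed = 42)
  b <- permAnova(Y, d, B = 199, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  shuf <- permAnova(Y[10:1, ], d, B = 199, seed = 42)
  expect_equal(shuf[rownames(a), "p_treatment"], a$p_treatment)
  expect_error(permAnova(Y, d, B = 50), ">= 99")
})

test_that("BH adjustment matches a literal step-up on random vectors", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1]")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1]")
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), oracleBH(p))
  }
})

test_that("significance selection is inclusive at the threshold", {
  tab <- S4Vectors::DataFrame(q_treatment = c(0.005, 0.01, 0.02, 1),
                              row.names = paste0("g", 1:4))
  expect_identical(selectSignificant(tab, "treatment", 0.01),
                   c("g1", "g2"))
  expect_length(selectSignificant(
    S4Vectors::DataFrame(q_treatment = rep(1, 3),
                         row.names = paste0("g", 1:3)), "treatment", 0.01), 0)
})

test_that("two-group test agrees with exhaustive label enumeration", {
  set.seed(13)
  y <- matrix(rnorm(3 * 8), 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  gA <- paste0("s", 1:4)
  gB <- paste0("s", 5:8)
  splits <- utils::combn(8, 4)
  mine <- twoGroupTest(y, gA, gB, splits = splits)
  ## oracle: recompute |mean difference| for every split directly
  for (g in 1:3) {
    obs <- abs(mean(y[g, 1:4]) - mean(y[g, 5:8]))
    stats <- apply(splits, 2, function(idx)
      abs(mean(y[g, idx]) - mean(y[g, -idx])))
    expect_equal(mine$p[g], (1 + sum(stats >= obs - 1e-12)) / (ncol(splits) + 1))
  }
  ## zero-variance identical groups: p = 1
  z <- matrix(5, 1, 8, dimnames = list("g", paste0("s", 1:8)))
  expect_equal(twoGroupTest(z, gA, gB, splits = splits)$p, 1)
  expect_error(twoGroupTest(y, gA, c(gA[1], gB)), "disjoint")
  expect_error(twoGroupTest(y, gA[1], gB), ">= 2 samples")
})

test_that("permutation p-values are valid under an exchangeable null", {
  ## P(p <= alpha) <= alpha + 1/(B+1), checked by simulation
  d <- canonicalDesign(coloniesPerTreatment = 1, tanksPerTreatment = 1)
  set.seed(77)
  Y <- matrix(rnorm(300 * nrow(d)), 300)
  tab <- permAnova(Y, d, B = 199, seed = 7)
  for (alpha in c(0.01, 0.05, 0.2)) {
    binTol <- 3 * sqrt(alpha * (1 - alpha) / 300)
    expect_lte(mean(tab$p_treatment <= alpha), alpha + 1 / 200 + binTol)
  }
})
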