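## Independent oracles used to freeze expected values. These deliberately
## avoid the package's own code paths: F statistics come from car::Anova on
## lm fits, BH from a literal step-up, eigen decompositions from eigen().

## all n! permutations of 1:n as an n x n! matrix
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(ncol(sub))) {
      k <- k + 1L
      out[, k] <- c(i, rest[sub[, j]])
    }
  }
  out
}

## Type-II F via car on an lm fit; returns c(treatment, day[, interaction])
oracleF <- function(y, design, interaction = FALSE) {
  trt <- factor(design$treatment)
  day <- factor(design$day)
  fml <- if (interaction) y ~ trt * day else y ~ trt + day
  fit <- stats::lm(fml)
  a <- car::Anova(fit, type = 2)
  f <- a[["F value"]]
  if (interaction) c(f[1], f[2], f[3]) else c(f[1], f[2])
}

## exhaustive permutation p-values from an independent QR-residual route:
## Type-II sums of squares assembled from per-model RSS via qr.resid on the
## fixed design matrices (oracleF above pins this construction to car::Anova
## on the observed data)
oraclePermP <- function(y, design, perms, interaction = FALSE) {
  trt <- factor(design$treatment)
  day <- factor(design$day)
  qrT <- qr(stats::model.matrix(~trt))
  qrD <- qr(stats::model.matrix(~day))
  qrA <- qr(stats::model.matrix(~ trt + day))
  qrFull <- if (interaction) qr(stats::model.matrix(~ trt * day)) else qrA
  dfT <- nlevels(trt) - 1
  dfD <- nlevels(day) - 1
  dfI <- qrFull$rank - qrA$rank
  dfRes <- length(y) - qrFull$rank
  fOf <- function(v) {
    rssT <- sum(qr.resid(qrT, v)^2)
    rssD <- sum(qr.resid(qrD, v)^2)
    rssA <- sum(qr.resid(qrA, v)^2)
    rssF <- sum(qr.resid(qrFull, v)^2)
    mse <- rssF / dfRes
    f <- c((rssD - rssA) / dfT / mse, (rssT - rssA) / dfD / mse)
    if (interaction) f <- c(f, (rssA - rssF) / dfI / mse)
    f
  }
  obs <- fOf(y)
  exceed <- rep(0L, length(obs))
  for (b in seq_len(ncol(perms))) {
    fp <- fOf(y[perms[, b]])
    exceed <- exceed + (fp >= obs - 1e-12 * pmax(abs(obs), 1))
  }
  (1 + exceed) / (ncol(perms) + 1)
}

## literal BH step-up
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- running
  }
  q
}

## adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

## two planted equicorrelated co-expression blocks (shared latent factor)
plantedBlocks <- function(nPerBlock = 20, nSamples = 60, rho = 0.9,
                          seed = 1) {
  set.seed(seed)
  make <- function() {
    f <- rnorm(nSamples)
    t(vapply(seq_len(nPerBlock),
             function(i) sqrt(rho) * f + sqrt(1 - rho) * rnorm(nSamples),
             numeric(nSamples)))
  }
  expr <- rbind(make(), make())
  rownames(expr) <- paste0("g", seq_len(2 * nPerBlock))
  colnames(expr) <- paste0("s", seq_len(nSamples))
  list(expr = expr,
       truth = rep(c("A", "B"), each = nPerBlock))
}

## tiny unbalanced two-factor design for oracle comparisons
toyDesign6 <- function() {
  data.frame(
    treatment = c("control29", "control29", "stable31",
                  "stable31", "variable29_33", "variable29_33"),
    day = c(0, 2, 0, 2, 0, 2),
    stringsAsFactors = FALSE)
}

## 2 treatments x 2 days x 2 replicates (interaction estimable, 8 samples;
## days chosen nonzero so day-0 exclusion tests can add disposable rows)
toyDesign8 <- function() {
  data.frame(
    treatment = rep(c("control29", "stable31"), each = 4),
    day = rep(c(2, 2, 7, 7), 2),
    stringsAsFactors = FALSE)
}
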