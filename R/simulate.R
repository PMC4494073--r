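#' Configuration for the synthetic experiment generator
#'
#' Bundles every knob of the simulator with defaults that emulate the
#' structure of the acclimation experiment: a 144-sample factorial design,
#' negative-binomial counts with per-sample size factors and per-colony
#' random effects, planted co-expressed gene modules whose acute-stress
#' response depends on acclimation treatment, a transplantation spike at
#' day 2, and a matching bleaching phenotype.
#'
#' Module semantics (all effects in log2 units): \code{up_dampened} /
#' \code{down_dampened} genes respond to acute stress (+/- \code{betaStress})
#' under the control treatment but with the response multiplied by
#' \code{dampening} under acclimated treatments at days in
#' \code{dampeningOnsetDays}; \code{frontloaded} genes additionally shift
#' their baseline by \code{deltaBase} under acclimated treatments;
#' \code{background_DE} genes respond to stress identically in every
#' treatment (magnitude uniform in \code{backgroundBetaRange}, random sign);
#' \code{acclim_DE} genes differ between acclimated and control treatments
#' in both arms at all days by \code{acclimEffect}, with a random sign per
#' gene so planted treatment effects stay balanced and leave depth
#' estimation identifiable (none planted by default); remaining genes are
#' null. The two acclimated treatments share
#' identical effect parameters, so a stable-versus-variable comparison is
#' null by construction.
#'
#' @param nGenes total genes (default 2000).
#' @param moduleSizes named integer vector over \{up_dampened,
#'   down_dampened, frontloaded, background_DE, acclim_DE\}; must sum to at
#'   most \code{nGenes}.
#' @param betaStress log2 acute-stress response magnitude of the dampened
#'   modules (default 1.5; sign is set by the module direction).
#' @param dampening multiplier d in [0, 1] applied to module stress
#'   responses under acclimated treatments (default 0.4).
#' @param deltaBase log2 baseline shift of frontloaded genes under
#'   acclimated treatments (default 1).
#' @param acclimEffect log2 treatment shift of acclim_DE genes (default 1.5).
#' @param backgroundBetaRange magnitude range for background_DE stress
#'   responses (default c(0.5, 2)).
#' @param baselineLog2Range per-gene baseline log2 mean range (default
#'   c(3, 8), i.e. mean counts 8--256 so nearly all genes pass the
#'   abundance filter).
#' @param dispersionRange NB dispersion range, drawn log-uniformly
#'   (default c(0.01, 0.5)).
#' @param sizeFactorRange per-sample true size-factor range (default
#'   c(0.5, 2)).
#' @param sigmaColony SD of the per-colony log2 random effect (default
#'   0.25).
#' @param day2Spike log2 transplantation-stress spike added to module genes
#'   in every treatment at day 2 (default 0.5).
#' @param dampeningOnsetDays days at which acclimated treatments express the
#'   dampened response (default c(7, 11)).
#' @param coloniesPerTreatment,tanksPerTreatment,days design layout passed
#'   to \code{\link{canonicalDesign}}.
#' @param basalDensity named per-treatment nonstressed chlorophyll density
#'   (ug/cm^2).
#' @param retainedControl,retainedAcclimated,retainedDay0 planted retained
#'   chlorophyll fractions (day 0 applies to every treatment).
#' @param sigmaPhenotype lognormal SD of density noise (default 0.05).
#' @param sigmaWax SD (g) of wax weight-gain measurement noise (default
#'   0.002).
#' @param waxSlope planted area-per-weight-gain slope (cm^2/g, default 25).
#' @param extractVolume ethanol extract volume in ml (default 3).
#' @return a \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nGenes = 2000L,
                             moduleSizes = c(up_dampened = 100L,
                                             down_dampened = 600L,
                                             frontloaded = 50L,
                                             background_DE = 1000L,
                                             acclim_DE = 0L),
                             betaStress = 1.5,
                             dampening = 0.4,
                             deltaBase = 1,
                             acclimEffect = 1.5,
                             backgroundBetaRange = c(0.5, 2),
                             baselineLog2Range = c(3, 8),
                             dispersionRange = c(0.01, 0.5),
                             sizeFactorRange = c(0.5, 2),
                             sigmaColony = 0.25,
                             day2Spike = 0.5,
                             dampeningOnsetDays = c(7, 11),
                             coloniesPerTreatment = 6L,
                             tanksPerTreatment = 2L,
                             days = ACCLIM_DAYS,
                             basalDensity = c(control29 = 4,
                                              stable31 = 5,
                                              variable29_33 = 5),
                             retainedControl = 0.4,
                             retainedAcclimated = 0.7,
                             retainedDay0 = 0.35,
                             sigmaPhenotype = 0.05,
                             sigmaWax = 0.002,
                             waxSlope = 25,
                             extractVolume = 3) {
  known <- c("up_dampened", "down_dampened", "frontloaded",
             "background_DE", "acclim_DE")
  full <- stats::setNames(integer(length(known)), known)
  if (length(moduleSizes)) {
    bad <- setdiff(names(moduleSizes), known)
    if (length(bad)) stop("unknown module(s): ", paste(bad, collapse = ", "))
    full[names(moduleSizes)] <- as.integer(moduleSizes)
  }
  if (sum(full) > nGenes) stop("module sizes exceed nGenes")
  stopifnot(dampening >= 0, dampening <= 1, nGenes >= 2,
            sigmaColony >= 0, day2Spike >= 0,
            all(dampeningOnsetDays %in% ACCLIM_DAYS))
  cfg <- list(nGenes = as.integer(nGenes), moduleSizes = full,
              betaStress = betaStress, dampening = dampening,
              deltaBase = deltaBase, acclimEffect = acclimEffect,
              backgroundBetaRange = backgroundBetaRange,
              baselineLog2Range = baselineLog2Range,
              dispersionRange = dispersionRange,
              sizeFactorRange = sizeFactorRange,
              sigmaColony = sigmaColony, day2Spike = day2Spike,
              dampeningOnsetDays = dampeningOnsetDays,
              coloniesPerTreatment = as.integer(coloniesPerTreatment),
              tanksPerTreatment = as.integer(tanksPerTreatment),
              days = days, basalDensity = basalDensity,
              retainedControl = retainedControl,
              retainedAcclimated = retainedAcclimated,
              retainedDay0 = retainedDay0,
              sigmaPhenotype = sigmaPhenotype, sigmaWax = sigmaWax,
              waxSlope = waxSlope, extractVolume = extractVolume)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate the factorial acclimation design
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return design data.frame (see \code{\link{canonicalDesign}}); the
#'   default configuration yields the canonical 144-sample layout.
#' @export
simulateDesign <- function(config = simulationConfig()) {
  canonicalDesign(coloniesPerTreatment = config$coloniesPerTreatment,
                  tanksPerTreatment = config$tanksPerTreatment,
                  days = config$days)
}

.acclimated <- c("stable31", "variable29_33")

#' Simulate negative-binomial counts with planted modules
#'
#' Draws count[g, s] ~ NB(mean = sf_s * 2^eta, dispersion phi_g) with
#' eta = baseline_g + colonyEffect + day2 spike + acclimation baseline
#' shifts + the treatment-dependent acute-stress response described in
#' \code{\link{simulationConfig}}. The full ground truth (per-gene module,
#' effect sizes, dispersions; per-sample size factors and colony effects) is
#' returned alongside the counts.
#'
#' @param design design data.frame.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with integer matrix \code{counts} (genes x samples) and
#'   \code{truth} (list of \code{genes} and \code{samples} data.frames plus
#'   scalar parameters).
#' @export
simulateCounts <- function(design, config = simulationConfig(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  G <- config$nGenes
  n <- nrow(design)
  geneIds <- sprintf("gene%05d", seq_len(G))
  module <- rep("none", G)
  idx <- 0L
  for (m in names(config$moduleSizes)) {
    k <- config$moduleSizes[[m]]
    if (k > 0) {
      module[idx + seq_len(k)] <- m
      idx <- idx + k
    }
  }
  baseline <- stats::runif(G, config$baselineLog2Range[1],
                           config$baselineLog2Range[2])
  dispersion <- exp(stats::runif(G, log(config$dispersionRange[1]),
                                 log(config$dispersionRange[2])))
  beta <- numeric(G)
  beta[module == "up_dampened"] <- config$betaStress
  beta[module == "down_dampened"] <- -config$betaStress
  beta[module == "frontloaded"] <- config$betaStress
  nBg <- sum(module == "background_DE")
  if (nBg)
    beta[module == "background_DE"] <-
      stats::runif(nBg, config$backgroundBetaRange[1],
                   config$backgroundBetaRange[2]) *
      sample(c(-1, 1), nBg, replace = TRUE)
  damp <- ifelse(module %in% c("up_dampened", "down_dampened", "frontloaded"),
                 config$dampening, 1)
  deltaBase <- ifelse(module == "frontloaded", config$deltaBase, 0)
  nAcc <- sum(module == "acclim_DE")
  acclimShift <- numeric(G)
  if (nAcc)   # random sign: keeps total output balanced so depth estimation
    acclimShift[module == "acclim_DE"] <-   # stays identifiable
      config$acclimEffect * sample(c(-1, 1), nAcc, replace = TRUE)
  spike <- ifelse(module %in% c("up_dampened", "down_dampened", "frontloaded"),
                  config$day2Spike, 0)

  sf <- stats::runif(n, config$sizeFactorRange[1], config$sizeFactorRange[2])
  colonies <- unique(design$colony_id)
  colEff <- stats::setNames(stats::rnorm(length(colonies), 0,
                                         config$sigmaColony), colonies)

  counts <- matrix(0L, G, n, dimnames = list(geneIds, design$sample_id))
  isAcc <- design$treatment %in% .acclimated
  isStr <- design$condition == "stressed"
  onset <- design$day %in% config$dampeningOnsetDays
  isDay2 <- design$day == 2
  for (s in seq_len(n)) {
    eta <- baseline + colEff[design$colony_id[s]] +
      spike * isDay2[s] +
      deltaBase * isAcc[s] +
      acclimShift * isAcc[s]
    if (isStr[s])
      eta <- eta + beta * (if (isAcc[s] && onset[s]) damp else 1)
    mu <- sf[s] * 2^eta
    counts[, s] <- stats::rnbinom(G, mu = mu, size = 1 / dispersion)
  }
  storage.mode(counts) <- "integer"
  truth <- list(
    genes = data.frame(gene_id = geneIds, module = module,
                       baseline_log2 = baseline, dispersion = dispersion,
                       beta_stress = beta, dampening = damp,
                       delta_base = deltaBase, acclim_shift = acclimShift,
                       day2_spike = spike, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = design$sample_id, size_factor = sf,
                         colony_effect = colEff[design$colony_id],
                         outlier = FALSE, row.names = NULL,
                         stringsAsFactors = FALSE),
    sigma_colony = config$sigmaColony, seed = seed)
  list(counts = counts, truth = truth)
}

#' Inject artifact outlier samples
#'
#' Multiplies a random subset of genes by \code{scale} in the chosen samples
#' only, mimicking a batch artifact confined to one acute-stress tank run.
#'
#' @param counts counts matrix.
#' @param sampleIds samples to corrupt (subset of colnames).
#' @param scale multiplicative factor (> 0; 1 leaves the matrix unchanged).
#' @param fractionGenes fraction of genes affected (default 0.3).
#' @param seed RNG seed for the gene subset.
#' @return counts matrix with the corrupted columns.
#' @export
injectOutliers <- function(counts, sampleIds, scale = 10,
                           fractionGenes = 0.3, seed = 1L) {
  if (scale <= 0) stop("scale must be > 0")
  missing <- setdiff(sampleIds, colnames(counts))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  if (!length(sampleIds) || scale == 1) return(counts)
  set.seed(seed)
  g <- sample.int(nrow(counts), round(fractionGenes * nrow(counts)))
  counts[g, sampleIds] <- round(counts[g, sampleIds] * scale)
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate the bleaching phenotype
#'
#' Plants per-treatment nonstressed chlorophyll densities and retained
#' fractions, then generates the raw measurements the phenotype pipeline
#' consumes: four absorbances per branch (by inverting the chlorophyll
#' equation), wax weights from planted areas through a planted standard
#' slope, and a table of area standards. With \code{sigmaPhenotype},
#' \code{sigmaWax} = 0 the full pipeline inverts the generator exactly.
#'
#' @param design design data.frame.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed RNG seed.
#' @return list: \code{phenotype} (per-sample absorbances, volume, wax
#'   weights), \code{standards} (weight_gain, area), and \code{truth}
#'   (planted densities, areas, retained fractions, wax slope).
#' @export
simulatePhenotype <- function(design, config = simulationConfig(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- nrow(design)
  coef <- chlCoefficients()
  shape <- c(0.10, 0.05, 0.30, 0.02)        # relative channel profile
  unitConc <- sum(coef * shape)             # conc of one shape unit
  retained <- ifelse(design$day == 0, config$retainedDay0,
                     ifelse(design$treatment %in% .acclimated,
                            config$retainedAcclimated,
                            config$retainedControl))
  base <- config$basalDensity[design$treatment]
  noise <- exp(stats::rnorm(n, 0, config$sigmaPhenotype))
  density <- ifelse(design$condition == "stressed",
                    base * retained, base) * noise
  area <- stats::runif(n, 5, 15)
  chlTotal <- density * area
  conc <- chlTotal / config$extractVolume
  absorb <- outer(conc / unitConc, shape)
  colnames(absorb) <- paste0("A", names(coef))
  gain2 <- area / config$waxSlope +
    stats::rnorm(n, 0, config$sigmaWax)
  w0 <- stats::runif(n, 4, 6)
  w1 <- w0 + 1.2 * area / config$waxSlope
  w2 <- w1 + gain2
  phenotype <- data.frame(sample_id = design$sample_id, absorb,
                          extract_volume = config$extractVolume,
                          w0 = w0, w1 = w1, w2 = w2,
                          stringsAsFactors = FALSE)
  stdArea <- seq(5, 30, by = 5)
  standards <- data.frame(
    weight_gain = stdArea / config$waxSlope +
      stats::rnorm(length(stdArea), 0, config$sigmaWax),
    area = stdArea)
  truth <- list(density = stats::setNames(density, design$sample_id),
                area = stats::setNames(area, design$sample_id),
                retained = stats::setNames(retained, design$sample_id),
                wax_slope = config$waxSlope, seed = seed)
  list(phenotype = phenotype, standards = standards, truth = truth)
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: design, counts (with truth) and phenotype from one
#' configuration and seed. Counts and phenotype use decorrelated seed
#' streams derived from \code{seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed master RNG seed.
#' @return list with \code{design}, \code{counts}, \code{truth},
#'   \code{phenotype}, \code{standards}, \code{phenotypeTruth}.
#' @export
simulateExperiment <- function(config = simulationConfig(), seed = 1L) {
  design <- simulateDesign(config)
  cts <- simulateCounts(design, config, seed = seed)
  ph <- simulatePhenotype(design, config, seed = seed + 1000003L)
  list(design = design, counts = cts$counts, truth = cts$truth,
       phenotype = ph$phenotype, standards = ph$standards,
       phenotypeTruth = ph$truth)
}
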