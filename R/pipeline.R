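.RUN_DEFAULTS <- list(
  counts = NULL, design = NULL, phenotype = NULL, standards = NULL,
  out_dir = NULL, simulate = FALSE,
  min_mean = 5, z_threshold = 3, pseudocount = 1,
  alpha = 0.01, B = 1999L, rho = 0.6, min_size = 10L,
  draws = 1000L, tau_baseline = 0.5, tau_response = 0.25,
  exclude_day0 = TRUE, response_days = c(7, 11), dampening_day = 11,
  seed = 1L)

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, checks types and ranges, and rejects unknown keys. The
#' returned list is the single source of every stage parameter and seed.
#'
#' @param config named list of overrides (possibly empty).
#' @return normalized configuration list.
#' @export
validateRunConfig <- function(config = list()) {
  unknown <- setdiff(names(config), names(.RUN_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.RUN_DEFAULTS, config)
  if (!(cfg$alpha > 0 && cfg$alpha < 1))
    stop("alpha must lie in (0, 1)")
  if (cfg$B < 99) stop("B must be >= 99")
  if (cfg$draws < 999) stop("draws must be >= 999")
  if (!(cfg$rho > 0 && cfg$rho < 1)) stop("rho must lie in (0, 1)")
  if (cfg$min_size < 2) stop("min_size must be >= 2")
  if (cfg$pseudocount <= 0) stop("pseudocount must be > 0")
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$counts) || is.null(cfg$design))
      stop("counts and design paths are required unless simulate = TRUE")
  }
  cfg$B <- as.integer(cfg$B)
  cfg$draws <- as.integer(cfg$draws)
  cfg$min_size <- as.integer(cfg$min_size)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

## deterministic per-stage seed stream from one master seed
.stageSeed <- function(master, stage) {
  offsets <- c(simulate = 11L, anova_nonstressed = 23L, anova_stressed = 37L,
               cluster = 53L, eigengene = 67L, respond = 79L,
               dampening = 97L, phenotype = 113L)
  (as.integer(master) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full acclimation analysis pipeline
#'
#' Composes the stages end-to-end: abundance filtering, median-of-ratios
#' normalization, PCA outlier flagging and removal, per-gene permutational
#' ANOVA run separately for nonstressed and stressed samples, selection of
#' acclimation-significant genes (stressed arm), co-expression clustering
#' with eigengenes and eigengene ANOVA, per-gene heat-stress responses with
#' cluster-level resampling null tests, dampening quantification and
#' mechanism classification, and (when phenotype inputs are present) the
#' chlorophyll bleaching analysis. All result tables are written as TSV to
#' \code{out_dir} together with a plain-text log of every parameter, seed
#' and per-stage row count.
#'
#' @param config named list, see \code{\link{validateRunConfig}}; with
#'   \code{simulate = TRUE} inputs are generated by
#'   \code{\link{simulateExperiment}} from the master seed.
#' @param simConfig \code{\link{simulationConfig}} used when simulating.
#' @return invisibly, a list of the in-memory stage results (experiment,
#'   test tables, clusters, responses, dampening, phenotype ANOVA).
#' @export
runAcclimPipeline <- function(config = list(),
                              simConfig = simulationConfig()) {
  cfg <- validateRunConfig(config)
  outDir <- cfg$out_dir
  if (is.null(outDir)) outDir <- tempfile("acclim_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run_log.txt")
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  note("coralAcclim pipeline; master seed %d", cfg$seed)
  note("config: %s", paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1)),
    sep = "=", collapse = "; "))

  ## ---- inputs ----
  if (isTRUE(cfg$simulate)) {
    sim <- simulateExperiment(simConfig, seed = .stageSeed(cfg$seed, "simulate"))
    counts <- sim$counts
    design <- sim$design
    phen <- sim$phenotype
    standards <- sim$standards
    writeResultTable(sim$truth$genes, file.path(outDir, "truth_genes.tsv"))
    note("simulated %d genes x %d samples", nrow(counts), ncol(counts))
  } else {
    counts <- readCounts(cfg$counts)
    design <- readDesign(cfg$design)
    phen <- if (!is.null(cfg$phenotype)) readResultTable(cfg$phenotype)
    standards <- if (!is.null(cfg$standards)) readResultTable(cfg$standards)
  }
  ae <- AcclimExperiment(counts, design)

  ## ---- filter + normalize + outliers ----
  ae <- filterContigs(ae, minMean = cfg$min_mean)
  note("abundance filter kept %d genes", nrow(ae))
  writeResultTable(metadata(ae)$filter_report,
                   file.path(outDir, "filter_report.tsv"))
  ae <- normalizeCounts(ae)
  writeResultTable(data.frame(sample_id = colnames(ae),
                              size_factor = colData(ae)$size_factor),
                   file.path(outDir, "size_factors.tsv"))
  qc <- flagOutlierSamples(ae, zThreshold = cfg$z_threshold,
                           pseudocount = cfg$pseudocount)
  writeResultTable(qc, file.path(outDir, "outlier_report.tsv"))
  if (any(qc$flagged)) {
    note("removing %d flagged outlier sample(s)", sum(qc$flagged))
    ae <- ae[, !qc$flagged]
    ae <- normalizeCounts(ae)   # refresh size factors without outliers
  } else note("no outlier samples flagged")
  ae <- logTransform(ae, pseudocount = cfg$pseudocount)

  ## ---- per-gene ANOVA, each condition separately ----
  tests <- list()
  sig <- list()
  for (cond in c("nonstressed", "stressed")) {
    sub <- ae[, colData(ae)$condition == cond]
    tab <- permAnova(assay(sub, "log2"), designTable(sub), B = cfg$B,
                     seed = .stageSeed(cfg$seed, paste0("anova_", cond)))
    tests[[cond]] <- tab
    sig[[cond]] <- selectSignificant(tab, "treatment", cfg$alpha)
    note("%s ANOVA: %d of %d genes significant for treatment at FDR %.3g",
         cond, length(sig[[cond]]), nrow(tab), cfg$alpha)
    writeResultTable(data.frame(gene_id = rownames(tab),
                                as.data.frame(tab)),
                     file.path(outDir, sprintf("anova_%s.tsv", cond)))
  }

  ## ---- clustering of stressed-arm acclimation genes ----
  clusters <- NULL
  eigTests <- NULL
  if (length(sig$stressed) >= cfg$min_size) {
    stressed <- ae[, colData(ae)$condition == "stressed"]
    exprSig <- assay(stressed, "log2")[sig$stressed, , drop = FALSE]
    corr <- spearmanMatrix(exprSig)
    clusters <- clusterGenes(corr, rhoThreshold = cfg$rho,
                             minSize = cfg$min_size)
    clusters <- addEigengenes(clusters, exprSig)
    note("clustering: %d cluster(s), %d unassigned of %d genes",
         length(clusterLabels(clusters)),
         sum(membership(clusters) == "unassigned"), length(sig$stressed))
    writeResultTable(data.frame(gene_id = names(membership(clusters)),
                                cluster = membership(clusters)),
                     file.path(outDir, "cluster_membership.tsv"))
    if (length(clusterLabels(clusters))) {
      writeResultTable(eigengenes(clusters),
                       file.path(outDir, "eigengenes.tsv"))
      eigTests <- do.call(rbind, lapply(clusterLabels(clusters), function(l)
        data.frame(cluster = l, as.data.frame(
          eigengeneAnova(eigengenes(clusters)[l, ], designTable(stressed),
                         B = cfg$B,
                         seed = .stageSeed(cfg$seed, "eigengene"))))))
      writeResultTable(eigTests, file.path(outDir, "eigengene_anova.tsv"))
    }
  } else note("too few significant genes to cluster (%d)",
              length(sig$stressed))

  ## ---- heat-stress responses + cluster null tests + dampening ----
  respStratum <- local({
    days <- cfg$response_days
    function(d) d$day %in% days
  })
  fcAll <- geneLog2fc(ae, stratum = respStratum,
                      pseudocount = cfg$pseudocount)
  writeResultTable(data.frame(gene_id = names(fcAll), log2fc = fcAll),
                   file.path(outDir, "stress_response.tsv"))
  nullTests <- list()
  if (!is.null(clusters)) {
    for (l in clusterLabels(clusters)) {
      genes <- names(membership(clusters))[membership(clusters) == l]
      nullTests[[l]] <- clusterNullTest(
        fcAll, genes, nDraws = cfg$draws,
        seed = .stageSeed(cfg$seed, "respond"))
      note("cluster %s null test: observed %.3f, p = %.4g", l,
           nullTests[[l]]@observed, pValue(nullTests[[l]]))
    }
    if (length(nullTests))
      writeResultTable(data.frame(
        cluster = names(nullTests),
        observed = vapply(nullTests, slot, numeric(1), "observed"),
        p = vapply(nullTests, pValue, numeric(1)),
        lower95 = vapply(nullTests, function(t) t@envelope[1], numeric(1)),
        upper95 = vapply(nullTests, function(t) t@envelope[2], numeric(1))),
        file.path(outDir, "cluster_null_tests.tsv"))
  }

  dampTable <- NULL
  mech <- NULL
  if (!is.null(clusters) && length(clusterLabels(clusters))) {
    dDay <- cfg$dampening_day
    fcControl <- geneLog2fc(ae, stratum = function(d)
      d$day == dDay & d$treatment == "control29",
      pseudocount = cfg$pseudocount)
    rows <- list()
    for (trt in c("stable31", "variable29_33")) {
      fcAcc <- geneLog2fc(ae, stratum = function(d)
        d$day == dDay & d$treatment == trt, pseudocount = cfg$pseudocount)
      for (l in clusterLabels(clusters)) {
        genes <- names(membership(clusters))[membership(clusters) == l]
        di <- dampeningIndex(fcControl[genes], fcAcc[genes],
                             seed = .stageSeed(cfg$seed, "dampening"))
        rows[[paste(trt, l)]] <- data.frame(
          treatment = trt, cluster = l, slope = di$slope,
          ci_lower = di$ci[1], ci_upper = di$ci[2], ratio = di$ratio,
          dampening = di$dampening)
        note("dampening %s / %s: slope %.3f [%.3f, %.3f]",
             trt, l, di$slope, di$ci[1], di$ci[2])
      }
    }
    dampTable <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    writeResultTable(dampTable, file.path(outDir, "dampening.tsv"))

    norm <- assay(ae, "normalized")
    dsg <- designTable(ae)
    armMean <- function(cond, trts) {
      keep <- dsg$day == dDay & dsg$condition == cond & dsg$treatment %in% trts
      rowMeans(norm[, dsg$sample_id[keep], drop = FALSE])
    }
    mech <- classifyMechanism(
      armMean("nonstressed", "control29"),
      armMean("nonstressed", .acclimated),
      armMean("stressed", "control29"),
      armMean("stressed", .acclimated),
      tauBaseline = cfg$tau_baseline, tauResponse = cfg$tau_response,
      pseudocount = cfg$pseudocount)
    writeResultTable(data.frame(gene_id = names(mech), mechanism = mech),
                     file.path(outDir, "mechanism_labels.tsv"))
  }

  ## ---- phenotype ----
  phenResult <- NULL
  if (!is.null(phen) && !is.null(standards)) {
    curve <- fitAreaCurve(standards)
    absCols <- grep("^A[0-9]+$", colnames(phen), value = TRUE)
    chl <- chlorophyllA(as.matrix(phen[, absCols]),
                        volume = phen$extract_volume[1])
    areas <- branchArea(phen$w1, phen$w2, curve)
    densTab <- data.frame(sample_id = phen$sample_id, chl_total = chl,
                          area = areas, chl_density = chl / areas)
    writeResultTable(densTab, file.path(outDir, "chl_density.tsv"))
    dd <- design[match(densTab$sample_id, design$sample_id), ]
    wide <- merge(
      cbind(dd[dd$condition == "stressed",
               c("colony_id", "treatment", "day")],
            stressed = densTab$chl_density[dd$condition == "stressed"]),
      cbind(dd[dd$condition == "nonstressed", c("colony_id", "day")],
            nonstressed = densTab$chl_density[dd$condition == "nonstressed"]),
      by = c("colony_id", "day"))
    wide$retained <- retainedFraction(
      stats::setNames(wide$stressed, wide$colony_id),
      stats::setNames(wide$nonstressed, wide$colony_id))
    writeResultTable(wide, file.path(outDir, "retained_fraction.tsv"))
    phenResult <- phenotypeAnova(
      wide$retained, data.frame(treatment = wide$treatment, day = wide$day),
      excludeDay0 = cfg$exclude_day0, B = cfg$B,
      seed = .stageSeed(cfg$seed, "phenotype"))
    note("phenotype ANOVA: p_treatment = %.4g", phenResult$p_treatment)
    writeResultTable(as.data.frame(phenResult),
                     file.path(outDir, "phenotype_anova.tsv"))
  }

  writeLines(logLines, logPath)
  invisible(list(experiment = ae, tests = tests, significant = sig,
                 clusters = clusters, eigengeneTests = eigTests,
                 responses = fcAll, nullTests = nullTests,
                 dampening = dampTable, mechanism = mech,
                 phenotypeAnova = phenResult, outDir = outDir,
                 config = cfg))
}
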