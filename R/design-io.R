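#' Canonical 144-sample acclimation design
#'
#' Builds the full factorial layout of the acclimation experiment: three
#' acclimation treatments (ambient 29 C control, stable 31 C, variable
#' 29-33 C) with two replicate tanks of three colonies each (six colonies per
#' treatment), assayed at four acclimation durations, with a heat-stressed
#' and a nonstressed branch per colony and day. Colonies assayed at days 0
#' and 2 come from a second collection batch (batch 2); days 7 and 11 from
#' batch 1. 3 treatments x 6 colonies x 4 days x 2 conditions = 144 samples.
#'
#' @param coloniesPerTreatment colonies per treatment per batch (default 6,
#'   split over \code{tanksPerTreatment} tanks).
#' @param tanksPerTreatment replicate acclimation tanks per treatment
#'   (default 2).
#' @param days acclimation durations assayed (default \code{c(0, 2, 7, 11)};
#'   days 0 and 2 are assigned to batch 2, later days to batch 1).
#' @param treatments acclimation treatments to include.
#' @return data.frame with columns \code{sample_id}, \code{colony_id},
#'   \code{tank_id}, \code{batch}, \code{treatment}, \code{day},
#'   \code{condition}.
#' @examples
#' d <- canonicalDesign()
#' nrow(d)  # 144
#' table(d$treatment, d$condition)
#' @export
canonicalDesign <- function(coloniesPerTreatment = 6L,
                            tanksPerTreatment = 2L,
                            days = ACCLIM_DAYS,
                            treatments = ACCLIM_TREATMENTS) {
  stopifnot(coloniesPerTreatment >= 1, tanksPerTreatment >= 1,
            coloniesPerTreatment %% tanksPerTreatment == 0,
            all(days %in% ACCLIM_DAYS),
            all(treatments %in% ACCLIM_TREATMENTS))
  rows <- list()
  for (tr in treatments) {
    for (day in sort(as.integer(days))) {
      batch <- if (day %in% c(0L, 2L)) 2L else 1L
      for (col in seq_len(coloniesPerTreatment)) {
        tank <- ((col - 1L) %/% (coloniesPerTreatment %/% tanksPerTreatment)) + 1L
        colony <- sprintf("%s_b%d_c%02d", tr, batch, col)
        for (cond in ACCLIM_CONDITIONS) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_d%02d_%s", colony, day, cond),
            colony_id = colony,
            tank_id = sprintf("%s_t%d", tr, tank),
            batch = batch,
            treatment = tr,
            day = day,
            condition = cond,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  validateDesign(design)
}

validateDesign <- function(design) {
  missing <- setdiff(DESIGN_COLUMNS, colnames(design))
  if (length(missing))
    stop("design lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(design$treatment), ACCLIM_TREATMENTS)
  if (length(bad))
    stop("unknown treatment level(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(ACCLIM_TREATMENTS, collapse = ", "))
  bad <- setdiff(unique(design$condition), ACCLIM_CONDITIONS)
  if (length(bad))
    stop("unknown condition level(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(ACCLIM_CONDITIONS, collapse = ", "))
  design$day <- as.integer(design$day)
  bad <- setdiff(unique(design$day), ACCLIM_DAYS)
  if (length(bad))
    stop("unknown day value(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(ACCLIM_DAYS, collapse = ", "))
  design$batch <- as.integer(design$batch)
  design[, DESIGN_COLUMNS]
}

#' Read a gene-by-sample count matrix
#'
#' Reads a delimited text file whose first column holds gene (contig) ids and
#' whose header row holds sample ids; all cells must be nonnegative integers.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab; use \code{","} for CSV).
#' @return integer matrix, genes in rows.
#' @export
readCounts <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count file needs a gene-id column plus >= 1 sample")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicated gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(m, 2, function(x) all(grepl("^-?[0-9]+$", x))))
    stop("non-integer cell(s) in column(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  if (any(abs(m - round(m)) > 0))
    stop("counts must be integers")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 ids[idx[1]], colnames(m)[idx[2]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Read a sample design table
#'
#' @param path file path to a TSV/CSV with columns \code{sample_id},
#'   \code{colony_id}, \code{tank_id}, \code{batch}, \code{treatment},
#'   \code{day}, \code{condition}.
#' @param delimiter field delimiter (default tab).
#' @return validated design data.frame.
#' @export
readDesign <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  validateDesign(tab)
}

#' Construct an AcclimExperiment
#'
#' Joins a count matrix to its sample design by sample id (order-independent:
#' design rows are matched to matrix columns by id) and returns a validated
#' \linkS4class{AcclimExperiment}.
#'
#' @param counts integer matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames.
#' @param design design data.frame as from \code{\link{readDesign}} or
#'   \code{\link{canonicalDesign}}.
#' @return an \linkS4class{AcclimExperiment}.
#' @examples
#' sim <- simulateExperiment(simulationConfig(nGenes = 50), seed = 1)
#' ae <- AcclimExperiment(sim$counts, sim$design)
#' @export
AcclimExperiment <- function(counts, design) {
  design <- validateDesign(design)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("count matrix needs at least 2 genes and 2 samples")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids (rownames) and sample ids (colnames)")
  if (!setequal(colnames(counts), design$sample_id))
    stop("sample ids in counts and design do not match; counts-only: ",
         paste(utils::head(setdiff(colnames(counts), design$sample_id), 5),
               collapse = ", "),
         "; design-only: ",
         paste(utils::head(setdiff(design$sample_id, colnames(counts)), 5),
               collapse = ", "))
  design <- design[match(colnames(counts), design$sample_id), ]
  cd <- S4Vectors::DataFrame(design[, setdiff(DESIGN_COLUMNS, "sample_id")],
                             row.names = design$sample_id)
  .AcclimExperiment(SummarizedExperiment(
    assays = list(counts = counts), colData = cd))
}

#' Write a result table as delimited text
#'
#' Writes any data.frame or matrix with a header row, in a fixed column
#' order, such that re-reading with \code{\link{readResultTable}} reproduces
#' integer values exactly and reals to better than 1e-12. Matrices are
#' written with their rownames in a leading \code{row_id} column.
#'
#' @param x data.frame or matrix.
#' @param path output path.
#' @param delimiter field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(x, path, delimiter = "\t") {
  if (is.matrix(x)) {
    x <- data.frame(row_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) sprintf("%.17g", v))
  utils::write.table(x, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeResultTable
#' @param numeric columns to coerce back to numeric on reading (default all
#'   columns that parse as numbers).
#' @export
readResultTable <- function(path, delimiter = "\t", numeric = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE)
  tab
}
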