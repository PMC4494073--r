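#' Default chlorophyll-a absorbance coefficients
#'
#' Coefficients of a published four-wavelength chlorophyll-a-in-ethanol
#' equation, applied to optical densities at 632, 649, 665 and 696 nm to
#' give a concentration in ug/ml. Field protocols sometimes list 655 nm for
#' the third wavelength; the calibration used here is defined at 665 nm and
#' both conventions are accepted by supplying your own coefficient vector.
#' All coefficients are fully user-overridable.
#'
#' @return named numeric vector of length 4.
#' @export
chlCoefficients <- function() {
  c(`632` = 0.0604, `649` = -4.5224, `665` = 13.2969, `696` = -1.7453)
}

#' Total chlorophyll a from absorbances
#'
#' Concentration (ug/ml) is the dot product of the coefficient vector with
#' the four absorbances; total chlorophyll (ug) multiplies by the ethanol
#' extract volume. Exactly linear in both absorbances and volume. A negative
#' computed value (possible with noisy low absorbances) is reported as-is
#' with a warning.
#'
#' @param absorbances numeric vector of 4 optical densities (632, 649, 665,
#'   696 nm order), or a matrix with 4 columns for many branches.
#' @param coefficients 4-vector of equation coefficients (default
#'   \code{\link{chlCoefficients}}).
#' @param volume extract volume in ml (default 3, the standard preservation
#'   volume per branch).
#' @return total chlorophyll a in ug (vector if a matrix was given).
#' @export
chlorophyllA <- function(absorbances, coefficients = chlCoefficients(),
                         volume = 3) {
  stopifnot(length(coefficients) == 4, volume > 0)
  if (is.matrix(absorbances)) {
    stopifnot(ncol(absorbances) == 4)
    if (any(absorbances < 0)) stop("absorbances must be >= 0")
    total <- as.numeric(absorbances %*% coefficients) * volume
  } else {
    stopifnot(length(absorbances) == 4)
    if (any(absorbances < 0)) stop("absorbances must be >= 0")
    total <- sum(coefficients * absorbances) * volume
  }
  if (any(total < 0))
    warning("negative chlorophyll value(s) computed; reported as-is")
  total
}

#' Fit the wax-dip surface-area standard curve
#'
#' Ordinary least-squares fit of known surface area on wax weight gain over
#' a set of standards dipped alongside the branches. The intercept is
#' reported (rather than forced to zero) so users can check it is near zero.
#'
#' @param standards data.frame with columns \code{weight_gain} (g) and
#'   \code{area} (cm^2); >= 3 rows with distinct weight gains.
#' @return an \linkS4class{AreaStandardCurve}.
#' @export
fitAreaCurve <- function(standards) {
  stopifnot(all(c("weight_gain", "area") %in% colnames(standards)))
  if (nrow(standards) < 3) stop("need >= 3 standards")
  if (length(unique(standards$weight_gain)) < 2)
    stop("standards must have distinct weight gains")
  fit <- stats::lm(area ~ weight_gain, data = standards)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((standards$area - mean(standards$area))^2)
  .AreaStandardCurve(slope = unname(stats::coef(fit)[2]),
                     intercept = unname(stats::coef(fit)[1]),
                     r.squared = r2,
                     standards = standards[, c("weight_gain", "area")])
}

#' Branch surface area from wax weights
#'
#' The branch is dipped in melted wax twice and weighed after each dip; the
#' first dip seals the porous skeleton, so the second-dip weight gain
#' (w2 - w1) is the quantity proportional to surface area and is converted
#' through the standard curve.
#'
#' @param w1,w2 branch weight (g) after the first and second dip.
#' @param curve an \linkS4class{AreaStandardCurve}.
#' @return surface area in cm^2 (must come out positive).
#' @export
branchArea <- function(w1, w2, curve) {
  if (any(w2 < w1)) stop("w2 must be >= w1")
  area <- curve@slope * (w2 - w1) + curve@intercept
  if (any(area <= 0))
    stop("non-positive predicted area; weight gain below calibration range")
  area
}

#' Retained chlorophyll fraction (bleaching resistance)
#'
#' Per colony and day, the chlorophyll-a density (ug/cm^2) of the
#' heat-stressed branch divided by that of the paired nonstressed branch.
#' Values above 1 are possible and kept.
#'
#' @param stressedDensity,nonstressedDensity named numeric vectors (names =
#'   colony ids, aligned pairs) of chlorophyll density.
#' @return named numeric vector of retained fractions.
#' @export
retainedFraction <- function(stressedDensity, nonstressedDensity) {
  stopifnot(length(stressedDensity) == length(nonstressedDensity))
  bad <- which(nonstressedDensity <= 0)
  if (length(bad))
    stop("nonstressed density is zero for colony(ies): ",
         paste(names(nonstressedDensity)[bad], collapse = ", "))
  stressedDensity / nonstressedDensity
}

#' Permutational ANOVA on a colony-level phenotype
#'
#' Tests acclimation treatment, day and their interaction on a per-colony
#' phenotype (e.g. retained chlorophyll fraction) with the same permutation
#' engine used for gene expression. Day 0 is excluded by default: the
#' day-0 assay reflects transplantation stress rather than acclimation.
#'
#' @param values named numeric vector (one value per design row, or named by
#'   \code{sample_id}).
#' @param design design data.frame with \code{treatment} and \code{day}
#'   (one row per value).
#' @param excludeDay0 drop day-0 rows before testing (default TRUE).
#' @param B permutations (default 999).
#' @param seed RNG seed.
#' @param permutations optional explicit permutation matrix.
#' @return one-row \link[S4Vectors]{DataFrame} with F/p/q for treatment,
#'   day and interaction.
#' @export
phenotypeAnova <- function(values, design, excludeDay0 = TRUE, B = 999L,
                           seed = 1L, permutations = NULL) {
  stopifnot(length(values) == nrow(design))
  if (excludeDay0) {
    keep <- design$day != 0
    values <- values[keep]
    design <- design[keep, , drop = FALSE]
  }
  permAnova(matrix(values, nrow = 1, dimnames = list("phenotype", NULL)),
            design, B = B, seed = seed, interaction = TRUE,
            permutations = permutations)
}
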