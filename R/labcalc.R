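# Shake-flask assay arithmetic: spectrophotometric calibration curves,
# detection/quantification limits, absorbance-to-concentration inversion,
# molar masses from molecular formulas, and conversion of a measured
# concentration to a mole-fraction solubility in a two-component DES.

# IUPAC conventional atomic weights, 5 significant figures. Extensible.
ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, Cl = 35.45,
  F = 18.998, P = 30.974, Br = 79.904, I = 126.90, Na = 22.990, K = 39.098
)

#' Fit a linear calibration curve
#'
#' Ordinary least squares of absorbance on concentration (A = slope * C +
#' intercept) with the standard coefficient of determination.
#'
#' @param concentrations numeric, mg/mL; at least 3 distinct values.
#' @param absorbances numeric, same length.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
fit_calibration <- function(concentrations, absorbances) {
  assert_that(length(concentrations) == length(absorbances),
              "concentration and absorbance vectors must match")
  assert_that(length(concentrations) >= 3L, "need at least 3 calibration points")
  assert_that(length(unique(concentrations)) >= 2L, "concentrations must be distinct")
  fit <- stats::lm(absorbances ~ concentrations)
  # summary.lm warns on an exactly collinear (perfect) fit; R^2 = 1 is the
  # correct report for noiseless calibration points
  r2 <- if (stats::var(absorbances) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Detection and quantification limits
#'
#' ICH convention: LOD = 3.3 sigma / slope, LOQ = 10 sigma / slope, where
#' sigma is the standard deviation of blank responses.
#'
#' @param blank_sd standard deviation of the blank absorbance (>= 0).
#' @param slope calibration slope (> 0), absorbance per (mg/mL).
#' @return list with `lod` and `loq` in mg/mL.
#' @export
lod_loq <- function(blank_sd, slope) {
  assert_that(is_scalar_number(blank_sd) && blank_sd >= 0, "blank_sd must be >= 0")
  if (!is_scalar_number(slope) || slope <= 0) stop_f("slope must be positive")
  list(lod = 3.3 * blank_sd / slope, loq = 10 * blank_sd / slope)
}

#' Construct a validated calibration curve
#'
#' @param compound_id compound identifier.
#' @param lambda_max analytical wavelength, nm.
#' @param slope,intercept linear regression coefficients (slope > 0).
#' @param r_squared determination coefficient in \[0, 1\].
#' @param lod,loq detection/quantification limits, mg/mL (0 < lod < loq).
#' @return object of class `calibration_curve`.
#' @export
calibration_curve <- function(compound_id, lambda_max, slope, intercept,
                              r_squared, lod, loq) {
  assert_that(is_scalar_number(slope) && slope > 0, "slope must be positive")
  assert_that(is_scalar_number(r_squared) && r_squared >= 0 && r_squared <= 1,
              "r_squared must lie in [0, 1]")
  assert_that(is_scalar_number(lod) && is_scalar_number(loq) && lod > 0 && loq > lod,
              "limits must satisfy loq > lod > 0")
  structure(list(compound_id = compound_id, lambda_max = lambda_max,
                 slope = slope, intercept = intercept, r_squared = r_squared,
                 lod = lod, loq = loq),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s @ %g nm: A = %.4g C + %.4g (R2 %.4g, LOD %.4g, LOQ %.4g mg/mL)\n",
              x$compound_id, x$lambda_max, x$slope, x$intercept,
              x$r_squared, x$lod, x$loq))
  invisible(x)
}

#' Concentration from a measured absorbance
#'
#' Inverts the calibration line and applies the dilution factor:
#' `dilution_factor * (absorbance - intercept) / slope`. An absorbance at
#' or below the intercept (the blank response) is an error; a result below
#' the curve's LOQ is flagged with a warning and a `below_loq` attribute.
#'
#' @param curve a [calibration_curve()].
#' @param absorbance measured absorbance (must exceed the intercept).
#' @param dilution_factor dilution applied before measurement (>= 1).
#' @return concentration in mg/mL.
#' @export
concentration_from_absorbance <- function(curve, absorbance, dilution_factor = 1) {
  assert_that(inherits(curve, "calibration_curve"), "curve must be a calibration_curve")
  assert_that(is_scalar_number(absorbance), "absorbance must be a single number")
  assert_that(is_scalar_number(dilution_factor) && dilution_factor >= 1,
              "dilution_factor must be >= 1")
  if (absorbance <= curve$intercept) {
    stop_f("absorbance %.4g does not exceed the blank response %.4g",
           absorbance, curve$intercept)
  }
  conc <- dilution_factor * (absorbance - curve$intercept) / curve$slope
  undiluted <- (absorbance - curve$intercept) / curve$slope
  if (undiluted < curve$loq) {
    warning(sprintf("measured concentration %.4g mg/mL is below the LOQ (%.4g mg/mL)",
                    undiluted, curve$loq), call. = FALSE)
    attr(conc, "below_loq") <- TRUE
  }
  conc
}

#' Molar mass from a Hill-notation molecular formula
#'
#' Sums conventional atomic weights over the parsed element counts and
#' reports the result to two decimals.
#'
#' @param formula Hill-notation string, e.g. `"C13H19NO4S"`.
#' @return molar mass in g/mol, rounded to 2 decimals.
#' @export
#' @examples
#' molar_mass("H2O")        # 18.02
#' molar_mass("C13H19NO4S") # probenecid, 285.36
molar_mass <- function(formula) {
  assert_that(is.character(formula) && length(formula) == 1L && nzchar(formula),
              "formula must be a non-empty string")
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    stop_f("malformed formula '%s'", formula)
  }
  total <- 0
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!el %in% names(ATOMIC_WEIGHTS)) stop_f("unknown element symbol '%s' in '%s'", el, formula)
    total <- total + cnt * ATOMIC_WEIGHTS[[el]]
  }
  round(total, 2)
}

#' Construct a shake-flask assay sample
#'
#' @param absorbance measured absorbance (> 0).
#' @param dilution_factor dilution before measurement (>= 1).
#' @param density sample density, g/mL (> 0).
#' @param solute_mw solute molar mass, g/mol.
#' @param hba_mw,hbd_mw molar masses of the DES constituents, g/mol.
#' @param molar_ratio HBD-to-HBA molar ratio r (e.g. 2 for a 1:2 DES).
#' @return object of class `assay_sample`.
#' @export
assay_sample <- function(absorbance, dilution_factor, density, solute_mw,
                         hba_mw, hbd_mw, molar_ratio = 2) {
  for (v in list(absorbance, density, solute_mw, hba_mw, hbd_mw, molar_ratio)) {
    assert_that(is_scalar_number(v) && v > 0, "assay sample fields must be positive numbers")
  }
  assert_that(is_scalar_number(dilution_factor) && dilution_factor >= 1,
              "dilution_factor must be >= 1")
  structure(list(absorbance = absorbance, dilution_factor = dilution_factor,
                 density = density, solute_mw = solute_mw, hba_mw = hba_mw,
                 hbd_mw = hbd_mw, molar_ratio = molar_ratio),
            class = "assay_sample")
}

#' Mole-fraction solubility from an assayed concentration
#'
#' Bookkeeping per 1 mL of saturated solution: the solute contributes
#' `c / MW_solute` moles (c in g/mL); the remaining mass
#' `density - c` is solvent, split into HBA and HBD moles according to the
#' DES molar ratio r (one formula unit weighs `MW_HBA + r * MW_HBD` and
#' yields 1 HBA and r HBD moles). HBA and HBD count as separate species.
#'
#' @param sample an [assay_sample()].
#' @param concentration solute concentration in the saturated sample, mg/mL.
#' @return mole fraction x in (0, 1) (0 when concentration is 0).
#' @export
mole_fraction_from_assay <- function(sample, concentration) {
  assert_that(inherits(sample, "assay_sample"), "sample must be an assay_sample")
  assert_that(is_scalar_number(concentration) && concentration >= 0,
              "concentration must be >= 0 (mg/mL)")
  c_g <- concentration / 1000  # g per mL
  if (c_g >= sample$density) {
    stop_f("solute mass %.4g g/mL is not below the sample mass %.4g g/mL",
           c_g, sample$density)
  }
  n_solute <- c_g / sample$solute_mw
  solvent_mass <- sample$density - c_g
  unit_mass <- sample$hba_mw + sample$molar_ratio * sample$hbd_mw
  units <- solvent_mass / unit_mass
  n_hba <- units
  n_hbd <- sample$molar_ratio * units
  n_solute / (n_solute + n_hba + n_hbd)
}
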