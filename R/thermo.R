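# Ideal solubility from fusion thermodynamics.
#
# At solid-liquid equilibrium the activity of the dissolved solute equals
# the activity of the pure subcooled liquid, which follows from the fusion
# properties of the solid: ln a_s = -dGfus/(R T). With a constant heat
# capacity change on melting the standard Hildebrand-Prausnitz form is
#   ln a_s = (dHfus/R)(1/Tm - 1/T) - (dCp/R)(T - Tm)/T + (dCp/R) ln(T/Tm)
# and with the approximation dCp ~ dSfus = dHfus/Tm it collapses to
#   ln a_s = (dHfus/(R Tm)) ln(T/Tm).

#' Gas constant, J/(mol K)
#' @export
R_GAS <- 8.31446

#' Fusion data for a solute
#'
#' @param compound_id character identifier.
#' @param Tm melting temperature, K (> 0).
#' @param dHfus heat of fusion, J/mol (> 0).
#' @return object of class `fusion_data` with derived entropy of fusion
#'   `dSfus = dHfus / Tm` (J/(mol K)).
#' @export
fusion_data <- function(compound_id, Tm, dHfus) {
  assert_that(is.character(compound_id) && length(compound_id) == 1L,
              "compound_id must be a string")
  assert_that(is_scalar_number(Tm) && Tm > 0, "Tm must be a positive number (kelvin)")
  assert_that(is_scalar_number(dHfus) && dHfus > 0, "dHfus must be a positive number (J/mol)")
  structure(list(compound_id = compound_id, Tm = Tm, dHfus = dHfus,
                 dSfus = dHfus / Tm),
            class = "fusion_data")
}

#' @export
print.fusion_data <- function(x, ...) {
  cat(sprintf("<fusion_data> %s: Tm = %.2f K, dHfus = %.1f J/mol, dSfus = %.3f J/(mol K)\n",
              x$compound_id, x$Tm, x$dHfus, x$dSfus))
  invisible(x)
}

#' Heat-capacity change on melting, approximated from fusion data
#'
#' The approximation dCp ~ dSfus = dHfus / Tm, used when measured heat
#' capacity data are unavailable (the usual case for drug-like solids).
#'
#' @param f a [fusion_data()] object.
#' @return dCp in J/(mol K).
#' @export
heat_capacity_approx <- function(f) {
  assert_that(inherits(f, "fusion_data"), "f must be a fusion_data object")
  f$dHfus / f$Tm
}

check_T <- function(f, T) {
  assert_that(is_scalar_number(T) && T > 0, "T must be a positive temperature (kelvin)")
  if (T > f$Tm + 1e-9) {
    stop_f("T = %.3f K exceeds the melting point %.3f K: no solid phase", T, f$Tm)
  }
  invisible(TRUE)
}

#' Ideal log-activity of the solid solute at saturation
#'
#' Natural logarithm of the ideal mole-fraction solubility, from the
#' constant-dCp solid-liquid equilibrium expression. By default dCp is the
#' [heat_capacity_approx()] value, under which the expression collapses to
#' `(dHfus / (R * Tm)) * log(T / Tm)`; pass `dCp` explicitly to override
#' (e.g. `dCp = 0` gives the van't Hoff term).
#'
#' @param f a [fusion_data()] object.
#' @param T temperature, K, with `0 < T <= Tm`.
#' @param dCp optional explicit heat-capacity change, J/(mol K).
#' @return ln a_s (dimensionless, <= 0).
#' @export
ideal_log_activity <- function(f, T, dCp = NULL) {
  assert_that(inherits(f, "fusion_data"), "f must be a fusion_data object")
  check_T(f, T)
  if (is.null(dCp)) dCp <- heat_capacity_approx(f)
  assert_that(is_scalar_number(dCp), "dCp must be a single finite number")
  (f$dHfus / R_GAS) * (1 / f$Tm - 1 / T) -
    (dCp / R_GAS) * ((T - f$Tm) / T) +
    (dCp / R_GAS) * log(T / f$Tm)
}

#' Gibbs energy of fusion at temperature T
#'
#' `dGfus = -R * T * ideal_log_activity(f, T, dCp)`; non-negative for
#' `T <= Tm` and zero at the melting point.
#'
#' @inheritParams ideal_log_activity
#' @return dGfus in J/mol.
#' @export
gibbs_fusion <- function(f, T, dCp = NULL) {
  -R_GAS * T * ideal_log_activity(f, T, dCp)
}

#' Read / write fusion data tables
#'
#' CSV with columns `compound_id,Tm_K,dHfus_J_per_mol`. `write_fusion_table`
#' optionally appends a `dGfus_J_per_mol` column evaluated at a reference
#' temperature for reproducibility of downstream solubility computations.
#'
#' @param path CSV path.
#' @return `read_fusion_table` returns a named list of `fusion_data`.
#' @export
read_fusion_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "Tm_K", "dHfus_J_per_mol")
  assert_that(all(need %in% names(df)), "fusion CSV must have columns %s",
              paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    fusion_data(df$compound_id[i], df$Tm_K[i], df$dHfus_J_per_mol[i])
  })
  names(out) <- df$compound_id
  out
}

#' @rdname read_fusion_table
#' @param fusions named list of `fusion_data` objects.
#' @param T_ref optional reference temperature (K) at which to export dGfus.
#' @export
write_fusion_table <- function(fusions, path, T_ref = NULL) {
  df <- data.frame(
    compound_id = vapply(fusions, `[[`, "", "compound_id"),
    Tm_K = vapply(fusions, `[[`, 0, "Tm"),
    dHfus_J_per_mol = vapply(fusions, `[[`, 0, "dHfus")
  )
  if (!is.null(T_ref)) {
    df$dGfus_J_per_mol <- vapply(fusions, gibbs_fusion, 0, T = T_ref)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
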