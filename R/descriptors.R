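# Descriptor assembly: six descriptor-set definitions built from relative
# sigma-potentials, relative interaction energies and (optionally) a
# computed-solubility feature.
#
#   A1 =  6-bin step-averaged relative potential + 5 energies + 1 solubility (12)
#   A2 =  A1 without the solubility feature                                  (11)
#   B1 = 12-bin step-averaged relative potential + 5 energies + 1 solubility (18)
#   B2 =  B1 without the solubility feature                                  (17)
#   C1 = full 61-point relative potential + 1 solubility                     (62)
#   C2 =  C1 without the solubility feature                                  (61)

DESCRIPTOR_SETS <- c(A1 = 12L, A2 = 11L, B1 = 18L, B2 = 17L, C1 = 62L, C2 = 61L)
ENERGY_NAMES <- c("d_mu_mix", "dE_tot", "dE_HB", "dE_misfit", "dE_vdW")

#' Descriptor-set cardinalities
#'
#' @return named integer vector of expected feature-vector lengths for the
#'   six descriptor sets.
#' @export
descriptor_set_lengths <- function() DESCRIPTOR_SETS

#' Relative interaction energies
#'
#' The five solute-minus-weighted-solvent energy terms: mixture chemical
#' potential, total energy, hydrogen bonding, electrostatic misfit and van
#' der Waals contributions (consistent arbitrary units).
#'
#' @param d_mu_mix,dE_tot,dE_HB,dE_misfit,dE_vdW finite numbers.
#' @return object of class `interaction_energies` (named numeric of 5).
#' @export
interaction_energies <- function(d_mu_mix, dE_tot, dE_HB, dE_misfit, dE_vdW) {
  v <- c(d_mu_mix = d_mu_mix, dE_tot = dE_tot, dE_HB = dE_HB,
         dE_misfit = dE_misfit, dE_vdW = dE_vdW)
  assert_that(length(v) == 5L && is.numeric(v) && all(is.finite(v)),
              "interaction energies must be 5 finite numbers")
  structure(v, class = "interaction_energies")
}

#' Relative (solute-minus-weighted-solvent) value of a scalar property
#'
#' The same mole-fraction weighting used for the relative sigma potential,
#' applied to any per-component scalar: `api_value - sum(x_star * value_i)`.
#'
#' @param api_value scalar property of the solute.
#' @param component_values one value per solvent component.
#' @param comp a [solvent_composition()].
#' @return the relative value.
#' @export
relative_energy <- function(api_value, component_values, comp) {
  assert_that(inherits(comp, "solvent_composition"), "comp must be a solvent_composition")
  assert_that(is_scalar_number(api_value), "api_value must be a single finite number")
  component_values <- as.numeric(component_values)
  if (length(component_values) != length(comp$component_ids)) {
    stop_f("need one value per component: got %d values for %d components",
           length(component_values), length(comp$component_ids))
  }
  api_value - sum(comp$x_star * component_values)
}

#' Assemble a feature vector for one record
#'
#' @param set_id one of `"A1","A2","B1","B2","C1","C2"`.
#' @param delta_profile relative sigma potential of the record, a
#'   `sigma_profile` (see [relative_sigma_potential()]).
#' @param energies an [interaction_energies()] object; required for the A
#'   and B sets, ignored by the C sets.
#' @param cosmors_log_solubility computed log10 mole-fraction solubility;
#'   required for the `*1` sets.
#' @param record_ref optional identifier carried along with the vector.
#' @return object of class `feature_vector` with fields `set_id`, `values`
#'   (named numeric of the set's expected length) and `record_ref`.
#' @export
build_features <- function(set_id, delta_profile, energies = NULL,
                           cosmors_log_solubility = NULL, record_ref = NA_character_) {
  assert_that(set_id %in% names(DESCRIPTOR_SETS),
              "unknown descriptor set '%s' (use one of %s)",
              set_id, paste(names(DESCRIPTOR_SETS), collapse = ", "))
  assert_that(inherits(delta_profile, "sigma_profile"),
              "delta_profile must be a sigma_profile")
  family <- substr(set_id, 1, 1)
  with_sol <- substr(set_id, 2, 2) == "1"
  if (family %in% c("A", "B") && is.null(energies)) {
    stop_f("descriptor set %s requires the 5 relative interaction energies", set_id)
  }
  if (with_sol && is.null(cosmors_log_solubility)) {
    stop_f("descriptor set %s requires the computed-solubility feature", set_id)
  }
  sig <- switch(family,
    A = stats::setNames(step_average(delta_profile, 6L), sprintf("dsig_%02d", 1:6)),
    B = stats::setNames(step_average(delta_profile, 12L), sprintf("dsig_%02d", 1:12)),
    C = stats::setNames(delta_profile$potential, sprintf("dsig_%02d", 1:61))
  )
  vals <- sig
  if (family %in% c("A", "B")) {
    assert_that(inherits(energies, "interaction_energies"),
                "energies must be an interaction_energies object")
    vals <- c(vals, unclass(energies))
  }
  if (with_sol) {
    assert_that(is_scalar_number(cosmors_log_solubility),
                "cosmors_log_solubility must be a single finite number")
    vals <- c(vals, cosmors_log10x = cosmors_log_solubility)
  }
  stopifnot(length(vals) == DESCRIPTOR_SETS[[set_id]])
  structure(list(set_id = set_id, values = vals, record_ref = record_ref),
            class = "feature_vector")
}

# ---------------------------------------------------------------------------
# Profile store: per-compound sigma potentials tabulated over temperature,
# with per-grid-point linear interpolation when an exact temperature is
# missing (profiles vary smoothly with T).

#' Create a sigma-profile store
#'
#' A container mapping compound id to its sigma potentials tabulated at one
#' or more temperatures. [get_profile()] returns the profile at a requested
#' temperature, linearly interpolating per grid point between the two
#' nearest tabulated temperatures when no exact match exists (a message
#' flags the interpolation); extrapolation outside the tabulated range is
#' an error.
#'
#' @param profiles optional list of [sigma_profile()]s to add.
#' @return object of class `profile_store`.
#' @export
profile_store <- function(profiles = list()) {
  store <- structure(list(env = new.env(parent = emptyenv())), class = "profile_store")
  for (p in profiles) add_profile(store, p)
  store
}

#' @rdname profile_store
#' @param store a `profile_store`.
#' @param profile a `sigma_profile` to add (replaces an existing entry at
#'   the same compound and temperature).
#' @export
add_profile <- function(store, profile) {
  assert_that(inherits(store, "profile_store"), "store must be a profile_store")
  assert_that(inherits(profile, "sigma_profile"), "profile must be a sigma_profile")
  id <- profile$compound_id
  entry <- if (exists(id, envir = store$env)) get(id, envir = store$env) else
    list(temps = numeric(0), pots = matrix(numeric(0), 0, N_GRID))
  hit <- which(abs(entry$temps - profile$temperature) < 1e-6)
  if (length(hit) == 1L) {
    entry$pots[hit, ] <- profile$potential
  } else {
    entry$temps <- c(entry$temps, profile$temperature)
    entry$pots <- rbind(entry$pots, profile$potential)
    o <- order(entry$temps)
    entry$temps <- entry$temps[o]
    entry$pots <- entry$pots[o, , drop = FALSE]
  }
  assign(id, entry, envir = store$env)
  invisible(store)
}

#' @rdname profile_store
#' @param compound_id compound to look up.
#' @param temperature requested temperature, K.
#' @export
get_profile <- function(store, compound_id, temperature) {
  assert_that(inherits(store, "profile_store"), "store must be a profile_store")
  if (!exists(compound_id, envir = store$env)) {
    stop_f("no sigma profiles stored for compound '%s'", compound_id)
  }
  entry <- get(compound_id, envir = store$env)
  hit <- which(abs(entry$temps - temperature) < 1e-6)
  if (length(hit) >= 1L) {
    return(sigma_profile(compound_id, temperature, entry$pots[hit[1], ]))
  }
  if (temperature < min(entry$temps) - 1e-6 || temperature > max(entry$temps) + 1e-6) {
    stop_f("no profile for '%s' at %.2f K (tabulated: %s); refusing to extrapolate",
           compound_id, temperature,
           paste(sprintf("%.2f", entry$temps), collapse = ", "))
  }
  hi <- which(entry$temps > temperature)[1]
  lo <- hi - 1L
  w <- (temperature - entry$temps[lo]) / (entry$temps[hi] - entry$temps[lo])
  message(sprintf("interpolating sigma potential of '%s' at %.2f K between %.2f and %.2f K",
                  compound_id, temperature, entry$temps[lo], entry$temps[hi]))
  sigma_profile(compound_id, temperature,
                (1 - w) * entry$pots[lo, ] + w * entry$pots[hi, ])
}

#' @export
print.profile_store <- function(x, ...) {
  ids <- ls(x$env)
  cat(sprintf("<profile_store> %d compound(s)\n", length(ids)))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Featurize a solubility dataset
#'
#' Builds one feature row per record under a descriptor-set definition:
#' the relative sigma potential is computed from the stored solute and
#' component profiles at the record temperature, coarse-grained per the
#' set, and concatenated with the per-record energies / computed
#' solubility where the set requires them. Row order equals input order;
#' targets are the records' `log10_x`.
#'
#' @param records list of [solubility_record()]s.
#' @param store a [profile_store()] covering every solute and solvent
#'   component at every record temperature.
#' @param set_id descriptor set id.
#' @param energies matrix or data frame with one row per record and the 5
#'   energy columns (`d_mu_mix, dE_tot, dE_HB, dE_misfit, dE_vdW`);
#'   required for A and B sets.
#' @param cosmors numeric vector of computed log10 solubilities, one per
#'   record; required for `*1` sets.
#' @return list with `X` (numeric matrix, columns `f_000...`), `y`
#'   (targets), `set_id` and `feature_names` (the descriptive names).
#' @export
featurize_dataset <- function(records, store, set_id, energies = NULL, cosmors = NULL) {
  assert_that(set_id %in% names(DESCRIPTOR_SETS), "unknown descriptor set '%s'", set_id)
  p <- DESCRIPTOR_SETS[[set_id]]
  n <- length(records)
  if (!is.null(energies)) {
    energies <- as.matrix(as.data.frame(energies)[, ENERGY_NAMES, drop = FALSE])
    assert_that(nrow(energies) == n, "energies must have one row per record (%d != %d)",
                nrow(energies), n)
  }
  if (!is.null(cosmors)) {
    assert_that(length(cosmors) == n, "cosmors must have one value per record")
  }
  X <- matrix(NA_real_, n, p)
  feature_names <- NULL
  for (i in seq_len(n)) {
    r <- records[[i]]
    api <- get_profile(store, r$solute_id, r$temperature)
    comps <- lapply(r$solvent$component_ids, get_profile,
                    store = store, temperature = r$temperature)
    mix <- mixture_potential(comps, r$solvent)
    dsig <- relative_sigma_potential(api, mix)
    en <- if (is.null(energies)) NULL else do.call(interaction_energies, as.list(energies[i, ]))
    fv <- build_features(set_id, dsig, energies = en,
                         cosmors_log_solubility = if (is.null(cosmors)) NULL else cosmors[i],
                         record_ref = sprintf("r%04d", i))
    X[i, ] <- fv$values
    if (is.null(feature_names)) feature_names <- names(fv$values)
  }
  if (n == 0L) {
    feature_names <- rep(NA_character_, p)
  }
  colnames(X) <- sprintf("f_%03d", seq_len(p) - 1L)
  list(X = X, y = vapply(records, `[[`, 0, "log10_x"), set_id = set_id,
       feature_names = feature_names)
}

#' Export a feature matrix to CSV with a JSON sidecar
#'
#' Writes `f_000...` columns plus a `target` column; the descriptor set id
#' and descriptive feature names go to `<path>.meta.json`.
#'
#' @param features result of [featurize_dataset()].
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features$X)
  df$target <- features$y
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(set_id = features$set_id, feature_names = features$feature_names),
    paste0(path, ".meta.json"), auto_unbox = TRUE
  )
  invisible(path)
}
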