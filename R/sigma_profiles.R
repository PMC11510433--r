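# Sigma-potential profiles on the canonical COSMO-RS charge-density grid.
#
# A sigma-potential mu(sigma) expresses the affinity of a liquid phase for
# molecular surface of screening charge density sigma (e/A^2). Profiles for
# pure components are combined with solute-free mole fractions and
# subtracted from the solute profile to give the relative potential used as
# the descriptor basis for solubility modeling.

N_GRID <- 61L
SIGMA_MIN <- -0.03
SIGMA_MAX <- 0.03
SIGMA_STEP <- 0.001

#' Canonical sigma grid
#'
#' The fixed 61-point charge-density grid, from −0.03 to +0.03 e/Å² in
#' steps of 0.001, on which every sigma-potential profile is tabulated.
#'
#' @return numeric vector of length 61, strictly increasing.
#' @export
#' @examples
#' g <- make_grid()
#' length(g)        # 61
#' range(g)         # -0.03 0.03
make_grid <- function() {
  seq(SIGMA_MIN, SIGMA_MAX, by = SIGMA_STEP)
}

#' Construct a sigma-potential profile
#'
#' @param compound_id character identifier of the compound.
#' @param temperature temperature in kelvin.
#' @param potential numeric vector of 61 finite potential values (energy per
#'   area, arbitrary-but-consistent units), one per grid point.
#' @return an object of class `sigma_profile`.
#' @export
sigma_profile <- function(compound_id, temperature, potential) {
  assert_that(is.character(compound_id) && length(compound_id) == 1L && nzchar(compound_id),
              "compound_id must be a non-empty string")
  assert_that(is_scalar_number(temperature) && temperature > 0,
              "temperature must be a single positive number (kelvin)")
  potential <- as.numeric(potential)
  if (length(potential) != N_GRID) {
    stop_f("potential must have exactly %d values, got %d", N_GRID, length(potential))
  }
  assert_that(all(is.finite(potential)), "potential values must all be finite")
  structure(
    list(compound_id = compound_id, temperature = temperature, potential = potential),
    class = "sigma_profile"
  )
}

#' @export
print.sigma_profile <- function(x, ...) {
  cat(sprintf("<sigma_profile> %s @ %.2f K, range [%.4g, %.4g]\n",
              x$compound_id, x$temperature, min(x$potential), max(x$potential)))
  invisible(x)
}

#' Solute-free solvent composition
#'
#' Composition of a solvent mixture computed ignoring the dissolved solute
#' (the x* of the relative-potential definition). One to four components;
#' fractions must sum to one.
#'
#' @param component_ids character vector of component identifiers.
#' @param x_star numeric vector of solute-free mole fractions.
#' @param roles optional character vector of component roles, each one of
#'   `"HBA"`, `"HBD"`, `"water"`, `"solvent"`. Needed for subset
#'   classification; defaults to `"solvent"` for every component.
#' @return an object of class `solvent_composition`.
#' @export
solvent_composition <- function(component_ids, x_star, roles = NULL) {
  assert_that(is.character(component_ids) && length(component_ids) >= 1L,
              "component_ids must be a character vector")
  n <- length(component_ids)
  assert_that(n >= 1L && n <= 4L, "a solvent has between 1 and 4 components, got %d", n)
  assert_that(!anyDuplicated(component_ids), "duplicate component ids")
  x_star <- as.numeric(x_star)
  assert_that(length(x_star) == n, "x_star length (%d) must match components (%d)",
              length(x_star), n)
  assert_that(all(is.finite(x_star)) && all(x_star >= 0),
              "solute-free mole fractions must be finite and non-negative")
  assert_that(abs(sum(x_star) - 1) <= 1e-9,
              "solute-free mole fractions must sum to 1 (got %.12g)", sum(x_star))
  if (is.null(roles)) roles <- rep("solvent", n)
  assert_that(length(roles) == n && all(roles %in% c("HBA", "HBD", "water", "solvent")),
              "roles must be HBA, HBD, water or solvent (one per component)")
  structure(
    list(component_ids = component_ids, x_star = x_star, roles = roles),
    class = "solvent_composition"
  )
}

#' @export
print.solvent_composition <- function(x, ...) {
  cat("<solvent_composition> ",
      paste(sprintf("%s(%s) %.4g", x$component_ids, x$roles, x$x_star), collapse = " + "),
      "\n", sep = "")
  invisible(x)
}

#' Mole-fraction weighted sigma potential of a solvent mixture
#'
#' Pointwise sum over components of x*_i · mu_i at a common temperature.
#'
#' @param profiles list of [sigma_profile()] objects covering every
#'   component of `comp` (extra profiles are ignored; matching is by
#'   `compound_id`).
#' @param comp a [solvent_composition()].
#' @return a `sigma_profile` with `compound_id` naming the mixture.
#' @export
mixture_potential <- function(profiles, comp) {
  assert_that(inherits(comp, "solvent_composition"), "comp must be a solvent_composition")
  assert_that(is.list(profiles) && all(vapply(profiles, inherits, TRUE, "sigma_profile")),
              "profiles must be a list of sigma_profile objects")
  ids <- vapply(profiles, `[[`, "", "compound_id")
  missing <- setdiff(comp$component_ids, ids)
  if (length(missing) > 0) {
    stop_f("no sigma profile for component(s): %s", paste(missing, collapse = ", "))
  }
  sel <- profiles[match(comp$component_ids, ids)]
  temps <- vapply(sel, `[[`, 0, "temperature")
  if (max(temps) - min(temps) > 1e-9) {
    stop_f("temperature mismatch among component profiles: %s",
           paste(sprintf("%.3f", temps), collapse = ", "))
  }
  pot <- rep(0, N_GRID)
  for (k in seq_along(sel)) pot <- pot + comp$x_star[k] * sel[[k]]$potential
  sigma_profile(paste(comp$component_ids, collapse = "+"), temps[1], pot)
}

#' Relative sigma potential of a solute in a solvent
#'
#' The descriptor-defining difference: solute potential minus the
#' (already mixture-weighted) solvent potential, pointwise on the grid.
#'
#' @param api solute `sigma_profile`.
#' @param solvent solvent `sigma_profile` (see [mixture_potential()]).
#' @return a `sigma_profile` of the difference, at the shared temperature.
#' @export
relative_sigma_potential <- function(api, solvent) {
  assert_that(inherits(api, "sigma_profile") && inherits(solvent, "sigma_profile"),
              "both arguments must be sigma_profile objects")
  if (abs(api$temperature - solvent$temperature) > 1e-9) {
    stop_f("temperature mismatch: solute at %.3f K, solvent at %.3f K",
           api$temperature, solvent$temperature)
  }
  sigma_profile(paste0("d(", api$compound_id, "|", solvent$compound_id, ")"),
                api$temperature, api$potential - solvent$potential)
}

#' Step-function coarse-graining of a profile
#'
#' Averages the profile over contiguous equal-width blocks of the grid,
#' left to right over sigma. The 61-point grid cannot be split evenly, so
#' the final point (sigma = +0.03) is dropped and the remaining 60 points
#' are binned (10 per bin for 6 bins, 5 per bin for 12 bins). The extreme
#' positive-sigma point carries negligible surface area for drug-like
#' molecules.
#'
#' @param profile a `sigma_profile`.
#' @param n_bins number of bins; must divide 60 (the step-function
#'   descriptor sets use 6 and 12).
#' @return numeric vector of `n_bins` block means.
#' @export
step_average <- function(profile, n_bins) {
  assert_that(inherits(profile, "sigma_profile"), "profile must be a sigma_profile")
  assert_that(is_scalar_number(n_bins) && n_bins == as.integer(n_bins) && n_bins >= 1,
              "n_bins must be a positive integer")
  n_bins <- as.integer(n_bins)
  binnable <- N_GRID - 1L
  if (binnable %% n_bins != 0L) {
    stop_f("n_bins = %d does not divide the binnable point count %d", n_bins, binnable)
  }
  v <- profile$potential[seq_len(binnable)]
  width <- binnable %/% n_bins
  colMeans(matrix(v, nrow = width, ncol = n_bins))
}

#' Hydrogen-bond region decomposition
#'
#' Mean potential over the three conventional charge-density regions:
#' hydrogen-bond acceptability for sigma in \[−0.03, −0.01\], hydrophobicity
#' for sigma in (−0.01, +0.01), and hydrogen-bond donicity for sigma in
#' \[+0.01, +0.03\]. The boundary points ±0.01 are assigned to the
#' hydrogen-bond regions so the split is mirror-symmetric and every grid
#' point belongs to exactly one region.
#'
#' @param profile a `sigma_profile` on the canonical grid.
#' @return named numeric vector `c(hba_mean=, hyd_mean=, hbd_mean=)`.
#' @export
region_decomposition <- function(profile) {
  assert_that(inherits(profile, "sigma_profile"), "profile must be a sigma_profile")
  g <- make_grid()
  hba <- g <= -0.01 + 1e-12
  hbd <- g >= 0.01 - 1e-12
  hyd <- !hba & !hbd
  c(hba_mean = mean(profile$potential[hba]),
    hyd_mean = mean(profile$potential[hyd]),
    hbd_mean = mean(profile$potential[hbd]))
}

#' Read / write sigma-potential profiles as plain text
#'
#' Format: a header line `# compound=<id> temperature_C=<float>` followed
#' by 61 whitespace-delimited lines `<sigma> <potential>`. Temperatures are
#' written in degrees Celsius on file and stored in kelvin in memory.
#'
#' @param path file path.
#' @return `read_profile` returns a `sigma_profile`; `write_profile`
#'   returns `path` invisibly.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) == 0) stop_f("missing '# compound=... temperature_C=...' header in %s", path)
  h <- hdr[1]
  cm <- regmatches(h, regexec("compound=([^ ]+)", h))[[1]]
  tm <- regmatches(h, regexec("temperature_C=([-0-9.eE+]+)", h))[[1]]
  if (length(cm) < 2) stop_f("header of %s lacks compound=<id>", path)
  if (length(tm) < 2) stop_f("header of %s lacks temperature_C=<float>", path)
  body <- lines[!grepl("^#", lines)]
  if (length(body) != N_GRID) {
    stop_f("expected %d data rows in %s, found %d", N_GRID, path, length(body))
  }
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"), as.numeric))
  if (ncol(m) != 2 || anyNA(m)) stop_f("malformed data rows in %s (need '<sigma> <potential>')", path)
  sig <- m[, 1]
  if (any(diff(sig) <= 0)) stop_f("sigma column in %s is not strictly increasing", path)
  if (max(abs(sig - make_grid())) > 1e-9) {
    stop_f("sigma column in %s does not match the canonical grid", path)
  }
  sigma_profile(cm[2], as.numeric(tm[2]) + 273.15, m[, 2])
}

#' @rdname read_profile
#' @param profile a `sigma_profile` to write.
#' @export
write_profile <- function(profile, path) {
  assert_that(inherits(profile, "sigma_profile"), "profile must be a sigma_profile")
  hdr <- sprintf("# compound=%s temperature_C=%.10g",
                 profile$compound_id, profile$temperature - 273.15)
  body <- sprintf("%.3f %.17g", make_grid(), profile$potential)
  writeLines(c(hdr, body), path)
  invisible(path)
}
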