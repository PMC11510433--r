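# Solubility dataset model: records, subset classification, I/O,
# train/test splitting, and coverage accounting.

SUBSET_LABELS <- c("neat", "binary", "dry_des", "wet_des")

#' Classify a solvent system into a dataset subset
#'
#' Rules, based on annotated component roles:
#' one component is a `neat` solvent; two generic components (either of
#' which may be water) form a `binary` mixture; exactly one hydrogen bond
#' acceptor plus one donor form a `dry_des`; an HBA and at least one HBD
#' together with water (3-4 components total) form a `wet_des`.
#'
#' @param comp a [solvent_composition()] with roles annotated.
#' @return one of `"neat"`, `"binary"`, `"dry_des"`, `"wet_des"`.
#' @export
classify_system <- function(comp) {
  assert_that(inherits(comp, "solvent_composition"), "comp must be a solvent_composition")
  r <- comp$roles
  n <- length(r)
  n_hba <- sum(r == "HBA"); n_hbd <- sum(r == "HBD")
  has_water <- any(r == "water"); n_generic <- sum(r == "solvent")
  if (n == 1L) return("neat")
  if (n == 2L && n_hba == 1L && n_hbd == 1L) return("dry_des")
  if (n == 2L && n_hba == 0L && n_hbd == 0L) return("binary")
  if (n >= 3L && has_water && n_hba >= 1L && n_hbd >= 1L && n_generic == 0L) {
    return("wet_des")
  }
  stop_f("unclassifiable solvent system: %d components with roles {%s}",
         n, paste(r, collapse = ", "))
}

#' Construct a solubility record
#'
#' One saturated-system observation: a solute dissolved in a solvent system
#' at a temperature, with the decadal logarithm of its mole-fraction
#' solubility. The subset label is derived from the composition roles via
#' [classify_system()].
#'
#' @param solute_id character identifier of the solute.
#' @param solvent a [solvent_composition()].
#' @param temperature temperature in kelvin.
#' @param log10_x decadal log of mole-fraction solubility; must be negative
#'   (a mole fraction is below one).
#' @param source_tag free-text provenance tag.
#' @return object of class `solubility_record`.
#' @export
solubility_record <- function(solute_id, solvent, temperature, log10_x,
                              source_tag = "") {
  assert_that(is.character(solute_id) && length(solute_id) == 1L && nzchar(solute_id),
              "solute_id must be a non-empty string")
  assert_that(inherits(solvent, "solvent_composition"), "solvent must be a solvent_composition")
  assert_that(is_scalar_number(temperature) && temperature > 0,
              "temperature must be positive (kelvin)")
  assert_that(is_scalar_number(log10_x), "log10_x must be a single finite number")
  if (log10_x >= 0) stop_f("log10_x must be negative (mole fraction < 1), got %g", log10_x)
  structure(
    list(solute_id = solute_id, solvent = solvent, temperature = temperature,
         log10_x = log10_x, subset_label = classify_system(solvent),
         source_tag = as.character(source_tag)),
    class = "solubility_record"
  )
}

#' @export
print.solubility_record <- function(x, ...) {
  cat(sprintf("<solubility_record> %s in %s [%s] @ %.2f K: log10(x) = %.4f\n",
              x$solute_id, paste(x$solvent$component_ids, collapse = "+"),
              x$subset_label, x$temperature, x$log10_x))
  invisible(x)
}

#' Convert records to a flat data frame (and back)
#'
#' Columns: `solute_id, component_ids, roles, x_star` (each `;`-joined),
#' `temperature_C, log10_x, source_tag`. This is the on-disk CSV schema.
#'
#' @param records list of [solubility_record()] objects.
#' @return a data frame with one row per record.
#' @export
records_to_frame <- function(records) {
  data.frame(
    solute_id = vapply(records, `[[`, "", "solute_id"),
    component_ids = vapply(records, function(r) paste(r$solvent$component_ids, collapse = ";"), ""),
    roles = vapply(records, function(r) paste(r$solvent$roles, collapse = ";"), ""),
    x_star = vapply(records, function(r) paste(sprintf("%.12g", r$solvent$x_star), collapse = ";"), ""),
    temperature_C = vapply(records, function(r) r$temperature - 273.15, 0),
    log10_x = vapply(records, `[[`, 0, "log10_x"),
    source_tag = vapply(records, `[[`, "", "source_tag"),
    stringsAsFactors = FALSE
  )
}

frame_row_to_record <- function(df, i) {
  comp <- solvent_composition(
    component_ids = strsplit(df$component_ids[i], ";", fixed = TRUE)[[1]],
    x_star = as.numeric(strsplit(df$x_star[i], ";", fixed = TRUE)[[1]]),
    roles = strsplit(df$roles[i], ";", fixed = TRUE)[[1]]
  )
  solubility_record(df$solute_id[i], comp, df$temperature_C[i] + 273.15,
                    df$log10_x[i], df$source_tag[i])
}

#' Read / write a solubility dataset CSV
#'
#' Invalid rows (non-negative `log10_x`, compositions not summing to one,
#' unknown roles, ...) are rejected with an error listing the offending row
#' numbers.
#'
#' @param path CSV path.
#' @return `read_dataset` returns a list of `solubility_record`s.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(x_star = "character"))
  need <- c("solute_id", "component_ids", "roles", "x_star",
            "temperature_C", "log10_x", "source_tag")
  assert_that(all(need %in% names(df)), "dataset CSV must have columns %s",
              paste(need, collapse = ", "))
  records <- vector("list", nrow(df))
  bad <- character(0)
  for (i in seq_len(nrow(df))) {
    records[[i]] <- tryCatch(frame_row_to_record(df, i), error = function(e) {
      bad <<- c(bad, sprintf("row %d: %s", i, conditionMessage(e)))
      NULL
    })
  }
  if (length(bad) > 0) {
    stop_f("invalid dataset rows:\n%s", paste(bad, collapse = "\n"))
  }
  records
}

#' @rdname read_dataset
#' @param records list of `solubility_record`s to write.
#' @export
write_dataset <- function(records, path) {
  utils::write.csv(records_to_frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Reproducible train/test split
#'
#' @param records list of records (or any list / vector of observations).
#' @param test_fraction fraction held out for testing, default 0.20.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return list with elements `train`, `test` (disjoint, exhaustive) and
#'   `test_idx` (the held-out indices).
#' @export
train_test_split <- function(records, test_fraction = 0.20, seed = 1L) {
  n <- length(records)
  assert_that(n >= 1L, "cannot split an empty dataset")
  assert_that(is_scalar_number(test_fraction) && test_fraction > 0 && test_fraction < 1,
              "test_fraction must be in (0, 1)")
  n_test <- max(1L, round(n * test_fraction))
  idx <- with_local_seed(seed, sample.int(n, n_test))
  idx <- sort(idx)
  list(train = records[-idx], test = records[idx], test_idx = idx)
}

#' Subset and HBA bookkeeping counts
#'
#' @param records list of `solubility_record`s.
#' @return list with `by_subset` (named counts over the four subset
#'   labels), `by_hba` (record counts per hydrogen bond acceptor id among
#'   DES records), and `total`.
#' @export
subset_counts <- function(records) {
  labels <- vapply(records, `[[`, "", "subset_label")
  by_subset <- vapply(SUBSET_LABELS, function(l) sum(labels == l), 0L)
  hba_ids <- unlist(lapply(records, function(r) {
    if (r$subset_label %in% c("dry_des", "wet_des")) {
      r$solvent$component_ids[r$solvent$roles == "HBA"]
    } else character(0)
  }))
  by_hba <- if (length(hba_ids) > 0) {
    tab <- table(hba_ids)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  list(by_subset = by_subset, by_hba = by_hba, total = length(records))
}

#' Coverage map over solute x solvent-system combinations
#'
#' @param solute_ids character vector (one axis).
#' @param system_ids character vector (other axis).
#' @param studied_pairs two-column matrix or data frame of
#'   (solute_id, system_id) combinations that have been measured.
#' @return object of class `coverage_map` holding the membership matrix.
#' @export
coverage_map <- function(solute_ids, system_ids, studied_pairs) {
  assert_that(length(solute_ids) >= 1L && length(system_ids) >= 1L,
              "coverage axes must be non-empty")
  m <- matrix(FALSE, length(solute_ids), length(system_ids),
              dimnames = list(solute_ids, system_ids))
  if (!is.null(studied_pairs) && NROW(studied_pairs) > 0) {
    studied_pairs <- as.matrix(studied_pairs)
    for (i in seq_len(nrow(studied_pairs))) {
      s <- studied_pairs[i, 1]; v <- studied_pairs[i, 2]
      assert_that(s %in% solute_ids, "unknown solute id in studied pair: %s", s)
      assert_that(v %in% system_ids, "unknown system id in studied pair: %s", v)
      m[s, v] <- TRUE
    }
  }
  structure(list(studied = m), class = "coverage_map")
}

#' Percent coverage of a coverage map
#'
#' @param map a [coverage_map()].
#' @return percentage of studied cells, in \[0, 100\].
#' @export
coverage_fraction <- function(map) {
  assert_that(inherits(map, "coverage_map"), "map must be a coverage_map")
  100 * mean(map$studied)
}
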