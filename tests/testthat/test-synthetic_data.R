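test_that("simulated profiles reflect their archetypes and pass invariants", {
  amph <- simulate_profile("amphiprotic", seed = 3)
  rd <- region_decomposition(amph)
  expect_equal(unname(rd["hba_mean"]), unname(rd["hbd_mean"]), tolerance = 1e-10)

  hyd <- simulate_profile("hydrophobic", seed = 4)
  rdh <- region_decomposition(hyd)
  expect_gt(abs(rdh["hyd_mean"]), abs(rdh["hbd_mean"]))
  expect_gt(abs(rdh["hyd_mean"]), abs(rdh["hba_mean"]))

  hbd <- simulate_profile("hbd-rich", seed = 5)
  rdd <- region_decomposition(hbd)
  expect_gt(abs(rdd["hbd_mean"]), abs(rdd["hba_mean"]))

  # determinism per seed; distinct seeds differ
  expect_identical(simulate_profile("hba-rich", seed = 7)$potential,
                   simulate_profile("hba-rich", seed = 7)$potential)
  expect_false(identical(simulate_profile("hba-rich", seed = 7)$potential,
                         simulate_profile("hba-rich", seed = 8)$potential))
  # valid sigma_profile on the canonical grid
  expect_s3_class(hbd, "sigma_profile")
  expect_length(hbd$potential, 61)
  expect_true(all(is.finite(hbd$potential)))
  expect_error(simulate_profile("metallic"), "archetype")
})

test_that("the temperature dependence of a profile is mild and linear", {
  p298 <- simulate_profile("hbd-rich", 298.15, seed = 2)
  p308 <- simulate_profile("hbd-rich", 308.15, seed = 2)
  p303 <- simulate_profile("hbd-rich", 303.15, seed = 2)
  expect_equal(p303$potential, (p298$potential + p308$potential) / 2,
               tolerance = 1e-12)
  expect_lt(max(abs(p308$potential - p298$potential)),
            0.05 * max(abs(p298$potential)))
})

test_that("simulate_dataset honors its combinatorial and sign contracts", {
  truth <- ground_truth(seed = 5)
  sim <- simulate_dataset(3, 4, temperatures = c(298.15, 313.15), truth = truth)
  expect_length(sim$records, 3 * 4 * 2)
  y <- vapply(sim$records, `[[`, 0, "log10_x")
  expect_true(all(y < 0))
  labels <- vapply(sim$records, `[[`, "", "subset_label")
  expect_true(all(labels %in% c("neat", "binary", "dry_des", "wet_des")))
  # determinism per truth seed; a different seed gives different data
  sim2 <- simulate_dataset(3, 4, temperatures = c(298.15, 313.15), truth = truth)
  expect_identical(vapply(sim2$records, `[[`, 0, "log10_x"), y)
  sim3 <- simulate_dataset(3, 4, temperatures = c(298.15, 313.15),
                           truth = ground_truth(seed = 6))
  expect_false(identical(vapply(sim3$records, `[[`, 0, "log10_x"), y))
})

test_that("zero-noise targets equal the generating model recomputed by the pipeline", {
  truth <- ground_truth(noise_sd = 0, seed = 9)
  sim <- simulate_dataset(2, 3, temperatures = c(298.15, 308.15), truth = truth)
  fe <- featurize_dataset(sim$records, sim$store, "B2", energies = sim$energies)
  # oracle recomputation: truth weights on the B2 features + temp term
  temps <- vapply(sim$records, `[[`, 0, "temperature")
  y_oracle <- truth$intercept +
    as.vector(fe$X[, 1:12] %*% truth$bin_weights) +
    as.vector(fe$X[, 13:17] %*% truth$energy_weights) +
    truth$temp_coef * (temps - 298.15)
  expect_equal(fe$y, pmin(y_oracle, -0.001), tolerance = 1e-10)
  expect_equal(sim$truth_y, y_oracle, tolerance = 1e-10)
})

test_that("generated records and profiles pass the domain invariants", {
  sim <- simulate_dataset(2, 4, temperatures = 303.15, truth = ground_truth(seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sim$records, path)     # write/read enforces every invariant
  expect_length(read_dataset(path), length(sim$records))
  p <- get_profile(sim$store, "API01", 303.15)
  expect_true(all(is.finite(p$potential)))
})

test_that("test error grows with the generator noise level", {
  med_rmsd <- function(noise) {
    vals <- vapply(1:5, function(s) {
      rec <- recovery_experiment(ground_truth(noise_sd = noise, seed = s),
                                 n_solutes = 4, n_systems = 4,
                                 regressor_names = "linear", n_trials = 1,
                                 seed = 50 + s)
      rec$test_rmsd
    }, 0)
    stats::median(vals)
  }
  expect_lt(med_rmsd(0.05), med_rmsd(0.3))
})

test_that("recovery_experiment reports a sensible linear recovery", {
  rec <- recovery_experiment(ground_truth(noise_sd = 0, temp_coef = 0, seed = 21),
                             n_solutes = 4, n_systems = 4,
                             regressor_names = "linear", n_trials = 1, seed = 3)
  expect_lt(rec$test_rmsd, 1e-6)
  expect_equal(rec$noise_floor_rmsd, 0, tolerance = 1e-12)
  expect_true(is.finite(rec$cosine_similarity))
})
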