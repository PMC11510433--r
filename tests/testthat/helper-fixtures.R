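# Shared fixture builders. Everything is generated in code; no data files.

const_profile <- function(value, temperature = 298.15, id = "const") {
  sigma_profile(id, temperature, rep(value, 61))
}

random_profile <- function(seed, temperature = 298.15, id = paste0("rp", seed)) {
  sigma_profile(id, temperature,
                dessol:::with_local_seed(seed, stats::rnorm(61)))
}

# A small all-subset record collection with known composition counts.
make_mixed_records <- function() {
  neat <- solvent_composition("water", 1, "water")
  bin <- solvent_composition(c("MeOH", "EtOH"), c(0.4, 0.6), c("solvent", "solvent"))
  dry1 <- solvent_composition(c("ChCl", "TEG"), c(1 / 3, 2 / 3), c("HBA", "HBD"))
  dry2 <- solvent_composition(c("BI", "TEG"), c(1 / 3, 2 / 3), c("HBA", "HBD"))
  wet <- solvent_composition(c("ChCl", "TEG", "water"), c(0.3, 0.6, 0.1),
                             c("HBA", "HBD", "water"))
  list(
    solubility_record("API1", neat, 298.15, -2.0, "a"),
    solubility_record("API1", bin, 298.15, -1.5, "b"),
    solubility_record("API1", dry1, 298.15, -1.2, "c"),
    solubility_record("API2", dry1, 303.15, -2.2, "c"),
    solubility_record("API2", dry2, 298.15, -2.4, "c"),
    solubility_record("API2", wet, 298.15, -1.9, "d")
  )
}

# Linear toy regression data: y = Xb + intercept (optionally + noise).
make_linear_toy <- function(n = 40, p = 3, noise_sd = 0, seed = 1) {
  dessol:::with_local_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    b <- seq_len(p) / p
    y <- -2 + as.vector(X %*% b) + stats::rnorm(n, 0, noise_sd)
    list(X = X, y = y, b = b)
  })
}

# A deterministic fake regressor that always predicts a constant value;
# used to probe the loss penalties in isolation.
constant_regressor <- function(value) {
  dessol:::make_regressor(
    "constant",
    function(X, y, params, seed) {
      list(predict_fun = function(Xnew) rep(value, nrow(Xnew)))
    },
    space = list(),
    default_params = list()
  )
}
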