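test_that("canonical grid has 61 points from -0.03 to +0.03 in steps of 0.001", {
  g <- make_grid()
  expect_length(g, 61)
  expect_equal(g[1], -0.030, tolerance = 1e-12)
  expect_equal(g[61], 0.030, tolerance = 1e-12)
  expect_equal(g[31], 0.000, tolerance = 1e-12)
  expect_true(all(abs(diff(g) - 0.001) < 1e-12))
  expect_true(all(diff(g) > 0))
})

test_that("sigma_profile validates length and finiteness", {
  expect_s3_class(const_profile(1), "sigma_profile")
  expect_error(sigma_profile("x", 298.15, rep(1, 60)), "61")
  expect_error(sigma_profile("x", 298.15, c(rep(1, 60), NA)), "finite")
})

test_that("mixture_potential is the x*-weighted pointwise sum", {
  p1 <- const_profile(1, id = "a")
  # single component, x* = 1 -> identity
  one <- mixture_potential(list(p1), solvent_composition("a", 1))
  expect_equal(one$potential, p1$potential)
  # equal profiles under any weights -> same profile (convexity)
  p2 <- sigma_profile("b", 298.15, p1$potential)
  mixed <- mixture_potential(list(p1, p2),
                             solvent_composition(c("a", "b"), c(0.3, 0.7)))
  expect_equal(mixed$potential, p1$potential)
  # weighted mean of constants
  m <- mixture_potential(list(const_profile(1, id = "a"), const_profile(3, id = "b")),
                         solvent_composition(c("a", "b"), c(0.25, 0.75)))
  expect_equal(m$potential, rep(2.5, 61))
  expect_equal(m$temperature, 298.15)
})

test_that("mixture_potential errors name the missing component and flag T mismatch", {
  p1 <- const_profile(1, id = "a")
  expect_error(mixture_potential(list(p1), solvent_composition(c("a", "zzz"), c(0.5, 0.5))),
               "zzz")
  p2 <- const_profile(1, temperature = 310, id = "b")
  expect_error(mixture_potential(list(p1, p2),
                                 solvent_composition(c("a", "b"), c(0.5, 0.5))),
               "[Tt]emperature")
})

test_that("relative_sigma_potential is an antisymmetric pointwise difference", {
  a <- random_profile(1, id = "a")
  expect_equal(relative_sigma_potential(a, a)$potential, rep(0, 61))
  d <- relative_sigma_potential(const_profile(2, id = "a"), const_profile(2.5, id = "b"))
  expect_equal(d$potential, rep(-0.5, 61))
  b <- random_profile(2, id = "b")
  ab <- relative_sigma_potential(a, b)$potential
  ba <- relative_sigma_potential(b, a)$potential
  expect_equal(ab + ba, rep(0, 61))
  a310 <- sigma_profile("a", 310, a$potential)
  expect_error(relative_sigma_potential(a310, b), "[Tt]emperature")
})

test_that("step_average bins 60 points into equal blocks, left to right", {
  expect_equal(step_average(const_profile(4.2), 6), rep(4.2, 6))
  expect_equal(step_average(const_profile(4.2), 12), rep(4.2, 12))
  expect_length(step_average(random_profile(3), 12), 12)
  # potential equal to sigma itself: bin means equal brute-force block means
  sig <- make_grid()
  p <- sigma_profile("sig", 298.15, sig)
  got <- step_average(p, 6)
  oracle <- vapply(seq_len(6), function(b) mean(sig[((b - 1) * 10 + 1):(b * 10)]), 0)
  expect_equal(got, oracle, tolerance = 1e-14)
  expect_error(step_average(p, 7), "divide")
  expect_error(step_average(p, 0), "positive")
})

test_that("region decomposition splits the grid symmetrically", {
  expect_equal(unname(region_decomposition(const_profile(2))), c(2, 2, 2))
  # support confined to (+0.01, +0.03]
  g <- make_grid()
  pot <- ifelse(g > 0.01, 1.5, 0)
  rd <- region_decomposition(sigma_profile("x", 298.15, pot))
  expect_equal(unname(rd["hba_mean"]), 0)
  expect_equal(unname(rd["hyd_mean"]), 0)
  expect_gt(rd["hbd_mean"], 0)
  # even profile -> equal hydrogen-bond region means
  even <- sigma_profile("e", 298.15, cos(g * 200))
  rde <- region_decomposition(even)
  expect_equal(unname(rde["hba_mean"]), unname(rde["hbd_mean"]), tolerance = 1e-12)
})

test_that("profile text round trip is exact and malformed files are rejected", {
  p <- random_profile(7, temperature = 303.15, id = "cmp1")
  path <- withr::local_tempfile(fileext = ".txt")
  write_profile(p, path)
  q <- read_profile(path)
  expect_equal(q$compound_id, "cmp1")
  expect_equal(q$temperature, 303.15, tolerance = 1e-9)
  expect_equal(q$potential, p$potential, tolerance = 1e-12)

  lines <- readLines(path)
  writeLines(lines[1:60], path)  # header + 59 rows
  expect_error(read_profile(path), "61")

  writeLines(c(lines[1], lines[c(3, 2, 4:62)]), path)  # shuffled sigma
  expect_error(read_profile(path), "increasing")

  writeLines(lines[-1], path)  # no header
  expect_error(read_profile(path), "header")
})

test_that("relative potential is linear in each component profile", {
  for (s in 1:5) {
    api <- random_profile(s * 10, id = "api")
    p1 <- random_profile(s * 10 + 1, id = "c1")
    p2 <- random_profile(s * 10 + 2, id = "c2")
    comp <- solvent_composition(c("c1", "c2"), c(0.4, 0.6))
    base <- relative_sigma_potential(api, mixture_potential(list(p1, p2), comp))
    # scaling component 1 by k changes the result by -x1 * (k - 1) * p1
    k <- 1.7
    p1k <- sigma_profile("c1", 298.15, k * p1$potential)
    scaled <- relative_sigma_potential(api, mixture_potential(list(p1k, p2), comp))
    expect_equal(scaled$potential,
                 base$potential - 0.4 * (k - 1) * p1$potential,
                 tolerance = 1e-10)
  }
})

test_that("step_average commutes with addition and scalar multiplication", {
  a <- random_profile(21)
  b <- random_profile(22)
  s <- sigma_profile("sum", 298.15, 2 * a$potential + b$potential)
  for (nb in c(6, 12)) {
    expect_equal(step_average(s, nb),
                 2 * step_average(a, nb) + step_average(b, nb),
                 tolerance = 1e-12)
  }
})

test_that("mixture_potential is invariant to component permutation", {
  p1 <- random_profile(31, id = "a"); p2 <- random_profile(32, id = "b")
  m1 <- mixture_potential(list(p1, p2), solvent_composition(c("a", "b"), c(0.3, 0.7)))
  m2 <- mixture_potential(list(p2, p1), solvent_composition(c("b", "a"), c(0.7, 0.3)))
  expect_equal(m1$potential, m2$potential, tolerance = 1e-14)
})

test_that("all resolutions of a constant profile carry the same constant", {
  p <- const_profile(-1.25)
  expect_equal(unique(p$potential), -1.25)
  expect_equal(unique(step_average(p, 12)), -1.25)
  expect_equal(unique(step_average(p, 6)), -1.25)
})
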