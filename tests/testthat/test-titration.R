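test_that("equilibrium absorbance honours limits and the mass-action root", {
  # no association, no signal
  expect_equal(equilibrium_absorbance(0, 2e-5, 4e-5, 1e4), 0)
  # saturation limit: all metal bound
  expect_equal(
    equilibrium_absorbance(1e12, 0.36e-4, 1.25e-4, 1e4),
    0.36, tolerance = 1e-3)
  # x = 1e-5 satisfies Kf = 1e-5 / ((1e-5)(2e-5)^2) = 2.5e9, so A = 0.1
  expect_equal(equilibrium_absorbance(2.5e9, 2e-5, 4e-5, 1e4), 0.1,
               tolerance = 1e-9)
  # bisection oracle: independently invert the same root
  root <- uniroot(function(x) 2.5e9 * (2e-5 - x) * (4e-5 - 2 * x)^2 - x,
                  c(0, 2e-5 * (1 - 1e-12)), tol = 1e-18)$root
  expect_equal(equilibrium_absorbance(2.5e9, 2e-5, 4e-5, 1e4) / 1e4, root,
               tolerance = 1e-10)
})

test_that("equilibrium absorbance is strictly increasing in Kf and C_L", {
  kfs <- 10^seq(2, 10, length.out = 9)
  a_kf <- vapply(kfs, equilibrium_absorbance, numeric(1),
                 metal_conc = 2e-5, ligand_conc = 4e-5, epsilon = 1e4)
  expect_true(all(diff(a_kf) > 0))
  cls <- seq(1e-5, 1e-4, length.out = 9)
  a_cl <- equilibrium_absorbance(1e6, 2e-5, cls, 1e4)
  expect_true(all(diff(a_cl) > 0))
})

test_that("pointwise Kf inverts the printed mass-action expression", {
  d <- tibble::tibble(metal_conc_M = 2e-5, ligand_conc_M = 4e-5,
                      absorbance = 0.1)
  d <- dplyr::bind_rows(d, d, d)  # minimum series length
  fit <- stability_constant(d, epsilon = 1e4)
  expect_equal(fit$points$kf_point, rep(2.5e9, 3), tolerance = 1e-9)
  expect_equal(fit$points$complex_conc_M, rep(1e-5, 3))
})

test_that("stability constant round-trips the forward model", {
  # the study grid, noise-free
  ser <- gen_metal_titration(kf = 1.47e5, noise_sigma = 0)
  fit <- stability_constant(ser, epsilon = 1e4)
  expect_equal(fit$kf, 1.47e5, tolerance = 1e-3)
  expect_equal(fit$kf_pointwise_mean, 1.47e5, tolerance = 1e-3)
  # property: recovery to <= 0.1% across eight decades of Kf
  for (kf in 10^seq(3, 8, length.out = 11)) {
    s <- gen_metal_titration(kf = kf, noise_sigma = 0)
    g <- stability_constant(s, epsilon = 1e4)
    expect_lt(abs(g$kf - kf) / kf, 1e-3)
    expect_lt(abs(g$kf_pointwise_mean - kf) / kf, 1e-3)
  }
})

test_that("unphysical and boundary absorbances are handled", {
  d <- tibble::tibble(metal_conc_M = 2e-5, ligand_conc_M = c(4e-5, 4e-5, 4e-5),
                      absorbance = c(0.1, 0.1, 0.5))  # 0.5/1e4 > C_M
  expect_error(stability_constant(d, epsilon = 1e4),
               class = "coordkit_unphysical_absorbance")
  d$absorbance <- c(0, 0.05, 0.1)
  fit <- stability_constant(d, epsilon = 1e4)
  expect_true(fit$points$boundary[1])
  expect_equal(fit$points$kf_point[1], 0)
})

test_that("epsilon is estimated from the saturation plateau when absent", {
  ser <- gen_metal_titration(kf = 1e9, metal_conc = 2e-5,
                             ligand_range = c(1e-5, 4e-4), n_points = 12,
                             noise_sigma = 0)
  fit <- stability_constant(ser)
  expect_equal(fit$epsilon_source, "estimated")
  # at Kf = 1e9 and 20-fold ligand excess the plateau is essentially eps*b*C_M
  expect_equal(fit$epsilon, 1e4, tolerance = 0.02)
})

test_that("molar-ratio breakpoint finds exact and shifted intersections", {
  b <- molar_ratio_breakpoint(make_breakpoint_series(1 / 3))
  expect_equal(b$ratio, 1 / 3, tolerance = 1e-9)
  expect_equal(b$stoichiometry, "1:2")

  b2 <- molar_ratio_breakpoint(make_breakpoint_series(0.5))
  expect_equal(b2$ratio, 0.5, tolerance = 1e-9)
  expect_equal(b2$stoichiometry, "1:1")
})

test_that("breakpoint recovery is robust to noise (Monte-Carlo)", {
  ratios <- vapply(1:200, function(s) {
    d <- make_breakpoint_series(1 / 3, noise_sigma = 0.005, seed = s)
    molar_ratio_breakpoint(d)$ratio
  }, numeric(1))
  expect_lt(abs(median(ratios) - 1 / 3), 0.02)
})

test_that("a single straight line is a degenerate molar-ratio series", {
  d <- tibble::tibble(mole_fraction = seq(0.1, 0.9, by = 0.1))
  d$absorbance <- 0.2 + 0.5 * d$mole_fraction
  expect_error(molar_ratio_breakpoint(d),
               class = "coordkit_degenerate_series")
})

test_that("Beer's law conversion is the plain quotient", {
  expect_equal(beer_lambert_concentration(0, 6600), 0)
  expect_equal(beer_lambert_concentration(0.7986, 6600), 1.21e-4,
               tolerance = 1e-3)
  expect_equal(beer_lambert_concentration(6600, 6600), 1)
})
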