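test_that("wavelength to wavenumber conversion matches band tables", {
  expect_equal(to_wavenumber(1000), 10000)
  expect_equal(to_wavenumber(685), 14599)
  expect_equal(to_wavenumber(589), 16978)
  expect_error(to_wavenumber(0))
})

test_that("cobalt closed forms reproduce the worked d7 case", {
  r <- cobalt_ligand_field(v2 = 14600, v3 = 16977)
  # tabulated value 7770; the printed closed form gives 7782 (0.2% apart)
  expect_equal(r$ten_Dq, 7782.5, tolerance = 1e-3)
  # printed B formula on the printed bands gives ~742, not the tabulated 708
  expect_equal(r$B, 741.6, tolerance = 1e-3)
  expect_equal(nephelauxetic_ratio(708, 971), 0.729, tolerance = 1e-3)
  # negative radicand: |V3 - 2 V2| too large for any octahedral assignment
  expect_error(cobalt_ligand_field(v2 = 3000, v3 = 1000),
               class = "coordkit_inconsistent_bands")
})

test_that("cobalt Dq is homogeneous of degree one in the band energies", {
  base <- cobalt_ligand_field(14600, 16977)
  for (k in c(0.5, 2, 3.7)) {
    scaled <- cobalt_ligand_field(14600 * k, 16977 * k)
    expect_equal(scaled$Dq, base$Dq * k, tolerance = 1e-12)
  }
})

test_that("nickel B relation is exact with a supplied splitting", {
  r <- nickel_ligand_field(v2 = 12900, v3 = 14700, ten_dq = 5400)
  expect_identical(r$B, 760)
  expect_equal(r$beta, 0.738, tolerance = 1e-3)
  # the printed d8 Dq closed form fails on these bands (negative radicand)
  expect_error(nickel_ligand_field(v2 = 12900, v3 = 14700),
               class = "coordkit_inconsistent_bands")
  expect_error(nickel_ligand_field(v2 = 12900, v3 = 14700),
               regexp = "radicand")
})

test_that("band generator round-trips B and scales homogeneously", {
  b <- gen_bandset(dq = 540, b = 760)
  r <- nickel_ligand_field(b$v2, b$v3, ten_dq = 5400)
  expect_equal(r$B, 760, tolerance = 1e-12)
  # property over a parameter grid
  for (dq in c(400, 700, 1100)) for (bb in c(600, 800, 1000)) {
    bs <- gen_bandset(dq = dq, b = bb)
    expect_equal((bs$v2 + bs$v3 - 30 * dq) / 15, bb, tolerance = 1e-12)
  }
  # homogeneity: scaling (Dq, B) scales both bands
  b1 <- gen_bandset(dq = 540, b = 760)
  b2 <- gen_bandset(dq = 1080, b = 1520)
  expect_equal(c(b2$v2, b2$v3), 2 * c(b1$v2, b1$v3), tolerance = 1e-12)
  expect_error(gen_bandset(dq = 540, b = 0))
  expect_error(gen_bandset(config = "d7_Co", dq = 540, b = 760))
})

test_that("average g-factor lies between its inputs and classifies covalency", {
  r <- g_average(2.044, 2.189)
  expect_equal(round(r$g_av, 2), 2.14)
  expect_equal(r$covalency, "covalent")
  expect_equal(g_average(2.0, 2.0)$g_av, 2.0)
  r2 <- g_average(2.6, 2.4)
  expect_equal(r2$g_av, 2.467, tolerance = 1e-3)
  expect_equal(r2$covalency, "ionic")
  # betweenness property
  for (gp in c(1.9, 2.1, 2.5)) for (gq in c(2.0, 2.3)) {
    gav <- g_average(gp, gq)$g_av
    expect_gte(gav, min(gp, gq))
    expect_lte(gav, max(gp, gq))
  }
})

test_that("spin-only moments and beta monotonicity behave", {
  expect_equal(spin_only_moment(0), 0)
  expect_equal(spin_only_moment(1), sqrt(3), tolerance = 1e-9)
  expect_equal(spin_only_moment(2), sqrt(8), tolerance = 1e-9)
  expect_error(spin_only_moment(-1))
  expect_error(spin_only_moment(1.5))
  bs <- seq(500, 1000, by = 100)
  expect_true(all(diff(nephelauxetic_ratio(bs, 1030)) > 0))
})
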