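test_that("parse_formula expands groups, hydrates and multipliers", {
  f <- parse_formula("H2O")
  expect_equal(f$composition, c(H = 2, O = 1)[names(f$composition)])
  expect_equal(f$hydrate_waters, 0L)

  # hand-expanded composition of the Cu complex
  f <- parse_formula(cu_complex)
  expect_equal(
    f$composition[c("Cu", "C", "H", "Cl", "N", "O", "S")],
    c(Cu = 1, C = 20, H = 18, Cl = 4, N = 8, O = 4, S = 2)
  )
  expect_equal(f$hydrate_waters, 0L)

  fh <- parse_formula(cu_complex_hydrate)
  expect_equal(fh$composition, f$composition)
  expect_equal(fh$hydrate_waters, 2L)
  # middle-dot hydrate separator is equivalent
  expect_equal(parse_formula("CuC20H18Cl4N8O4S2·2H2O")$hydrate_waters, 2L)

  # leading multiplier shorthand used in fragment lists
  expect_equal(parse_formula("2H2O")$composition,
               c(H = 4, O = 2)[names(parse_formula("2H2O")$composition)])

  # nested groups to depth 3
  f3 <- parse_formula("Fe((C2(H2O)2)2N)3")
  expect_equal(unname(f3$composition[c("Fe", "C", "H", "O", "N")]),
               c(1, 12, 24, 12, 3))
})

test_that("parse_formula rejects malformed input", {
  expect_error(parse_formula("Xx2O"), class = "coordkit_unknown_element")
  expect_error(parse_formula("(H2O"), class = "coordkit_unbalanced_parens")
  expect_error(parse_formula("H2O)"), class = "coordkit_unbalanced_parens")
  expect_error(parse_formula("H0O"), class = "coordkit_bad_multiplier")
  expect_error(parse_formula("(H2O)0"), class = "coordkit_bad_multiplier")
})

test_that("formula rendering round-trips to an identical composition", {
  for (s in c("H2O", cu_complex, cu_complex_hydrate, "Fe((C2H5)2N)3",
              "Co(C10H9ClN4O2S)2ClOH2Cl.2H2O")) {
    f1 <- parse_formula(s)
    f2 <- parse_formula(format_formula(f1))
    expect_equal(f2$composition, f1$composition, info = s)
    expect_equal(f2$hydrate_waters, f1$hydrate_waters, info = s)
  }
})

test_that("molecular weight matches hand sums and is additive", {
  expect_equal(molecular_weight("H2O"), 18.015, tolerance = 0.001 / 18)
  expect_equal(molecular_weight(cu_complex), 703.88, tolerance = 0.05 / 704)
  expect_equal(molecular_weight(cu_complex_hydrate, basis = "hydrate"),
               739.91, tolerance = 0.05 / 740)
  # additivity: weight(A) + weight(B) = weight(A merged with B)
  expect_equal(molecular_weight("C6H12O6") + molecular_weight("NaCl"),
               molecular_weight("C6H12O6NaCl"))
})

test_that("percent composition matches the worked elemental analyses", {
  pc <- percent_composition(cu_complex)
  pct <- setNames(pc$percent, pc$element)
  expect_equal(pct[["C"]], 34.13, tolerance = 0.02 / 34)
  expect_equal(pct[["N"]], 15.92, tolerance = 0.02 / 16)
  expect_equal(pct[["Cu"]], 9.03, tolerance = 0.02 / 9)
  expect_equal(percent_composition("H2O")$percent[
    percent_composition("H2O")$element == "O"], 88.81, tolerance = 1e-3)
  expect_equal(percent_composition("Fe")$percent, 100)
})

test_that("percent composition sums to 100 on both bases", {
  for (s in c("H2O", cu_complex, cu_complex_hydrate, "NaCl")) {
    for (basis in c("anhydrous", "hydrate")) {
      expect_equal(sum(percent_composition(s, basis)$percent), 100,
                   tolerance = 1e-6, info = paste(s, basis))
    }
  }
})

test_that("fragment loss percent reproduces the thermal ledger cells", {
  # dihydrate water loss on the hydrate mass
  expect_equal(fragment_loss_percent(cu_complex_hydrate, "2H2O", "hydrate"),
               4.87, tolerance = 0.01 / 4.87)
  # metal-oxide residue on the anhydrous mass
  expect_equal(fragment_loss_percent(cu_complex, "CuO"),
               11.30, tolerance = 0.01 / 11.3)
  # fragments identical to the parent account for all mass
  expect_equal(fragment_loss_percent("CuO", "CuO"), 100)
  # fragments exceeding the parent are a mass-balance error
  expect_error(fragment_loss_percent("H2O", "2H2O"),
               class = "coordkit_mass_balance")
})

test_that("electrolyte classification follows the conductance cut-offs", {
  res <- classify_electrolyte(c(94, 1.56, 152, 30, 100))
  expect_equal(res$category,
               c("1:1 electrolyte", "non-electrolyte", "2:1 electrolyte",
                 "ambiguous", "ambiguous"))
  expect_error(classify_electrolyte(-1))
})
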