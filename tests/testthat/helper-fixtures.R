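# Shared fixture builders (constructed in code; no stored data).

# Exact two-line molar-ratio series: ascending branch to the breakpoint,
# then a flat plateau; optional Gaussian noise on absorbance.
make_breakpoint_series <- function(break_ratio = 1 / 3,
                                   x = seq(0.1, 0.9, by = 0.1),
                                   a_max = 1, noise_sigma = 0, seed = NULL) {
  a <- pmin(x / break_ratio, 1) * a_max
  if (noise_sigma > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    a <- a + rnorm(length(a), sd = noise_sigma)
  }
  tibble::tibble(mole_fraction = x, absorbance = a)
}

# The Cu complex of the worked examples: two sulfonamide ligands, one
# coordinated and one ionic chloride (plus dihydrate variant).
cu_complex <- "Cu(C10H9ClN4O2S)2Cl2"
cu_complex_hydrate <- "CuC20H18Cl4N8O4S2.2H2O"
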