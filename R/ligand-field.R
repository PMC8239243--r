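# Ligand-field (Dq, Racah B, nephelauxetic beta) and EPR g-factor analysis
# for octahedral d7 (Co) and d8 (Ni) ions.

#' Convert wavelength to wavenumber
#'
#' `10^7 / lambda(nm)`, rounded to the nearest cm^-1 (the granularity of the
#' band tables this feeds).
#'
#' @param wavelength_nm Wavelength(s) in nm, > 0.
#' @return Wavenumber(s) in cm^-1.
#' @examples
#' to_wavenumber(c(685, 589))
#' @export
to_wavenumber <- function(wavelength_nm) {
  check_positive(wavelength_nm, "wavelength_nm")
  round(1e7 / wavelength_nm)
}

#' Ligand-field parameters for an octahedral d7 (Co(II)) ion
#'
#' Closed forms from the two spin-allowed d-d bands (cm^-1):
#' `Dq = [(85 V3^2 - 4 (V3 - 2 V2)^2)^(1/2) - 9 (V3 - 2 V2)] / 340` and
#' `B = (V3 - 2 V2 + 30 Dq) / 15`, with the nephelauxetic ratio
#' `beta = B / B0` against the free-ion value `B0 = 971` cm^-1.
#'
#' @param v2,v3 Transition energies in cm^-1 (V2 the lower-energy band).
#' @param b0 Free-ion Racah B, cm^-1.
#' @return One-row tibble: `config`, `Dq`, `ten_Dq`, `B`, `beta`, `B0`.
#' @examples
#' cobalt_ligand_field(v2 = 14600, v3 = 16977)
#' @export
cobalt_ligand_field <- function(v2, v3, b0 = 971) {
  check_positive(v2, "v2"); check_positive(v3, "v3"); check_positive(b0, "b0")
  delta <- v3 - 2 * v2
  radicand <- 85 * v3^2 - 4 * delta^2
  if (radicand < 0) {
    abort(sprintf(
      "Inconsistent bands: radicand 85 V3^2 - 4 (V3 - 2 V2)^2 = %.6g < 0.",
      radicand), class = "coordkit_inconsistent_bands")
  }
  dq <- (sqrt(radicand) - 9 * delta) / 340
  b <- (delta + 30 * dq) / 15
  tibble(config = "d7_Co", Dq = dq, ten_Dq = 10 * dq,
         B = b, beta = b / b0, B0 = b0)
}

#' Ligand-field parameters for an octahedral d8 (Ni(II)) ion
#'
#' The Racah parameter follows the linear relation
#' `B = (V2 + V3 - 30 Dq) / 15` with `beta = B / B0`, `B0 = 1030` cm^-1.
#' When `ten_dq` is not supplied the closed form
#' `Dq = [(9 V2 + V3) - (85 (V2 - V3)^2 - 4 (V2 + V3)^2)^(1/2)] / 340` is
#' attempted; its radicand is negative for many realistic band pairs (it is
#' for the worked Ni example in this package), in which case a tabulated
#' `ten_dq` must be supplied and the failure is recorded in `dq_source`.
#'
#' @param v2,v3 Transition energies in cm^-1 (V2 the lower-energy band).
#' @param ten_dq Optional ligand-field splitting 10Dq, cm^-1.
#' @param b0 Free-ion Racah B, cm^-1.
#' @return One-row tibble: `config`, `Dq`, `ten_Dq`, `B`, `beta`, `B0`,
#'   `dq_source` (`"closed_form"` or `"supplied"`).
#' @examples
#' nickel_ligand_field(v2 = 12900, v3 = 14700, ten_dq = 5400)
#' @export
nickel_ligand_field <- function(v2, v3, ten_dq = NULL, b0 = 1030) {
  check_positive(v2, "v2"); check_positive(v3, "v3"); check_positive(b0, "b0")
  radicand <- 85 * (v2 - v3)^2 - 4 * (v2 + v3)^2
  if (is.null(ten_dq)) {
    if (radicand < 0) {
      abort(sprintf(
        paste("Inconsistent bands: closed-form Dq radicand",
              "85 (V2 - V3)^2 - 4 (V2 + V3)^2 = %.6g < 0;",
              "supply `ten_dq` explicitly."), radicand),
        class = "coordkit_inconsistent_bands")
    }
    dq <- ((9 * v2 + v3) - sqrt(radicand)) / 340
    ten_dq <- 10 * dq
    src <- "closed_form"
  } else {
    check_positive(ten_dq, "ten_dq")
    src <- if (radicand < 0) "supplied" else "supplied (closed form available)"
  }
  b <- (v2 + v3 - 3 * ten_dq) / 15
  tibble(config = "d8_Ni", Dq = ten_dq / 10, ten_Dq = ten_dq,
         B = b, beta = b / b0, B0 = b0, dq_source = src)
}

#' Nephelauxetic ratio
#'
#' `beta = B / B0`, the reduction of interelectronic repulsion relative to
#' the free ion; values below 1 indicate covalent metal--ligand bonding.
#'
#' @param b Complex Racah B, cm^-1.
#' @param b0 Free-ion Racah B, cm^-1.
#' @return `b / b0`.
#' @examples
#' nephelauxetic_ratio(708, 971)
#' @export
nephelauxetic_ratio <- function(b, b0) {
  check_positive(b, "b"); check_positive(b0, "b0")
  b / b0
}

#' Average EPR g-factor and covalency class
#'
#' `g_av = (g_par + 2 g_perp) / 3`; values below the threshold (2.3 by
#' convention) indicate a highly covalent metal--ligand bond, above it an
#' ionic one.
#'
#' @param g_parallel,g_perpendicular Principal g values, > 0.
#' @param threshold Covalency threshold on `g_av`.
#' @return One-row tibble: `g_parallel`, `g_perpendicular`, `g_av`,
#'   `covalency`.
#' @examples
#' g_average(2.044, 2.189)
#' @export
g_average <- function(g_parallel, g_perpendicular, threshold = 2.3) {
  check_positive(g_parallel, "g_parallel")
  check_positive(g_perpendicular, "g_perpendicular")
  g_av <- (g_parallel + 2 * g_perpendicular) / 3
  tibble(g_parallel = g_parallel, g_perpendicular = g_perpendicular,
         g_av = g_av,
         covalency = ifelse(g_av < threshold, "covalent", "ionic"))
}

#' Spin-only magnetic moment
#'
#' `mu = sqrt(n (n + 2))` Bohr magnetons for `n` unpaired electrons; the
#' standard comparison value for assigning coordination geometry from a
#' measured moment.
#'
#' @param n_unpaired Non-negative integer count(s) of unpaired electrons.
#' @return Moment(s) in Bohr magnetons.
#' @examples
#' spin_only_moment(2) # compare Ni(II) octahedral
#' @export
spin_only_moment <- function(n_unpaired) {
  if (any(!is.finite(n_unpaired)) || any(n_unpaired < 0) ||
      any(n_unpaired != round(n_unpaired))) {
    abort("`n_unpaired` must be non-negative integer(s).")
  }
  sqrt(n_unpaired * (n_unpaired + 2))
}
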