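# Conceptual-DFT global reactivity descriptors from frontier-orbital
# energies (Koopmans-style finite-difference forms).

#' Global reactivity descriptors from frontier-orbital energies
#'
#' Computes the standard conceptual-DFT set from HOMO/LUMO energies (eV):
#' gap `Eg = E_LUMO - E_HOMO`, chemical potential
#' `mu = (E_HOMO + E_LUMO)/2` (negative-midpoint convention), hardness
#' `eta = Eg/2`, softness `S = 1/(2 eta)` and electrophilicity
#' `omega = mu^2/(2 eta)`.
#'
#' Inverted input (`E_LUMO < E_HOMO`) is rejected with a swap hint rather
#' than silently reordered, and a degenerate gap is rejected because the
#' softness diverges.
#'
#' @param e_homo,e_lumo Orbital energies in eV (vectorized).
#' @param label Optional label(s) carried through.
#' @return A tibble with `label`, `e_homo`, `e_lumo`, `e_gap`, `mu`, `eta`,
#'   `softness`, `omega` (energies in eV, softness in eV^-1).
#' @examples
#' global_descriptors(e_homo = -6.75, e_lumo = -3.97)
#' @export
global_descriptors <- function(e_homo, e_lumo, label = NULL) {
  if (!is.numeric(e_homo) || !is.numeric(e_lumo) ||
      any(!is.finite(e_homo)) || any(!is.finite(e_lumo))) {
    abort("`e_homo` and `e_lumo` must be finite numbers.")
  }
  if (length(e_homo) != length(e_lumo)) {
    abort("`e_homo` and `e_lumo` must have the same length.")
  }
  inverted <- e_lumo < e_homo
  if (any(inverted)) {
    abort(sprintf(
      paste("E_LUMO < E_HOMO at position(s) %s. If the two energies were",
            "printed in swapped order, exchange them and retry."),
      paste(which(inverted), collapse = ", ")),
      class = "coordkit_inverted_orbitals")
  }
  degenerate <- e_lumo == e_homo
  if (any(degenerate)) {
    abort(sprintf(
      "Degenerate gap (E_LUMO = E_HOMO) at position(s) %s: softness is infinite.",
      paste(which(degenerate), collapse = ", ")),
      class = "coordkit_degenerate_gap")
  }
  eg <- e_lumo - e_homo
  mu <- (e_homo + e_lumo) / 2
  eta <- eg / 2
  tibble(
    label = label %||% NA_character_,
    e_homo = e_homo, e_lumo = e_lumo,
    e_gap = eg, mu = mu, eta = eta,
    softness = 1 / (2 * eta),
    omega = mu^2 / (2 * eta)
  )
}
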