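# Seeded synthetic-data generators emulating every raw input the analysis
# consumes, each a pure function of its parameters and seed, with the
# ground truth attached as an attribute and retrievable via truth().

with_seed_if <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(seed, expr)
}

#' Ground truth of a generated dataset
#'
#' @param x A tibble produced by one of the `gen_*()` generators.
#' @return The list of ground-truth parameters attached by the generator.
#' @export
truth <- function(x) attr(x, "truth")

#' Generate a metal-ligand titration series
#'
#' Absorbances from the ML2 equilibrium forward model
#' ([equilibrium_absorbance()]) plus additive Gaussian noise. Defaults
#' reproduce the study conditions: constant metal concentration
#' 0.36e-4 M and ligand varied from 0.18e-4 to 1.25e-4 M.
#'
#' @param kf Ground-truth formation constant, M^-2.
#' @param metal_conc Constant metal concentration, mol/L.
#' @param ligand_range Range of ligand concentrations, mol/L.
#' @param n_points Number of titration points.
#' @param epsilon Complex molar absorptivity, L mol^-1 cm^-1.
#' @param path_length Path length, cm.
#' @param noise_sigma Additive Gaussian noise s.d. on absorbance.
#' @param seed Seed making the series reproducible; `NULL` uses the current
#'   RNG state.
#' @return Tibble `metal_conc_M`, `ligand_conc_M`, `absorbance` with the
#'   ground truth as attribute `"truth"`.
#' @examples
#' gen_metal_titration(kf = 1.47e5, noise_sigma = 0)
#' @export
gen_metal_titration <- function(kf = 1.47e5, metal_conc = 0.36e-4,
                                ligand_range = c(0.18e-4, 1.25e-4),
                                n_points = 10, epsilon = 1e4,
                                path_length = 1, noise_sigma = 0,
                                seed = NULL) {
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  cl <- seq(ligand_range[1], ligand_range[2], length.out = n_points)
  a0 <- equilibrium_absorbance(kf, metal_conc, cl, epsilon, path_length)
  a <- with_seed_if(seed, a0 + rnorm(n_points, sd = noise_sigma))
  out <- tibble(metal_conc_M = metal_conc, ligand_conc_M = cl, absorbance = a)
  attr(out, "truth") <- list(kf = kf, epsilon = epsilon,
                             path_length = path_length,
                             noise_sigma = noise_sigma, seed = seed)
  out
}

#' Generate a DNA titration series
#'
#' Apparent extinction coefficients from the two-state hyperbolic binding
#' model `eps_a = eps_f + (eps_b - eps_f) Kb [DNA] / (1 + Kb [DNA])` plus
#' additive Gaussian noise. The default grid spans the study's DNA
#' concentrations, 1.69e-6 to 5.55e-6 M (base pairs).
#'
#' @param kb Ground-truth binding constant, M^-1 (0 gives a flat series at
#'   `epsilon_free`).
#' @param dna_range Range of DNA concentrations, mol/L base pairs.
#' @param n_points Number of points.
#' @param epsilon_free,epsilon_bound Free/bound extinction coefficients;
#'   `epsilon_bound < epsilon_free` yields a hypochromic series.
#' @param noise_sigma Additive Gaussian noise s.d. on `epsilon_apparent`
#'   (absolute units); see also `noise_relative`.
#' @param noise_relative If `TRUE`, `noise_sigma` is multiplicative
#'   (relative to each epsilon value).
#' @param seed Reproducibility seed.
#' @return Tibble `dna_conc_M`, `epsilon_apparent` with ground-truth
#'   attribute.
#' @examples
#' gen_dna_titration(kb = 9e5, noise_sigma = 0)
#' @export
gen_dna_titration <- function(kb = 9e5, dna_range = c(1.69e-6, 5.55e-6),
                              n_points = 6, epsilon_free = 10000,
                              epsilon_bound = 5000, noise_sigma = 0,
                              noise_relative = FALSE, seed = NULL) {
  if (kb < 0) abort("`kb` must be >= 0.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  dna <- seq(dna_range[1], dna_range[2], length.out = n_points)
  eps0 <- epsilon_free + (epsilon_bound - epsilon_free) * kb * dna / (1 + kb * dna)
  eps <- with_seed_if(seed, {
    if (noise_relative) eps0 * (1 + rnorm(n_points, sd = noise_sigma))
    else eps0 + rnorm(n_points, sd = noise_sigma)
  })
  out <- tibble(dna_conc_M = dna, epsilon_apparent = eps)
  attr(out, "truth") <- list(kb = kb, epsilon_free = epsilon_free,
                             epsilon_bound = epsilon_bound,
                             noise_sigma = noise_sigma,
                             noise_relative = noise_relative, seed = seed)
  out
}

# Arrhenius rate over heating-rate, per K: lambda(T) = (A / beta_s) e^(-Ea/RT)
arrhenius_lambda <- function(t_k, ea, a, beta_s) {
  (a / beta_s) * exp(-ea / (.const$R * t_k))
}

# alpha(T) for one first-order step on a fixed grid: exact update of the
# linear ODE dalpha/dT = lambda(T)(1 - alpha) with Simpson (4th-order)
# quadrature of lambda over each interval -- unconditionally stable.
integrate_step_alpha <- function(t_k, ea, a, beta_s) {
  h <- diff(t_k)
  mid <- (t_k[-1] + t_k[-length(t_k)]) / 2
  lam <- arrhenius_lambda(t_k, ea, a, beta_s)
  lam_mid <- arrhenius_lambda(mid, ea, a, beta_s)
  seg <- h / 6 * (lam[-length(lam)] + 4 * lam_mid + lam[-1])
  cum <- c(0, cumsum(seg))
  1 - exp(-cum)
}

#' Generate a non-isothermal TGA curve
#'
#' Composes a mass-percent trace from one or more independent first-order
#' decomposition steps, each integrated as
#' `dalpha/dT = (A / beta) exp(-Ea/RT) (1 - alpha)` on a fixed 0.5 K grid
#' (fourth-order scheme). Defaults follow the study protocol: 10 K/min
#' from 25 to 800 degC. Step onsets are controlled by each step's (Ea, A)
#' pair; a warning is issued when two steps' conversion windows overlap.
#'
#' @param steps List of steps, each a named vector or list with `ea`
#'   (J/mol), `a` (s^-1) and `fraction` (of initial mass lost); fractions
#'   must sum to <= 1.
#' @param heating_rate Heating rate, K/min.
#' @param temp_range_C Temperature range, degC.
#' @param resolution_K Grid spacing, K.
#' @param noise_sigma Additive Gaussian noise s.d. on mass percent
#'   (default 0: segmentation is exercised clean and noisy separately).
#' @param seed Reproducibility seed.
#' @return Tibble `temp_C`, `mass_pct`; ground-truth attribute carries each
#'   step's parameters, its alpha = 1%, 50%, 99% temperatures and DTG peak
#'   `t_s_K`.
#' @examples
#' gen_tga_curve(steps = list(c(ea = 1e5, a = 1e10, fraction = 0.6)))
#' @export
gen_tga_curve <- function(steps = list(), heating_rate = 10,
                          temp_range_C = c(25, 800), resolution_K = 0.5,
                          noise_sigma = 0, seed = NULL) {
  check_positive(heating_rate, "heating_rate")
  check_positive(resolution_K, "resolution_K")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  temp_c <- seq(temp_range_C[1], temp_range_C[2], by = resolution_K)
  t_k <- temp_c + 273.15
  beta_s <- heating_rate / 60

  steps <- lapply(steps, as.list)
  fracs <- vapply(steps, function(s) s$fraction, numeric(1))
  if (any(fracs <= 0)) abort("Step fractions must be > 0.")
  if (sum(fracs) > 1 + 1e-12) abort("Step fractions must sum to <= 1.")

  mass <- rep(100, length(t_k))
  truth_rows <- list()
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    check_positive(s$ea, "ea"); check_positive(s$a, "a")
    alpha <- integrate_step_alpha(t_k, s$ea, s$a, beta_s)
    mass <- mass - 100 * s$fraction * alpha
    dadt <- c(0, diff(alpha) / diff(t_k))
    crossing <- function(p) {
      if (max(alpha) < p) return(NA_real_)
      temp_c[which(alpha >= p)[1]]
    }
    truth_rows[[i]] <- tibble(
      step = i, ea = s$ea, a = s$a, fraction = s$fraction,
      loss_pct = 100 * s$fraction * max(alpha),
      t_onset_C = crossing(0.01), t_half_C = crossing(0.5),
      t_end_C = crossing(0.99),
      t_s_K = t_k[which.max(dadt)]
    )
  }
  truth_steps <- if (length(truth_rows) > 0) bind_rows(truth_rows) else
    tibble(step = integer())
  if (nrow(truth_steps) > 1) {
    ord <- order(truth_steps$t_half_C)
    on <- truth_steps$t_onset_C[ord]; off <- truth_steps$t_end_C[ord]
    if (any(head(off, -1) > tail(on, -1), na.rm = TRUE)) {
      warn("Generated decomposition steps overlap in temperature.")
    }
  }

  mass <- with_seed_if(seed, mass + rnorm(length(mass), sd = noise_sigma))
  out <- tibble(temp_C = temp_c, mass_pct = mass)
  attr(out, "truth") <- list(steps = truth_steps, heating_rate = heating_rate,
                             noise_sigma = noise_sigma, seed = seed)
  out
}

#' Generate an MTT plate
#'
#' Survival follows a Hill curve `100 / (1 + (dose/IC50)^hill)`, mapped to
#' 560 nm optical densities between the plate background and the control
#' OD, with additive Gaussian noise expressed as a fraction of the
#' corrected control OD. Control wells are emitted as dose-0 rows and the
#' 620 nm background as an `od620_bg` column, matching what
#' [survival_fractions()] consumes. The default dose ladder is a twofold
#' dilution series, as in the assay protocol.
#'
#' @param ic50 Ground-truth IC50, ug/ml.
#' @param hill Hill slope.
#' @param doses Dose ladder, ug/ml.
#' @param od_control Control OD at 560 nm.
#' @param od_background Background OD (620 nm wells).
#' @param noise_sigma Noise s.d. as a fraction of the corrected control OD.
#' @param replicates Replicates per dose.
#' @param seed Reproducibility seed.
#' @return Tibble `dose_ug_ml`, `replicate`, `od560`, `od620_bg` (controls
#'   at dose 0) with ground-truth attribute.
#' @examples
#' gen_mtt_plate(ic50 = 50, noise_sigma = 0)
#' @export
gen_mtt_plate <- function(ic50 = 50, hill = 1, doses = 400 / 2^(7:0),
                          od_control = 1.2, od_background = 0.08,
                          noise_sigma = 0.02, replicates = 3, seed = NULL) {
  check_positive(ic50, "ic50"); check_positive(hill, "hill")
  check_positive(doses, "doses")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  span <- od_control - od_background
  if (span <= 0) abort("`od_control` must exceed `od_background`.")
  grid <- tidyr::expand_grid(dose_ug_ml = c(0, doses),
                             replicate = seq_len(replicates))
  surv <- ifelse(grid$dose_ug_ml == 0, 100,
                 100 / (1 + (grid$dose_ug_ml / ic50)^hill))
  od <- od_background + span * surv / 100
  od <- with_seed_if(seed, od + rnorm(length(od), sd = noise_sigma * span))
  out <- tibble(dose_ug_ml = grid$dose_ug_ml, replicate = grid$replicate,
                od560 = od, od620_bg = od_background)
  attr(out, "truth") <- list(ic50 = ic50, hill = hill,
                             od_control = od_control,
                             od_background = od_background,
                             noise_sigma = noise_sigma, seed = seed)
  out
}

#' Generate a d8 two-band set from ligand-field parameters
#'
#' Inverse of the d8 (Ni) ligand-field relations: the two spin-allowed
#' transition energies are
#' `V2,3 = 15 Dq + 7.5 B -/+ (1/2) sqrt(225 B^2 + 100 Dq^2 - 180 Dq B)`,
#' so that `(V2 + V3 - 30 Dq) / 15` recovers `B` exactly
#' (round-trips through [nickel_ligand_field()]).
#'
#' @param config Electron configuration; only `"d8_Ni"` has a closed-form
#'   band inverse.
#' @param dq Ligand-field splitting parameter Dq, cm^-1 (> 0).
#' @param b Racah B, cm^-1 (> 0).
#' @return One-row tibble `config`, `v2`, `v3`, `dq`, `b`.
#' @examples
#' gen_bandset(dq = 540, b = 760)
#' @export
gen_bandset <- function(config = "d8_Ni", dq, b) {
  if (!identical(config, "d8_Ni")) {
    abort("Only the d8 (Ni) configuration has a closed-form band inverse.")
  }
  check_positive(dq, "dq"); check_positive(b, "b")
  radicand <- 225 * b^2 + 100 * dq^2 - 180 * dq * b
  if (radicand < 0) {
    abort("Negative radicand in the band-forward model.",
          class = "coordkit_inconsistent_bands")
  }
  s <- sqrt(radicand)
  tibble(config = config,
         v2 = 15 * dq + 7.5 * b - s / 2,
         v3 = 15 * dq + 7.5 * b + s / 2,
         dq = dq, b = b)
}
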