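# Wolfe-Shimer DNA-binding analysis.

#' Wolfe-Shimer DNA-binding fit
#'
#' Linearizes the two-state binding isotherm as
#' `[DNA]/(eps_a - eps_f) = [DNA]/(eps_b - eps_f) + 1/(Kb (eps_b - eps_f))`
#' and fits it by least squares. The binding constant is the slope-to-
#' intercept ratio; the bound-compound extinction coefficient is
#' `eps_f + 1/slope`. `[DNA]` is base-pair molarity throughout.
#'
#' @param data Data frame with column `dna_conc_M` and either
#'   `epsilon_apparent` or `absorbance` (the latter requires
#'   `compound_conc` to convert via Beer's law). At least 3 points.
#' @param epsilon_free Extinction coefficient of the free compound,
#'   L mol^-1 cm^-1.
#' @param temperature Temperature in kelvin for the Gibbs free energy.
#' @param compound_conc Compound concentration (mol/L), only needed when
#'   `data` carries raw absorbances.
#' @param path_length Path length, cm.
#' @return A `binding_fit` with `kb` (M^-1), `epsilon_bound`, `delta_G`
#'   (J/mol at `temperature`), signed `chromism_pct` (negative =
#'   hypochromic), and `r_squared`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' ti <- gen_dna_titration(kb = 9e5, noise_sigma = 0)
#' wolfe_shimer_fit(ti, epsilon_free = 10000)
#' @export
wolfe_shimer_fit <- function(data, epsilon_free, temperature = 298,
                             compound_conc = NULL, path_length = 1) {
  stop_not_df(data, "dna_conc_M")
  if (nrow(data) < 3) abort("Need at least 3 DNA titration points.")
  check_positive(data$dna_conc_M, "dna_conc_M")
  check_positive(epsilon_free, "epsilon_free")
  check_positive(temperature, "temperature")

  if ("epsilon_apparent" %in% names(data)) {
    eps_a <- data$epsilon_apparent
  } else if ("absorbance" %in% names(data)) {
    if (is.null(compound_conc)) {
      abort("`compound_conc` is required to convert absorbance to epsilon_apparent.")
    }
    check_positive(compound_conc, "compound_conc")
    eps_a <- data$absorbance / (path_length * compound_conc)
  } else {
    abort("`data` needs an `epsilon_apparent` or `absorbance` column.",
          class = "coordkit_missing_column")
  }

  d_eps <- eps_a - epsilon_free
  if (any(d_eps == 0) || length(unique(sign(d_eps))) > 1) {
    abort(paste("Inconsistent chromism: (eps_a - eps_f) must be non-zero and",
                "of one sign at every point."),
          class = "coordkit_inconsistent_chromism")
  }

  dna <- data$dna_conc_M
  y <- dna / d_eps
  fit <- lm(y ~ dna)
  intercept <- coef(fit)[[1]]
  slope <- coef(fit)[[2]]
  if (abs(intercept) < 1e-10 * max(abs(y))) {
    abort("Intercept indistinguishable from zero: Kb is unbounded.",
          class = "coordkit_unbounded_kb")
  }
  kb <- slope / intercept
  eps_b <- epsilon_free + 1 / slope
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  dg <- if (kb > 0) gibbs_free_energy(kb, temperature) else NA_real_

  structure(list(
    kb = kb,
    epsilon_bound = eps_b,
    epsilon_free = epsilon_free,
    delta_G = dg,
    temperature = temperature,
    chromism_pct = 100 * (eps_b - epsilon_free) / epsilon_free,
    r_squared = r2,
    slope = slope,
    intercept = intercept,
    n = nrow(data),
    points = tibble(dna_conc_M = dna, epsilon_apparent = eps_a, ws_y = y)
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Wolfe-Shimer DNA-binding fit\n")
  cat(sprintf("  Kb        : %.4g M^-1\n", x$kb))
  cat(sprintf("  eps_bound : %.4g L mol^-1 cm^-1\n", x$epsilon_bound))
  cat(sprintf("  deltaG    : %.2f kJ/mol at %g K\n", x$delta_G / 1000, x$temperature))
  cat(sprintf("  chromism  : %+.1f%% (%s)\n", x$chromism_pct,
              if (x$chromism_pct < 0) "hypochromic" else "hyperchromic"))
  cat(sprintf("  R^2 = %.5f over %d points\n", x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  tibble(kb = x$kb, epsilon_bound = x$epsilon_bound,
         epsilon_free = x$epsilon_free, delta_G = x$delta_G,
         temperature = x$temperature, chromism_pct = x$chromism_pct,
         r_squared = x$r_squared, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.binding_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$dna_conc_M, .data$ws_y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "[DNA] (M)", y = "[DNA] / (eps_a - eps_f)",
                  title = sprintf("Wolfe-Shimer plot: Kb = %.3g M^-1", object$kb)) +
    ggplot2::theme_minimal()
}

#' Gibbs free energy of binding
#'
#' `deltaG = -R T ln(K)` with R = 8.314 J K^-1 mol^-1.
#'
#' @param k Equilibrium constant(s), > 0.
#' @param temperature Temperature in kelvin.
#' @return Free energy in J/mol.
#' @examples
#' gibbs_free_energy(9e5, 298)
#' @export
gibbs_free_energy <- function(k, temperature = 298) {
  if (any(!is.finite(k)) || any(k <= 0)) abort("`k` must be > 0.")
  check_positive(temperature, "temperature")
  -.const$R * temperature * log(k)
}

#' Chromism percent
#'
#' Signed percent change of absorbance on binding: negative values are
#' hypochromic, positive hyperchromic.
#'
#' @param a_free Absorbance of the free compound (> 0).
#' @param a_bound Absorbance of the bound compound.
#' @return `100 * (a_bound - a_free) / a_free`.
#' @examples
#' chromism_percent(1.0, 0.8)
#' @export
chromism_percent <- function(a_free, a_bound) {
  check_positive(a_free, "a_free")
  100 * (a_bound - a_free) / a_free
}
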