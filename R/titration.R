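# M + 2L <-> ML2 equilibrium forward model and estimators.

# Unique physical root x = [ML2] of Kf = x / ((C_M - x)(C_L - 2x)^2) on
# [0, min(C_M, C_L/2)). g(x) = Kf (C_M - x)(C_L - 2x)^2 - x is strictly
# decreasing there, so bisection is guaranteed to bracket the single root.
solve_complex_conc <- function(kf, c_m, c_l) {
  if (kf <= 0) return(0)
  upper <- min(c_m, c_l / 2)
  g <- function(x) kf * (c_m - x) * (c_l - 2 * x)^2 - x
  lo <- 0
  hi <- upper * (1 - 1e-12)
  if (g(hi) >= 0) return(hi)  # numerically fully saturated
  for (i in seq_len(200)) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) <= 2 * .Machine$double.eps * hi) break
  }
  0.5 * (lo + hi)
}

#' Equilibrium absorbance of an ML2 complex
#'
#' Forward model for a 1:2 metal--ligand association M + 2L <-> ML2 read out
#' by Beer's law: solves the mass-action cubic for the complex concentration
#' and returns epsilon * b * \[ML2\].
#'
#' @param kf Formation constant, M^-2 (>= 0; 0 returns absorbance 0).
#' @param metal_conc Total metal concentration C_M, mol/L.
#' @param ligand_conc Total ligand concentration(s) C_L, mol/L (vectorized).
#' @param epsilon Molar absorptivity of the complex, L mol^-1 cm^-1.
#' @param path_length Optical path length b, cm.
#' @return Absorbance(s), same length as `ligand_conc`.
#' @examples
#' equilibrium_absorbance(2.5e9, 2e-5, 4e-5, epsilon = 1e4)
#' @export
equilibrium_absorbance <- function(kf, metal_conc, ligand_conc, epsilon,
                                   path_length = 1) {
  if (!is.numeric(kf) || length(kf) != 1 || !is.finite(kf) || kf < 0) {
    abort("`kf` must be a single non-negative number.")
  }
  check_positive(metal_conc, "metal_conc")
  check_positive(ligand_conc, "ligand_conc")
  check_positive(epsilon, "epsilon")
  check_positive(path_length, "path_length")
  x <- vapply(ligand_conc, function(cl) solve_complex_conc(kf, metal_conc, cl),
              numeric(1))
  epsilon * path_length * x
}

#' Stability constant from a spectrophotometric titration
#'
#' Estimates the ML2 formation constant from an absorbance series at
#' constant metal concentration. Two estimates are reported: the pointwise
#' mass-action expression
#' `Kf = x / ((C_M - x)(C_L - 2x)^2)` with `x = A/(epsilon b)` averaged over
#' points, and (the headline value) a one-parameter least-squares fit of the
#' equilibrium forward model, which is far less noise-amplifying near
#' saturation.
#'
#' When `epsilon` is not supplied it is estimated from the saturation
#' plateau as `max(A) / (b C_M)`; points within 0.1% of that plateau are
#' excluded from the pointwise estimate (they sit on the singular boundary
#' of the mass-action expression) but retained in the model fit.
#'
#' @param data Data frame with columns `metal_conc_M`, `ligand_conc_M`,
#'   `absorbance` (>= 3 rows, constant metal concentration).
#' @param epsilon Molar absorptivity of the complex; `NULL` to estimate.
#' @param path_length Path length, cm.
#' @return A `stability_fit` object with headline `kf`, `kf_pointwise_mean`,
#'   per-point complex concentrations, and fit diagnostics. Supports
#'   [tidy()], [glance()], [autoplot()].
#' @examples
#' ser <- gen_metal_titration(kf = 1.47e5, noise_sigma = 0)
#' stability_constant(ser, epsilon = 1e4)
#' @export
stability_constant <- function(data, epsilon = NULL, path_length = 1) {
  stop_not_df(data, c("metal_conc_M", "ligand_conc_M", "absorbance"))
  if (nrow(data) < 3) abort("Need at least 3 titration points.")
  c_m <- unique(data$metal_conc_M)
  if (length(c_m) > 1) {
    if (diff(range(c_m)) > 1e-9 * max(c_m)) {
      abort("`metal_conc_M` must be constant across the series.")
    }
    c_m <- c_m[1]
  }
  check_positive(c_m, "metal_conc_M")
  check_positive(data$ligand_conc_M, "ligand_conc_M")
  if (any(data$absorbance < 0)) abort("Absorbances must be >= 0.")
  b <- path_length

  eps_source <- "supplied"
  plateau_excluded <- rep(FALSE, nrow(data))
  if (is.null(epsilon)) {
    epsilon <- max(data$absorbance) / (b * c_m)
    eps_source <- "estimated"
    plateau_excluded <- data$absorbance >= max(data$absorbance) * (1 - 1e-3)
  }
  check_positive(epsilon, "epsilon")

  x <- data$absorbance / (epsilon * b)
  cap <- pmin(c_m, data$ligand_conc_M / 2)
  bad <- !plateau_excluded & x >= cap
  if (any(bad)) {
    abort(sprintf(
      "Unphysical absorbance at row(s) %s: A/(eps b) >= min(C_M, C_L/2).",
      paste(which(bad), collapse = ", ")),
      class = "coordkit_unphysical_absorbance")
  }

  kf_point <- ifelse(
    plateau_excluded | x <= 0, NA_real_,
    x / ((c_m - x) * (data$ligand_conc_M - 2 * x)^2)
  )
  boundary <- x <= 0
  kf_point[boundary] <- 0

  # headline: least-squares fit of the forward model over log10 Kf
  obj <- function(log10_kf) {
    a_hat <- equilibrium_absorbance(10^log10_kf, c_m, data$ligand_conc_M,
                                    epsilon, b)
    sum((a_hat - data$absorbance)^2)
  }
  opt <- optimize(obj, interval = c(-6, 16), tol = 1e-10)
  kf_ls <- 10^opt$minimum

  pts <- tibble(
    ligand_conc_M = data$ligand_conc_M,
    absorbance = data$absorbance,
    complex_conc_M = x,
    kf_point = kf_point,
    boundary = boundary,
    plateau_excluded = plateau_excluded
  )
  structure(list(
    kf = kf_ls,
    kf_pointwise_mean = mean(kf_point[!boundary], na.rm = TRUE),
    epsilon = epsilon,
    epsilon_source = eps_source,
    path_length = b,
    metal_conc_M = c_m,
    rss = opt$objective,
    n = nrow(data),
    points = pts
  ), class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat("ML2 stability-constant fit\n")
  cat(sprintf("  Kf (model fit)      : %.4g M^-2\n", x$kf))
  cat(sprintf("  Kf (pointwise mean) : %.4g M^-2\n", x$kf_pointwise_mean))
  cat(sprintf("  epsilon (%s) : %.4g L mol^-1 cm^-1\n", x$epsilon_source, x$epsilon))
  cat(sprintf("  n = %d points, RSS = %.3g\n", x$n, x$rss))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stability_fit <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.stability_fit <- function(x, ...) {
  tibble(kf = x$kf, kf_pointwise_mean = x$kf_pointwise_mean,
         epsilon = x$epsilon, epsilon_source = x$epsilon_source,
         metal_conc_M = x$metal_conc_M, rss = x$rss, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.stability_fit <- function(object, ...) {
  grid <- tibble(ligand_conc_M = seq(min(object$points$ligand_conc_M),
                                     max(object$points$ligand_conc_M),
                                     length.out = 200))
  grid$absorbance <- equilibrium_absorbance(
    object$kf, object$metal_conc_M, grid$ligand_conc_M,
    object$epsilon, object$path_length)
  ggplot2::ggplot(object$points, ggplot2::aes(.data$ligand_conc_M, .data$absorbance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "[L] (M)", y = "Absorbance",
                  title = sprintf("ML2 equilibrium fit: Kf = %.3g", object$kf)) +
    ggplot2::theme_minimal()
}

#' Molar-ratio breakpoint and implied stoichiometry
#'
#' Fits two least-squares lines (ascending branch and plateau branch) to an
#' absorbance versus metal mole-fraction series, choosing the split that
#' minimizes total residual sum of squares (ties broken toward the smaller
#' breakpoint). The intersection abscissa is the stoichiometric breakpoint:
#' a value near 1/3 implies a 1:2 metal:ligand complex, near 1/2 a 1:1.
#'
#' @param data Data frame with columns `mole_fraction`
#'   (= \[M\]/(\[M\]+\[L\])) and `absorbance`; at least 5 points spanning
#'   both sides of the break.
#' @return A `breakpoint_fit` with `ratio`, `stoichiometry` (`"1:2"` for
#'   ratio in \[0.28, 0.38\], `"1:1"` for \[0.45, 0.55\], else
#'   `"indeterminate"`), branch coefficients and diagnostics.
#' @examples
#' d <- tibble::tibble(mole_fraction = seq(0.1, 0.9, by = 0.1))
#' d$absorbance <- pmin(d$mole_fraction / (1 / 3), 1)
#' molar_ratio_breakpoint(d)
#' @export
molar_ratio_breakpoint <- function(data) {
  stop_not_df(data, c("mole_fraction", "absorbance"))
  data <- arrange(as_tibble(data), .data$mole_fraction)
  n <- nrow(data)
  if (n < 5) abort("Need at least 5 points to locate a breakpoint.")
  x <- data$mole_fraction
  y <- data$absorbance

  best <- NULL
  for (k in 2:(n - 2)) {
    f1 <- lm(y[1:k] ~ x[1:k])
    f2 <- lm(y[(k + 1):n] ~ x[(k + 1):n])
    rss <- sum(f1$residuals^2) + sum(f2$residuals^2)
    m1 <- coef(f1)[[2]]; b1 <- coef(f1)[[1]]
    m2 <- coef(f2)[[2]]; b2 <- coef(f2)[[1]]
    if (!is.finite(m1) || !is.finite(m2)) next
    if (abs(m1 - m2) < 1e-10 * max(abs(m1), abs(m2), 1)) next
    ratio <- (b2 - b1) / (m1 - m2)
    cand <- list(k = k, rss = rss, ratio = ratio,
                 slope_rise = m1, intercept_rise = b1,
                 slope_plateau = m2, intercept_plateau = b2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && ratio < best$ratio)) {
      best <- cand
    }
  }
  if (is.null(best) || !is.finite(best$ratio) ||
      best$ratio < min(x) - 0.25 || best$ratio > max(x) + 0.25) {
    abort("No detectable slope change: degenerate molar-ratio series.",
          class = "coordkit_degenerate_series")
  }
  r <- best$ratio
  stoich <- if (r >= 0.28 && r <= 0.38) "1:2"
            else if (r >= 0.45 && r <= 0.55) "1:1"
            else "indeterminate"
  structure(list(
    ratio = r,
    stoichiometry = stoich,
    ligand_per_metal = (1 - r) / r,
    split_index = best$k,
    rss = best$rss,
    slope_rise = best$slope_rise, intercept_rise = best$intercept_rise,
    slope_plateau = best$slope_plateau, intercept_plateau = best$intercept_plateau,
    data = data
  ), class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Molar-ratio breakpoint\n")
  cat(sprintf("  ratio [M]/([M]+[L]) : %.4f\n", x$ratio))
  cat(sprintf("  stoichiometry       : %s (%.2f L per M)\n",
              x$stoichiometry, x$ligand_per_metal))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.breakpoint_fit <- function(x, ...) {
  tibble(branch = c("rise", "plateau"),
         slope = c(x$slope_rise, x$slope_plateau),
         intercept = c(x$intercept_rise, x$intercept_plateau))
}

#' @exportS3Method generics::glance
glance.breakpoint_fit <- function(x, ...) {
  tibble(ratio = x$ratio, stoichiometry = x$stoichiometry,
         ligand_per_metal = x$ligand_per_metal,
         split_index = x$split_index, rss = x$rss, n = nrow(x$data))
}

#' @exportS3Method ggplot2::autoplot
autoplot.breakpoint_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$mole_fraction, .data$absorbance)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope_rise,
                         intercept = object$intercept_rise,
                         colour = "steelblue", linetype = 2) +
    ggplot2::geom_abline(slope = object$slope_plateau,
                         intercept = object$intercept_plateau,
                         colour = "firebrick", linetype = 2) +
    ggplot2::geom_vline(xintercept = object$ratio, colour = "grey40") +
    ggplot2::labs(x = "[M] / ([M] + [L])", y = "Absorbance",
                  title = sprintf("Breakpoint at %.3f (%s)",
                                  object$ratio, object$stoichiometry)) +
    ggplot2::theme_minimal()
}

#' Concentration from Beer's law
#'
#' @param absorbance Absorbance(s), dimensionless.
#' @param epsilon Molar absorptivity, L mol^-1 cm^-1.
#' @param path_length Path length, cm.
#' @return Concentration(s) in mol/L: `A / (epsilon * b)`.
#' @examples
#' beer_lambert_concentration(0.7986, 6600)
#' @export
beer_lambert_concentration <- function(absorbance, epsilon, path_length = 1) {
  if (any(absorbance < 0)) abort("`absorbance` must be >= 0.")
  check_positive(epsilon, "epsilon")
  check_positive(path_length, "path_length")
  absorbance / (epsilon * path_length)
}
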