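# TGA curve segmentation, Coats-Redfern / Horowitz-Metzger kinetics and
# activation thermodynamics.

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]  # keep raw values at the edges
  sm
}

# smoothed mass-loss rate, % per K (central differences, one-sided at ends)
loss_rate <- function(temp, mass, window) {
  sm <- moving_average(mass, window)
  n <- length(sm)
  r <- numeric(n)
  r[2:(n - 1)] <- -(sm[3:n] - sm[1:(n - 2)]) / (temp[3:n] - temp[1:(n - 2)])
  r[1] <- -(sm[2] - sm[1]) / (temp[2] - temp[1])
  r[n] <- -(sm[n] - sm[n - 1]) / (temp[n] - temp[n - 1])
  r
}

#' Segment a TGA curve into decomposition steps
#'
#' Detects mass-loss steps as contiguous regions where the smoothed
#' derivative-thermogravimetry (DTG) rate exceeds a threshold. Step losses
#' are measured plateau-to-plateau (boundaries at the rate minima between
#' adjacent steps), so the detected losses plus the final residue mass
#' telescope back to the initial mass. `t_s_K` is the DTG peak temperature
#' of each step.
#'
#' @param data Data frame with columns `temp_C` (strictly increasing, >= 50
#'   points) and `mass_pct`.
#' @param min_loss_percent Steps losing less than this are discarded.
#' @param smoothing_window Centered moving-average window (points) applied
#'   before differentiation.
#' @param rate_threshold DTG threshold in %/K; `NULL` (default) uses
#'   `max(0.02, 0.02 * max(rate))`.
#' @return A tibble of steps (possibly 0 rows, with a message, for a flat
#'   curve): `step`, `temp_start_C`/`temp_end_C` (threshold crossings),
#'   `t_s_K`, `mass_start_pct`, `mass_end_pct`, `mass_loss_pct`, and the
#'   plateau-to-plateau row indices `idx_start`/`idx_end` for
#'   [extract_step()].
#' @examples
#' cur <- gen_tga_curve(steps = list(c(ea = 9e4, a = 1e10, fraction = 0.05),
#'                                   c(ea = 1.6e5, a = 1e12, fraction = 0.75)))
#' segment_steps(cur)
#' @export
segment_steps <- function(data, min_loss_percent = 1, smoothing_window = 7,
                          rate_threshold = NULL) {
  stop_not_df(data, c("temp_C", "mass_pct"))
  if (nrow(data) < 50) abort("Need at least 50 TGA points.")
  temp <- data$temp_C
  mass <- data$mass_pct
  if (any(diff(temp) <= 0)) {
    abort("`temp_C` must be strictly increasing.",
          class = "coordkit_nonmonotone_temperature")
  }
  rate <- loss_rate(temp, mass, smoothing_window)
  thresh <- rate_threshold %||% max(0.02, 0.02 * max(rate))

  above <- rate > thresh
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cores <- data.frame(start = starts[runs$values], end = ends[runs$values])
  if (nrow(cores) == 0) {
    message("No decomposition step found (flat curve).")
    return(empty_steps())
  }

  partition_losses <- function(cores) {
    k <- nrow(cores)
    b_lo <- integer(k); b_hi <- integer(k)
    for (i in seq_len(k)) {
      b_lo[i] <- if (i == 1) 1L else {
        gap <- cores$end[i - 1]:cores$start[i]
        gap[which.min(rate[gap])]
      }
      b_hi[i] <- if (i == k) length(temp) else {
        gap <- cores$end[i]:cores$start[i + 1]
        gap[which.min(rate[gap])]
      }
    }
    data.frame(cores, b_lo = b_lo, b_hi = b_hi,
               loss = mass[b_lo] - mass[b_hi])
  }

  parts <- partition_losses(cores)
  keep <- parts$loss >= min_loss_percent
  if (!any(keep)) {
    message("No decomposition step exceeds min_loss_percent (flat curve).")
    return(empty_steps())
  }
  if (!all(keep)) parts <- partition_losses(cores[keep, , drop = FALSE])

  t_s <- vapply(seq_len(nrow(parts)), function(i) {
    seg <- parts$start[i]:parts$end[i]
    temp[seg[which.max(rate[seg])]] + 273.15
  }, numeric(1))

  tibble(
    step = seq_len(nrow(parts)),
    temp_start_C = temp[parts$start],
    temp_end_C = temp[parts$end],
    t_s_K = t_s,
    mass_start_pct = mass[parts$b_lo],
    mass_end_pct = mass[parts$b_hi],
    mass_loss_pct = parts$loss,
    idx_start = parts$b_lo,
    idx_end = parts$b_hi
  )
}

empty_steps <- function() {
  tibble(step = integer(), temp_start_C = numeric(), temp_end_C = numeric(),
         t_s_K = numeric(), mass_start_pct = numeric(),
         mass_end_pct = numeric(), mass_loss_pct = numeric(),
         idx_start = integer(), idx_end = integer())
}

#' Extract the points of one detected step
#'
#' @param data The TGA data frame passed to [segment_steps()].
#' @param steps The tibble returned by [segment_steps()].
#' @param step Which step (row of `steps`) to extract.
#' @return The plateau-to-plateau slice of `data` for that step.
#' @export
extract_step <- function(data, steps, step = 1) {
  stop_not_df(steps, c("idx_start", "idx_end"), "steps")
  i <- which(steps$step == step)
  if (length(i) != 1) abort("`step` not found in `steps`.")
  data[steps$idx_start[i]:steps$idx_end[i], , drop = FALSE]
}

# alpha (extent of conversion) for a single-step slice
step_alpha <- function(data) {
  if ("alpha" %in% names(data)) return(data$alpha)
  stop_not_df(data, c("temp_C", "mass_pct"))
  m0 <- max(data$mass_pct); mf <- min(data$mass_pct)
  if (m0 - mf <= 0) {
    abort("No conversion in this step: mass is constant.",
          class = "coordkit_non_arrhenius")
  }
  (m0 - data$mass_pct) / (m0 - mf)
}

kinetic_fit_obj <- function(method, ea, a, r2, alpha_range, n, slope,
                            intercept, t_s, heating_rate, points) {
  structure(list(method = method, ea = ea, a = a, r_squared = r2,
                 alpha_range = alpha_range, n = n, slope = slope,
                 intercept = intercept, t_s_K = t_s,
                 heating_rate = heating_rate, points = points),
            class = "kinetic_fit")
}

#' Coats-Redfern kinetic fit (first order)
#'
#' Linear regression of `ln[-ln(1 - alpha) / T^2]` on `1/T` over the
#' conversion window. The activation energy is `-slope * R`; the
#' pre-exponential factor uses the standard intercept approximation
#' `ln(A R / (beta Ea))` (the `1 - 2RT/Ea` factor is dropped, conventional
#' and sub-percent for Ea >> RT). Heating rate is converted to K/s so `A`
#' is in s^-1.
#'
#' @param data One step's points: columns `temp_C` and `mass_pct` (alpha is
#'   computed from the within-step mass range) or a precomputed `alpha`
#'   column with `temp_C`.
#' @param heating_rate Heating rate in K/min.
#' @param alpha_range Conversion window used for the fit.
#' @return A `kinetic_fit` (method `"CR"`): `ea` (J/mol), `a` (s^-1),
#'   `r_squared`, window and line coefficients. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' cur <- gen_tga_curve(steps = list(c(ea = 1e5, a = 1e10, fraction = 0.6)))
#' coats_redfern_fit(cur, heating_rate = 10)
#' @export
coats_redfern_fit <- function(data, heating_rate, alpha_range = c(0.05, 0.95)) {
  stop_not_df(data, "temp_C")
  check_positive(heating_rate, "heating_rate")
  alpha <- step_alpha(data)
  t_k <- data$temp_C + 273.15
  use <- alpha >= alpha_range[1] & alpha <= alpha_range[2]
  if (sum(use) < 5) {
    abort("Fewer than 5 usable points in the conversion window.",
          class = "coordkit_non_arrhenius")
  }
  a_u <- alpha[use]; t_u <- t_k[use]
  y <- log(-log(1 - a_u) / t_u^2)
  x <- 1 / t_u
  fit <- lm(y ~ x)
  slope <- coef(fit)[[2]]; intercept <- coef(fit)[[1]]
  # a physical CR slope is -Ea/R, i.e. of order -1e3 K or steeper
  if (!is.finite(slope) || slope >= -1e-6) {
    abort("Non-Arrhenius behaviour: Coats-Redfern slope is not negative.",
          class = "coordkit_non_arrhenius")
  }
  ea <- -slope * .const$R
  beta_s <- heating_rate / 60
  a_pre <- beta_s * ea / .const$R * exp(intercept)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  kinetic_fit_obj("CR", ea, a_pre, r2, alpha_range, sum(use), slope,
                  intercept, NA_real_, heating_rate,
                  tibble(temp_K = t_u, alpha = a_u, cr_y = y))
}

#' Horowitz-Metzger kinetic fit (first order)
#'
#' Linear regression of `ln[-ln(1 - alpha)]` on `theta = T - T_s`, where
#' `T_s` is the DTG peak temperature of the step. The activation energy is
#' `slope * R * T_s^2`; `A` follows from the first-order rate equality at
#' `T_s`: `A = (beta Ea / (R T_s^2)) exp(Ea / (R T_s))`.
#'
#' @inheritParams coats_redfern_fit
#' @param t_s DTG peak temperature in kelvin; `NULL` computes it from the
#'   maximum mass-loss rate of `data`.
#' @return A `kinetic_fit` (method `"HM"`).
#' @examples
#' cur <- gen_tga_curve(steps = list(c(ea = 1e5, a = 1e10, fraction = 0.6)))
#' horowitz_metzger_fit(cur, heating_rate = 10)
#' @export
horowitz_metzger_fit <- function(data, heating_rate, t_s = NULL,
                                 alpha_range = c(0.05, 0.95)) {
  stop_not_df(data, "temp_C")
  check_positive(heating_rate, "heating_rate")
  alpha <- step_alpha(data)
  t_k <- data$temp_C + 273.15
  if (is.null(t_s)) {
    if (!"mass_pct" %in% names(data)) {
      abort("`t_s` must be supplied when `data` has no `mass_pct` column.")
    }
    r <- loss_rate(t_k, data$mass_pct, min(7, nrow(data)))
    t_s <- t_k[which.max(r)]
  }
  check_positive(t_s, "t_s")
  use <- alpha >= alpha_range[1] & alpha <= alpha_range[2]
  if (sum(use) < 5) {
    abort("Fewer than 5 usable points in the conversion window.",
          class = "coordkit_non_arrhenius")
  }
  a_u <- alpha[use]
  theta <- t_k[use] - t_s
  y <- log(-log(1 - a_u))
  fit <- lm(y ~ theta)
  slope <- coef(fit)[[2]]; intercept <- coef(fit)[[1]]
  # a physical HM slope is Ea/(R T_s^2), i.e. of order 1e-2 K^-1 or steeper
  if (!is.finite(slope) || slope <= 1e-8) {
    abort("Non-Arrhenius behaviour: Horowitz-Metzger slope is not positive.",
          class = "coordkit_non_arrhenius")
  }
  ea <- slope * .const$R * t_s^2
  beta_s <- heating_rate / 60
  a_pre <- beta_s * ea / (.const$R * t_s^2) * exp(ea / (.const$R * t_s))
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  kinetic_fit_obj("HM", ea, a_pre, r2, alpha_range, sum(use), slope,
                  intercept, t_s, heating_rate,
                  tibble(theta_K = theta, alpha = a_u, hm_y = y))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s kinetic fit (first order)\n",
              if (x$method == "CR") "Coats-Redfern" else "Horowitz-Metzger"))
  cat(sprintf("  Ea  : %.2f kJ/mol\n", x$ea / 1000))
  cat(sprintf("  A   : %.3g s^-1\n", x$a))
  if (is.finite(x$t_s_K)) cat(sprintf("  T_s : %.1f K\n", x$t_s_K))
  cat(sprintf("  R^2 = %.5f over %d points (alpha %g-%g)\n",
              x$r_squared, x$n, x$alpha_range[1], x$alpha_range[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kinetic_fit <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.kinetic_fit <- function(x, ...) {
  tibble(method = x$method, ea = x$ea, a = x$a, r_squared = x$r_squared,
         t_s_K = x$t_s_K, alpha_lo = x$alpha_range[1],
         alpha_hi = x$alpha_range[2], n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.kinetic_fit <- function(object, ...) {
  p <- object$points
  if (object$method == "CR") {
    p$xvar <- 1 / p$temp_K; p$yvar <- p$cr_y
    labs <- c("1 / T (K^-1)", "ln[-ln(1 - alpha) / T^2]")
  } else {
    p$xvar <- p$theta_K; p$yvar <- p$hm_y
    labs <- c("theta = T - T_s (K)", "ln[-ln(1 - alpha)]")
  }
  ggplot2::ggplot(p, ggplot2::aes(.data$xvar, .data$yvar)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = labs[1], y = labs[2],
                  title = sprintf("%s fit: Ea = %.1f kJ/mol", object$method,
                                  object$ea / 1000)) +
    ggplot2::theme_minimal()
}

#' Activation thermodynamics of a decomposition step
#'
#' `deltaH = Ea - R T_s`, `deltaS = R ln(A h / (kB T_s))`,
#' `deltaG = deltaH - T_s deltaS`, evaluated at the step's DTG peak
#' temperature.
#'
#' @param ea Activation energy, J/mol (> 0). Vectorized.
#' @param a Pre-exponential factor, s^-1 (> 0).
#' @param t_s DTG peak temperature, K (> 0).
#' @return Tibble with `ea`, `a`, `t_s_K`, `delta_H`, `delta_S`, `delta_G`
#'   (J/mol, J/(K mol), J/mol).
#' @examples
#' activation_thermodynamics(1e5, 1e10, 500)
#' @export
activation_thermodynamics <- function(ea, a, t_s) {
  check_positive(ea, "ea"); check_positive(a, "a"); check_positive(t_s, "t_s")
  dh <- ea - .const$R * t_s
  ds <- .const$R * log(a * .const$h / (.const$kB * t_s))
  tibble(ea = ea, a = a, t_s_K = t_s,
         delta_H = dh, delta_S = ds, delta_G = dh - t_s * ds)
}

#' Thermogravimetric mass-balance ledger
#'
#' Computes the calculated weight-loss percent of each decomposition step
#' from its assigned fragments, the total loss, and the residue percent,
#' with found-minus-calculated residuals when observed values are supplied.
#' Steps quoted on the hydrate mass and residues on the anhydrous mass can
#' coexist: the basis is declared per step.
#'
#' @param parent Parent `chem_formula` or string (hydrate suffix allowed).
#' @param step_fragments List with one fragment spec per step (see
#'   [fragment_loss_percent()] for the spec format).
#' @param residue Residue formula spec, or `NULL`.
#' @param basis Mass basis per step (recycled), `"hydrate"` or
#'   `"anhydrous"`.
#' @param residue_basis Basis for the residue percent.
#' @param found_loss Optional observed per-step losses (%).
#' @param found_residue Optional observed residue (%).
#' @return A tibble ledger with rows for each step, the total, and the
#'   residue: `entry`, `basis`, `fragments`, `calc_pct`, `found_pct`,
#'   `residual`.
#' @examples
#' step_mass_balance("CuC20H18Cl4N8O4S2.2H2O",
#'                   list("2H2O", "2HCl+2SO2+4N2+7C2H4"),
#'                   residue = "CuO",
#'                   found_loss = c(4.5, 75.3), found_residue = 11.3)
#' @export
step_mass_balance <- function(parent, step_fragments, residue = NULL,
                              basis = "hydrate", residue_basis = "anhydrous",
                              found_loss = NULL, found_residue = NULL) {
  parent <- parse_formula(parent)
  if (!is.list(step_fragments)) step_fragments <- as.list(step_fragments)
  k <- length(step_fragments)
  basis <- rep(basis, length.out = k)
  found_loss <- found_loss %||% rep(NA_real_, k)
  if (length(found_loss) != k) abort("`found_loss` must match the step count.")

  frag_lists <- lapply(step_fragments, expand_fragments)
  # Published step assignments are often mass-approximate rather than
  # atom-balanced, so the hard error here is on mass only; element-count
  # excesses are reported as a warning.
  all_frags <- unlist(frag_lists, recursive = FALSE)
  all_counts <- fragment_counts(all_frags)
  res_frags <- NULL
  if (!is.null(residue)) {
    res_frags <- expand_fragments(residue)
    res_counts <- fragment_counts(res_frags)
    for (sym in names(res_counts)) {
      all_counts[sym] <- (if (sym %in% names(all_counts)) all_counts[[sym]] else 0) +
        res_counts[[sym]]
    }
  }
  frag_mass_of <- function(frags) {
    fc <- fragment_counts(frags)
    sum(fc * atomic_weight_of(names(fc)))
  }
  parent_mass <- molecular_weight(parent, "hydrate")
  total_mass <- frag_mass_of(all_frags) +
    (if (is.null(res_frags)) 0 else frag_mass_of(res_frags))
  if (total_mass > parent_mass * (1 + 1e-9)) {
    abort(sprintf(
      "Mass-balance error: fragments + residue (%.2f g/mol) exceed the parent (%.2f g/mol).",
      total_mass, parent_mass), class = "coordkit_mass_balance")
  }
  pool <- basis_composition(parent, "hydrate")
  excess <- names(all_counts)[vapply(names(all_counts), function(sym) {
    all_counts[[sym]] > (if (sym %in% names(pool)) pool[[sym]] else 0) + 1e-9
  }, logical(1))]
  if (length(excess) > 0) {
    warn(sprintf(
      "Fragment assignments exceed the parent's element counts for: %s.",
      paste(excess, collapse = ", ")),
      class = "coordkit_element_imbalance")
  }

  calc <- vapply(seq_len(k), function(i) {
    step_mass <- frag_mass_of(frag_lists[[i]])
    pm <- molecular_weight(parent, basis[i])
    if (step_mass > pm * (1 + 1e-9)) {
      abort(sprintf("Mass-balance error in step %d: fragment mass %.2f > parent %.2f.",
                    i, step_mass, pm), class = "coordkit_mass_balance")
    }
    100 * step_mass / pm
  }, numeric(1))
  frag_str <- vapply(frag_lists, function(fl) {
    paste(vapply(fl, format_formula, character(1)), collapse = " + ")
  }, character(1))

  rows <- tibble(
    entry = paste0("step", seq_len(k)),
    basis = basis,
    fragments = frag_str,
    calc_pct = calc,
    found_pct = as.numeric(found_loss)
  )
  total <- tibble(entry = "total",
                  basis = if (length(unique(basis)) == 1) basis[1] else "mixed",
                  fragments = NA_character_,
                  calc_pct = sum(calc),
                  found_pct = if (all(is.na(found_loss))) NA_real_
                              else sum(found_loss, na.rm = TRUE))
  rows <- bind_rows(rows, total)
  if (!is.null(residue)) {
    res_calc <- fragment_loss_percent(parent, res_frags, basis = residue_basis)
    rows <- bind_rows(rows, tibble(
      entry = "residue", basis = residue_basis,
      fragments = paste(vapply(res_frags, format_formula, character(1)),
                        collapse = " + "),
      calc_pct = res_calc,
      found_pct = found_residue %||% NA_real_))
  }
  rows$residual <- rows$found_pct - rows$calc_pct
  rows
}
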