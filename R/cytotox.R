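# MTT plate reduction, IC50 interpolation and potency classification.

#' Survival fractions from MTT plate readings
#'
#' Per-dose survival percent
#' `100 * (OD_treated - OD_bg) / (OD_control - OD_bg)` with a per-plate
#' scalar background (the mean of the 620 nm background wells) and
#' replicate averaging. Control wells are the rows with `dose_ug_ml == 0`
#' unless `od_control` is given.
#'
#' @param plate Data frame with columns `dose_ug_ml` and `od560`; optional
#'   `od620_bg` (background wells, averaged) and `replicate`. Rows with
#'   dose 0 are treated as untreated controls.
#' @param od_control Optional control OD(s) at 560 nm (overrides dose-0
#'   rows).
#' @param od_background Optional background OD (overrides the `od620_bg`
#'   column; defaults to 0 when neither is present).
#' @return A tibble `dose_ug_ml`, `survival` (percent), `n_rep`.
#' @examples
#' plate <- gen_mtt_plate(ic50 = 50, noise_sigma = 0)
#' survival_fractions(plate)
#' @export
survival_fractions <- function(plate, od_control = NULL, od_background = NULL) {
  stop_not_df(plate, c("dose_ug_ml", "od560"), "plate")
  bg <- od_background %||%
    (if ("od620_bg" %in% names(plate)) mean(plate$od620_bg) else 0)
  ctrl <- od_control %||% plate$od560[plate$dose_ug_ml == 0]
  if (length(ctrl) == 0) {
    abort("No control wells: supply `od_control` or dose-0 rows.")
  }
  ctrl_corr <- mean(ctrl) - bg
  if (ctrl_corr <= 0) {
    abort("Background-corrected control OD must be positive.",
          class = "coordkit_bad_control")
  }
  treated <- plate[plate$dose_ug_ml > 0, , drop = FALSE]
  if (any(plate$dose_ug_ml < 0)) abort("Doses must be non-negative.")
  out <- treated |>
    group_by(dose_ug_ml = .data$dose_ug_ml) |>
    summarise(survival = 100 * (mean(.data$od560) - bg) / ctrl_corr,
              n_rep = dplyr::n(), .groups = "drop") |>
    arrange(.data$dose_ug_ml)
  out
}

#' Interpolate the half-inhibitory concentration (IC50)
#'
#' Log10-dose linear interpolation between the doses bracketing the 50%
#' survival crossing; if survival is non-monotone the first crossing is
#' used with a warning. A series that never crosses 50% yields a censored
#' result (`"> max dose"` or `"< min dose"`) rather than an error.
#'
#' @param dose_response Data frame with columns `dose_ug_ml` (> 0) and
#'   `survival` (percent), as returned by [survival_fractions()].
#' @return An `ic50_fit` with `ic50` (ug/ml, `NA` when censored),
#'   `censored` (`NA`, `"> max dose"` or `"< min dose"`), `potency_class`,
#'   and the bracketing doses. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' ic50_interpolate(tibble::tibble(dose_ug_ml = c(10, 100),
#'                                 survival = c(80, 30)))
#' @export
ic50_interpolate <- function(dose_response) {
  stop_not_df(dose_response, c("dose_ug_ml", "survival"), "dose_response")
  d <- dose_response[dose_response$dose_ug_ml > 0, , drop = FALSE]
  d <- arrange(as_tibble(d), .data$dose_ug_ml)
  if (nrow(d) < 2 && !any(d$survival == 50)) {
    abort("Need at least 2 positive-dose points to interpolate.")
  }
  s <- d$survival
  dose <- d$dose_ug_ml
  nonmono <- any(diff(s) > 1e-8)
  ic50 <- NA_real_; censored <- NA_character_
  bracket <- c(NA_real_, NA_real_)

  exact <- which(s == 50)
  crossing <- which((s[-length(s)] - 50) * (s[-1] - 50) < 0)
  if (length(exact) > 0 && (length(crossing) == 0 || exact[1] <= crossing[1])) {
    ic50 <- dose[exact[1]]
    bracket <- c(ic50, ic50)
  } else if (length(crossing) > 0) {
    i <- crossing[1]
    ic50 <- 10^(log10(dose[i]) +
                  (s[i] - 50) / (s[i] - s[i + 1]) *
                  (log10(dose[i + 1]) - log10(dose[i])))
    bracket <- dose[c(i, i + 1)]
  } else if (all(s > 50)) {
    censored <- "> max dose"
  } else {
    censored <- "< min dose"
  }
  if (nonmono && !is.na(ic50)) {
    warn("Survival is non-monotone; first 50% crossing used.")
  }
  pclass <- if (!is.na(ic50)) {
    potency_class(ic50)
  } else if (identical(censored, "> max dose") && max(dose) >= 100) {
    "non-cytotoxic"
  } else {
    NA_character_
  }
  structure(list(ic50 = ic50, censored = censored, potency_class = pclass,
                 bracket_lo = bracket[1], bracket_hi = bracket[2],
                 data = d), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("IC50 interpolation\n")
  if (is.na(x$ic50)) {
    cat(sprintf("  censored: IC50 %s\n", x$censored))
  } else {
    cat(sprintf("  IC50 = %.2f ug/ml (bracket %.3g-%.3g)\n",
                x$ic50, x$bracket_lo, x$bracket_hi))
  }
  cat(sprintf("  potency: %s\n", x$potency_class %||% NA))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ic50_fit <- function(x, ...) x$data

#' @exportS3Method generics::glance
glance.ic50_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, censored = x$censored,
         potency_class = x$potency_class,
         bracket_lo = x$bracket_lo, bracket_hi = x$bracket_hi,
         n = nrow(x$data))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ic50_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$dose_ug_ml, .data$survival)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 50, linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (ug/ml, log scale)", y = "survival (%)",
                  title = if (is.na(object$ic50)) {
                    sprintf("IC50 censored (%s)", object$censored)
                  } else {
                    sprintf("IC50 = %.1f ug/ml (%s)", object$ic50,
                            object$potency_class)
                  }) +
    ggplot2::theme_minimal()
  if (!is.na(object$ic50)) {
    p <- p + ggplot2::geom_vline(xintercept = object$ic50,
                                 colour = "firebrick", linetype = 2)
  }
  p
}

#' Potency class of an IC50 value
#'
#' Band lookup with inclusive upper edges: (0, 10] very strong, (10, 20]
#' strong, (20, 50] moderate, (50, 100] weak, above 100 non-cytotoxic
#' (ug/ml).
#'
#' @param ic50 IC50 value(s) in ug/ml, > 0.
#' @return Character vector of classes.
#' @examples
#' potency_class(c(23.84, 45.62, 284.25))
#' @export
potency_class <- function(ic50) {
  check_positive(ic50, "ic50")
  as.character(cut(ic50, breaks = c(0, 10, 20, 50, 100, Inf),
                   labels = c("very strong", "strong", "moderate", "weak",
                              "non-cytotoxic"),
                   right = TRUE))
}
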