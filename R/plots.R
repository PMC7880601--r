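#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_hline
#'   scale_x_log10 labs theme_minimal facet_wrap autoplot
NULL

#' Plot a dose-response curve with its 4PL fit
#'
#' @param object A `pl4_fit` from [fit_4pl()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pl4_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot(dat, aes(x = .data$conc_uM, y = .data$npi)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "Concentration (µM)", y = "NPI (%)",
         title = sprintf("%s  IC50 = %.3g µM%s",
                         object$drug_id %||% "", object$ic50,
                         if (object$capped != "none")
                           paste0(" (capped ", object$capped, ")") else "")) +
    theme_minimal()
  if (object$converged) {
    grid <- tibble(conc_uM = 10^seq(log10(min(dat$conc_uM)),
                                    log10(max(dat$conc_uM)), length.out = 100))
    grid$npi <- object$bottom + (object$top - object$bottom) /
      (1 + 10^((object$log_ic50 - log10(grid$conc_uM)) * object$hill))
    p <- p + geom_line(data = grid)
  }
  p
}

#' Plot phase-normalized temporal IC50 profiles
#'
#' One line per drug; the horizontal reference marks the first-phase
#' anchor (relative IC50 = 1).
#'
#' @param profiles Tibble from [temporal_profile()].
#' @return A ggplot.
#' @export
plot_temporal_profiles <- function(profiles) {
  ggplot(profiles, aes(x = .data$phase_h, y = .data$rel_ic50,
                       colour = .data$drug_id)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_line() + geom_point() +
    labs(x = "Treatment time (h post-dex)", y = "Relative IC50",
         colour = "Drug") +
    theme_minimal()
}

#' Histogram of rhythmic entities by peak-phase bin
#'
#' @param classification A `rhythm_classification` from
#'   [classify_rhythmic()].
#' @return A ggplot.
#' @export
plot_phase_histogram <- function(classification) {
  ggplot(classification$summary,
         aes(x = factor(.data$best_lag), y = .data$n_rhythmic)) +
    geom_col() +
    labs(x = "Peak-phase bin (h)", y = "Rhythmic entities") +
    theme_minimal()
}

#' Plot a reporter trace with its damped-cosine fit
#'
#' @param object A `rhythm_fit` from [fit_damped_cosine()].
#' @param trace The trace that was fitted (`time_h`, `signal`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rhythm_fit <- function(object, trace, ...) {
  trace <- filter(as_tibble(trace), .data$time_h >= object$t0)
  t <- trace$time_h - object$t0
  b <- object$baseline_coeffs
  a <- 2 * pi / object$period
  fitted <- b[1] + b[2] * t + b[3] * t^2 +
    object$amplitude * exp(-object$damping_rate * t) *
      cos(a * (trace$time_h - object$phase))
  ggplot(trace, aes(x = .data$time_h, y = .data$signal)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_line(aes(y = fitted), colour = "red") +
    labs(x = "Time (h)", y = "Bioluminescence",
         title = sprintf("Period %.2f h, amplitude %.3g (%s)",
                         object$period, object$amplitude,
                         if (object$rhythmic) "rhythmic" else "arrhythmic")) +
    theme_minimal()
}

#' Plot normalized tumor growth curves with fitted group slopes
#'
#' @param growth Result of [growth_rates()].
#' @return A ggplot.
#' @export
plot_growth_curves <- function(growth) {
  ggplot(growth$normalized,
         aes(x = .data$day, y = .data$rel_volume, group = .data$mouse_id,
             colour = .data$group)) +
    geom_line(alpha = 0.4) + geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(
      data = growth$rates,
      aes(slope = .data$slope, intercept = .data$intercept,
          colour = .data$group),
      linewidth = 1) +
    labs(x = "Day", y = "Relative tumor volume", colour = "Group") +
    theme_minimal()
}
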