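#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a four-parameter logistic fit
#'
#' @param x A `pl4_fit` from [fit_4pl()].
#' @param ... Unused.
#' @return One-row tibble of the fitted parameters and capping status.
#' @export
tidy.pl4_fit <- function(x, ...) {
  bind_cols(tibble(drug_id = x$drug_id, phase_h = x$phase),
            tidy_pl4_row(x))
}

#' Fit-quality summary of a four-parameter logistic fit
#'
#' @param x A `pl4_fit`.
#' @param ... Unused.
#' @return One-row tibble: `rss`, `sigma` (residual SD), `n`, `converged`.
#' @export
glance.pl4_fit <- function(x, ...) {
  tibble(rss = x$rss,
         sigma = if (is.na(x$rss)) NA_real_ else sqrt(x$rss / max(1, x$n - 4)),
         n = x$n, converged = x$converged)
}

#' @export
print.pl4_fit <- function(x, ...) {
  cat(sprintf("4PL fit%s%s: IC50 = %.4g uM (log10 = %.3f), hill = %.2f, capped = %s\n",
              if (is.na(x$drug_id)) "" else paste0(" [", x$drug_id, "]"),
              if (is.na(x$phase)) "" else sprintf(" phase %g h", x$phase),
              x$ic50, x$log_ic50, if (is.na(x$hill)) NA else x$hill, x$capped))
  invisible(x)
}

#' Tidy a JTK-Cycle test result
#'
#' @param x A `jtk_result` from [jtk_test()].
#' @param ... Unused.
#' @return One-row tibble of the test summary.
#' @export
tidy.jtk_result <- function(x, ...) {
  tibble(entity_id = x$entity_id, period = x$period, best_lag = x$best_lag,
         S = x$S, K = x$K, tau = x$tau, p_exact = x$p_exact,
         p_adj = x$p_adj, n_templates = x$n_templates,
         amplitude = x$amplitude, rhythmic = x$rhythmic, exact = x$exact)
}

#' @export
print.jtk_result <- function(x, ...) {
  cat(sprintf(
    "JTK-Cycle: period %g h, best lag %g h, S = %d/%d, p_adj = %.4g (%s)\n",
    x$period, x$best_lag, x$S, x$K, x$p_adj,
    if (x$rhythmic) "rhythmic" else "not rhythmic"))
  invisible(x)
}

#' Tidy a damped-cosine rhythm fit
#'
#' @param x A `rhythm_fit` from [fit_damped_cosine()].
#' @param ... Unused.
#' @return One-row tibble of the fitted rhythm parameters.
#' @export
tidy.rhythm_fit <- function(x, ...) {
  tibble(period = x$period, amplitude = x$amplitude, phase = x$phase,
         damping_rate = x$damping_rate, gof = x$gof,
         rel_amplitude_error = x$rel_amplitude_error, rhythmic = x$rhythmic)
}

#' Fit-quality summary of a damped-cosine fit
#'
#' @param x A `rhythm_fit`.
#' @param ... Unused.
#' @return One-row tibble: `rss`, `gof`, `n`.
#' @export
glance.rhythm_fit <- function(x, ...) {
  tibble(rss = x$rss, gof = x$gof, n = x$n)
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf(
    "Damped cosinor: period %.2f h, amplitude %.3g, phase %.2f h, damping %.3g /h (%s)\n",
    x$period, x$amplitude, x$phase, x$damping_rate,
    if (x$rhythmic) "rhythmic" else "arrhythmic"))
  invisible(x)
}

#' Tidy a FUCCI synchrony result
#'
#' @param x A `synchrony_result` from [fucci_synchrony()].
#' @param ... Unused.
#' @return One-row tibble of the synchrony metrics.
#' @export
tidy.synchrony_result <- function(x, ...) {
  tibble(dominant_period = x$dominant_period,
         channel_phase_offset = x$channel_phase_offset,
         synchrony_index = x$synchrony_index,
         synchronized = x$synchronized)
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf(
    "FUCCI synchrony: period %.1f h, channel offset %.1f h, index %.2f (%s)\n",
    x$dominant_period, x$channel_phase_offset, x$synchrony_index,
    if (x$synchronized) "synchronized" else "not synchronized"))
  invisible(x)
}
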