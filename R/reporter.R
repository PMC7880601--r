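#' Detrend a reporter trace with a centered moving average
#'
#' Subtracts a centered moving average of the stated window from the
#' signal, the standard pre-processing for luminometer traces before
#' rhythm fitting. Near the endpoints the window shrinks symmetrically so
#' every point keeps a centered estimate; the output has mean approximately
#' zero and a linear trend is removed exactly in the interior.
#'
#' @param trace Tibble with `time_h` and `signal` (uniform grid).
#' @param window Averaging window in hours; should be at least the longest
#'   period of interest.
#' @return The trace with `signal` replaced by its detrended values.
#' @export
detrend_trace <- function(trace, window = 32) {
  trace <- arrange(as_tibble(trace), .data$time_h)
  dt <- unique(round(diff(trace$time_h), 9))
  assert_that(length(dt) == 1, "non-uniform sampling: resample the trace first")
  n <- nrow(trace)
  half <- floor(window / dt / 2)
  assert_that(n > 2 * half, "trace shorter than the detrending window")
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)   # shrink symmetrically at the edges
    mean(trace$signal[(i - h):(i + h)])
  }, numeric(1))
  mutate(trace, signal = .data$signal - sm)
}

# Linear least squares of a damped cosine plus quadratic baseline at fixed
# (period, damping); returns the profiled RSS and linear coefficients.
damped_cosine_profile <- function(t, y, period, damping) {
  e <- exp(-damping * t)
  X <- cbind(1, t, t^2,
             e * cos(2 * pi * t / period),
             e * sin(2 * pi * t / period))
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients,
       residuals = fit$residuals)
}

#' Fit a damped cosine to a bioluminescence reporter trace
#'
#' Model: `signal(t) = b0 + b1 t + b2 t^2 + A exp(-d t) cos(2*pi*(t -
#' phase)/period)`. The fit profiles the linear coefficients (baseline and
#' cosine/sine amplitudes) at fixed `(period, damping)` and searches the
#' nonlinear pair by a 1-h period grid over `period_bounds` refined with
#' bounded quasi-Newton steps. A trace is called rhythmic when the fitted
#' initial amplitude exceeds `k` residual standard deviations and the fit
#' improves the baseline-only RSS by more than 20%.
#'
#' The first hours of a recording (medium-change transient) are excluded
#' by default.
#'
#' @param trace Tibble with `time_h` and `signal` on a uniform grid
#'   spanning at least twice the lower period bound.
#' @param period_bounds Period search range in hours.
#' @param damping_bounds Damping-rate search range per hour.
#' @param k Amplitude threshold in residual SDs for the rhythmic call.
#' @param transient_h Hours discarded from the start of the trace.
#'
#' @return A `rhythm_fit` list: `period`, `amplitude` (at the start of the
#'   fitted window), `phase` (peak time, hours), `damping_rate`,
#'   `baseline_coeffs`, `gof` (relative RSS vs baseline-only),
#'   `rel_amplitude_error`, `rhythmic`, `n`.
#' @export
#' @examples
#' tr <- simulate_reporter(period = 24, amplitude = 80, noise_sd = 4,
#'                         duration = 96, seed = 2)
#' fit_damped_cosine(tr)$period
fit_damped_cosine <- function(trace, period_bounds = c(18, 32),
                              damping_bounds = c(0, 0.2), k = 2,
                              transient_h = 4) {
  trace <- arrange(as_tibble(trace), .data$time_h)
  dt <- unique(round(diff(trace$time_h), 9))
  assert_that(length(dt) == 1, "non-uniform sampling: resample the trace first")
  trace <- filter(trace, .data$time_h >= min(.data$time_h) + transient_h)
  t0 <- min(trace$time_h)
  t <- trace$time_h - t0
  y <- trace$signal
  assert_that(max(t) >= 2 * period_bounds[1],
              "trace shorter than two periods: period not identifiable")

  obj <- function(par) damped_cosine_profile(t, y, par[1], par[2])$rss
  grid <- expand.grid(period = seq(period_bounds[1], period_bounds[2], by = 1),
                      damping = c(0.005, 0.02, 0.08))
  rss_grid <- mapply(function(p, d) obj(c(p, d)), grid$period, grid$damping)
  start <- as.numeric(grid[which.min(rss_grid), ])
  opt <- optim(start, obj, method = "L-BFGS-B",
               lower = c(period_bounds[1], damping_bounds[1]),
               upper = c(period_bounds[2], damping_bounds[2]))
  prof <- damped_cosine_profile(t, y, opt$par[1], opt$par[2])
  cf <- prof$coef
  amp <- sqrt(cf[4]^2 + cf[5]^2)
  phase <- wrap_phase(atan2(cf[5], cf[4]) * opt$par[1] / (2 * pi) + t0,
                      opt$par[1])
  base_fit <- stats::lm.fit(cbind(1, t, t^2), y)
  rss0 <- sum(base_fit$residuals^2)
  gof <- if (rss0 > 0) prof$rss / rss0 else 1
  resid_sd <- sqrt(prof$rss / max(1, length(y) - 5))
  rel_amp_err <- if (amp > 0) resid_sd / amp else Inf

  structure(list(period = opt$par[1], amplitude = unname(amp),
                 phase = unname(phase), damping_rate = opt$par[2],
                 baseline_coeffs = unname(cf[1:3]), rss = prof$rss,
                 gof = gof, rel_amplitude_error = unname(rel_amp_err),
                 rhythmic = amp > k * resid_sd && gof < 0.8,
                 n = length(y), t0 = t0),
            class = "rhythm_fit")
}

#' Compare rhythm parameters between groups of reporter traces
#'
#' Fits each trace with [fit_damped_cosine()], summarizes period and
#' amplitude per group (mean +/- SD), and tests pairwise group differences
#' in means with a seeded permutation test (group labels shuffled).
#' Groups with fewer than `min_n` traces are excluded with a warning.
#'
#' @param traces Long tibble: `entity_id`, `group`, `time_h`, `signal`.
#' @param parameters Which fitted parameters to compare.
#' @param n_perm Number of permutation resamples.
#' @param min_n Minimum traces per group.
#' @param seed Integer seed for the permutation draw.
#' @param ... Passed to [fit_damped_cosine()].
#'
#' @return List with `fits` (per-trace tidy fits), `summary` (per group x
#'   parameter mean/sd/n), and `tests` (pairwise permutation p per
#'   parameter).
#' @export
compare_rhythm_groups <- function(traces, parameters = c("period", "amplitude"),
                                  n_perm = 10000, min_n = 3, seed = 1L, ...) {
  fits <- traces |>
    group_by(.data$entity_id, .data$group) |>
    group_modify(function(df, key) tidy(fit_damped_cosine(df, ...))) |>
    ungroup()

  sizes <- count(fits, .data$group)
  small <- sizes$group[sizes$n < min_n]
  if (length(small)) {
    warn(paste("groups excluded (<", min_n, "traces):",
               paste(small, collapse = ", ")))
    fits <- filter(fits, !.data$group %in% small)
  }

  summary <- fits |>
    tidyr::pivot_longer(all_of(parameters), names_to = "parameter") |>
    group_by(.data$group, .data$parameter) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n = dplyr::n(), .groups = "drop")

  groups <- unique(fits$group)
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2, simplify = FALSE)
           else list()
  tests <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(parameters, function(param) {
      x <- fits[[param]][fits$group == pr[1]]
      y <- fits[[param]][fits$group == pr[2]]
      tibble(group1 = pr[1], group2 = pr[2], parameter = param,
             diff = mean(x) - mean(y),
             p = permutation_p_two_sample(x, y, n_perm = n_perm,
                                          seed = derive_seed(seed, paste(pr, param, collapse = "_"))))
    })
  })
  list(fits = fits, summary = summary, tests = tests)
}

# Two-sided permutation p-value for a difference in group means.
# With identical data in both groups every resample ties the observed
# statistic, giving p = 1.
permutation_p_two_sample <- function(x, y, n_perm = 10000, seed = NULL) {
  obs <- abs(mean(x) - mean(y))
  z <- c(x, y); nx <- length(x)
  with_seed(seed, {
    exceed <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(z), nx)
      abs(mean(z[idx]) - mean(z[-idx])) >= obs - 1e-12
    }, logical(1))
    (1 + sum(exceed)) / (n_perm + 1)
  })
}
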