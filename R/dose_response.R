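#' Fit a variable-slope four-parameter logistic dose-response curve
#'
#' Least-squares fit of `NPI(c) = bottom + (top - bottom) / (1 +
#' 10^((log_ic50 - log10(c)) * hill))` to percent-inhibition data, the model
#' used to summarize each drug x treatment-phase viability series. The fit
#' is multi-started in `log_ic50` (5 starts spaced across the tested
#' log-dose range; best residual sum of squares wins, ties broken toward
#' `|hill - 1|` smallest) under box constraints, and the resulting IC50 is
#' passed through [apply_caps()]: computed values at or beyond 25 uM are
#' assigned 25 uM (inactive/weak compounds), values at or below 0.001 uM
#' are assigned 0.001 uM (dilution failed to titrate activity away).
#' Degenerate data (flat NPI) never raise; they return a non-converged
#' result that is routed through the capping policy (mean NPI < 25: treated
#' inactive; > 75: fully active; otherwise left uncapped and unconverged).
#'
#' @param conc Concentrations in uM (replicated points allowed; >= 4
#'   distinct values required).
#' @param npi Percent-inhibition values matching `conc`.
#' @param drug_id,phase Optional labels carried into the result.
#' @param bounds Named list of `lower`/`upper` numeric vectors over
#'   `(top, bottom, log_ic50, hill)`.
#' @param n_starts Number of log_ic50 starting values.
#'
#' @return An object of class `pl4_fit`: fields `drug_id`, `phase`, `ic50`,
#'   `log_ic50`, `hill`, `top`, `bottom`, `capped` (`"none"`, `"high"`,
#'   `"low"`), `converged`, `rss`, `n`, plus the data. Use [tidy()] /
#'   [glance()] for tabular views.
#' @export
#' @examples
#' d <- dose_ladder(screen_design())
#' y <- 100 / (1 + 10^((-0.5 - log10(d)) * 1.2))
#' fit <- fit_4pl(d, y)
#' fit$log_ic50
fit_4pl <- function(conc, npi, drug_id = NA_character_, phase = NA_real_,
                    bounds = list(lower = c(top = 50, bottom = -20,
                                            log_ic50 = -4, hill = 0.1),
                                  upper = c(top = 120, bottom = 50,
                                            log_ic50 = 3, hill = 5)),
                    n_starts = 5) {
  keep <- is.finite(conc) & is.finite(npi) & conc > 0
  conc <- conc[keep]; npi <- npi[keep]
  assert_that(length(unique(conc)) >= 4,
              ">= 4 distinct concentrations required for 4PL fitting")
  lx <- log10(conc)
  dat <- data.frame(lx = lx, y = npi)

  result <- list(drug_id = drug_id, phase = phase,
                 ic50 = NA_real_, log_ic50 = NA_real_, hill = NA_real_,
                 top = NA_real_, bottom = NA_real_, capped = "none",
                 converged = FALSE, rss = NA_real_, n = length(npi),
                 data = tibble(conc_uM = conc, npi = npi))

  flat <- sd(npi) < 1e-8
  if (!flat) {
    starts <- seq(min(lx), max(lx), length.out = n_starts)
    fits <- lapply(starts, function(s0) {
      tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + 10^((log_ic50 - lx) * hill)),
          data = dat,
          start = list(top = min(max(npi), bounds$upper[["top"]]),
                       bottom = max(min(npi), bounds$lower[["bottom"]]),
                       log_ic50 = s0, hill = 1),
          lower = bounds$lower, upper = bounds$upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits)) {
      rsss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
      hills <- vapply(fits, function(f) abs(coef(f)[["hill"]] - 1), numeric(1))
      best <- fits[[order(round(rsss, 9), hills)[1]]]
      cf <- coef(best)
      result[c("top", "bottom", "log_ic50", "hill")] <-
        as.list(cf[c("top", "bottom", "log_ic50", "hill")])
      result$rss <- sum(residuals(best)^2)
      # a fit whose plateau separation is negligible carries no dose
      # information; treat as non-converged so capping policy applies
      result$converged <- abs(cf[["top"]] - cf[["bottom"]]) > 5
      result$ic50 <- 10^cf[["log_ic50"]]
    }
  }

  capped <- apply_caps(ic50 = result$ic50, converged = result$converged,
                       mean_npi = mean(npi))
  result$ic50 <- capped$ic50
  result$capped <- capped$capped
  if (!is.na(result$ic50)) result$log_ic50 <- log10(result$ic50)
  structure(result, class = "pl4_fit")
}

#' Cap out-of-range IC50 estimates
#'
#' Codifies the manual assignment rule for compounds whose fitted IC50
#' extrapolates outside the tested concentration range: computed IC50 >= 25
#' uM (or a non-converged, inactive curve with mean NPI < 25%) is assigned
#' 25 uM; computed IC50 <= 0.001 uM (or a non-converged, fully active curve
#' with mean NPI > 75%) is assigned 0.001 uM. In-range estimates pass
#' through unchanged. Idempotent.
#'
#' @param ic50 Computed IC50 in uM (may be `NA` when the fit failed).
#' @param converged Did the 4PL fit converge with a usable dose response?
#' @param mean_npi Mean NPI of the curve, used only for non-converged data.
#' @return List with `ic50` and `capped` (`"none"`, `"high"`, `"low"`).
#' @export
#' @examples
#' apply_caps(30)      # capped high at 25
#' apply_caps(4e-4)    # capped low at 0.001
#' apply_caps(1.7)     # unchanged
apply_caps <- function(ic50, converged = TRUE, mean_npi = NA_real_) {
  if (!isTRUE(converged)) {
    if (!is.na(mean_npi) && mean_npi < 25)
      return(list(ic50 = 25, capped = "high"))
    if (!is.na(mean_npi) && mean_npi > 75)
      return(list(ic50 = 0.001, capped = "low"))
    return(list(ic50 = NA_real_, capped = "none"))
  }
  if (is.na(ic50)) return(list(ic50 = NA_real_, capped = "none"))
  if (ic50 >= 25) return(list(ic50 = 25, capped = "high"))
  if (ic50 <= 0.001) return(list(ic50 = 0.001, capped = "low"))
  list(ic50 = ic50, capped = "none")
}

#' Fit IC50s for every drug x phase in an NPI table
#'
#' Replicate wells enter the fit as individual points (no pre-averaging),
#' so better-replicated concentrations carry proportionally more weight.
#'
#' @param npi_tab NPI-annotated test-well table from [qc_and_normalize()]:
#'   columns `drug_id`, `phase_h`, `conc_uM`, `npi` (and `replicate` when
#'   fitting per replicate).
#' @param by_replicate Fit one curve per replicate instead of pooling
#'   replicate wells into a single curve. Per-replicate fits preserve the
#'   replicate structure needed by downstream rhythm testing on the
#'   resulting temporal profiles.
#' @param ... Passed to [fit_4pl()].
#' @return Tibble with one row per drug x phase (x replicate): the
#'   `pl4_fit` fields.
#' @export
fit_ic50 <- function(npi_tab, by_replicate = FALSE, ...) {
  keys <- c("drug_id", "phase_h", if (by_replicate) "replicate")
  assert_that(all(keys %in% names(npi_tab)),
              paste("NPI table must contain:", paste(keys, collapse = ", ")))
  npi_tab |>
    group_by(across(all_of(keys))) |>
    group_modify(function(df, key) {
      f <- fit_4pl(df$conc_uM, df$npi, drug_id = key$drug_id,
                   phase = key$phase_h, ...)
      tidy_pl4_row(f)
    }) |>
    ungroup()
}

tidy_pl4_row <- function(f) {
  tibble(ic50 = f$ic50, log_ic50 = f$log_ic50, hill = f$hill,
         top = f$top, bottom = f$bottom, capped = f$capped,
         converged = f$converged, rss = f$rss, n = f$n)
}

#' Phase-normalized temporal IC50 profile
#'
#' Expresses a drug's IC50 at each treatment phase as a ratio to its IC50
#' at the first phase (the 24 h post-dex anchor), the normalization used
#' for time-of-day efficacy heatmaps. Missing interior phases are flagged
#' (`complete = FALSE`), never interpolated; a missing first phase is an
#' error because the profile has no anchor.
#'
#' @param ic50_tab IC50 table from [fit_ic50()] for one drug, or several
#'   drugs (profiled independently): columns `drug_id`, `phase_h`, `ic50`,
#'   optionally `replicate` (each replicate series is then anchored to its
#'   own first-phase IC50).
#' @param phases Expected phase grid; defaults to the phases present.
#' @return Tibble: `drug_id` (and `replicate` if supplied), `phase_h`,
#'   `ic50`, `rel_ic50` (first phase = 1 exactly), `complete`.
#' @export
temporal_profile <- function(ic50_tab, phases = NULL) {
  keys <- intersect(c("drug_id", "replicate"), names(ic50_tab))
  ic50_tab |>
    group_by(across(all_of(keys))) |>
    group_modify(function(df, key) {
      ph <- phases %||% sort(unique(df$phase_h))
      assert_that(length(ph) >= 3, ">= 3 phases required for a profile")
      df <- df |> filter(!is.na(.data$ic50)) |> arrange(.data$phase_h)
      anchor <- df$ic50[df$phase_h == ph[1]]
      if (length(anchor) != 1)
        abort(sprintf("drug %s: first-phase IC50 absent, no anchor for normalization",
                      key$drug_id))
      complete <- all(ph %in% df$phase_h)
      tibble(phase_h = df$phase_h, ic50 = df$ic50,
             rel_ic50 = df$ic50 / anchor, complete = complete)
    }) |>
    ungroup()
}

#' Peak-phase bin of a temporal IC50 profile
#'
#' Returns the treatment phase at which the normalized IC50 profile is
#' maximal, among the non-anchor phases (the anchor phase is 1 by
#' construction and cannot be a peak candidate). Ties break toward the
#' earlier phase.
#'
#' @param profile Profile tibble from [temporal_profile()] (one drug;
#'   replicate profiles are averaged per phase first).
#' @return The peak phase in hours.
#' @export
peak_phase_bin <- function(profile) {
  assert_that(all(profile$complete %||% TRUE), "profile must be complete")
  avg <- profile |>
    group_by(.data$phase_h) |>
    summarise(rel_ic50 = mean(.data$rel_ic50), .groups = "drop") |>
    arrange(.data$phase_h)
  cand <- avg[-1, ]  # drop the normalization anchor
  cand$phase_h[which.max(cand$rel_ic50)]
}
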