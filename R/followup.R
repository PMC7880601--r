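#' Caliper tumor volume
#'
#' Standard ellipsoid approximation for subcutaneous tumors measured with
#' a digital caliper: `length * width^2 / 2` (mm^3). By the caliper
#' convention length is the longer dimension; swapped inputs are corrected
#' with a warning.
#'
#' @param length_mm,width_mm Caliper dimensions in mm (positive).
#' @return Volume in mm^3 (vectorized).
#' @export
#' @examples
#' tumor_volume(10, 5)  # 125
tumor_volume <- function(length_mm, width_mm) {
  assert_that(all(length_mm > 0) && all(width_mm > 0),
              "caliper dimensions must be positive")
  swapped <- width_mm > length_mm
  if (any(swapped)) {
    warn("width > length: dimensions swapped to the caliper convention")
    tmp <- length_mm[swapped]
    length_mm[swapped] <- width_mm[swapped]
    width_mm[swapped] <- tmp
  }
  length_mm * width_mm^2 / 2
}

#' FUCCI cell-cycle synchrony metrics
#'
#' Quantifies how coherently a cell population traverses the cell cycle
#' from two-channel FUCCI fraction series (red = G1, green = S-G2-M). The
#' dominant period comes from the detrended red channel's periodogram peak
#' within the plausible cell-cycle band; the synchrony index is the
#' spectral power at that frequency divided by the total band power (1 =
#' pure oscillation, ~0 = no rhythm); the channel phase offset is the lag
#' maximizing the circular cross-correlation between channels. A
#' population is called synchronized when the index reaches the threshold
#' and the offset is antiphasic (within the stated tolerance of half a
#' period). Flat or noise-only channels yield an index near 0 and
#' `synchronized = FALSE` without error.
#'
#' @param fucci Tibble: `time_h`, `red_fraction`, `green_fraction` on a
#'   uniform grid spanning at least two putative cell-cycle periods.
#' @param band Period band searched for the dominant frequency, hours.
#' @param index_threshold Minimum synchrony index.
#' @param antiphase_tol Offset tolerance as a fraction of the period.
#'
#' @return A `synchrony_result` list: `dominant_period`,
#'   `channel_phase_offset`, `synchrony_index`, `synchronized`.
#' @export
fucci_synchrony <- function(fucci, band = c(8, 48), index_threshold = 0.5,
                            antiphase_tol = 0.25) {
  fucci <- arrange(as_tibble(fucci), .data$time_h)
  dt <- unique(round(diff(fucci$time_h), 9))
  assert_that(length(dt) == 1, "non-uniform sampling")
  n <- nrow(fucci)
  assert_that(n * dt >= 2 * band[1],
              "series shorter than two cell-cycle periods")

  red <- fucci$red_fraction - mean(fucci$red_fraction)
  green <- fucci$green_fraction - mean(fucci$green_fraction)

  spec <- Mod(fft(red))^2 / n
  freq <- seq(0, n - 1) / (n * dt)           # cycles per hour
  half <- 2:floor(n / 2)                     # positive frequencies
  periods <- 1 / freq[half]
  in_band <- periods >= band[1] & periods <= band[2]
  if (!any(in_band) || sum(spec[half][in_band]) == 0) {
    return(structure(list(dominant_period = NA_real_,
                          channel_phase_offset = NA_real_,
                          synchrony_index = 0, synchronized = FALSE),
                     class = "synchrony_result"))
  }
  band_power <- spec[half][in_band]
  k <- which.max(band_power)
  dominant_period <- periods[in_band][k]
  synchrony_index <- band_power[k] / sum(band_power)

  # circular cross-correlation between channels at lags over one period
  lags <- seq(0, floor(dominant_period / dt) - 1)
  cc <- vapply(lags, function(L) {
    sum(red * green[((seq_len(n) - 1 + L) %% n) + 1])
  }, numeric(1))
  offset <- lags[which.max(cc)] * dt

  antiphase <- abs(circ_diff(offset, dominant_period / 2, dominant_period)) <=
    antiphase_tol * dominant_period
  structure(list(dominant_period = dominant_period,
                 channel_phase_offset = offset,
                 synchrony_index = unname(synchrony_index),
                 synchronized = synchrony_index >= index_threshold && antiphase),
            class = "synchrony_result")
}

#' Tumor growth rates from normalized volume curves
#'
#' Each mouse's volumes are normalized to its day-0 value; the per-group
#' relative growth rate is the ordinary least-squares slope through the
#' pooled normalized points (relative volume per day), as used for
#' treatment-timing comparisons of xenograft growth. Pairwise group
#' contrasts use a seeded permutation test that shuffles mouse labels
#' between groups (slopes refitted per resample), keeping within-mouse
#' correlation intact. Mice without a day-0 measurement are excluded with
#' a warning. A per-mouse variant (slope per mouse, then group mean) is
#' available.
#'
#' @param tumors Tibble: `mouse_id`, `group`, `day`, and either
#'   `volume_mm3` or caliper columns `length_mm`/`width_mm` (converted via
#'   [tumor_volume()]).
#' @param method `"pooled"` (default) or `"per_mouse"`.
#' @param log_scale Fit `log(relative volume)` instead of the relative
#'   volume itself. The default linear fit follows the normalized-data
#'   convention of treatment-timing figures; the log-linear flag recovers
#'   the exponential growth-rate (per day) directly and so estimates rate
#'   ratios without the convexity bias of a linear slope through an
#'   exponential arc.
#' @param n_perm Permutation resamples for group contrasts.
#' @param compare Run the pairwise permutation contrasts (disable for
#'   rate-only use, e.g. parameter-recovery studies).
#' @param seed Integer seed.
#'
#' @return List: `rates` (per group: `slope`, `intercept`, `ci_low`,
#'   `ci_high`, `n_mice`), `comparisons` (pairwise permutation p-values),
#'   `normalized` (the normalized data used).
#' @export
growth_rates <- function(tumors, method = c("pooled", "per_mouse"),
                         log_scale = FALSE, n_perm = 10000, compare = TRUE,
                         seed = 1L) {
  method <- match.arg(method)
  tumors <- as_tibble(tumors)
  if (!"volume_mm3" %in% names(tumors))
    tumors$volume_mm3 <- tumor_volume(tumors$length_mm, tumors$width_mm)

  baseline <- tumors |>
    filter(.data$day == min(.data$day)) |>
    select("mouse_id", v0 = "volume_mm3")
  missing <- setdiff(unique(tumors$mouse_id), baseline$mouse_id)
  if (length(missing))
    warn(paste("mice without a day-0 measurement excluded:",
               paste(missing, collapse = ", ")))
  norm <- tumors |>
    inner_join(baseline, by = "mouse_id") |>
    mutate(rel_volume = .data$volume_mm3 / .data$v0)
  if (log_scale) norm$rel_volume <- log(norm$rel_volume)

  grp_sizes <- norm |> distinct(.data$group, .data$mouse_id) |>
    count(.data$group)
  assert_that(all(grp_sizes$n >= 2), "each group needs >= 2 mice")

  fit_slope <- function(df) {
    if (method == "pooled") {
      f <- lm(rel_volume ~ day, data = df)
      ci <- stats::confint(f)["day", ]
      tibble(slope = coef(f)[["day"]], intercept = coef(f)[["(Intercept)"]],
             ci_low = ci[1], ci_high = ci[2],
             n_mice = dplyr::n_distinct(df$mouse_id))
    } else {
      per <- df |> group_by(.data$mouse_id) |>
        summarise(s = coef(lm(rel_volume ~ day,
                              data = pick(everything())))[["day"]],
                  .groups = "drop")
      se <- sd(per$s) / sqrt(nrow(per))
      tibble(slope = mean(per$s), intercept = NA_real_,
             ci_low = mean(per$s) - 1.96 * se,
             ci_high = mean(per$s) + 1.96 * se, n_mice = nrow(per))
    }
  }

  rates <- norm |> group_by(.data$group) |>
    group_modify(function(df, key) fit_slope(df)) |> ungroup()

  slope_of <- function(df) coef(lm(rel_volume ~ day, data = df))[["day"]]
  groups <- unique(norm$group)
  pairs <- if (compare && length(groups) >= 2)
             utils::combn(groups, 2, simplify = FALSE) else list()
  comparisons <- purrr::map_dfr(pairs, function(pr) {
    sub <- filter(norm, .data$group %in% pr)
    mice <- distinct(sub, .data$mouse_id, .data$group)
    obs <- abs(slope_of(filter(sub, .data$group == pr[1])) -
                 slope_of(filter(sub, .data$group == pr[2])))
    p <- with_seed(derive_seed(seed, paste(pr, collapse = "_")), {
      exceed <- vapply(seq_len(n_perm), function(i) {
        relab <- mice; relab$group <- sample(relab$group)
        s2 <- sub |> select(-"group") |>
          inner_join(relab, by = "mouse_id")
        abs(slope_of(filter(s2, .data$group == pr[1])) -
              slope_of(filter(s2, .data$group == pr[2]))) >= obs - 1e-12
      }, logical(1))
      (1 + sum(exceed)) / (n_perm + 1)
    })
    tibble(group1 = pr[1], group2 = pr[2], diff_slope = obs, p = p)
  })

  list(rates = rates, comparisons = comparisons, normalized = norm)
}
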