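test_that("tumor_volume implements the caliper ellipsoid formula", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(2, 1), 1)
  w <- 3.7
  expect_equal(tumor_volume(w, w), w^3 / 2)
  # homogeneous of degree 3 under uniform scaling
  expect_equal(tumor_volume(2 * 10, 2 * 5), 8 * tumor_volume(10, 5))
  expect_warning(v <- tumor_volume(5, 10), "swapped")
  expect_equal(v, 125)
  expect_error(tumor_volume(0, 1), "positive")
})

test_that("fucci_synchrony recognizes a coherent antiphasic population", {
  f <- simulate_fucci(period = 24, duration = 96, dt = 1, noise_sd = 0)
  res <- fucci_synchrony(f)
  expect_equal(res$dominant_period, 24, tolerance = 0.1)
  expect_gt(res$synchrony_index, 0.9)
  expect_equal(abs(circ_diff(res$channel_phase_offset, 12, 24)), 0,
               tolerance = 1.01)
  expect_true(res$synchronized)
  # affine rescaling of the fractions leaves the index unchanged
  f2 <- dplyr::mutate(f, red_fraction = 0.5 * red_fraction + 0.2,
                      green_fraction = 0.5 * green_fraction + 0.2)
  res2 <- fucci_synchrony(f2)
  expect_equal(res2$synchrony_index, res$synchrony_index, tolerance = 1e-9)
})

test_that("phase-jittered populations lose synchrony and white noise is
           never called synchronized", {
  f <- simulate_fucci(period = 24, duration = 96, dt = 1,
                      phase_jitter_sd = 8, seed = 2)  # period/3 jitter
  expect_lt(fucci_synchrony(f)$synchrony_index, 0.3)
  n_sync <- sum(vapply(1:40, function(s) {
    noise <- withr::with_seed(s, tibble::tibble(
      time_h = seq(0, 96), red_fraction = runif(97),
      green_fraction = runif(97)))
    fucci_synchrony(noise)$synchronized
  }, logical(1)))
  expect_lte(n_sync, 2)
})

test_that("growth_rates recovers noise-free kinetics and honors
           normalization", {
  g <- tibble::tibble(group = c("ctl", "trt"), n_mice = 3,
                      baseline_volume = c(100, 250), growth_rate = 0.2,
                      treatment_effect = c(1, 0.5))
  tab <- simulate_tumors(g, days = 0:7, noise_cv = 0, seed = 1)
  res <- growth_rates(tab, compare = FALSE)
  # analytic oracle: OLS slope of the exponential arc exp(r * d) over the
  # measured days, computed in closed form
  ols_slope <- function(r, d = 0:7) {
    y <- exp(r * d)
    sum((d - mean(d)) * y) / sum((d - mean(d))^2)
  }
  r_ctl <- res$rates$slope[res$rates$group == "ctl"]
  r_trt <- res$rates$slope[res$rates$group == "trt"]
  expect_equal(r_ctl, ols_slope(0.2), tolerance = 1e-9)
  expect_equal(r_trt, ols_slope(0.1), tolerance = 1e-9)
  # the first-day increment exp(r) - 1 underestimates the 7-day linear
  # slope of the arc; the fitted slope must sit between the arc's first-
  # and last-day increments
  expect_gt(r_ctl, exp(0.2) - 1)
  expect_lt(r_ctl, exp(0.2 * 7) - exp(0.2 * 6))
  # normalization removes the baseline: scaling volumes changes nothing
  tab2 <- dplyr::mutate(tab, volume_mm3 = volume_mm3 * 17)
  res2 <- growth_rates(tab2, compare = FALSE)
  expect_equal(res2$rates$slope, res$rates$slope, tolerance = 1e-12)
  # CI contains the slope
  expect_true(all(res$rates$ci_low <= res$rates$slope &
                    res$rates$slope <= res$rates$ci_high))
})

test_that("growth_rates accepts caliper dimensions and flags missing day 0", {
  tab <- tidyr::expand_grid(mouse_id = c("m1", "m2", "m3"), group = "g",
                            day = 0:4) |>
    dplyr::mutate(length_mm = 8 + day, width_mm = 4 + 0.5 * day)
  res <- growth_rates(tab, compare = FALSE)
  expect_gt(res$rates$slope, 0)
  tab_missing <- dplyr::filter(tab, !(mouse_id == "m3" & day == 0))
  expect_warning(res_m <- growth_rates(tab_missing, compare = FALSE), "m3")
  expect_equal(res_m$rates$n_mice, 2)
})

test_that("group contrast finds a halved growth rate and stays quiet under
           the null", {
  g <- tibble::tibble(group = c("ctl", "trt"), n_mice = 6,
                      baseline_volume = 100, growth_rate = 0.2,
                      treatment_effect = c(1, 0.5))
  tab <- simulate_tumors(g, days = 0:7, noise_cv = 0.15, seed = 5)
  res <- growth_rates(tab, n_perm = 400, seed = 1)
  expect_lt(res$comparisons$p, 0.05)
  null_sig <- vapply(1:25, function(s) {
    gn <- dplyr::mutate(g, treatment_effect = 1)
    tabn <- simulate_tumors(gn, days = 0:7, noise_cv = 0.15, seed = 500 + s)
    growth_rates(tabn, n_perm = 200, seed = s)$comparisons$p < 0.05
  }, logical(1))
  expect_lte(mean(null_sig), 0.2)
})
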