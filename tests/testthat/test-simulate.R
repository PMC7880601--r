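test_that("dose ladder reproduces the eight-point threefold dilution series", {
  d <- dose_ladder(screen_design())
  expect_length(d, 8)
  expect_equal(d[1], 10)
  expect_equal(d[2] / d[3], 3)
  # printed series ends at 4.6 nM (2 significant figures)
  expect_equal(signif(d[8] * 1000, 2), 4.6)
})

test_that("simulate_screen is deterministic and structurally sound", {
  des <- screen_design()
  drugs <- drug_panel(c("a", "b"), c(-0.5, 0), c(0.3, 0), c(12, 0))
  sc <- scenario("wildtype", seed = 11)
  t1 <- simulate_screen(des, drugs, sc)
  t2 <- simulate_screen(des, drugs, sc)
  expect_identical(t1, t2)
  expect_true(all(t1$signal >= 0))
  # one record per well: no duplicated addresses within a plate
  expect_false(any(duplicated(t1[, c("plate_id", "well")])))
  # test wells have drug and dose, controls have neither
  expect_true(all(!is.na(t1$drug_id[t1$role == "test"])))
  expect_true(all(is.na(t1$conc_uM[t1$role != "test"])))
  # every phase is represented
  expect_setequal(unique(t1$phase_h), des$phases)
})

test_that("noise-free screen signals are monotone in dose and flat for
           zero-amplitude drugs", {
  des <- screen_design()
  drugs <- drug_panel(c("rhy", "flat"), c(-0.5, -0.5), c(0.3, 0), c(12, 0))
  sc <- scenario("wildtype", noise_cv = 0, seed = 1)
  tab <- simulate_screen(des, drugs, sc)
  tw <- dplyr::filter(tab, role == "test", replicate == 1)
  # inhibitor: signal non-increasing as concentration rises
  by_curve <- dplyr::group_by(tw, drug_id, phase_h)
  mono <- dplyr::summarise(
    by_curve,
    ok = all(diff(signal[order(conc_uM)]) <= 1e-9), .groups = "drop")
  expect_true(all(mono$ok))
  # zero-amplitude drug: identical expected signal across all phases
  flat <- dplyr::filter(tw, drug_id == "flat")
  spread <- dplyr::summarise(dplyr::group_by(flat, conc_uM),
                             d = diff(range(signal)), .groups = "drop")
  expect_true(all(spread$d < 1e-9))
})

test_that("clock-knockout and cell-cycle-arrest scenarios abolish phase
           dependence but keep the dose response", {
  des <- screen_design()
  drugs <- drug_panel("a", -0.5, 0.4, 12)
  for (nm in c("clock_ko", "cc_arrest")) {
    tab <- simulate_screen(des, drugs, scenario(nm, noise_cv = 0, seed = 1))
    tw <- dplyr::filter(tab, role == "test", replicate == 1)
    spread <- dplyr::summarise(dplyr::group_by(tw, conc_uM),
                               d = diff(range(signal)), .groups = "drop")
    expect_true(all(spread$d < 1e-9), label = nm)
    expect_gt(diff(range(tw$signal)), 10)  # dose dependence intact
  }
})

test_that("simulate_expression honors the cosine mean structure and rejects
           amplitudes that allow negative expression", {
  genes <- tibble::tibble(gene_id = "g", mesor = 100, rel_amplitude = 0,
                          peak_phase = 0)
  e0 <- simulate_expression(genes, c(0, 6, 12, 18), 2, noise_cv = 0, seed = 1)
  expect_true(all(abs(e0$value - 100) < 1e-9))
  genes$rel_amplitude <- 0.4
  e1 <- simulate_expression(genes, c(0, 6, 12, 18), 1, noise_cv = 0, seed = 1)
  expect_equal(which.max(e1$value), 1)   # peak at phase 0
  expect_equal(which.min(e1$value), 3)   # trough at 12 h
  genes$rel_amplitude <- 1.2
  expect_error(simulate_expression(genes, c(0, 6, 12, 18)), "rel_amplitude")
})

test_that("simulate_reporter enforces identifiability and matches its model", {
  expect_error(simulate_reporter(period = 24, duration = 40), "two periods")
  tr <- simulate_reporter(period = 24, amplitude = 50, damping_rate = 0.01,
                          phase = 6, baseline = c(100, -0.1),
                          duration = 96, dt = 1, noise_sd = 0)
  t <- tr$time_h
  expect_equal(tr$signal,
               100 - 0.1 * t + 50 * exp(-0.01 * t) * cos(2 * pi * (t - 6) / 24))
})

test_that("simulate_fucci builds antiphasic raised cosines and rejects
           undersampling", {
  expect_error(simulate_fucci(period = 20, dt = 6), "undersampled")
  f <- simulate_fucci(period = 24, duration = 96, dt = 1, noise_sd = 0)
  expect_true(all(f$red_fraction >= 0 & f$red_fraction <= 1))
  # antiphase construction: green is red shifted by half a period
  shift <- 12  # samples at dt = 1
  n <- nrow(f)
  expect_equal(f$green_fraction[(shift + 1):n], f$red_fraction[1:(n - shift)],
               tolerance = 1e-9)
})

test_that("simulate_tumors recovers exact exponential kinetics without noise", {
  g <- tibble::tibble(group = "t", n_mice = 3, baseline_volume = 100,
                      growth_rate = 0.2, treatment_effect = 0.5)
  tab <- simulate_tumors(g, days = 0:7, noise_cv = 0, seed = 1)
  m1 <- dplyr::filter(tab, mouse_id == "t_m1")
  fit <- lm(log(volume_mm3) ~ day, data = m1)
  expect_equal(unname(coef(fit)[2]), 0.1, tolerance = 1e-9)
  expect_error(simulate_tumors(dplyr::mutate(g, n_mice = 1)), ">= 2 mice")
})

test_that("write_sim_table writes the table and a metadata sidecar", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(x = 1:3, y = letters[1:3])
  write_sim_table(tab, path, meta = list(scenario = "wildtype", seed = 1))
  back <- read_plate_table(path)
  expect_equal(back$x, 1:3)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$scenario, "wildtype")
})
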