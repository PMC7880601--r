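#' Screen design for a staggered-synchronization chronopharmacology screen
#'
#' Describes the plate/dose layout of a time-of-day drug screen in which
#' groups of circadian-synchronized cells are treated at staggered times
#' after dexamethasone stimulation. The defaults reproduce the canonical
#' design: five treatment phases at 6-h spacing (24-48 h post-dex),
#' eight-point threefold dilutions from 10 uM, three replicate wells,
#' 384-well plates with column 1 solvent (DMSO) and column 2 positive
#' (doxorubicin full-kill) controls.
#'
#' @param phases Treatment times in hours post-synchronization, strictly
#'   increasing.
#' @param n_doses Number of points in the serial dilution (>= 2).
#' @param top_dose Highest tested concentration in uM (> 0).
#' @param dilution_factor Fold-change between adjacent doses (> 1).
#' @param n_replicates Replicate wells per drug x dose x phase.
#' @param plate_format Wells per plate, 384 (16 x 24) or 96 (8 x 12).
#' @param control_cols Named integer vector mapping plate columns to control
#'   roles; names are roles (`solvent`, `positive`).
#'
#' @return A `screen_design` list.
#' @export
#' @examples
#' d <- screen_design()
#' dose_ladder(d)
screen_design <- function(phases = c(24, 30, 36, 42, 48),
                          n_doses = 8,
                          top_dose = 10,
                          dilution_factor = 3,
                          n_replicates = 3,
                          plate_format = 384,
                          control_cols = c(solvent = 1, positive = 2)) {
  assert_that(length(phases) >= 1 && all(diff(phases) > 0),
              "`phases` must be strictly increasing")
  assert_that(n_doses >= 2, "`n_doses` must be >= 2")
  assert_that(top_dose > 0, "`top_dose` must be positive")
  assert_that(dilution_factor > 1, "`dilution_factor` must exceed 1")
  assert_that(plate_format %in% c(96, 384),
              "`plate_format` must be 96 or 384")
  assert_that(all(names(control_cols) %in% c("solvent", "positive")),
              "control roles must be 'solvent' or 'positive'")
  structure(
    list(phases = as.numeric(phases), n_doses = as.integer(n_doses),
         top_dose = top_dose, dilution_factor = dilution_factor,
         n_replicates = as.integer(n_replicates),
         plate_format = as.integer(plate_format),
         control_cols = control_cols),
    class = "screen_design")
}

#' Serial-dilution concentration ladder of a screen design
#'
#' @param design A [screen_design()].
#' @return Numeric vector of concentrations in uM, highest first.
#' @export
dose_ladder <- function(design) {
  design$top_dose / design$dilution_factor^(seq_len(design$n_doses) - 1)
}

#' Ground-truth drug panel for simulation
#'
#' Each row defines one compound's generative truth: its mid-range log10
#' IC50, the fractional amplitude by which log-IC50 oscillates over the
#' circadian day, the circadian phase (hours, [0, 24)) of maximal IC50
#' (least efficacy), its Hill slope, and a comma-separated list of target
#' genes.
#'
#' @param drug_id Character identifiers.
#' @param mid_log_ic50 Mid-line log10 IC50 (log10 uM).
#' @param rel_amplitude Oscillation amplitude of log-IC50 (>= 0; 0 defines a
#'   non-rhythmic drug).
#' @param peak_phase Circadian phase of peak IC50, hours; wrapped mod 24.
#' @param hill Hill slope (>= 0.5).
#' @param targets Comma-separated gene symbols per drug (uppercased).
#'
#' @return A tibble with class `drug_panel`.
#' @export
drug_panel <- function(drug_id, mid_log_ic50, rel_amplitude = 0,
                       peak_phase = 0, hill = 1, targets = NA_character_) {
  assert_that(length(drug_id) >= 1, "empty drug list")
  assert_that(all(rel_amplitude >= 0), "`rel_amplitude` must be >= 0")
  assert_that(all(hill >= 0.5), "`hill` must be >= 0.5")
  out <- tibble(
    drug_id = as.character(drug_id),
    mid_log_ic50 = as.numeric(mid_log_ic50),
    rel_amplitude = rep_len(as.numeric(rel_amplitude), length(drug_id)),
    peak_phase = wrap_phase(rep_len(as.numeric(peak_phase), length(drug_id))),
    hill = rep_len(as.numeric(hill), length(drug_id)),
    targets = toupper(rep_len(as.character(targets), length(drug_id))))
  class(out) <- c("drug_panel", class(out))
  out
}

#' Simulation scenario
#'
#' Names the biological condition being emulated. `wildtype` cells carry an
#' intact circadian clock; `clock_ko` (e.g. BMAL1-null) cells have no
#' cell-autonomous oscillation, so every rhythm amplitude is forced to zero;
#' `cc_arrest` (cell-cycle-arrested) cells keep their dose response but lose
#' the phase dependence of drug efficacy.
#'
#' @param name One of `"wildtype"`, `"clock_ko"`, `"cc_arrest"`.
#' @param clock_amplitude_scale Multiplier in `[0, 1]` applied to all rhythm
#'   amplitudes (forced to 0 for the two arrhythmic scenarios).
#' @param noise_cv Coefficient of variation of the multiplicative well noise.
#' @param seed Integer RNG seed.
#'
#' @return A `scenario` list.
#' @export
scenario <- function(name = c("wildtype", "clock_ko", "cc_arrest"),
                     clock_amplitude_scale = 1, noise_cv = 0.05,
                     seed = 1L) {
  name <- match.arg(name)
  assert_that(clock_amplitude_scale >= 0 && clock_amplitude_scale <= 1,
              "`clock_amplitude_scale` must lie in [0, 1]")
  assert_that(noise_cv >= 0, "`noise_cv` must be >= 0")
  if (name %in% c("clock_ko", "cc_arrest")) clock_amplitude_scale <- 0
  structure(list(name = name,
                 clock_amplitude_scale = clock_amplitude_scale,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "scenario")
}

# Expected (noise-free) viability fraction of a test well under the 4PL
# truth: phase-dependent log-IC50 with cosine modulation.
true_log_ic50 <- function(drug, phase_h, amplitude_scale = 1) {
  drug$mid_log_ic50 + amplitude_scale * drug$rel_amplitude *
    cos(2 * pi * (wrap_phase(phase_h) - drug$peak_phase) / 24)
}

viability_fraction <- function(conc, log_ic50, hill) {
  1 / (1 + 10^((log10(conc) - log_ic50) * hill))
}

well_label <- function(row, col) sprintf("%s%02d", LETTERS[row + 1L], col + 1L)

#' Simulate a staggered-phase viability screen
#'
#' Generates one plate table row per well. Test-well expected signal follows
#' a four-parameter logistic in log concentration whose log-IC50 equals
#' `mid_log_ic50 + rel_amplitude * cos(2*pi*(phase - peak_phase)/24)`, the
#' amplitude scaled by the scenario; solvent wells sit at the full-viability
#' mean and positive-control wells at the full-kill mean. Noise is
#' multiplicative lognormal with the scenario's CV. Identical inputs and
#' seed give an identical table.
#'
#' @param design A [screen_design()].
#' @param drugs A [drug_panel()].
#' @param scen A [scenario()].
#' @param solvent_mean,positive_mean Expected raw signal of solvent
#'   (full-viability) and positive-control (full-kill) wells.
#'
#' @return A tibble of well records: `plate_id`, `well`, `row`, `col`,
#'   `role`, `drug_id`, `conc_uM`, `replicate`, `phase_h`, `signal`.
#' @export
#' @examples
#' tab <- simulate_screen(screen_design(),
#'                        drug_panel("drugA", -0.5, 0.3, 12),
#'                        scenario("wildtype", seed = 1))
#' dplyr::count(tab, role)
simulate_screen <- function(design, drugs, scen,
                            solvent_mean = 100, positive_mean = 5) {
  assert_that(inherits(design, "screen_design"), "`design` must be a screen_design")
  assert_that(nrow(drugs) >= 1, "empty drug list")
  assert_that(inherits(scen, "scenario"), "`scen` must be a scenario")
  assert_that(all(drugs$peak_phase >= 0 & drugs$peak_phase < 24),
              "drug peak phases must lie in [0, 24)")

  doses <- dose_ladder(design)
  n_rows <- if (design$plate_format == 384) 16L else 8L
  n_cols <- if (design$plate_format == 384) 24L else 12L
  test_cols <- setdiff(seq_len(n_cols), design$control_cols)
  wells_per_drug <- design$n_doses * design$n_replicates
  drugs_per_plate <- max(1L, (n_rows * length(test_cols)) %/% wells_per_drug)

  with_seed(scen$seed, {
    tabs <- lapply(design$phases, function(phase_h) {
      n_plates <- ceiling(nrow(drugs) / drugs_per_plate)
      plate_tabs <- lapply(seq_len(n_plates), function(p) {
        plate_id <- sprintf("P%02.0f_%d", phase_h, p)
        idx <- seq((p - 1) * drugs_per_plate + 1,
                   min(p * drugs_per_plate, nrow(drugs)))
        dsub <- drugs[idx, ]
        # controls fill the designated columns top to bottom
        ctrl <- purrr::imap_dfr(as.list(design$control_cols), function(cc, rl) {
          tibble(plate_id = plate_id,
                 row = seq_len(n_rows) - 1L, col = as.integer(cc) - 1L,
                 role = rl, drug_id = NA_character_, conc_uM = NA_real_,
                 phase_h = phase_h,
                 mu = if (rl == "solvent") solvent_mean else positive_mean)
        })
        # test wells: drugs laid out in row-major blocks over test columns
        tw <- tidyr::expand_grid(drug_id = dsub$drug_id,
                                 conc_uM = doses,
                                 rep = seq_len(design$n_replicates))
        slot <- seq_len(nrow(tw)) - 1L
        tw$row <- slot %/% length(test_cols)
        tw$col <- test_cols[slot %% length(test_cols) + 1L] - 1L
        tw <- tw |>
          left_join(dsub, by = "drug_id") |>
          mutate(
            plate_id = plate_id, role = "test", phase_h = phase_h,
            mu = positive_mean + (solvent_mean - positive_mean) *
              viability_fraction(
                .data$conc_uM,
                true_log_ic50(pick(everything()), phase_h,
                              scen$clock_amplitude_scale),
                .data$hill)) |>
          select("plate_id", "row", "col", "role", "drug_id",
                 "conc_uM", replicate = "rep", "phase_h", "mu")
        bind_rows(ctrl, tw)
      })
      bind_rows(plate_tabs)
    })
    tab <- bind_rows(tabs)
    tab$signal <- tab$mu * lognormal_factor(nrow(tab), scen$noise_cv)
    tab |>
      mutate(well = well_label(.data$row, .data$col)) |>
      select("plate_id", "well", "row", "col", "role", "drug_id",
             "conc_uM", "replicate", "phase_h", "signal")
  })
}

#' Simulate circadian gene-expression time courses
#'
#' Expression follows `mesor * (1 + rel_amplitude * cos(2*pi*(t -
#' peak_phase)/24))` with multiplicative lognormal noise.
#'
#' @param genes Data frame with columns `gene_id`, `mesor` (> 0),
#'   `rel_amplitude` (in `[0, 1]`; larger values would permit negative
#'   expression and are rejected), `peak_phase` (hours).
#' @param timepoints Sampling times in hours (non-empty).
#' @param n_replicates Replicates per gene x timepoint.
#' @param noise_cv CV of the multiplicative noise.
#' @param seed Integer seed.
#'
#' @return Long tibble: `gene_id`, `time_h`, `replicate`, `value`.
#' @export
simulate_expression <- function(genes, timepoints, n_replicates = 3,
                                noise_cv = 0.05, seed = 1L) {
  genes <- as_tibble(genes)
  assert_that(length(timepoints) >= 1, "`timepoints` must be non-empty")
  assert_that(all(genes$mesor > 0), "`mesor` must be positive")
  assert_that(all(genes$rel_amplitude >= 0 & genes$rel_amplitude <= 1),
              "`rel_amplitude` must lie in [0, 1]")
  with_seed(seed, {
    tab <- tidyr::expand_grid(gene_id = genes$gene_id,
                              time_h = as.numeric(timepoints),
                              replicate = seq_len(n_replicates)) |>
      left_join(genes, by = "gene_id") |>
      mutate(mu = .data$mesor * (1 + .data$rel_amplitude *
               cos(2 * pi * (.data$time_h - .data$peak_phase) / 24)))
    tab$value <- tab$mu * lognormal_factor(nrow(tab), noise_cv)
    select(tab, "gene_id", "time_h", "replicate", "value")
  })
}

#' Simulate a circadian bioluminescence reporter trace
#'
#' `signal(t) = baseline(t) + amplitude * exp(-damping_rate * t) *
#' cos(2*pi*(t - phase)/period) + N(0, noise_sd)`, with `baseline` given as
#' polynomial coefficients (constant first).
#'
#' @param period Oscillation period in hours (> 0).
#' @param amplitude Initial oscillation amplitude in signal units.
#' @param damping_rate Exponential damping per hour.
#' @param phase Peak time in hours.
#' @param baseline Polynomial coefficients, lowest order first.
#' @param duration Trace length in hours; must be at least `2 * period` or
#'   the period is not identifiable.
#' @param dt Sampling interval in hours.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @param entity_id Trace label.
#'
#' @return Tibble: `entity_id`, `time_h`, `signal`.
#' @export
simulate_reporter <- function(period = 24, amplitude = 100,
                              damping_rate = 0.01, phase = 0,
                              baseline = c(0), duration = 120, dt = 0.5,
                              noise_sd = 0, seed = 1L,
                              entity_id = "trace1") {
  assert_that(period > 0, "`period` must be positive")
  assert_that(dt > 0, "`dt` must be positive")
  assert_that(duration >= 2 * period,
              "`duration` must be at least two periods (period not identifiable)")
  t <- seq(0, duration, by = dt)
  base <- vapply(t, function(x) sum(baseline * x^(seq_along(baseline) - 1)),
                 numeric(1))
  mu <- base + amplitude * exp(-damping_rate * t) *
    cos(2 * pi * (t - phase) / period)
  with_seed(seed,
    tibble(entity_id = entity_id, time_h = t,
           signal = mu + rnorm(length(t), 0, noise_sd)))
}

#' Simulate two-channel FUCCI cell-cycle fraction series
#'
#' The red (G1) and green (S-G2-M) fractions are raised cosines separated by
#' `phase_offset` (default half a period, i.e. antiphasic). In the
#' desynchronized mode (`phase_jitter_sd > 0`) each of `n_cells` simulated
#' cells carries its own phase undergoing Brownian drift -- the standard
#' picture of cell-cycle dephasing through variable cycle lengths -- scaled
#' so the per-cell phase SD grows by `phase_jitter_sd` hours over each
#' elapsed period. Cells drift apart as the recording proceeds, so the
#' population rhythm collapses rather than merely shrinking in amplitude.
#'
#' @param period Cell-cycle period in hours.
#' @param phase_offset Offset between channels in hours (default `period/2`).
#' @param duration,dt Trace length and sampling interval (hours); `dt` must
#'   be below `period / 4` or the series is rejected as undersampled.
#' @param noise_sd Additive Gaussian noise on fractions (clipped to `[0,1]`).
#' @param phase_jitter_sd Phase-diffusion scale in hours per period
#'   (0 = coherent population).
#' @param n_cells Cells averaged when `phase_jitter_sd > 0`.
#' @param seed Integer seed.
#' @param entity_id Series label.
#'
#' @return Tibble: `entity_id`, `time_h`, `red_fraction`, `green_fraction`.
#' @export
simulate_fucci <- function(period = 24, phase_offset = period / 2,
                           duration = 96, dt = 1, noise_sd = 0,
                           phase_jitter_sd = 0, n_cells = 200, seed = 1L,
                           entity_id = "fucci1") {
  assert_that(dt < period / 4, "`dt` >= period/4: undersampled series rejected")
  t <- seq(0, duration, by = dt)
  with_seed(seed, {
    if (phase_jitter_sd > 0) {
      # per-cell Brownian phase paths: SD grows by phase_jitter_sd per period
      inc_sd <- phase_jitter_sd * sqrt(dt / period)
      shifts <- vapply(seq_len(n_cells), function(i) {
        rnorm(1, 0, phase_jitter_sd) +
          cumsum(c(0, rnorm(length(t) - 1, 0, inc_sd)))
      }, numeric(length(t)))                  # time x cell matrix
      raised <- function(off)
        rowMeans((1 + cos(2 * pi * (t - off - shifts) / period)) / 2)
    } else {
      raised <- function(off) (1 + cos(2 * pi * (t - off) / period)) / 2
    }
    red <- raised(0)
    green <- raised(phase_offset)
    red <- pmin(1, pmax(0, red + rnorm(length(t), 0, noise_sd)))
    green <- pmin(1, pmax(0, green + rnorm(length(t), 0, noise_sd)))
    tibble(entity_id = entity_id, time_h = t,
           red_fraction = red, green_fraction = green)
  })
}

#' Simulate tumor growth volume tables
#'
#' Per-mouse volumes follow `baseline * exp(rate * effect * day)` with
#' multiplicative lognormal noise. Treatment effect multiplies the growth
#' rate (1 = untreated kinetics).
#'
#' @param groups Data frame with columns `group`, `n_mice` (>= 2),
#'   `baseline_volume` (> 0, mm^3), `growth_rate` (per day),
#'   `treatment_effect` (rate multiplier).
#' @param days Measurement days, increasing, starting at day 0.
#' @param noise_cv CV of the multiplicative noise.
#' @param seed Integer seed.
#'
#' @return Tibble: `mouse_id`, `group`, `day`, `volume_mm3`.
#' @export
simulate_tumors <- function(groups, days = 0:7, noise_cv = 0.15, seed = 1L) {
  groups <- as_tibble(groups)
  assert_that(all(groups$n_mice >= 2),
              "each group needs >= 2 mice for downstream comparison")
  assert_that(all(groups$baseline_volume > 0), "`baseline_volume` must be > 0")
  assert_that(all(diff(days) > 0), "`days` must be increasing")
  with_seed(seed, {
    tab <- groups |>
      mutate(mouse = purrr::map(.data$n_mice, seq_len)) |>
      tidyr::unnest("mouse") |>
      mutate(mouse_id = paste0(.data$group, "_m", .data$mouse)) |>
      tidyr::expand_grid(day = as.numeric(days)) |>
      mutate(mu = .data$baseline_volume *
               exp(.data$growth_rate * .data$treatment_effect * .data$day))
    tab$volume_mm3 <- tab$mu * lognormal_factor(nrow(tab), noise_cv)
    select(tab, "mouse_id", "group", "day", "volume_mm3")
  })
}

#' Write a simulated table with a sidecar metadata file
#'
#' Writes the table as tab-separated text and a `<path>.meta.json` sidecar
#' recording the scenario, seed and free-form parameters, so a run can be
#' reproduced from its outputs alone.
#'
#' @param tab Data frame to write.
#' @param path Output path.
#' @param meta Named list of provenance fields (scenario, seed, parameters).
#' @return `path`, invisibly.
#' @export
write_sim_table <- function(tab, path, meta = list()) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
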