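#' Z'-factor assay-quality statistic
#'
#' Screening-window statistic comparing control separation to control
#' variability: `1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Values
#' above 0.5 conventionally denote an acceptable plate; the maximum
#' attainable value is 1 (zero-variance controls).
#'
#' @param mean_neg,sd_neg Negative-control (solvent) signal mean and SD.
#' @param mean_pos,sd_pos Positive-control (full-kill) signal mean and SD.
#' @return The Z'-factor (dimensionless, <= 1).
#' @export
#' @examples
#' zprime(100, 3, 10, 3)  # 0.8
zprime <- function(mean_neg, sd_neg, mean_pos, sd_pos) {
  assert_that(all(c(sd_neg, sd_pos) >= 0), "control SDs must be >= 0")
  if (isTRUE(all.equal(mean_neg, mean_pos)))
    abort("zero dynamic range: control means are equal, Z' undefined")
  1 - 3 * (sd_pos + sd_neg) / abs(mean_pos - mean_neg)
}

#' Normalized percent inhibition (NPI)
#'
#' Rescales a raw well signal so that solvent-control signal maps to 0%
#' inhibition and positive-control (full-kill) signal to 100%:
#' `NPI = (mean_solvent - signal) / (mean_solvent - mean_positive) * 100`.
#' Values outside `[0, 100]` are permitted and carry diagnostic information.
#'
#' @param test_signal Raw signal of the test well(s).
#' @param mean_solvent,mean_positive Per-plate control means.
#' @return Percent inhibition (vectorized over `test_signal`).
#' @export
npi <- function(test_signal, mean_solvent, mean_positive) {
  if (isTRUE(all.equal(mean_solvent, mean_positive)))
    abort("zero dynamic range: control means are equal, NPI undefined")
  (mean_solvent - test_signal) / (mean_solvent - mean_positive) * 100
}

trimmed_stats <- function(x, trim) {
  c(mean = mean(x, trim = trim), sd = sd(x), n = length(x))
}

#' Per-plate quality control and NPI normalization
#'
#' Analyzes each plate independently: computes control statistics and the
#' Z'-factor from that plate's own solvent and positive wells, flags plates
#' whose Z' does not exceed the threshold, and annotates every test well
#' with its NPI. Test wells on failing plates are excluded from the
#' normalized table (they would feed unreliable fits) but are never
#' mutated in place; plates missing controls yield a per-plate error record
#' while the remaining plates are still processed.
#'
#' @param plate_tab Well table as produced by [simulate_screen()] or read
#'   from disk: columns `plate_id`, `role`, `drug_id`, `conc_uM`, `phase_h`,
#'   `signal`.
#' @param zprime_threshold Minimum acceptable Z' (plate passes iff
#'   `zprime > threshold`).
#' @param trim Trim fraction for the control means (0 for plain means);
#'   SDs are never trimmed.
#'
#' @return List with `qc` (one row per plate: control statistics, `zprime`,
#'   `pass`, `note`) and `npi` (test wells of passing plates with an `npi`
#'   column added).
#' @export
qc_and_normalize <- function(plate_tab, zprime_threshold = 0.5, trim = 0.1) {
  plate_tab <- as_tibble(plate_tab)
  need <- c("plate_id", "role", "signal")
  assert_that(all(need %in% names(plate_tab)),
              paste("plate table must contain columns:",
                    paste(need, collapse = ", ")))

  qc <- plate_tab |>
    group_by(.data$plate_id) |>
    group_modify(function(df, key) {
      sv <- df$signal[df$role == "solvent"]
      po <- df$signal[df$role == "positive"]
      if (length(sv) < 2 || length(po) < 2) {
        return(tibble(n_solvent = length(sv), n_positive = length(po),
                      mean_solvent = NA_real_, sd_solvent = NA_real_,
                      mean_positive = NA_real_, sd_positive = NA_real_,
                      zprime = NA_real_, pass = FALSE,
                      note = "missing control wells (need >= 2 of each)"))
      }
      ms <- mean(sv, trim = trim); mp <- mean(po, trim = trim)
      z <- tryCatch(zprime(ms, sd(sv), mp, sd(po)),
                    error = function(e) NA_real_)
      tibble(n_solvent = length(sv), n_positive = length(po),
             mean_solvent = ms, sd_solvent = sd(sv),
             mean_positive = mp, sd_positive = sd(po),
             zprime = z, pass = !is.na(z) && z > zprime_threshold,
             note = if (is.na(z)) "zero dynamic range" else NA_character_)
    }) |>
    ungroup()

  passing <- qc$plate_id[qc$pass]
  npi_tab <- plate_tab |>
    filter(.data$role == "test", .data$plate_id %in% passing)
  npi_tab <- if (nrow(npi_tab) == 0) {
    mutate(npi_tab, npi = numeric(0))
  } else {
    npi_tab |>
      left_join(select(qc, "plate_id", "mean_solvent", "mean_positive"),
                by = "plate_id") |>
      mutate(npi = npi(.data$signal, .data$mean_solvent, .data$mean_positive)) |>
      select(-"mean_solvent", -"mean_positive")
  }

  list(qc = qc, npi = npi_tab)
}

#' Read a plate table written by the simulator (or compatible tools)
#'
#' Accepts either the single-file long format (one row per well with a
#' `signal` column) or a two-file dialect: a signal matrix (rows x columns
#' of the plate) plus a plate map with the same well addressing giving
#' role/drug/concentration/phase.
#'
#' @param path Path to the long-format table, or the signal matrix when
#'   `map_path` is given.
#' @param map_path Optional plate-map path for the two-file dialect.
#' @param plate_id Plate identifier used in the two-file dialect.
#' @return Well-record tibble.
#' @export
read_plate_table <- function(path, map_path = NULL, plate_id = "plate1") {
  if (is.null(map_path)) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    return(as_tibble(tab))
  }
  sig <- as.matrix(utils::read.delim(path, sep = "\t", row.names = 1,
                                     check.names = FALSE))
  map <- as_tibble(utils::read.delim(map_path, sep = "\t",
                                     stringsAsFactors = FALSE))
  assert_that(all(c("well", "role") %in% names(map)),
              "plate map needs `well` and `role` columns")
  long <- tibble(
    well = as.vector(outer(rownames(sig), colnames(sig),
                           function(r, c) sprintf("%s%02d", r, as.integer(c)))),
    signal = as.vector(sig))
  map |>
    left_join(long, by = "well") |>
    mutate(plate_id = plate_id, .before = 1)
}
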