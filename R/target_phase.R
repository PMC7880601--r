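#' Cross-reference rhythmic drugs with rhythmic target-gene expression
#'
#' For each drug classified as rhythmically acting, asks whether at least
#' one of its annotated target genes shows significant periodic expression
#' (any-target rule; an all-target variant is available). Unmapped
#' rhythmic drugs are reported, never dropped silently.
#'
#' @param rhythmic_drugs Character vector of rhythmically acting drug ids.
#' @param gene_labels Per-gene JTK results: tibble with `entity_id` and
#'   `p_adj` (e.g. `classify_rhythmic(...)$labels`).
#' @param mapping Drug-target map: tibble with `drug_id`, `gene_id`
#'   (one row per pair; gene ids are uppercased on input).
#' @param alpha Significance level for calling a gene rhythmic.
#' @param rule `"any"` (default) or `"all"`: how many targets must cycle.
#'
#' @return List: `n_rhythmic_drugs`, `n_with_rhythmic_target`, `detail`
#'   (per-drug tibble with its targets, rhythmic-target count and flag),
#'   `unmapped` (rhythmic drugs absent from the mapping).
#' @export
cross_reference_targets <- function(rhythmic_drugs, gene_labels, mapping,
                                    alpha = 0.05, rule = c("any", "all")) {
  rule <- match.arg(rule)
  mapping <- as_tibble(mapping)
  assert_that(nrow(mapping) > 0, "empty drug-target mapping")
  mapping$gene_id <- toupper(mapping$gene_id)
  gene_labels <- as_tibble(gene_labels) |>
    mutate(entity_id = toupper(.data$entity_id))

  rhythmic_genes <- gene_labels$entity_id[gene_labels$p_adj < alpha]
  detail <- mapping |>
    filter(.data$drug_id %in% rhythmic_drugs) |>
    group_by(.data$drug_id) |>
    summarise(n_targets = dplyr::n(),
              n_rhythmic_targets = sum(unique(.data$gene_id) %in% rhythmic_genes),
              .groups = "drop") |>
    mutate(has_rhythmic_target = if (rule == "any")
             .data$n_rhythmic_targets >= 1
           else .data$n_rhythmic_targets == .data$n_targets)

  unmapped <- setdiff(rhythmic_drugs, mapping$drug_id)
  if (length(unmapped))
    warn(paste("rhythmic drugs missing from the target map:",
               paste(unmapped, collapse = ", ")))

  list(n_rhythmic_drugs = length(rhythmic_drugs),
       n_with_rhythmic_target = sum(detail$has_rhythmic_target),
       detail = detail, unmapped = unmapped)
}

#' Circular phase relation between drug efficacy and target expression
#'
#' The efficacy peak phase is where cytotoxicity is maximal, i.e. where
#' the IC50 profile is minimal; it is taken from the JTK best lag of the
#' negated IC50 profile (noise-robust, unlike a raw argmax). The circular
#' difference to the expression peak is wrapped to `(-12, 12]` h, and the
#' drug is flagged `at_trough` when its efficacy peak falls within
#' `trough_window` hours of the expression trough (antiphase).
#'
#' @param drug_jtk JTK result for the drug's negated IC50 profile (or any
#'   object with `best_lag`, `p_adj`, `period`).
#' @param gene_jtk JTK result for the target gene's expression series.
#' @param alpha Both series must be rhythmic at this level, else the
#'   relation is undefined and `NULL` is returned (structured skip).
#' @param trough_window Half-width of the trough window in hours.
#'
#' @return One-row tibble: `efficacy_peak_phase`, `expression_peak_phase`,
#'   `delta` (circular, `(-12, 12]`), `at_trough`; or `NULL` when either
#'   series is non-rhythmic.
#' @export
phase_relation <- function(drug_jtk, gene_jtk, alpha = 0.05,
                           trough_window = 3) {
  if (drug_jtk$p_adj >= alpha || gene_jtk$p_adj >= alpha) return(NULL)
  period <- drug_jtk$period
  eff <- wrap_phase(drug_jtk$best_lag, period)
  expr <- wrap_phase(gene_jtk$best_lag, period)
  delta <- circ_diff(eff, expr, period)
  # map the (-period/2, period/2] convention to (-12, 12] for period 24
  tibble(efficacy_peak_phase = eff, expression_peak_phase = expr,
         delta = delta,
         at_trough = abs(abs(delta) - period / 2) <= trough_window)
}

#' Test for enrichment of drug efficacy at target-expression troughs
#'
#' Computes the mean resultant length of the deltas re-centered on the
#' antiphase direction (delta - 12 h as angles) and a permutation p-value
#' for trough concordance obtained by shuffling the drug-gene pairings.
#'
#' @param relations Tibble of phase relations (rows from
#'   [phase_relation()]); at least 5 required.
#' @param n_perm Permutation resamples.
#' @param seed Integer seed.
#' @param period Circadian period in hours.
#'
#' @return List: `resultant_length` in `[0, 1]`, `mean_direction_h`
#'   (mean deviation from exact antiphase, hours), `p` (permutation),
#'   `n`.
#' @export
phase_concordance_test <- function(relations, n_perm = 10000, seed = 1L,
                                   period = 24) {
  relations <- as_tibble(relations)
  assert_that(nrow(relations) >= 5,
              "fewer than 5 phase relations: insufficient data")
  ang <- function(eff, expr) {
    d <- circ_diff(eff, expr, period) - period / 2
    2 * pi * d / period
  }
  resultant <- function(theta)
    sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)

  obs_theta <- ang(relations$efficacy_peak_phase,
                   relations$expression_peak_phase)
  obs <- resultant(obs_theta)
  mean_dir <- atan2(mean(sin(obs_theta)), mean(cos(obs_theta))) *
    period / (2 * pi)

  p <- with_seed(seed, {
    exceed <- vapply(seq_len(n_perm), function(i) {
      perm <- sample(relations$expression_peak_phase)
      resultant(ang(relations$efficacy_peak_phase, perm)) >= obs - 1e-12
    }, logical(1))
    (1 + sum(exceed)) / (n_perm + 1)
  })
  list(resultant_length = obs, mean_direction_h = mean_dir, p = p,
       n = nrow(relations))
}
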