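fake_jtk <- function(lag, p = 0.01, period = 24)
  list(best_lag = lag, p_adj = p, period = period)

test_that("cross_reference_targets counts drugs by the any-target rule", {
  mapping <- tibble::tibble(
    drug_id = c(paste0("d", 1:10), "d1"),   # d1 has two targets
    gene_id = c(paste0("g", 1:10), "g11"))
  # genes g1..g7 rhythmic, g8..g11 not
  gene_labels <- tibble::tibble(entity_id = paste0("g", 1:11),
                                p_adj = c(rep(0.001, 7), rep(0.5, 4)))
  res <- cross_reference_targets(paste0("d", 1:10), gene_labels, mapping)
  expect_equal(res$n_rhythmic_drugs, 10)
  expect_equal(res$n_with_rhythmic_target, 7)
  # no double counting: d1 counted once despite two targets
  expect_equal(nrow(res$detail), 10)
  # alpha = 0: nothing is rhythmic
  res0 <- cross_reference_targets(paste0("d", 1:10), gene_labels, mapping,
                                  alpha = 0)
  expect_equal(res0$n_with_rhythmic_target, 0)
  # counts are monotone in alpha
  alphas <- c(0, 1e-4, 0.05, 0.2, 1.1)
  counts <- vapply(alphas, function(a)
    cross_reference_targets(paste0("d", 1:10), gene_labels, mapping,
                            alpha = a)$n_with_rhythmic_target, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # unmapped rhythmic drugs are reported
  expect_warning(
    res_u <- cross_reference_targets(c("d1", "ghost"), gene_labels, mapping),
    "ghost")
  expect_equal(res_u$unmapped, "ghost")
  expect_error(cross_reference_targets("d1", gene_labels, mapping[0, ]),
               "empty")
})

test_that("phase_relation computes the circular delta and trough flag", {
  # exact antiphase: gene peak 0, efficacy peak 12
  r <- phase_relation(fake_jtk(12), fake_jtk(0))
  expect_equal(r$delta, 12)
  expect_true(r$at_trough)
  # in phase
  r2 <- phase_relation(fake_jtk(6), fake_jtk(6))
  expect_equal(r2$delta, 0)
  expect_false(r2$at_trough)
  # within the +/- 3 h window
  r3 <- phase_relation(fake_jtk(14), fake_jtk(0))
  expect_true(r3$at_trough)
  r4 <- phase_relation(fake_jtk(16), fake_jtk(0))
  expect_false(r4$at_trough)
  # either series non-rhythmic -> structured skip
  expect_null(phase_relation(fake_jtk(12, p = 0.2), fake_jtk(0)))
  # circular antisymmetry of the delta
  a <- phase_relation(fake_jtk(15), fake_jtk(4))
  b <- phase_relation(fake_jtk(4), fake_jtk(15))
  expect_equal((a$delta + b$delta) %% 24, 0)
})

test_that("phase_concordance_test measures trough enrichment", {
  rel <- function(eff, expr)
    tibble::tibble(efficacy_peak_phase = eff, expression_peak_phase = expr)
  # all deltas exactly 12: resultant length 1, p at the permutation minimum
  all12 <- rel(c(12, 14, 2, 20, 8), c(0, 2, 14, 8, 20))
  res <- phase_concordance_test(all12, n_perm = 400, seed = 1)
  expect_equal(res$resultant_length, 1, tolerance = 1e-9)
  # rotation invariance of the resultant length
  rot <- rel(all12$efficacy_peak_phase + 5, all12$expression_peak_phase + 5)
  res_rot <- phase_concordance_test(rot, n_perm = 10, seed = 1)
  expect_equal(res_rot$resultant_length, res$resultant_length,
               tolerance = 1e-9)
  expect_error(phase_concordance_test(all12[1:4, ]), "insufficient")
})

test_that("uniform deltas are not called enriched, concentrated ones are", {
  n_null_sig <- sum(vapply(1:30, function(s) {
    eff <- withr::with_seed(s, runif(8, 0, 24))
    expr <- withr::with_seed(s + 1000, runif(8, 0, 24))
    phase_concordance_test(
      tibble::tibble(efficacy_peak_phase = eff, expression_peak_phase = expr),
      n_perm = 200, seed = s)$p < 0.05
  }, logical(1)))
  expect_lte(n_null_sig, 3)  # ~uniform null: rarely significant
  # troughs plus 2 h of jitter: strongly concordant
  withr::with_seed(2, {
    expr <- runif(10, 0, 24)
    eff <- (expr + 12 + rnorm(10, 0, 2)) %% 24
  })
  res <- phase_concordance_test(
    tibble::tibble(efficacy_peak_phase = eff, expression_peak_phase = expr),
    n_perm = 400, seed = 3)
  expect_lt(res$p, 0.05)
  expect_gt(res$resultant_length, 0.7)
})

test_that("drugs generated to act at target troughs are flagged at_trough", {
  hits <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      expr_peak <- runif(1, 0, 24)
      eff_peak <- (expr_peak + 12 + rnorm(1, 0, 2)) %% 24
    })
    phase_relation(fake_jtk(eff_peak), fake_jtk(expr_peak))$at_trough
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
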