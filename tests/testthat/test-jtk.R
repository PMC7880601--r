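test_that("templates group congruent timepoints and cover the lag grid", {
  tpl <- jtk_templates(rep(screen_phases, each = 3), period = 24)
  expect_length(tpl, 4)
  expect_equal(vapply(tpl, `[[`, numeric(1), "lag"), c(0, 6, 12, 18))
  # 24 h and 48 h share a rank group in every template
  for (tp in tpl) {
    r <- tp$ranks
    idx24 <- which(rep(screen_phases, each = 3) %in% c(24, 48))
    expect_length(unique(r[idx24]), 1)
  }
  # lag L and L + 12 have exactly reversed orderings
  r0 <- tpl[[1]]$ranks; r12 <- tpl[[3]]$ranks
  expect_equal(rank(r0), rank(max(r12) + 1 - r12))
  expect_error(jtk_templates(c(0, 8, 16), period = 24), "4 distinct")
})

test_that("kendall_S agrees with brute-force pair enumeration", {
  tpl <- jtk_templates(rep(screen_phases, each = 2), period = 24)[[2]]
  withr::with_seed(7, {
    for (i in 1:10) {
      y <- rnorm(10)
      got <- kendall_S(y, tpl$ranks)
      want <- brute_kendall_S(y, tpl$ranks)
      expect_equal(got$S, want$S)
      expect_equal(got$K, want$K)
    }
  })
  # full concordance and constant-series edge cases
  expect_equal(with(kendall_S(1:6, 1:6), S - K), 0)
  expect_equal(kendall_S(rep(2, 6), 1:6)$S, 0)
})

test_that("exact null equals the exhaustive permutation distribution", {
  designs <- list(c(1, 1), rep(1, 5), rep(1, 6), c(2, 2, 2), c(1, 2, 3),
                  c(2, 2, 2, 2), c(3, 3, 2), c(1, 1, 2, 4))
  for (gs in designs) {
    nd <- jtk_null_distribution(gs)
    expect_true(nd$exact)
    expect_equal(sum(nd$prob), 1, tolerance = 1e-12)
    expect_equal(sum(nd$S * nd$prob), 0, tolerance = 1e-9)
    oracle <- perm_null_S(gs)
    got <- setNames(nd$prob, nd$S)[names(oracle)]
    expect_equal(unname(got), unname(as.numeric(oracle)), tolerance = 1e-10,
                 label = paste("design", paste(gs, collapse = "+")))
  }
  # single comparable pair: S = +/-1 with probability 1/2 each
  nd <- jtk_null_distribution(c(1, 1))
  expect_equal(sort(nd$S), c(-1, 1))
  expect_equal(nd$prob, c(0.5, 0.5))
})

test_that("variance of the exact null matches the tie-corrected formula", {
  for (gs in list(rep(1, 7), c(3, 3, 2), c(2, 2, 2, 2))) {
    nd <- jtk_null_distribution(gs)
    n <- sum(gs)
    v_formula <- (n * (n - 1) * (2 * n + 5) -
                    sum(gs * (gs - 1) * (2 * gs + 5))) / 18
    expect_equal(sum(nd$prob * nd$S^2), v_formula, tolerance = 1e-9)
  }
})

test_that("normal fallback engages above the exact limit and is flagged", {
  nd <- jtk_null_distribution(rep(3, 12), exact_limit = 30)
  expect_false(nd$exact)
  expect_gt(nd$sd, 0)
  y <- withr::with_seed(1, rnorm(36))
  r <- jtk_test(y, rep(seq(0, 33, by = 3), each = 3) %% 24, exact_limit = 30)
  expect_false(r$exact)
  expect_true(r$p_adj >= 0 && r$p_adj <= 1)
})

test_that("jtk_test detects a clean rhythm and respects its symmetries", {
  s <- make_timed_series(0.3, peak_phase = 12, seed = 5)
  r <- jtk_test(s$value, s$time)
  expect_lt(r$p_adj, 0.05)
  expect_equal(r$best_lag, 12)
  # monotone-transform invariance (rank test)
  r_exp <- jtk_test(exp(3 * s$value), s$time)
  expect_equal(r$p_adj, r_exp$p_adj)
  expect_equal(r$S, r_exp$S)
  # polarity symmetry: negation flips the lag by half a period
  r_neg <- jtk_test(-s$value, s$time)
  expect_equal(r_neg$p_adj, r$p_adj)
  expect_equal((r_neg$best_lag - r$best_lag) %% 24, 12)
})

test_that("a constant series is not rhythmic and a noiseless cosine attains
           the design minimum p", {
  t <- rep(screen_phases, each = 3)
  flat <- jtk_test(rep(1, 15), t)
  expect_equal(flat$p_adj, 1)
  expect_false(flat$rhythmic)
  # noiseless cosine reaches the smallest attainable adjusted p: its data
  # ties coincide with the template ties, so S equals K at the true lag
  y <- cos(2 * pi * (t - 30) / 24)
  r <- jtk_test(y, t)
  expect_equal(r$best_lag, 6)
  expect_equal(r$S, r$K)
  tpl <- jtk_templates(t, 24)[[2]]          # lag 6 template (peak at 30)
  nd <- jtk_null_distribution(tabulate(tpl$ranks))
  p_min <- nd$prob[which.max(nd$S)]         # P(S = max attainable)
  expect_equal(r$p_exact, p_min)
  expect_equal(r$p_adj, min(1, 4 * p_min))
})

test_that("cosinor amplitude reflects half the peak-to-trough range", {
  t <- rep(screen_phases, each = 3)
  y <- 5 + 2 * cos(2 * pi * (t - 36) / 24)
  r <- jtk_test(y, t)
  expect_equal(r$amplitude, 2, tolerance = 1e-6)
})

test_that("classify_rhythmic separates rhythmic from flat entities", {
  tabs <- lapply(1:6, function(i) {
    amp <- if (i <= 3) 0.4 else 0
    s <- make_timed_series(amp, peak_phase = 6 * (i %% 4), seed = 20 + i)
    tibble::tibble(entity_id = paste0("e", i), time_h = s$time, value = s$value)
  })
  cls <- classify_rhythmic(dplyr::bind_rows(tabs))
  lab <- cls$labels
  expect_gte(sum(lab$rhythmic[lab$entity_id %in% c("e1", "e2", "e3")]), 2)
  expect_lte(sum(lab$rhythmic[lab$entity_id %in% c("e4", "e5", "e6")]), 1)
  expect_equal(sum(cls$summary$n_rhythmic), sum(lab$rhythmic))
  # degenerate thresholds
  all_r <- classify_rhythmic(dplyr::bind_rows(tabs), alpha = 1.0000001)
  expect_true(all(all_r$labels$rhythmic))
  empty <- classify_rhythmic(tibble::tibble(entity_id = character(),
                                            time_h = numeric(),
                                            value = numeric()))
  expect_equal(nrow(empty$labels), 0)
  expect_equal(nrow(empty$summary), 0)
})

test_that("power is non-decreasing in relative amplitude", {
  amps <- c(0, 0.1, 0.2, 0.4)
  power <- vapply(amps, function(a) {
    mean(vapply(1:40, function(s) {
      ser <- make_timed_series(a, peak_phase = 12, seed = 100 * s + 1)
      jtk_test(ser$value, ser$time)$p_adj < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(power) >= -0.075))  # monotone up to simulation noise
  expect_lt(power[1], 0.1)
  expect_gt(power[4], 0.9)
})
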