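#' Reference templates for the JTK-Cycle test
#'
#' Builds one rank template per candidate lag on the sampling grid over a
#' full period. The reference value at time `t` is `cos(2*pi*(t -
#' lag)/period)` reduced to ranks; timepoints whose reference values are
#' equal receive tied ranks. In particular timepoints congruent modulo the
#' period (e.g. 24 h and 48 h for a 24-h period) are always tied, as are
#' symmetric cosine values (phases 6 h and 18 h at lag 0).
#'
#' @param timepoints Observation times in hours (replicates allowed).
#' @param period Candidate period in hours.
#' @param lags Candidate peak lags in hours; defaults to the distinct
#'   sampling phases modulo the period.
#' @return List of templates; each holds `period`, `lag`, and `ranks`, the
#'   tied reference rank of every observation.
#' @export
jtk_templates <- function(timepoints, period = 24, lags = NULL) {
  ph <- wrap_phase(timepoints, period)
  distinct <- sort(unique(round(ph, 9)))
  assert_that(length(distinct) >= 4,
              "fewer than 4 distinct circadian phases: rhythm not testable")
  lags <- lags %||% distinct
  lapply(lags, function(lag) {
    ref <- round(cos(2 * pi * (ph - lag) / period), 9)
    list(period = period, lag = lag,
         ranks = match(ref, sort(unique(ref))))
  })
}

#' Kendall S statistic against a tied reference template
#'
#' Counts concordant minus discordant observation pairs between the data
#' and a reference ordering with ties. Pairs tied in the template are not
#' comparable and are excluded; pairs tied in the data contribute zero.
#'
#' @param values Observations.
#' @param ranks Template rank (with ties) of each observation.
#' @return List with `S` (concordant - discordant) and `K` (number of
#'   template-comparable pairs).
#' @export
kendall_S <- function(values, ranks) {
  n <- length(values)
  assert_that(length(ranks) == n, "values and template ranks differ in length")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dr <- sign(ranks[ij[, 2]] - ranks[ij[, 1]])
  dv <- sign(values[ij[, 2]] - values[ij[, 1]])
  comparable <- dr != 0
  list(S = sum(dr[comparable] * dv[comparable]),
       K = sum(comparable))
}

# Distribution of cross-inversions when a tied block of size b is merged
# into an arrangement of size a: normalized Gaussian-binomial coefficients
# [a+b choose b]_q, computed by the last-letter recursion
# N(a,b) = q^b N(a-1,b) + N(a,b-1).
gauss_inversion_probs <- function(a, b) {
  if (a == 0 || b == 0) return(1)
  prev <- vector("list", b + 1)
  for (j in 0:b) prev[[j + 1]] <- 1           # a' = 0
  for (ai in 1:a) {
    cur <- vector("list", b + 1)
    cur[[1]] <- 1                             # b' = 0
    for (j in 1:b) {
      up <- prev[[j + 1]]                     # N(ai-1, j), shift by q^j
      left <- cur[[j]]                        # N(ai, j-1)
      len <- max(length(up) + j, length(left))
      acc <- numeric(len)
      acc[seq_along(left)] <- left
      acc[j + seq_along(up)] <- acc[j + seq_along(up)] + up
      cur[[j + 1]] <- acc
    }
    prev <- cur
  }
  p <- prev[[b + 1]]
  p / sum(p)
}

.jtk_null_cache <- new.env(parent = emptyenv())

#' Exact null distribution of the JTK Kendall S statistic
#'
#' Under exchangeability of the observations, the number of discordances D
#' against a tied template with group sizes `n1, ..., ng` is distributed as
#' the inversion count of a random multiset permutation; its generating
#' function is the Gaussian q-multinomial, computed here by convolving
#' per-group merge distributions. `S = K - 2D` where `K` is the number of
#' comparable pairs, so the distribution is symmetric about zero and sums
#' to one. Beyond `exact_limit` observations a normal approximation with
#' the tie-corrected Kendall variance and a continuity correction is used
#' and flagged.
#'
#' @param group_sizes Sizes of the template's tied rank groups.
#' @param exact_limit Maximum total observations for exact computation.
#' @return List with `S` (support), `prob`, `K`, and `exact` flag; under
#'   the normal fallback `S`/`prob` are `NULL` and `sd` is supplied.
#' @export
jtk_null_distribution <- function(group_sizes, exact_limit = 30) {
  group_sizes <- as.integer(group_sizes[group_sizes > 0])
  n <- sum(group_sizes)
  K <- (n^2 - sum(group_sizes^2)) / 2
  if (n > exact_limit) {
    v <- (n * (n - 1) * (2 * n + 5) -
            sum(group_sizes * (group_sizes - 1) * (2 * group_sizes + 5))) / 18
    return(list(S = NULL, prob = NULL, K = K, exact = FALSE, sd = sqrt(v)))
  }
  key <- paste(sort(group_sizes), collapse = ",")
  probs <- .jtk_null_cache[[key]]
  if (is.null(probs)) {
    probs <- 1
    a <- 0
    for (b in group_sizes) {
      g <- gauss_inversion_probs(a, b)
      probs <- if (length(g) == 1) probs else
        stats::convolve(probs, rev(g), type = "open")
      a <- a + b
    }
    probs[probs < 0] <- 0
    probs <- probs / sum(probs)
    .jtk_null_cache[[key]] <- probs
  }
  list(S = K - 2 * (seq_along(probs) - 1), prob = probs, K = K, exact = TRUE)
}

# One-sided P(S >= s) for a template null.
jtk_p_value <- function(s, null) {
  if (null$exact) {
    sum(null$prob[null$S >= s])
  } else {
    stats::pnorm((s - 1) / null$sd, lower.tail = FALSE)  # continuity-corrected
  }
}

#' JTK-Cycle nonparametric rhythmicity test
#'
#' Rank-based test for a periodic component: the data ordering is compared
#' with phase-shifted cosine reference orderings via Kendall's S, the best
#' lag is the one with the largest standardized concordance, the one-sided
#' exact p-value is taken at that template, and a Bonferroni factor equal
#' to the number of templates adjusts for the lag search. The amplitude is
#' half the peak-to-trough range of a least-squares cosine with period and
#' lag fixed at the selected values. Invariant under strictly monotone
#' transformations of the data (p and S depend on ranks only). A constant
#' series returns `p_adj = 1`, `rhythmic = FALSE`.
#'
#' @param values Observations.
#' @param timepoints Matching times in hours (replicates = repeated times).
#' @param period Test period in hours (default 24).
#' @param alpha Significance level for the `rhythmic` call.
#' @param lags Candidate lags; defaults to the sampling grid.
#' @param exact_limit Passed to [jtk_null_distribution()].
#' @param entity_id Label carried into the result.
#'
#' @return A `jtk_result` list: `entity_id`, `period`, `best_lag`, `S`,
#'   `K`, `tau`, `p_exact`, `p_adj`, `n_templates`, `amplitude`,
#'   `rhythmic`, `exact`. [tidy()] gives a one-row tibble.
#' @export
#' @examples
#' t <- rep(c(24, 30, 36, 42, 48), each = 3)
#' y <- cos(2 * pi * (t - 36) / 24) + rnorm(length(t), 0, 0.1)
#' jtk_test(y, t)$p_adj
jtk_test <- function(values, timepoints, period = 24, alpha = 0.05,
                     lags = NULL, exact_limit = 30, entity_id = NA_character_) {
  assert_that(length(values) == length(timepoints),
              "values and timepoints differ in length")
  keep <- is.finite(values) & is.finite(timepoints)
  values <- values[keep]; timepoints <- timepoints[keep]
  templates <- jtk_templates(timepoints, period, lags)

  per_template <- lapply(templates, function(tpl) {
    ks <- kendall_S(values, tpl$ranks)
    null <- jtk_null_distribution(tabulate(tpl$ranks), exact_limit)
    sdS <- if (null$exact) sqrt(sum(null$prob * null$S^2)) else null$sd
    list(lag = tpl$lag, S = ks$S, K = ks$K,
         z = if (sdS > 0) ks$S / sdS else 0,
         p = jtk_p_value(ks$S, null), exact = null$exact)
  })

  zs <- vapply(per_template, `[[`, numeric(1), "z")
  best <- per_template[[which.max(zs)]]   # ties -> earliest lag
  n_templates <- length(templates)
  p_adj <- min(1, n_templates * best$p)

  # fixed-phase cosinor refit for the amplitude, in the series' units
  cosref <- cos(2 * pi * (timepoints - best$lag) / period)
  amp <- if (sd(cosref) > 0) abs(unname(coef(lm(values ~ cosref))[2])) else 0

  structure(list(entity_id = entity_id, period = period,
                 best_lag = best$lag, S = best$S, K = best$K,
                 tau = if (best$K > 0) best$S / best$K else 0,
                 p_exact = best$p, p_adj = p_adj,
                 n_templates = n_templates, amplitude = amp,
                 rhythmic = p_adj < alpha, exact = best$exact,
                 alpha = alpha),
            class = "jtk_result")
}

#' Classify a collection of time series as rhythmic or not
#'
#' Runs [jtk_test()] on each entity of a long table and summarizes counts
#' of rhythmic entities by peak-phase bin.
#'
#' @param series_tab Long tibble: `entity_id`, `time_h`, `value`.
#' @param period,alpha,lags,exact_limit Passed to [jtk_test()].
#' @return List of class `rhythm_classification` with `labels` (one row
#'   per entity: JTK fields plus `rhythmic`) and `summary` (counts of
#'   rhythmic entities per `best_lag` bin).
#' @export
classify_rhythmic <- function(series_tab, period = 24, alpha = 0.05,
                              lags = NULL, exact_limit = 30) {
  series_tab <- as_tibble(series_tab)
  if (nrow(series_tab) == 0) {
    return(structure(list(labels = tibble(entity_id = character(),
                                          best_lag = numeric(),
                                          p_adj = numeric(),
                                          amplitude = numeric(),
                                          rhythmic = logical()),
                          summary = tibble(best_lag = numeric(),
                                           n_rhythmic = integer())),
                     class = "rhythm_classification"))
  }
  labels <- series_tab |>
    group_by(.data$entity_id) |>
    group_modify(function(df, key) {
      r <- jtk_test(df$value, df$time_h, period = period, alpha = alpha,
                    lags = lags, exact_limit = exact_limit,
                    entity_id = key$entity_id)
      tidy(r)[, -1]
    }) |>
    ungroup()
  summary <- labels |>
    filter(.data$rhythmic) |>
    count(.data$best_lag, name = "n_rhythmic")
  structure(list(labels = labels, summary = summary),
            class = "rhythm_classification")
}

#' @export
print.rhythm_classification <- function(x, ...) {
  cat(sprintf("Rhythmicity classification: %d of %d entities rhythmic\n",
              sum(x$labels$rhythmic), nrow(x$labels)))
  if (nrow(x$summary)) {
    cat("Rhythmic entities by peak-phase bin:\n")
    print(x$summary)
  }
  invisible(x)
}
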