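# Shared fixtures built in code.

screen_phases <- c(24, 30, 36, 42, 48)

# One replicated viability-style series with cosine modulation and
# multiplicative lognormal noise, mirroring the timed-efficacy design.
make_timed_series <- function(rel_amplitude, peak_phase = 12, noise_cv = 0.05,
                              n_reps = 3, timepoints = screen_phases,
                              seed = 1) {
  t <- rep(timepoints, each = n_reps)
  mu <- 1 + rel_amplitude * cos(2 * pi * (t - peak_phase) / 24)
  withr::with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    list(time = t, value = mu * stats::rlnorm(length(t), -sdlog^2 / 2, sdlog))
  })
}

# Noise-free NPI points from a 4PL truth on the standard dose ladder.
make_4pl_points <- function(log_ic50, hill = 1.2, top = 100, bottom = 0,
                            doses = dose_ladder(screen_design())) {
  list(conc = doses,
       npi = bottom + (top - bottom) /
         (1 + 10^((log_ic50 - log10(doses)) * hill)))
}

# Brute-force Kendall S via explicit O(n^2) pair enumeration.
brute_kendall_S <- function(values, ranks) {
  S <- 0L; K <- 0L
  n <- length(values)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dr <- sign(ranks[j] - ranks[i])
    if (dr == 0) next
    K <- K + 1L
    S <- S + dr * sign(values[j] - values[i])
  }
  list(S = S, K = K)
}

# Exhaustive-permutation null distribution of S for a tied template with
# the given group sizes (feasible for <= 8 observations); vectorized over
# the permutation matrix.
perm_null_S <- function(group_sizes) {
  ranks <- rep(seq_along(group_sizes), group_sizes)
  n <- length(ranks)
  perms <- gtools_permutations(n)
  S <- numeric(nrow(perms))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dr <- sign(ranks[j] - ranks[i])
    if (dr == 0) next
    S <- S + dr * sign(perms[, j] - perms[, i])
  }
  table(S) / nrow(perms)
}

# All partitions of n into at least `min_parts` positive parts
# (non-increasing order).
partitions_of <- function(n, max_part = n, min_parts = 2) {
  rec <- function(n, max_part) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (p in seq_len(min(n, max_part)))
      out <- c(out, lapply(rec(n - p, p), function(rest) c(p, rest)))
    out
  }
  Filter(function(p) length(p) >= min_parts, rec(n, max_part))
}

# All permutations of 1..n (no dependency on gtools).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    out[rows, -1] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}
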