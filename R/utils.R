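#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats coef lm median optim quantile rnorm runif sd setNames
#' @importFrom stats fft p.adjust var rlnorm residuals
#' @importFrom utils head modifyList write.csv
NULL

# Evaluate an expression under a local RNG state seeded with `seed`.
# seed = NULL leaves the caller's RNG stream untouched/used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed from a parent seed and a stage label,
# kept within 32-bit integer range.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1000003L + as.integer(h %% 2147480L)) %% 2147483647L
}

# Multiplicative lognormal noise factors with mean 1 and coefficient of
# variation cv (sdlog chosen so that the factor's CV equals cv exactly).
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Wrap hours onto the circadian circle [0, period).
wrap_phase <- function(h, period = 24) ((h %% period) + period) %% period

# Signed circular difference a - b wrapped to (-period/2, period/2].
circ_diff <- function(a, b, period = 24) {
  d <- wrap_phase(a - b, period)
  ifelse(d > period / 2, d - period, d)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) abort(msg)
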