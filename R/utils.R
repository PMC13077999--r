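# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats pnorm pt pchisq qchisq rnorm runif median mad sd
#'   complete.cases ppoints p.adjust dnorm setNames
NULL

# Two-sided normal p-value; z = 0 maps to p = 1 and extreme z is clamped
# away from 0 so p stays in (0, 1].
p_from_z <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

STRAND_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_alleles <- function(x) unname(STRAND_COMPLEMENT[x])

is_palindromic <- function(ea, oa) {
  !is.na(ea) & !is.na(oa) & complement_alleles(ea) == oa
}

# Deterministic per-key substream seed, independent of evaluation order:
# polynomial rolling hash of the key folded into the base, modulo a large
# prime so the result stays below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(base, key) {
  m <- 2147483563
  h <- as.numeric(base) %% m
  for (b in utf8ToInt(as.character(key))) h <- (h * 131 + b) %% m
  as.integer(h + 1)
}

#' Derive a named substream seed
#'
#' Maps a base seed and a stream name to a reproducible integer seed below
#' 2^31, so that independent experiments (screens, bootstrap streams,
#' simulation replicates) can each get their own stream from one master
#' seed. Used internally for per-exposure bootstrap seeds and by the
#' reproduction script for its experiment substreams.
#'
#' @param base integer master seed.
#' @param key character stream name.
#' @return integer seed in [1, 2^31 - 19).
#' @export
deriveSeed <- function(base, key) derive_seed(base, key)

# Weighted empirical quantile function at probability 0.5, linear
# interpolation through midpoint cumulative weights s_j = cum_j - w_j / 2.
weighted_median_est <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w[ord])
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(r[1L])
  n <- length(r)
  if (0.5 >= s[n]) return(r[n])
  k <- findInterval(0.5, s)
  r[k] + (r[k + 1L] - r[k]) * (0.5 - s[k]) / (s[k + 1L] - s[k])
}

# Argmax of a Gaussian-kernel weighted density over a fine grid.
weighted_mode_est <- function(r, w, h, grid_n = 512L) {
  if (!is.finite(h) || h <= 0) {
    # degenerate spread: all ratios (numerically) identical
    return(r[which.max(w)])
  }
  x <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = grid_n)
  dens <- as.vector((w / sum(w)) %*% stats::dnorm(outer(r, x, "-") / h))
  x[which.max(dens)]
}

# Modified Silverman bandwidth on the ratio estimates (Hartwig-style).
mode_bandwidth <- function(r, bandwidth_factor = 1) {
  spread <- min(stats::sd(r), stats::mad(r))
  if (!is.finite(spread) || spread <= 0) spread <- stats::sd(r)
  bandwidth_factor * 0.9 * spread * length(r)^(-1 / 5)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
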