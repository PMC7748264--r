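# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL runs expr as-is.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-stage substream seeds derived from one global seed.
# Kept below 2^31 - 1 so they remain valid R integers.
.substream <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 99991 * as.double(k)) %% 2147483646 + 1)
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# deterministic low-discrepancy point set on the unit disc
# (sunflower / golden-angle spiral)
.disc_points <- function(n = 256L) {
  k <- seq_len(n)
  rho <- sqrt((k - 0.5) / n)
  theta <- k * pi * (3 - sqrt(5))
  cbind(rho * cos(theta), rho * sin(theta))
}

# weighted quantile (type-7-like linear interpolation on the weighted cdf)
.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - 0.5 * w
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

.weighted_median <- function(x, w) .weighted_quantile(x, w, 0.5)
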