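# Independent brute-force oracles used to check the vectorized statistics.

# Discrete spatial Ripley's K by direct double loop over events.
k_spatial_bruteforce <- function(h, s, dmat, radii, w = NULL) {
  S <- length(s)
  A <- h$area
  if (is.null(w)) w <- matrix(1, S, length(radii))
  sapply(seq_along(radii), function(ri) {
    tot <- 0
    for (ii in seq_len(S)) {
      cnt <- 0
      for (jj in seq_len(S)) {
        if (jj != ii && dmat[s[ii], s[jj]] <= radii[ri]) cnt <- cnt + 1
      }
      tot <- tot + w[ii, ri] * cnt
    }
    (A / S) * tot / S
  })
}

# Spatiotemporal K by direct double loop (j = i not excluded).
k_st_bruteforce <- function(h, s1, s2, dmat, radii, w = NULL) {
  A <- h$area
  if (is.null(w)) w <- matrix(1, length(s1), length(radii))
  sapply(seq_along(radii), function(ri) {
    tot <- 0
    for (ii in seq_along(s1)) {
      cnt <- sum(dmat[s1[ii], s2] <= radii[ri])
      tot <- tot + w[ii, ri] * cnt
    }
    (A / length(s1)) * tot / length(s2)
  })
}

# Interaction placement log-likelihood by direct enumeration of the
# categorical weight table (no histogram / log-sum-exp machinery): every
# candidate cell k carries weight g^(number of S1 cells within r of k),
# and each Time-2 event is one categorical draw over the candidates.
loglik_enumeration <- function(n, s1, s2, g, r, dmat) {
  cand <- setdiff(seq_len(n), s1)
  w <- vapply(cand, function(k) {
    g^sum(dmat[s1, k] <= r)
  }, 0)
  denom <- sum(w)
  tot <- 0
  for (j in s2) {
    tot <- tot + log(w[match(j, cand)]) - log(denom)
  }
  tot
}

# small jittered grid hemisphere for quick tests
grid_hemisphere <- function(nx = 6, ny = 6, spacing = 10, jitter = 0,
                            seed = 1) {
  set.seed(seed)
  g <- as.matrix(expand.grid(x = seq_len(nx) * spacing,
                             y = seq_len(ny) * spacing))
  g <- g + matrix(stats::runif(length(g), -jitter, jitter), ncol = 2)
  hemisphere(cbind(g, 0))
}
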