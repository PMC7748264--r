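#' Labeled S-phase pattern on a hemisphere
#'
#' Holds the indices of NSCs in S-phase at one or two labeling time points.
#' Cells labeled at both time points within a single S-phase (double-labeled
#' S-phases, DLS) carry the Time-1 label by construction and are listed in
#' `dls`; they are assigned to Time 1 only in spatiotemporal analyses.
#'
#' @param h a [hemisphere()].
#' @param s1 integer indices of cells in S-phase at Time 1 (or the single
#'   event set for purely spatial analyses).
#' @param s2 optional integer indices of cells in S-phase at Time 2.
#' @param delta_t labeling interval in hours (`NA` for single-time patterns).
#' @param dls indices of double-labeled S-phases; must be a subset of `s1`.
#' @param doublet_groups optional list of integer vectors grouping sibling
#'   cells that stem from one division event.
#' @return object of class `"labeled_pattern"`.
#' @export
labeled_pattern <- function(h, s1, s2 = NULL, delta_t = NA_real_,
                            dls = integer(), doublet_groups = NULL) {
  .assert(inherits(h, "hemisphere"), "h must be a hemisphere")
  n <- n_cells(h)
  s1 <- as.integer(s1)
  .assert(!anyDuplicated(s1), "duplicate indices in s1")
  .assert(all(s1 >= 1 & s1 <= n), "s1 indices out of range")
  if (!is.null(s2)) {
    s2 <- as.integer(s2)
    .assert(!anyDuplicated(s2), "duplicate indices in s2")
    .assert(all(s2 >= 1 & s2 <= n), "s2 indices out of range")
  }
  dls <- as.integer(dls)
  .assert(all(dls %in% s1), "dls must be a subset of s1")
  structure(list(hemisphere = h, s1 = s1, s2 = s2, delta_t = delta_t,
                 dls = dls, doublet_groups = doublet_groups),
            class = "labeled_pattern")
}

#' @export
print.labeled_pattern <- function(x, ...) {
  cat(sprintf(
    "labeled pattern on '%s': %d Time-1 events%s%s%s\n",
    x$hemisphere$id, length(x$s1),
    if (!is.null(x$s2)) sprintf(", %d Time-2 events", length(x$s2)) else "",
    if (!is.na(x$delta_t)) sprintf(", dt = %g h", x$delta_t) else "",
    if (length(x$dls)) sprintf(", %d DLS", length(x$dls)) else ""))
  invisible(x)
}

# shared K computation: rows of `dsub` are the reference events (with weights
# `w`, one column per radius), columns are the target events; `norm` is the
# final normalisation (A / (n_ref * n_target_divisor)).
.k_from_counts <- function(dsub, w, radii, norm, exclude_self = FALSE) {
  vapply(seq_along(radii), function(ri) {
    cnt <- rowSums(dsub <= radii[ri])
    if (exclude_self) cnt <- cnt - 1 # own zero distance always counted
    norm * sum(w[, ri] * cnt)
  }, numeric(1))
}

.edge_w <- function(h, cells, radii, edge_correction, n_points = 256L) {
  if (edge_correction == "none")
    matrix(1, length(cells), length(radii))
  else
    edge_weights(h, cells, radii, n_points)
}

#' Discrete spatial Ripley's K
#'
#' For S cells in S-phase on a hemisphere with N NSCs and area A, counts
#' S-phase neighbours within radius r of each S-phase cell:
#' \deqn{K_S(r) = (S/A)^{-1} \sum_i w(i,r) \frac{\sum_{j \ne i} 1\{d(i,j) \le r\}}{S}}
#' The pattern is "discrete" because events can only occur at NSC positions;
#' the corresponding null model resamples event locations from all NSCs
#' (see [sampling_envelope()]).
#'
#' @param p a [labeled_pattern()]; its `s1` set is analysed.
#' @param d a [distance_matrix()] for the pattern's hemisphere.
#' @param radii increasing positive radius grid (micrometres).
#' @param edge_correction `"fraction"` applies the inside-disc-fraction
#'   weight w(i,r); `"none"` sets all weights to 1.
#' @return numeric vector of K values (square micrometres), one per radius.
#' @export
ripley_spatial <- function(p, d, radii = seq(10, 300, by = 10),
                           edge_correction = c("fraction", "none")) {
  edge_correction <- match.arg(edge_correction)
  .assert(all(diff(radii) > 0) && all(radii > 0),
          "radii must be positive and increasing")
  s <- p$s1
  if (length(s) == 0) stop("no events to analyze", call. = FALSE)
  if (length(s) == 1) return(rep(0, length(radii)))
  ent <- .dist_entries(d)
  h <- p$hemisphere
  w <- .edge_w(h, s, radii, edge_correction)
  dsub <- ent[s, s, drop = FALSE]
  .k_from_counts(dsub, w, radii,
                 norm = h$area / length(s)^2, exclude_self = TRUE)
}

#' Discrete spatiotemporal Ripley's K
#'
#' Counts Time-2 S-phase cells within radius r around each Time-1 S-phase
#' cell:
#' \deqn{K_{ST}(r) = (S_1/A)^{-1} \sum_{i \in S_1} w(i,r) \frac{\sum_{j \in S_2} 1\{d(i,j) \le r\}}{S_2}}
#' A cell appearing in both sets contributes its own zero distance (the
#' inner sum does not exclude j = i).
#'
#' @inheritParams ripley_spatial
#' @return numeric vector of K values, one per radius.
#' @export
ripley_spatiotemporal <- function(p, d, radii = seq(10, 300, by = 10),
                                  edge_correction = c("fraction", "none")) {
  edge_correction <- match.arg(edge_correction)
  .assert(all(diff(radii) > 0) && all(radii > 0),
          "radii must be positive and increasing")
  if (length(p$s1) == 0 || length(p$s2) == 0)
    stop("no events to analyze: both S1 and S2 must be non-empty",
         call. = FALSE)
  ent <- .dist_entries(d)
  h <- p$hemisphere
  w <- .edge_w(h, p$s1, radii, edge_correction)
  .st_k(ent[p$s1, , drop = FALSE], p$s2, w, radii,
        h$area / (length(p$s1) * length(p$s2)))
}

# K_ST from a (S1 x N) distance block; reused by the envelope resampler
.st_k <- function(d1all, s2, w, radii, norm) {
  dsub <- d1all[, s2, drop = FALSE]
  .k_from_counts(dsub, w, radii, norm, exclude_self = FALSE)
}

#' Random-sampling envelope for discrete Ripley's K
#'
#' Builds the discrete-randomness null by resampling event locations from
#' all NSCs (without replacement): in spatial mode the S observed events are
#' resampled; in spatiotemporal mode only the Time-2 events are resampled
#' while Time-1 locations stay fixed. Returns the per-radius 5% and 95%
#' quantiles (linear interpolation) across `n_samples` resamplings.
#'
#' @inheritParams ripley_spatial
#' @param mode `"spatial"` or `"spatiotemporal"`.
#' @param n_samples number of random resamplings (>= 2).
#' @param seed optional integer seed for reproducible envelopes.
#' @return list with `q05`, `q95` (numeric per radius) and `k_samples`
#'   (matrix `n_samples` x `length(radii)`).
#' @export
sampling_envelope <- function(p, d, radii = seq(10, 300, by = 10),
                              mode = c("spatial", "spatiotemporal"),
                              n_samples = 20L, seed = NULL,
                              edge_correction = c("fraction", "none")) {
  mode <- match.arg(mode)
  edge_correction <- match.arg(edge_correction)
  .assert(n_samples >= 2, "n_samples must be >= 2")
  h <- p$hemisphere
  n <- n_cells(h)
  ent <- .dist_entries(d)
  ks <- .with_seed(seed, {
    if (mode == "spatial") {
      s <- length(p$s1)
      .assert(s <= n, "more events than NSCs")
      do.call(rbind, lapply(seq_len(n_samples), function(b) {
        samp <- sort(sample.int(n, s))
        ripley_spatial(labeled_pattern(h, samp), ent, radii,
                       edge_correction)
      }))
    } else {
      .assert(length(p$s2) <= n, "more events than NSCs")
      w <- .edge_w(h, p$s1, radii, edge_correction)
      d1all <- ent[p$s1, , drop = FALSE]
      norm <- h$area / (length(p$s1) * length(p$s2))
      do.call(rbind, lapply(seq_len(n_samples), function(b) {
        samp <- sort(sample.int(n, length(p$s2)))
        .st_k(d1all, samp, w, radii, norm)
      }))
    }
  })
  q <- apply(ks, 2, stats::quantile, probs = c(0.05, 0.95), type = 7)
  list(q05 = q[1, ], q95 = q[2, ], k_samples = ks)
}

#' Standardize K values against a sampling envelope
#'
#' Linear rescaling per radius so that a K value on the 95% envelope
#' quantile maps to +1 and one on the 5% quantile maps to -1. Radii where
#' the envelope is degenerate (q95 = q05) map to 0, i.e. "not
#' distinguishable from random".
#'
#' @param k_values observed K values.
#' @param q05,q95 envelope quantiles from [sampling_envelope()].
#' @return numeric vector of standardized values (z-scores).
#' @export
standardize_k <- function(k_values, q05, q95) {
  .assert(length(k_values) == length(q05) && length(q05) == length(q95),
          "k_values, q05 and q95 must have the same length")
  .assert(all(q95 >= q05), "q95 must be >= q05")
  m <- (q95 + q05) / 2
  hw <- (q95 - q05) / 2
  z <- ifelse(hw > 0, (k_values - m) / hw, 0)
  as.numeric(z)
}

#' Classify a standardized K curve
#'
#' Averages the standardized K over the radius window (30-150 micrometres by
#' default) and classifies: mean above +1 is "aggregated", below -1 is
#' "dispersed", otherwise "random".
#'
#' @param z_scores standardized K values from [standardize_k()].
#' @param radii radius grid matching `z_scores`.
#' @param window inclusive radius window over which the mean is taken.
#' @return one of `"aggregated"`, `"random"`, `"dispersed"`, with the mean
#'   z-score attached as attribute `"mean_z"`.
#' @export
classify_pattern <- function(z_scores, radii, window = c(30, 150)) {
  .assert(length(z_scores) == length(radii), "length mismatch")
  sel <- radii >= window[1] & radii <= window[2]
  if (!any(sel)) stop("no radii fall inside the classification window",
                      call. = FALSE)
  mz <- mean(z_scores[sel])
  cls <- if (mz > 1) "aggregated" else if (mz < -1) "dispersed" else "random"
  structure(cls, mean_z = mz)
}

#' Full discrete Ripley's K analysis of one pattern
#'
#' Convenience wrapper running the observed K, the random-sampling envelope,
#' standardization and classification in one call.
#'
#' @inheritParams sampling_envelope
#' @param window classification window passed to [classify_pattern()].
#' @return object of class `"ripley_curve"`: list with `radii`, `k`,
#'   `q05`, `q95`, `z`, `classification`, `mean_z` and `mode`.
#' @export
ripley_curve <- function(p, d, radii = seq(10, 300, by = 10),
                         mode = c("spatial", "spatiotemporal"),
                         n_samples = 20L, seed = NULL,
                         edge_correction = c("fraction", "none"),
                         window = c(30, 150)) {
  mode <- match.arg(mode)
  edge_correction <- match.arg(edge_correction)
  k <- if (mode == "spatial") ripley_spatial(p, d, radii, edge_correction)
       else ripley_spatiotemporal(p, d, radii, edge_correction)
  env <- sampling_envelope(p, d, radii, mode, n_samples, seed,
                           edge_correction)
  z <- standardize_k(k, env$q05, env$q95)
  cls <- classify_pattern(z, radii, window)
  structure(list(radii = radii, k = k, q05 = env$q05, q95 = env$q95,
                 z = z, classification = as.character(cls),
                 mean_z = attr(cls, "mean_z"), mode = mode),
            class = "ripley_curve")
}

#' @export
print.ripley_curve <- function(x, ...) {
  cat(sprintf("discrete Ripley's K (%s): %s (mean z = %.2f over window)\n",
              x$mode, x$classification, x$mean_z))
  invisible(x)
}
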