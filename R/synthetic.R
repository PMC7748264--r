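#' Generate a synthetic hemisphere
#'
#' Quasi-regular NSC point cloud: a hexagonal packing with positional
#' jitter, either on a flat disc or on a spherical cap. NSC somata tile the
#' ventricular surface as a single cell layer, so a perturbed regular
#' packing is a closer stand-in than uniform random placement (which would
#' change the envelope widths of the discrete statistics). The default
#' spacing reproduces the observed density of roughly 200 NSCs within a
#' 100-micrometre radius.
#'
#' @param n_cells number of NSCs (>= 3).
#' @param geometry `"flat-disc"` (z = 0) or `"spherical-cap"`.
#' @param spacing hexagonal lattice spacing in micrometres.
#' @param jitter uniform positional jitter amplitude in micrometres; a
#'   warning is raised at `jitter >= spacing / 2`.
#' @param cap_radius sphere radius for the spherical cap, micrometres; the
#'   lattice is laid out in geodesic polar coordinates so all points lie at
#'   distance `cap_radius` from the sphere centre (the origin).
#' @param seed optional integer seed.
#' @param id hemisphere identifier.
#' @return a [hemisphere()].
#' @export
generate_hemisphere <- function(n_cells, geometry = c("flat-disc",
                                                      "spherical-cap"),
                                spacing = 13.4, jitter = 2,
                                cap_radius = 300, seed = NULL,
                                id = "synthetic") {
  geometry <- match.arg(geometry)
  .assert(n_cells >= 3, "n_cells must be at least 3")
  if (jitter >= spacing / 2)
    warning("jitter of half the lattice spacing or more risks coincident ",
            "points", call. = FALSE)
  .with_seed(seed, {
    pts <- .hex_disc(n_cells, spacing)
    ang <- stats::runif(n_cells, 0, 2 * pi)
    rad <- jitter * sqrt(stats::runif(n_cells))
    pts <- pts + cbind(rad * cos(ang), rad * sin(ang))
    if (geometry == "flat-disc") {
      hemisphere(cbind(pts, 0), id = id)
    } else {
      # interpret lattice radius as geodesic distance on the sphere
      rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
      theta <- atan2(pts[, 2], pts[, 1])
      phi <- rho / cap_radius # colatitude
      .assert(max(phi) < pi / 2,
              "cap exceeds a hemisphere; increase cap_radius or spacing")
      hemisphere(cap_radius * cbind(sin(phi) * cos(theta),
                                    sin(phi) * sin(theta),
                                    cos(phi)), id = id)
    }
  })
}

#' Generate a labeled division pattern with known ground truth
#'
#' Time-1 events are drawn uniformly without replacement from all NSCs;
#' Time-2 events are drawn sequentially without replacement from the
#' categorical distribution with weight `g^c(k)`, where `c(k)` counts the
#' Time-1 events within distance `r` of candidate NSC `k` - the enrichment
#' compounds per nearby Time-1 event, which is the generative twin of the
#' per-cell interaction placement likelihood, so the interaction fit is
#' identified on these patterns. `g = 1` reduces to uniform sampling
#' (random pattern), `g > 1` produces aggregation, `g < 1` dispersion.
#'
#' @param h a [hemisphere()].
#' @param n1,n2 number of Time-1 / Time-2 events.
#' @param g interaction strength (> 0).
#' @param r interaction radius, micrometres.
#' @param d optional precomputed [distance_matrix()] (geodesic by default).
#' @param delta_t labeling interval stored with the pattern.
#' @param seed optional integer seed.
#' @return a [labeled_pattern()] with attribute `"truth"` (list `g`, `r`).
#' @export
generate_pattern <- function(h, n1, n2, g = 1, r = 100, d = NULL,
                             delta_t = NA_real_, seed = NULL) {
  .assert(g > 0 && r > 0, "g and r must be positive")
  n <- n_cells(h)
  .assert(n1 + n2 <= n, "n1 + n2 must not exceed the number of NSCs")
  if (is.null(d)) d <- distance_matrix(h, "geodesic")
  ent <- .dist_entries(d)
  .with_seed(seed, {
    s1 <- sort(sample.int(n, n1))
    cand <- setdiff(seq_len(n), s1)
    if (length(cand) < n2) stop("fewer candidates than n2", call. = FALSE)
    cnt <- colSums(ent[s1, cand, drop = FALSE] <= r)
    w <- g^cnt
    s2 <- integer(n2)
    avail <- seq_along(cand)
    for (b in seq_len(n2)) {
      pick <- avail[sample.int(length(avail), 1, prob = w[avail])]
      s2[b] <- cand[pick]
      avail <- avail[avail != pick]
    }
    out <- labeled_pattern(h, s1 = s1, s2 = sort(s2), delta_t = delta_t)
    attr(out, "truth") <- list(g = g, r = r)
    out
  })
}

#' Simulate per-interval labeling fraction tables from known kinetics
#'
#' Runs one independent cohort simulation per hemisphere and labeling
#' interval and collects the observed redivision and DLS fractions - a
#' synthetic counterpart of the per-hemisphere double-labeling data that
#' feeds [abc_fit()].
#'
#' @param kinetics a [cell_cycle_params()].
#' @param hemispheres_per_interval replicate hemispheres per interval.
#' @param intervals labeling intervals in hours.
#' @param n_cells founder cells per cohort.
#' @param t_end simulated span, hours.
#' @param seed optional integer seed.
#' @param per_daughter redivision variant passed to [simulate_cohort()].
#' @return data.frame with columns `hemisphere`, `delta_t`, `n_labeled_t1`,
#'   `rediv`, `dls`.
#' @export
generate_observed_fractions <- function(kinetics,
                                        hemispheres_per_interval = 6L,
                                        intervals = c(9, 18, 24, 32, 48, 72),
                                        n_cells = 10000L, t_end = 450,
                                        seed = NULL, per_daughter = TRUE) {
  rows <- list()
  k <- 0L
  for (ii in seq_along(intervals)) {
    for (b in seq_len(hemispheres_per_interval)) {
      k <- k + 1L
      coh <- simulate_cohort(kinetics, n_cells = n_cells, t_end = t_end,
                             seed = .substream(seed, k),
                             per_daughter = per_daughter)
      rd <- virtual_double_label(coh, t_end - intervals[ii], t_end)
      rows[[k]] <- data.frame(
        hemisphere = sprintf("sim-%02d", k), delta_t = intervals[ii],
        n_labeled_t1 = rd$n_labeled_t1,
        rediv = rd$rediv_fraction, dls = rd$dls_fraction)
    }
  }
  do.call(rbind, rows)
}

#' Synthetic per-hemisphere count table
#'
#' A synthetic stand-in for a per-hemisphere summary table of a 36-
#' hemisphere double-labeling study (6 hemispheres per labeling interval,
#' 9-72 h): NSC counts drawn around 2,356 +/- 460 and adjusted to sum to
#' 87,807; about 1.9% of NSCs in S-phase per snapshot; redivision and DLS
#' counts drawn from the cell-division model at the supplied kinetics. The
#' packaged copy (`inst/extdata/s1_table_synthetic.csv`) was written by this
#' function with `seed = 42`.
#'
#' @param seed integer seed (the fixture uses 42).
#' @param kinetics kinetics used for the expected redivision/DLS fractions.
#' @param n_total total NSC count the table is adjusted to.
#' @param s_fraction mean snapshot S-phase fraction of NSCs.
#' @return data.frame with columns `hemisphere`, `delta_t`, `n_nsc`,
#'   `s_t1`, `s_t2`, `nsc_s_t1`, `nsc_s_t2`, `rediv`, `nsc_rediv`, `dls`,
#'   `nsc_dls`.
#' @export
synthetic_s1_table <- function(seed = 42L, kinetics = fitted_kinetics(),
                               n_total = 87807L, s_fraction = 0.019) {
  intervals <- c(9, 18, 24, 32, 48, 72)
  n_hemi <- 36L
  .with_seed(seed, {
    # expected observable fractions per interval from the division model
    probs <- lapply(intervals, function(dt) {
      coh <- simulate_cohort(kinetics, n_cells = 30000L, t_end = 450)
      rd <- virtual_double_label(coh, 450 - dt, 450)
      list(rediv = rd$rediv_fraction, dls = rd$dls_fraction)
    })
    names(probs) <- intervals
    n_nsc <- pmax(1000L, round(stats::rnorm(n_hemi, 2356, 460)))
    n_nsc <- n_nsc + round((n_total - sum(n_nsc)) / n_hemi)
    n_nsc[n_hemi] <- n_nsc[n_hemi] + (n_total - sum(n_nsc))
    dt <- rep(intervals, each = n_hemi / length(intervals))
    nsc_s_t1 <- stats::rbinom(n_hemi, n_nsc, s_fraction)
    nsc_s_t2 <- stats::rbinom(n_hemi, n_nsc, s_fraction)
    # intermediate progenitors add roughly 40% more S-phases on top of NSCs
    s_t1 <- nsc_s_t1 + stats::rbinom(n_hemi, n_nsc, 0.4 * s_fraction)
    s_t2 <- nsc_s_t2 + stats::rbinom(n_hemi, n_nsc, 0.4 * s_fraction)
    pr <- vapply(as.character(dt), function(i) probs[[i]]$rediv, 0)
    pd <- vapply(as.character(dt), function(i) probs[[i]]$dls, 0)
    nsc_rediv <- stats::rbinom(n_hemi, nsc_s_t1, pr)
    nsc_dls <- stats::rbinom(n_hemi, nsc_s_t1, pd)
    rediv <- nsc_rediv + stats::rbinom(n_hemi, s_t1 - nsc_s_t1, pr)
    dls <- nsc_dls + stats::rbinom(n_hemi, s_t1 - nsc_s_t1, pd)
    data.frame(hemisphere = sprintf("H%02d", seq_len(n_hemi)),
               delta_t = as.integer(dt), n_nsc = as.integer(n_nsc),
               s_t1 = as.integer(s_t1), s_t2 = as.integer(s_t2),
               nsc_s_t1 = as.integer(nsc_s_t1),
               nsc_s_t2 = as.integer(nsc_s_t2),
               rediv = as.integer(rediv), nsc_rediv = as.integer(nsc_rediv),
               dls = as.integer(dls), nsc_dls = as.integer(nsc_dls))
  })
}
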