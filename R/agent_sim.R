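# hexagonal packing of n points centred at the origin (used both by the
# synthetic hemisphere generator and the agent simulator's initial sheet)
.hex_disc <- function(n, spacing) {
  rows_needed <- ceiling(sqrt(n / (2 / sqrt(3)))) + 3L
  j <- seq(-rows_needed, rows_needed)
  pts <- do.call(rbind, lapply(j, function(row) {
    y <- row * spacing * sqrt(3) / 2
    xoff <- if (row %% 2 == 0) 0 else spacing / 2
    x <- seq(-rows_needed, rows_needed) * spacing + xoff
    cbind(x, y)
  }))
  ord <- order(pts[, 1]^2 + pts[, 2]^2)
  pts[ord[seq_len(n)], , drop = FALSE]
}

#' Configuration of the agent-based NSC sheet simulation
#'
#' Defaults follow the redivision variant: baseline spontaneous division
#' rate 9e-4 per hour (the control variant without redivisions uses 1e-3),
#' redivision probability 0.38, 10% of divisions producing a gfap-negative
#' daughter that leaves the stem-cell pool one cell cycle later, growth from
#' 500 cells until the colony reaches a target size drawn from
#' Normal(2356, 460) truncated at 1000.
#'
#' @param p_div baseline division rate per hour per quiescent eligible cell.
#' @param p_rediv probability that a division spawns one immediately
#'   re-entering daughter.
#' @param differentiation_fraction probability that a division produces a
#'   gfap-negative daughter.
#' @param n_init initial number of cells.
#' @param n_target stopping population size (gfap-positive cells); `NULL`
#'   draws from Normal(2356, 460) truncated at 1000.
#' @param timestep simulation step in hours for the spontaneous-entry
#'   Bernoulli trials.
#' @param cell_diameter min/max cell diameter in micrometres (sets the
#'   daughter placement offset).
#' @param spacing equilibrium centre-to-centre spacing of the sheet in
#'   micrometres; the default reproduces the observed packing of roughly
#'   200 NSCs within a 100-micrometre radius.
#' @param t_max hard cap on simulated time (hours); exceeding it is an
#'   error with diagnostics.
#' @param t_stop optional fixed horizon (hours): the run ends at `t_stop`
#'   even if the target size was not reached (useful for event-free
#'   configurations).
#' @param per_daughter_rediv logical; if `TRUE` each of the two daughters
#'   re-enters the cycle independently with probability `p_rediv`, if
#'   `FALSE` at most one daughter per division re-enters.
#' @param seed optional integer seed stored with the configuration.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(p_div = 9e-4, p_rediv = 0.38,
                       differentiation_fraction = 0.10,
                       n_init = 500L, n_target = NULL, timestep = 0.5,
                       cell_diameter = c(7, 10), spacing = 13.4,
                       t_max = 40000, t_stop = NULL,
                       per_daughter_rediv = TRUE, seed = NULL) {
  .assert(p_div >= 0 && p_rediv >= 0 && differentiation_fraction >= 0,
          "rates must be non-negative")
  .assert(timestep > 0, "timestep must be positive")
  if (!is.null(n_target)) .assert(n_init < n_target, "n_init < n_target")
  structure(list(p_div = p_div, p_rediv = p_rediv,
                 differentiation_fraction = differentiation_fraction,
                 n_init = as.integer(n_init), n_target = n_target,
                 timestep = timestep, cell_diameter = cell_diameter,
                 spacing = spacing, t_max = t_max, t_stop = t_stop,
                 per_daughter_rediv = per_daughter_rediv, seed = seed),
            class = "sim_config")
}

#' Control-variant configuration (no redivisions)
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()] with `p_div = 1e-3` and `p_rediv = 0`.
#' @export
control_config <- function(...) {
  args <- list(...)
  defaults <- list(p_div = 1e-3, p_rediv = 0)
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Agent-based simulation of a growing NSC sheet
#'
#' Off-lattice 2D simulation of centroid-based soft-disc cells. Each
#' quiescent gfap-positive cell divides spontaneously per `timestep` with
#' probability `p_div * timestep`, so the per-cell division rate equals
#' `p_div` - the calibration used to derive the rate from the observed
#' S-phase fraction and S-phase length. Every cell waits one
#' lag-exponential cell-cycle duration after its creation before its
#' Bernoulli trials begin; that drawn cycle is placed immediately before
#' the eventual division, so its S-phase occupies the cycle end. At a
#' division the two daughters are placed adjacently and local overlap is
#' relaxed by soft repulsion, with a uniform dilation of the sheet
#' accommodating the inserted area; daughters re-enter the cycle
#' immediately with probability `p_rediv` (redivisions divide after one
#' lag-exponential cycle, independently of the base rate, and chains
#' continue); with probability `differentiation_fraction` one
#' non-re-entering daughter is gfap-negative, never divides, and is
#' removed one further cycle duration later. The run ends when the
#' gfap-positive population reaches the target size.
#'
#' The per-step Bernoulli trials are simulated exactly but lazily: each
#' quiescent cell draws the geometric number of steps until its division,
#' making the simulation event-driven without changing the distribution.
#'
#' @param config a [sim_config()].
#' @param kinetics a [cell_cycle_params()] (cycle-length distribution).
#' @param seed optional integer seed (defaults to `config$seed`).
#' @return object of class `"population_trajectory"`: list with `cells`
#'   (data.frame: id, parent, x, y, gfap, birth, alive), `cycles`
#'   (data.frame: cell, start, division - including the cycle in progress
#'   at the end of the run), `divisions` (data.frame: time, mother,
#'   daughter, redivider, gfapneg), `t_end`, `t_transient`, `config`,
#'   `kinetics`.
#' @export
simulate_population <- function(config, kinetics, seed = NULL) {
  .assert(inherits(config, "sim_config"), "invalid config")
  .assert(inherits(kinetics, "cell_cycle_params"), "invalid kinetics")
  seed <- seed %||% config$seed
  .with_seed(seed, .simulate_population_impl(config, kinetics))
}

.simulate_population_impl <- function(config, kinetics) {
  dt <- config$timestep
  p_step <- min(1, config$p_div * dt)
  n_target <- config$n_target %||%
    max(1000, round(stats::rnorm(1, 2356, 460)))
  .assert(config$n_init < n_target, "n_init must be below n_target")
  cap <- 3L * as.integer(n_target) + 1000L

  # state vectors
  x <- y <- birth <- div_at <- rem_at <- rep(NA_real_, cap)
  parent <- rep(NA_integer_, cap)
  gfap <- alive <- rediv_flag <- rep(FALSE, cap)
  init <- .hex_disc(config$n_init, config$spacing)
  n <- config$n_init
  x[1:n] <- init[, 1] + stats::runif(n, -0.5, 0.5)
  y[1:n] <- init[, 2] + stats::runif(n, -0.5, 0.5)
  birth[1:n] <- 0; gfap[1:n] <- TRUE; alive[1:n] <- TRUE
  div_at[1:n] <- Inf; rem_at[1:n] <- Inf

  cyc_cap <- 4L * cap
  cyc_cell <- integer(cyc_cap); cyc_start <- numeric(cyc_cap)
  cyc_div <- numeric(cyc_cap); cyc_n <- 0L
  log_cycle <- function(cell, start, division) {
    cyc_n <<- cyc_n + 1L
    cyc_cell[cyc_n] <<- cell
    cyc_start[cyc_n] <<- start
    cyc_div[cyc_n] <<- division
  }
  # schedule the next spontaneous division of a quiescent gfap-positive
  # cell: per step it divides with probability p_div * dt (drawn lazily as
  # a geometric step count), so the per-cell division rate equals p_div -
  # which is how the rate was calibrated from the observed S-phase fraction
  # (0.019 / 18 h). The cell cycle preceding the division is implicit: its
  # length is drawn from the lag-exponential and the S-phase window is
  # placed at its end. Only the initial cells carry the one-cycle maturity
  # wait before their Bernoulli trials start.
  schedule_division <- function(i, t0) {
    if (p_step <= 0) { div_at[i] <<- Inf; return(invisible()) }
    cyc_len <- rlagexp(1, kinetics$beta_cc, kinetics$d_cc)
    k <- stats::rgeom(1, p_step)
    division <- (ceiling((t0 + cyc_len) / dt) + k + 1) * dt
    div_at[i] <<- division
    log_cycle(i, division - cyc_len, division)
  }
  for (i in 1:n) schedule_division(i, 0)

  dv_time <- numeric(cap); dv_mother <- dv_daughter <- integer(cap)
  dv_rediv <- integer(cap); dv_gfapneg <- logical(cap); dv_n <- 0L
  offset <- mean(config$cell_diameter) / 2
  t_transient <- NA_real_
  n_gfap <- n

  r0 <- config$spacing
  # cheap local relaxation right after a division
  relax_local <- function(cx, cy) {
    d2 <- (x - cx)^2 + (y - cy)^2
    sel <- which(alive & !is.na(d2) & d2 < 40^2)
    if (length(sel) < 2) return(invisible())
    px <- x[sel]; py <- y[sel]
    m <- length(sel)
    for (it in 1:2) {
      dxm <- outer(px, px, "-"); dym <- outer(py, py, "-")
      dm <- sqrt(dxm^2 + dym^2)
      ov <- which(dm < r0 - 0.05 & upper.tri(dm), arr.ind = TRUE)
      if (!nrow(ov)) break
      d <- pmax(dm[ov], 1e-6)
      ux <- dxm[ov] / d; uy <- dym[ov] / d
      push <- 0.4 * (r0 - d)
      idx <- c(ov[, 1], ov[, 2])
      fx <- rowsum(c(ux * push, -ux * push), idx)
      fy <- rowsum(c(uy * push, -uy * push), idx)
      at <- as.integer(rownames(fx))
      px[at] <- px[at] + fx; py[at] <- py[at] + fy
    }
    x[sel] <<- px; y[sel] <<- py
    invisible()
  }
  # uniform tissue dilation: scaling all positions by sqrt(m/(m-1)) about
  # the colony centroid creates exactly the area one inserted cell needs,
  # so the sheet keeps its equilibrium packing while it grows; the local
  # relaxation then redistributes the insertion spot itself
  dilate <- function() {
    sel <- which(alive)
    m <- length(sel)
    k <- sqrt(m / (m - 1))
    cx <- mean(x[sel]); cy <- mean(y[sel])
    x[sel] <<- cx + (x[sel] - cx) * k
    y[sel] <<- cy + (y[sel] - cy) * k
    invisible()
  }

  repeat {
    # dead or event-free cells hold Inf, so the scans need no masking
    i_div <- which.min(div_at)
    i_rem <- which.min(rem_at)
    t_div <- if (length(i_div)) div_at[i_div] else Inf
    t_rem <- if (length(i_rem)) rem_at[i_rem] else Inf
    t <- min(t_div, t_rem)
    if (!is.null(config$t_stop) && t > config$t_stop) {
      t_end <- config$t_stop
      break
    }
    if (!is.finite(t))
      stop("population target unreachable: no scheduled events remain ",
           "(p_div = ", config$p_div, ", population ", n_gfap, "/",
           n_target, ")", call. = FALSE)
    if (t > config$t_max)
      stop("simulation exceeded t_max = ", config$t_max, " h at population ",
           n_gfap, "/", n_target, call. = FALSE)
    if (t_rem <= t_div) {
      alive[i_rem] <- FALSE
      rem_at[i_rem] <- Inf
      next
    }
    i <- i_div
    div_at[i] <- Inf
    # create daughter: mother keeps its id (carrying any Time-1 label),
    # the newborn gets a fresh id; both are displaced symmetrically
    n <- n + 1L
    if (n > cap) stop("cell capacity exceeded", call. = FALSE)
    j <- n
    ang <- stats::runif(1, 0, 2 * pi)
    ux <- cos(ang); uy <- sin(ang)
    x[j] <- x[i] + offset * ux; y[j] <- y[i] + offset * uy
    x[i] <- x[i] - offset * ux; y[i] <- y[i] - offset * uy
    parent[j] <- i; birth[j] <- t; alive[j] <- TRUE
    gfap[j] <- TRUE; div_at[j] <- Inf; rem_at[j] <- Inf

    if (config$per_daughter_rediv) {
      rediv_i <- stats::runif(1) < config$p_rediv
      rediv_j <- stats::runif(1) < config$p_rediv
    } else {
      rediv_i <- FALSE
      rediv_j <- stats::runif(1) < config$p_rediv
    }
    want_diff <- stats::runif(1) < config$differentiation_fraction
    # differentiation takes a daughter that is not re-entering the cycle
    diff_cand <- c(if (!rediv_i) i, if (!rediv_j) j)
    diff_id <- if (want_diff && length(diff_cand))
      diff_cand[sample.int(length(diff_cand), 1)] else NA_integer_
    dv_n <- dv_n + 1L
    dv_time[dv_n] <- t
    dv_mother[dv_n] <- i
    dv_daughter[dv_n] <- j
    dv_rediv[dv_n] <- rediv_i + rediv_j
    dv_gfapneg[dv_n] <- !is.na(diff_id)

    start_cycle <- function(id) {
      rediv_flag[id] <<- TRUE
      division <- t + rlagexp(1, kinetics$beta_cc, kinetics$d_cc)
      div_at[id] <<- division
      log_cycle(id, t, division)
    }
    for (id in c(i, j)) {
      if ((id == i && rediv_i) || (id == j && rediv_j)) {
        start_cycle(id)
      } else if (!is.na(diff_id) && id == diff_id) {
        gfap[id] <- FALSE
        rem_at[id] <- t + rlagexp(1, kinetics$beta_cc, kinetics$d_cc)
        n_gfap <- n_gfap - 1L
      } else {
        schedule_division(id, t)
      }
    }
    n_gfap <- n_gfap + 1L
    dilate()
    relax_local(x[j], y[j])
    if (is.na(t_transient) && n_gfap >= 2L * config$n_init)
      t_transient <- t
    if (n_gfap >= n_target) {
      t_end <- t
      break
    }
  }

  structure(list(
    cells = data.frame(id = 1:n, parent = parent[1:n], x = x[1:n],
                       y = y[1:n], gfap = gfap[1:n], birth = birth[1:n],
                       alive = alive[1:n], redivider = rediv_flag[1:n]),
    cycles = data.frame(cell = cyc_cell[seq_len(cyc_n)],
                        start = cyc_start[seq_len(cyc_n)],
                        division = cyc_div[seq_len(cyc_n)]),
    divisions = data.frame(time = dv_time[seq_len(dv_n)],
                           mother = dv_mother[seq_len(dv_n)],
                           daughter = dv_daughter[seq_len(dv_n)],
                           redivider = dv_rediv[seq_len(dv_n)],
                           gfapneg = dv_gfapneg[seq_len(dv_n)]),
    t_end = t_end, t_transient = t_transient %||% NA_real_,
    n_target = n_target, config = config, kinetics = kinetics),
    class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf(
    "population trajectory: %d cells (%d gfap+ alive) after %.0f h, %d divisions\n",
    nrow(x$cells), sum(x$cells$alive & x$cells$gfap), x$t_end,
    nrow(x$divisions)))
  invisible(x)
}

#' Virtual double-labeling measurement on an agent simulation
#'
#' Takes two snapshot measurements, Time 2 at the end of the run and Time 1
#' `delta_t` hours earlier. S-phase windows are drawn post hoc for every
#' logged cell cycle from the lag-exponential S-phase distribution (length
#' capped by the cycle length, placed at the end of the cycle). Cells whose
#' window covers Time 1 form `s1`; cells whose window covers Time 2 and
#' that do not carry the Time-1 label form `s2`; a single window covering
#' both times is a DLS and is assigned to Time 1 only. The pattern lives on
#' the final positions of all alive gfap-positive cells.
#'
#' @param traj a [simulate_population()] result.
#' @param delta_t labeling interval in hours; Time 1 must fall after the
#'   initial transient of the simulation.
#' @param kinetics a [cell_cycle_params()] for the S-phase distribution
#'   (defaults to the trajectory's kinetics).
#' @param seed optional integer seed for the post-hoc S-phase draws.
#' @param t2_labels `"all"` marks every cell in S-phase at Time 2 (the
#'   virtual-measurement protocol: marks carry no label chemistry, so a
#'   re-entered cell appears in both sets and the spatiotemporal K counts
#'   its zero distance, as the statistic permits); `"exclusive"` mirrors
#'   the experimental assignment of double-labeled cells to Time 1 only.
#' @return a [labeled_pattern()] on the final hemisphere; attribute
#'   `"n_rediv"` counts s2 cells descending from an s1-labeled cell, and
#'   attribute `"empty"` flags patterns without events at either time.
#' @export
virtual_measurement <- function(traj, delta_t, kinetics = traj$kinetics,
                                seed = NULL,
                                t2_labels = c("all", "exclusive")) {
  t2_labels <- match.arg(t2_labels)
  t2 <- traj$t_end
  t1 <- t2 - delta_t
  .assert(t1 > 0, "delta_t exceeds the simulated span")
  if (!is.na(traj$t_transient) && t1 < traj$t_transient)
    warning("Time 1 falls inside the initial transient of the simulation",
            call. = FALSE)
  cyc <- traj$cycles[traj$cycles$start <= t2, , drop = FALSE]
  len <- cyc$division - cyc$start
  sp <- .with_seed(seed, {
    sp <- rlagexp(nrow(cyc), kinetics$beta_sp, kinetics$d_sp)
    bad <- which(sp > len)
    while (length(bad)) {
      sp[bad] <- rlagexp(length(bad), kinetics$beta_sp, kinetics$d_sp)
      bad <- bad[sp[bad] > len[bad]]
    }
    sp
  })
  s_start <- cyc$division - sp
  s_end <- cyc$division
  cov1 <- s_start <= t1 & t1 <= s_end
  cov2 <- s_start <= t2 & t2 <= s_end
  lab1_ids <- unique(cyc$cell[cov1])
  dls_ids <- unique(cyc$cell[cov1 & cov2])
  lab2_ids <- unique(cyc$cell[cov2])
  if (t2_labels == "exclusive")
    lab2_ids <- setdiff(lab2_ids, lab1_ids)

  cells <- traj$cells
  keep <- cells$alive & cells$gfap
  final_ids <- cells$id[keep]
  h <- hemisphere(cbind(cells$x[keep], cells$y[keep], 0),
                  id = sprintf("sim-dt%g", delta_t))
  s1 <- match(intersect(lab1_ids, final_ids), final_ids)
  s2 <- match(intersect(lab2_ids, final_ids), final_ids)
  dls <- match(intersect(dls_ids, final_ids), final_ids)

  # redivision annotation: s2 cells descending from an s1-labeled cell
  par <- cells$parent
  lab1_set <- cells$id %in% lab1_ids
  n_rediv <- 0L
  for (id in intersect(lab2_ids, final_ids)) {
    p <- par[id]
    while (!is.na(p)) {
      if (lab1_set[p]) { n_rediv <- n_rediv + 1L; break }
      p <- par[p]
    }
  }
  # sibling groups among labeled division events between the two times
  dv <- traj$divisions
  sel <- dv$time >= t1 & dv$time <= t2 & dv$mother %in% lab1_ids
  groups <- if (any(sel))
    lapply(which(sel), function(k) {
      idx <- match(intersect(c(dv$mother[k], dv$daughter[k]), final_ids),
                   final_ids)
      idx[!is.na(idx)]
    })
  else NULL

  out <- labeled_pattern(h, s1 = sort(s1), s2 = sort(s2),
                         delta_t = delta_t, dls = sort(dls),
                         doublet_groups = groups)
  attr(out, "n_rediv") <- n_rediv
  attr(out, "empty") <- length(s1) == 0 || length(s2) == 0
  out
}

#' Run a full in-silico double-labeling experiment
#'
#' Simulates `n_hemispheres` independent colonies, takes a virtual
#' double-labeling measurement per colony (labeling intervals assigned
#' cyclically from `delta_t`), computes the spatiotemporal discrete
#' Ripley's K with sampling envelopes and classifies every pattern, and
#' fits the interaction model jointly per labeling interval.
#'
#' @param n_hemispheres number of simulated colonies.
#' @param delta_t labeling intervals in hours, recycled over hemispheres.
#' @param config a [sim_config()].
#' @param kinetics a [cell_cycle_params()].
#' @param seed integer seed; every colony uses a derived substream.
#' @param radii radius grid for the Ripley's K analysis.
#' @param n_samples envelope resamplings.
#' @param mh_samples posterior draws per interaction fit.
#' @param t2_labels Time-2 labeling protocol, see [virtual_measurement()].
#' @return list with `results` (data.frame per hemisphere: delta_t, n1, n2,
#'   classification, mean_z, n_rediv), `fits` (named list of
#'   [fit_interaction()] objects per interval), `aggregated_fraction`,
#'   `strengths` (most-likely g per interval) and `significance`
#'   (from [strength_significance()]).
#' @export
run_insilico_experiment <- function(n_hemispheres = 36L,
                                    delta_t = c(9, 18, 24, 32, 48, 72),
                                    config = sim_config(),
                                    kinetics = fitted_kinetics(),
                                    seed = NULL,
                                    radii = seq(10, 150, by = 10),
                                    n_samples = 20L,
                                    mh_samples = 4000L,
                                    t2_labels = "all") {
  dts <- rep_len(delta_t, n_hemispheres)
  res <- vector("list", n_hemispheres)
  groups <- split(seq_len(n_hemispheres), dts)
  fit_data <- vector("list", n_hemispheres)
  for (k in seq_len(n_hemispheres)) {
    traj <- simulate_population(config, kinetics,
                                seed = .substream(seed, 7L * k))
    p <- virtual_measurement(traj, dts[k], kinetics,
                             seed = .substream(seed, 7L * k + 1L),
                             t2_labels = t2_labels)
    if (isTRUE(attr(p, "empty"))) {
      res[[k]] <- data.frame(hemisphere = k, delta_t = dts[k],
                             n1 = length(p$s1), n2 = length(p$s2),
                             classification = NA_character_,
                             mean_z = NA_real_, n_rediv = attr(p, "n_rediv"))
      next
    }
    # the flat sheet only needs distances from the Time-1 events to all
    # cells, both for the spatiotemporal K (S1 rows) and for the fit
    h <- p$hemisphere
    n <- n_cells(h)
    cross <- .cross_dist(h$coords[p$s1, , drop = FALSE], h$coords)
    w <- edge_weights(h, p$s1, radii)
    norm <- h$area / (length(p$s1) * length(p$s2))
    kobs <- .st_k(cross, p$s2, w, radii, norm)
    ks <- .with_seed(.substream(seed, 7L * k + 2L),
      do.call(rbind, lapply(seq_len(n_samples), function(b) {
        samp <- sort(sample.int(n, length(p$s2)))
        .st_k(cross, samp, w, radii, norm)
      })))
    q <- apply(ks, 2, stats::quantile, probs = c(0.05, 0.95), type = 7)
    z <- standardize_k(kobs, q[1, ], q[2, ])
    cls <- classify_pattern(z, radii)
    cand <- setdiff(seq_len(n), p$s1)
    s2fit <- setdiff(p$s2, p$s1)
    dS1cand <- apply(cross[, cand, drop = FALSE], 2, sort)
    if (is.null(dim(dS1cand)))
      dS1cand <- matrix(dS1cand, nrow = length(p$s1))
    fit_data[[k]] <- list(
      dS1cand = dS1cand,
      pooled_s2 = sort(as.vector(cross[, s2fit, drop = FALSE])),
      n_s2 = length(s2fit))
    res[[k]] <- data.frame(hemisphere = k, delta_t = dts[k],
                           n1 = length(p$s1), n2 = length(p$s2),
                           classification = as.character(cls),
                           mean_z = attr(cls, "mean_z"),
                           n_rediv = attr(p, "n_rediv"))
  }
  results <- do.call(rbind, res)
  fits <- list()
  for (dt in sort(unique(dts))) {
    ds <- fit_data[groups[[as.character(dt)]]]
    ds <- ds[!vapply(ds, is.null, TRUE)]
    if (!length(ds)) next
    fits[[as.character(dt)]] <-
      fit_interaction(ds, n_samples = mh_samples,
                      seed = .substream(seed, 100003L + dt))
  }
  strengths <- vapply(fits, function(f) unname(f$point["g"]), 0)
  cls <- results$classification[!is.na(results$classification)]
  list(results = results, fits = fits,
       aggregated_fraction = mean(cls == "aggregated"),
       strengths = strengths,
       significance = if (length(strengths) >= 2)
         strength_significance(strengths, as.numeric(names(fits)))
       else NULL)
}
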