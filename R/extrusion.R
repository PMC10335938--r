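# Stochastic loop-extrusion engine: R surface over the C++ step kernel.

#' Simulation parameters
#'
#' Parameters of the discrete-time loop-extrusion engine. Probabilities are
#' per step of `dt` model-hours; `v` is the extrusion speed in bins per
#' anchor per step, so the physical speed is `v * bin_size / dt` bp per
#' model-hour.
#'
#' @param bin_size lattice bin width in bp (default 2 kb, the finest
#'   contact-map resolution the model is compared against).
#' @param dt model-hours per simulation step.
#' @param v bins traveled per anchor per step.
#' @param load_rate expected cohesin loadings per model-hour.
#' @param w_active loading weight per active-gene-body bin (transcription-
#'   coupled loading; NIPBL enrichment over transcribed segments).
#' @param w_background loading weight per other bin of the cluster-plus-T-DOM
#'   span.
#' @param unload_prob per-extruder, per-step release probability.
#' @param stall_unload_factor multiplier on `unload_prob` while at least one
#'   anchor is stalled at a CBS: CTCF-anchored cohesin is stabilized against
#'   release, which lets a loop migrate down the CBS series over several
#'   stall-bypass cycles; 1 = no stabilization.
#' @param p_stall probability that an anchor halts when its path crosses an
#'   occupied CBS whose blocking face opposes its travel direction.
#' @param p_bypass per-step probability that a stalled anchor passes the
#'   barrier.
#' @param max_extruders cap on simultaneously bound extruders.
#' @param alpha background contact distance-decay exponent.
#' @param c0 background contact amplitude.
#' @param seed integer RNG seed used by [init_lattice()].
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(bin_size = 2000, dt = 0.01, v = 1L, load_rate = 20,
                       w_active = 50, w_background = 0.1,
                       unload_prob = 0.0067, stall_unload_factor = 0.3,
                       p_stall = 1, p_bypass = 5e-04, max_extruders = 400L,
                       alpha = 1, c0 = 0.05, seed = 1L) {
  p <- list(bin_size = bin_size, dt = dt, v = as.integer(v),
            load_rate = load_rate, w_active = w_active,
            w_background = w_background, unload_prob = unload_prob,
            stall_unload_factor = stall_unload_factor,
            p_stall = p_stall, p_bypass = p_bypass,
            max_extruders = as.integer(max_extruders), alpha = alpha,
            c0 = c0, seed = as.integer(seed))
  probs <- c(unload_prob = p$unload_prob, p_stall = p$p_stall,
             p_bypass = p$p_bypass,
             stalled_unload = p$unload_prob * p$stall_unload_factor)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (p$v < 1L) stop("v must be >= 1")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$alpha <= 0) stop("alpha must be > 0")
  if (p$load_rate < 0 || p$w_active < 0 || p$w_background < 0)
    stop("rates and weights must be non-negative")
  structure(p, class = "sim_params")
}

# blocking direction per orientation: TOWARD_TDOM sites stall anchors
# travelling toward C-DOM (decreasing bins); TOWARD_CDOM sites stall anchors
# travelling toward T-DOM (increasing bins). Convergent in-cluster/T-DOM
# pairs therefore trap loops between them.
barrier_table <- function(lattice) {
  s <- lattice$cbs[lattice$cbs$occupied, , drop = FALSE]
  s <- s[order(s$bin), , drop = FALSE]
  list(bin = as.integer(s$bin - 1L),
       dir = ifelse(s$orientation == "TOWARD_TDOM", -1L, 1L))
}

empty_zones <- function(n_bins) {
  list(gene_lo = integer(0), gene_hi = integer(0),
       maint_lo = integer(0), maint_hi = integer(0),
       enh_mask = rep(FALSE, n_bins), enh_first = n_bins)
}

#' Initialize an empty lattice state
#'
#' @param lattice a `hox_lattice` from [discretize()].
#' @param params a `sim_params`.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return a `lattice_state` with no extruders at time `t0`.
#' @export
init_lattice <- function(lattice, params, seed = params$seed, t0 = 0) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  structure(list(time = t0,
                 left = integer(0), right = integer(0),
                 left_stalled = logical(0), right_stalled = logical(0),
                 birth = numeric(0),
                 lattice = lattice),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> t = %.3f h, %d extruders\n", x$time,
              length(x$left)))
  invisible(x)
}

state_to_cpp <- function(state) {
  list(left = as.integer(state$left - 1L), right = as.integer(state$right - 1L),
       left_stalled = state$left_stalled, right_stalled = state$right_stalled,
       birth = state$birth, time = state$time)
}

state_from_cpp <- function(res, lattice) {
  structure(list(time = res$time,
                 left = as.integer(res$left + 1L),
                 right = as.integer(res$right + 1L),
                 left_stalled = res$left_stalled,
                 right_stalled = res$right_stalled,
                 birth = res$birth, lattice = lattice),
            class = "lattice_state")
}

run_kernel <- function(state, n_steps, params, loading_values, zones = NULL,
                       log_events = TRUE) {
  lattice <- state$lattice
  if (is.null(zones)) zones <- empty_zones(lattice$n_bins)
  if (length(loading_values) != lattice$n_bins)
    stop("loading profile length must equal n_bins")
  if (any(loading_values < 0)) stop("loading profile must be non-negative")
  bars <- barrier_table(lattice)
  cp <- c(unclass(params), list(n_bins = lattice$n_bins))
  res <- .ht_run_steps(state_to_cpp(state), as.integer(n_steps), cp,
                       bars$bin, bars$dir, as.numeric(loading_values),
                       as.integer(zones$gene_lo), as.integer(zones$gene_hi),
                       as.integer(zones$maint_lo), as.integer(zones$maint_hi),
                       zones$enh_mask, as.integer(zones$enh_first), log_events)
  res
}

#' Advance the simulation by one step
#'
#' Applies, in order: loading (Poisson, positions proportional to the
#' loading profile), movement with orientation-dependent CTCF stalling,
#' stochastic bypass of stalled anchors, and unloading. Anchors clamp at the
#' lattice edges.
#'
#' @param state a `lattice_state`.
#' @param loading_profile a `hox_track` of per-bin loading weights (length
#'   `n_bins`, non-negative), or a plain numeric vector.
#' @param params a `sim_params`.
#' @return the updated `lattice_state`; step events are attached as
#'   attribute `"events"`.
#' @export
simulate_step <- function(state, loading_profile, params) {
  vals <- if (inherits(loading_profile, "hox_track")) loading_profile$values else loading_profile
  res <- run_kernel(state, 1L, params, vals)
  out <- state_from_cpp(res, state$lattice)
  attr(out, "events") <- data.frame(time = res$ev_time,
                                    kind = c("load", "unload", "stall", "bypass")[res$ev_kind],
                                    position = res$ev_pos + 1L)
  out
}

#' Run the extrusion engine over a time window
#'
#' Repeatedly applies the step kernel from `t_start` to `t_end`, recording
#' snapshots of all anchor positions at a fixed cadence. The loading
#' function is evaluated at the start of each snapshot interval and held
#' constant within it (piecewise-constant loading).
#'
#' @param lattice a `hox_lattice`.
#' @param loading_fn function `time -> hox_track` (or numeric vector) of
#'   loading weights; may also be a single constant track.
#' @param params a `sim_params`.
#' @param t_start,t_end simulation window in model-hours.
#' @param snapshot_every snapshot cadence in model-hours.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return a `hox_trajectory` with snapshot times, anchor-pair snapshots and
#'   the event log.
#' @export
run_extrusion <- function(lattice, loading_fn, params, t_start = 0,
                          t_end = 1, snapshot_every = 1, seed = params$seed) {
  stopifnot(t_end >= t_start)
  if (!is.function(loading_fn)) {
    prof <- loading_fn
    loading_fn <- function(t) prof
  }
  state <- init_lattice(lattice, params, seed = seed, t0 = t_start)
  times <- state$time
  snaps <- list(cbind(left = state$left, right = state$right))
  ev <- list()
  steps_per_snap <- max(1L, round(snapshot_every / params$dt))
  n_total <- round((t_end - t_start) / params$dt)
  done <- 0L
  while (done < n_total) {
    k <- min(steps_per_snap, n_total - done)
    prof <- loading_fn(state$time)
    vals <- if (inherits(prof, "hox_track")) prof$values else prof
    res <- run_kernel(state, k, params, vals)
    state <- state_from_cpp(res, lattice)
    done <- done + k
    times <- c(times, state$time)
    snaps[[length(snaps) + 1L]] <- cbind(left = state$left, right = state$right)
    if (length(res$ev_time))
      ev[[length(ev) + 1L]] <- data.frame(time = res$ev_time,
                                          kind = c("load", "unload", "stall", "bypass")[res$ev_kind],
                                          position = res$ev_pos + 1L)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time = numeric(0), kind = character(0), position = integer(0))
  new_trajectory(times, snaps, events, lattice)
}

new_trajectory <- function(times, snapshots, events, lattice) {
  structure(list(times = times, snapshots = snapshots, events = events,
                 n_bins = lattice$n_bins, bin_size = lattice$bin_size,
                 axis_start = lattice$axis_start, chrom = lattice$chrom),
            class = "hox_trajectory")
}

#' @export
print.hox_trajectory <- function(x, ...) {
  cat(sprintf("<hox_trajectory> %d snapshots (%.4g..%.4g h), %d events\n",
              length(x$times), min(x$times), max(x$times), nrow(x$events)))
  invisible(x)
}

#' Anchor occupancy track
#'
#' Counts anchor observations per bin across all snapshots (the RAD21 ChIP
#' proxy): every left and every right anchor of every snapshot contributes
#' one count to each bin within `half_window` of its position. With
#' `half_window = 0` the track sums to twice the total number of
#' extruder-snapshots.
#'
#' @param traj a `hox_trajectory`.
#' @param half_window smoothing half-window in bins.
#' @param t_range optional `c(t_min, t_max)` restricting the snapshots used.
#' @return a `hox_track` of counts.
#' @export
anchor_occupancy <- function(traj, half_window = 0L, t_range = NULL) {
  if (!length(traj$snapshots)) stop("empty trajectory")
  idx <- seq_along(traj$times)
  if (!is.null(t_range))
    idx <- idx[traj$times >= t_range[1] & traj$times <= t_range[2]]
  counts <- numeric(traj$n_bins)
  for (i in idx) {
    sn <- traj$snapshots[[i]]
    if (!nrow(sn)) next
    pos <- c(sn[, "left"], sn[, "right"])
    tab <- tabulate(pos, nbins = traj$n_bins)
    counts <- counts + tab
  }
  if (half_window > 0L) {
    cs <- cumsum(c(0, counts))
    b <- seq_len(traj$n_bins)
    lo <- pmax(1L, b - half_window)
    hi <- pmin(traj$n_bins, b + half_window)
    counts <- cs[hi + 1L] - cs[lo]
  }
  track(counts, chrom = traj$chrom, axis_start = traj$axis_start,
        bin_size = traj$bin_size)
}

#' Contact map from a trajectory
#'
#' Distance-decay background plus anchor bridging: the background is
#' `c0 * |i - j|^-alpha` off the diagonal, and every extruder of every
#' snapshot adds one (symmetrized) count at its anchor pair, scaled by
#' `1 / n_snapshots`.
#'
#' @param traj a `hox_trajectory`.
#' @param params a `sim_params` (for `alpha` and `c0`).
#' @param t_range optional `c(t_min, t_max)` restricting the snapshots used
#'   (e.g. a window around one timepoint of a timecourse).
#' @return a `hox_map` (symmetric matrix with axis metadata).
#' @export
contact_map <- function(traj, params, t_range = NULL) {
  if (!length(traj$snapshots)) stop("empty trajectory")
  idx <- seq_along(traj$times)
  if (!is.null(t_range))
    idx <- idx[traj$times >= t_range[1] & traj$times <= t_range[2]]
  if (!length(idx)) stop("no snapshots in t_range")
  n <- traj$n_bins
  m <- power_law_background(n, params$alpha, params$c0)
  add <- matrix(0, n, n)
  for (i in idx) {
    sn <- traj$snapshots[[i]]
    if (!nrow(sn)) next
    for (k in seq_len(nrow(sn))) {
      l <- sn[k, "left"]; r <- sn[k, "right"]
      add[l, r] <- add[l, r] + 1
      add[r, l] <- add[r, l] + 1
    }
  }
  m <- m + add / length(idx)
  new_contact_map(m, traj$chrom, traj$axis_start, traj$bin_size)
}

power_law_background <- function(n, alpha, c0) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  m <- ifelse(d == 0, 0, c0 * d^(-alpha))
  m
}

new_contact_map <- function(matrix, chrom = "chr", axis_start = 0,
                            bin_size = 1) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  structure(list(matrix = matrix, chrom = chrom,
                 axis_start = as.numeric(axis_start),
                 bin_size = as.numeric(bin_size)),
            class = "hox_map")
}

#' @export
print.hox_map <- function(x, ...) {
  cat(sprintf("<hox_map> %d x %d bins of %g bp (%s)\n", nrow(x$matrix),
              ncol(x$matrix), x$bin_size, x$chrom))
  invisible(x)
}

#' Mean contact between two bin regions
#'
#' @param map a `hox_map`.
#' @param region_a,region_b integer bin ranges.
#' @return mean of the matrix entries over `region_a x region_b`.
#' @export
region_contact <- function(map, region_a, region_b) {
  if (!length(region_a) || !length(region_b)) stop("empty region")
  n <- nrow(map$matrix)
  if (any(c(region_a, region_b) < 1) || any(c(region_a, region_b) > n))
    stop("region outside axis")
  mean(map$matrix[region_a, region_b, drop = FALSE])
}
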