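# Shared fixtures and independent oracles for the test suite.

# A minimal flat locus: one gene, one left-blocking CBS, no regions beyond
# the cluster. Used to exercise the engine without HoxD geometry.
flat_locus <- function(n_kb = 100, cbs_pos = 60000,
                       orientation = "TOWARD_TDOM") {
  genes <- data.frame(name = "g1", start = 80000, end = 84000,
                      domain = "anterior", stringsAsFactors = FALSE)
  ctcf <- data.frame(id = "CBS1", pos = cbs_pos, orientation = orientation,
                     occupied = TRUE, in_cluster = TRUE,
                     stringsAsFactors = FALSE)
  regions <- data.frame(name = "cluster", start = 0, end = n_kb * 1000,
                        active_from = NA_real_, stringsAsFactors = FALSE)
  hox_locus("flat", 0, n_kb * 1000, genes, ctcf, regions, genotype = "flat")
}

# Place extruders by hand into a lattice state.
place_extruders <- function(state, left, right, left_stalled = FALSE,
                            right_stalled = FALSE) {
  n <- length(left)
  state$left <- as.integer(left)
  state$right <- as.integer(right)
  state$left_stalled <- rep_len(left_stalled, n)
  state$right_stalled <- rep_len(right_stalled, n)
  state$birth <- rep(state$time, n)
  state
}

# Hand-built trajectory object (no simulation).
manual_trajectory <- function(snapshots, n_bins, bin_size = 1,
                              axis_start = 0, times = seq_along(snapshots)) {
  structure(list(times = times, snapshots = snapshots,
                 events = data.frame(time = numeric(0), kind = character(0),
                                     position = integer(0)),
                 n_bins = n_bins, bin_size = bin_size,
                 axis_start = axis_start, chrom = "chr"),
            class = "hox_trajectory")
}

# Independent brute-force recount of the bridging contact model.
brute_force_map <- function(traj, alpha, c0) {
  n <- traj$n_bins
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) m[i, j] <- c0 * abs(i - j)^(-alpha)
  for (sn in traj$snapshots) {
    if (!nrow(sn)) next
    for (k in seq_len(nrow(sn))) {
      l <- sn[k, 1]; r <- sn[k, 2]
      m[l, r] <- m[l, r] + 1 / length(traj$snapshots)
      if (l != r) m[r, l] <- m[r, l] + 1 / length(traj$snapshots)
      else m[l, r] <- m[l, r] + 1 / length(traj$snapshots)
    }
  }
  m
}

# Textbook Welch unequal-variances t-test, written independently.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Fast simulation settings for engine unit tests.
fast_sim <- function(...) {
  args <- list(load_rate = 0, w_active = 1, w_background = 1,
               unload_prob = 0, stall_unload_factor = 1, p_stall = 1,
               p_bypass = 0, c0 = 0.05, alpha = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

# Cache expensive replicate sets across acceptance-test blocks.
.accept_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .accept_cache))
    assign(key, expr, envir = .accept_cache)
  get(key, envir = .accept_cache)
}
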