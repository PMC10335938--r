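test_that("parameter validation and lattice initialization", {
  expect_error(sim_params(p_stall = 1.2), "probabilities")
  expect_error(sim_params(v = 0), "v must be")
  expect_error(sim_params(dt = 0), "dt must be")
  expect_error(sim_params(alpha = -1), "alpha")
  lat <- discretize(flat_locus(), 1000)
  st <- init_lattice(lat, fast_sim(seed = 7), t0 = 0)
  expect_equal(length(st$left), 0L)
  expect_equal(st$time, 0)
  # same seed gives identical RNG state
  init_lattice(lat, fast_sim(seed = 11))
  s1 <- .Random.seed
  init_lattice(lat, fast_sim(seed = 11))
  expect_identical(.Random.seed, s1)
})

test_that("a free extruder separates by 2*v bins per step; time advances", {
  lat <- discretize(flat_locus(), 1000)
  loc_noCBS <- flat_locus()
  loc_noCBS$ctcf <- loc_noCBS$ctcf[0, ]
  lat0 <- discretize(loc_noCBS, 1000)
  for (v in c(1L, 3L)) {
    p <- fast_sim(v = v)
    st <- init_lattice(lat0, p, t0 = 0)
    st <- place_extruders(st, 50, 50)
    prof <- rep(1, lat0$n_bins)
    for (k in 1:5) st <- simulate_step(st, prof, p)
    expect_equal(st$right - st$left, 2L * v * 5L)
    expect_equal(st$time, 5 * p$dt)
  }
  # no loading, no extruders: state unchanged except time
  p <- fast_sim()
  st <- init_lattice(lat0, p, t0 = 0)
  st2 <- simulate_step(st, rep(1, lat0$n_bins), p)
  expect_equal(length(st2$left), 0L)
  expect_equal(st2$time, p$dt)
})

test_that("stalled-anchor residence matches the geometric closed form", {
  # barrier blocking leftward travel; anchors start one bin to its right
  loc <- flat_locus(cbs_pos = 50500)
  lat <- discretize(loc, 1000)
  cbs_bin <- lat$cbs$bin[1]
  p <- fast_sim(p_bypass = 0.1, seed = 42)
  set.seed(42)
  n <- 2000
  st <- init_lattice(lat, p, t0 = 0)
  st <- place_extruders(st, rep(cbs_bin + 1L, n), rep(cbs_bin + 1L, n))
  prof <- rep(1, lat$n_bins)
  stalled_steps <- 0
  for (k in 1:250) {
    st <- simulate_step(st, prof, p)
    stalled_steps <- stalled_steps + sum(st$left_stalled)
  }
  # residence in bypass draws = steps observed stalled + the releasing draw;
  # mean of Geometric(p_bypass) = 1/p_bypass = 10 draws
  residence <- stalled_steps / n + 1
  expect_lt(abs(residence - 10) / 10, 0.05)
})

test_that("steady-state anchor separation matches a brute-force renewal average", {
  # big barrier-free lattice, loading confined to the center
  loc <- flat_locus(n_kb = 2000)
  loc$ctcf <- loc$ctcf[0, ]
  lat <- discretize(loc, 1000)
  p <- sim_params(load_rate = 400, unload_prob = 0.02,
                  stall_unload_factor = 1, p_stall = 0, p_bypass = 0,
                  w_active = 1, w_background = 1, seed = 5)
  prof <- numeric(lat$n_bins)
  prof[900:1100] <- 1
  traj <- run_extrusion(lat, prof, p, t_start = 0, t_end = 6,
                        snapshot_every = 0.05)
  # discard burn-in; average separation across snapshots
  keep <- traj$times > 2
  seps <- unlist(lapply(traj$snapshots[keep],
                        function(s) s[, "right"] - s[, "left"]))
  # oracle: age of an extruder observed at a random time is length-biased;
  # enumerate ages over 10,000 simulated geometric lifetimes
  set.seed(99)
  L <- rgeom(10000, p$unload_prob) + 1
  ages <- unlist(lapply(L, seq_len))
  expected <- 2 * p$v * mean(ages)
  expect_lt(abs(mean(seps) - expected) / expected, 0.1)
})

test_that("barrier semantics: orientation-gated, absolute at p_stall=1/p_bypass=0", {
  loc <- flat_locus(cbs_pos = 50500)   # TOWARD_TDOM: blocks leftward anchors
  lat <- discretize(loc, 1000)
  cbs_bin <- lat$cbs$bin[1]
  p <- fast_sim(load_rate = 50, unload_prob = 0.01,
                stall_unload_factor = 1, seed = 3)
  prof <- numeric(lat$n_bins)
  prof[(cbs_bin + 5):(cbs_bin + 40)] <- 1   # loading 3' of the barrier only
  traj <- run_extrusion(lat, prof, p, 0, 100, snapshot_every = 0.1,
                        seed = 3)
  all_pos <- do.call(rbind, traj$snapshots)
  expect_gt(nrow(all_pos), 1000)
  expect_true(all(all_pos[, "left"] >= cbs_bin))       # nothing passes 5'
  expect_true(all(all_pos[, "left"] <= all_pos[, "right"]))  # ordering
  # the reverse orientation is transparent to the same traffic
  loc2 <- flat_locus(cbs_pos = 50500, orientation = "TOWARD_CDOM")
  traj2 <- run_extrusion(discretize(loc2, 1000), prof, p, 0, 50,
                         snapshot_every = 0.1, seed = 3)
  all2 <- do.call(rbind, traj2$snapshots)
  expect_true(any(all2[, "left"] < cbs_bin))
})

test_that("first passage past a barrier is monotone in the bypass rate", {
  loc <- flat_locus(cbs_pos = 50500)
  lat <- discretize(loc, 1000)
  cbs_bin <- lat$cbs$bin[1]
  prof <- numeric(lat$n_bins); prof[(cbs_bin + 2):(cbs_bin + 20)] <- 1
  fp_median <- function(p_bypass) {
    fps <- vapply(1:100, function(s) {
      p <- fast_sim(load_rate = 20, p_bypass = p_bypass, seed = s)
      traj <- run_extrusion(lat, prof, p, 0, 10, snapshot_every = 0.05,
                            seed = s)
      hit <- vapply(traj$snapshots, function(sn)
        nrow(sn) > 0 && any(sn[, "left"] < cbs_bin), TRUE)
      if (any(hit)) traj$times[which(hit)[1]] else Inf
    }, 0)
    median(fps)
  }
  meds <- vapply(c(0.001, 0.01, 0.1), fp_median, 0)
  expect_true(all(diff(meds) < 0))
})

test_that("trajectories are bit-identical under identical seeds", {
  loc <- hoxd_locus()
  lat <- discretize(loc, 2000)
  p <- sim_params(seed = 17)
  prof <- numeric(lat$n_bins); prof[400:500] <- 1
  t1 <- run_extrusion(lat, prof, p, 0, 5, snapshot_every = 0.5, seed = 17)
  t2 <- run_extrusion(lat, prof, p, 0, 5, snapshot_every = 0.5, seed = 17)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$events, t2$events)
})

test_that("anchor occupancy counts are conserved and localize at barriers", {
  # conservation: window-0 sum equals twice the total extruder-snapshots
  snaps <- list(cbind(left = c(2L, 5L), right = c(7L, 5L)),
                cbind(left = 3L, right = 9L))
  traj <- manual_trajectory(snaps, n_bins = 10)
  occ <- anchor_occupancy(traj, 0)
  expect_equal(sum(occ$values), 2 * 3)
  expect_equal(occ$values[5], 2)  # both anchors of the point extruder
  # smoothing window preserves nothing but spreads counts
  occ1 <- anchor_occupancy(traj, 1)
  expect_equal(occ1$values[4], sum(occ$values[3:5]))
  # empty trajectory of snapshots -> zero track
  traj0 <- manual_trajectory(list(cbind(left = integer(0), right = integer(0))),
                             n_bins = 10)
  expect_equal(sum(anchor_occupancy(traj0, 0)$values), 0)
  # strong barrier + 3' loading concentrates left anchors at the CBS bin
  loc <- flat_locus(cbs_pos = 50500)
  lat <- discretize(loc, 1000)
  cbs_bin <- lat$cbs$bin[1]
  p <- fast_sim(load_rate = 100, unload_prob = 0.005,
                stall_unload_factor = 1, seed = 1)
  prof <- numeric(lat$n_bins); prof[(cbs_bin + 3):(cbs_bin + 30)] <- 1
  traj <- run_extrusion(lat, prof, p, 0, 50, snapshot_every = 0.5, seed = 1)
  occ <- anchor_occupancy(traj, 0)
  expect_equal(which.max(occ$values), cbs_bin)
})

test_that("contact maps equal background plus bridging, exactly", {
  p <- fast_sim()
  # pure power-law background and its analytic ratios
  traj0 <- manual_trajectory(list(cbind(left = integer(0), right = integer(0))),
                             n_bins = 30)
  m0 <- contact_map(traj0, p)
  i <- 5L
  expect_equal(m0$matrix[i, i + 2] / m0$matrix[i, i + 4], 2^p$alpha)
  expect_equal(m0$matrix, t(m0$matrix))
  expect_equal(diag(m0$matrix), rep(0, 30))
  # a permanent loop adds exactly 1.0 over background after scaling
  snaps <- replicate(3, cbind(left = 4L, right = 20L), simplify = FALSE)
  traj <- manual_trajectory(snaps, n_bins = 30)
  m <- contact_map(traj, p)
  expect_equal(m$matrix[4, 20] - m0$matrix[4, 20], 1.0)
  expect_equal(m$matrix[20, 4] - m0$matrix[20, 4], 1.0)
  # oracle equivalence on small random trajectories
  set.seed(31)
  for (rep in 1:5) {
    snaps <- lapply(1:4, function(k) {
      n <- sample(0:2, 1)
      l <- sort(sample(1:30, n, replace = TRUE))
      r <- pmin(30L, l + sample(0:10, n, replace = TRUE))
      cbind(left = as.integer(l), right = as.integer(r))
    })
    traj <- manual_trajectory(snaps, n_bins = 30)
    m <- contact_map(traj, p)
    expect_equal(m$matrix, brute_force_map(traj, p$alpha, p$c0))
  }
})

test_that("region contact means obey symmetry and trivial identities", {
  m <- new_contact_map(matrix(3, 6, 6))
  expect_equal(region_contact(m, 2:3, 4:6), 3)
  mm <- matrix(runif(36), 6); mm <- (mm + t(mm)) / 2
  m2 <- new_contact_map(mm)
  expect_equal(region_contact(m2, 1:2, 5:6), region_contact(m2, 5:6, 1:2))
  expect_equal(region_contact(m2, 2, 5), mm[2, 5])
  expect_error(region_contact(m2, integer(0), 1:2), "empty region")
  expect_error(region_contact(m2, 1:2, 7), "outside axis")
})

test_that("anchored extruders are stabilized against release", {
  loc <- flat_locus(cbs_pos = 50500)
  lat <- discretize(loc, 1000)
  cbs_bin <- lat$cbs$bin[1]
  prof <- numeric(lat$n_bins); prof[(cbs_bin + 2):(cbs_bin + 20)] <- 1
  pool_size <- function(sf, seed) {
    p <- sim_params(load_rate = 20, unload_prob = 0.01, p_bypass = 0,
                    p_stall = 1, stall_unload_factor = sf, seed = seed)
    traj <- run_extrusion(lat, prof, p, 0, 40, snapshot_every = 1, seed = seed)
    mean(vapply(traj$snapshots[20:41],
                function(s) sum(s[, "left"] == cbs_bin), 0))
  }
  pools_prot <- vapply(1:5, function(s) pool_size(0.1, s), 0)
  pools_free <- vapply(1:5, function(s) pool_size(1, s), 0)
  expect_gt(median(pools_prot), 2 * median(pools_free))
})
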