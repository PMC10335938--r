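test_that("initial chromatin is condensed: repressed everywhere, no active mark", {
  loc <- hoxd_locus()
  lat <- discretize(loc, 2000)
  ch <- init_chromatin(loc, lat)
  expect_equal(sum(ch$k27ac$values), 0)
  for (i in seq_len(nrow(lat$genes)))
    expect_true(all(ch$k27me3$values[lat$genes$start_bin[i]:lat$genes$end_bin[i]] > 0))
  expect_true(all(ch$k27me3$values * ch$k27ac$values == 0))
  expect_true(all(ch$gene_states$state == "SILENT"))
})

test_that("Wnt firing follows the exponential closed form", {
  loc <- toy_locus()
  lat <- discretize(loc, 2000)
  tp <- timer_params(t_wnt = 2, anterior_activation_rate = 0.5)
  ch0 <- init_chromatin(loc, lat)
  # before the pulse: nothing
  expect_identical(wnt_activation(ch0, loc, 1, tp)$gene_states,
                   ch0$gene_states)
  # infinite rate: everything anterior fires exactly at t_wnt
  tpi <- timer_params(t_wnt = 2, anterior_activation_rate = Inf)
  ch1 <- wnt_activation(ch0, loc, 2, tpi)
  expect_equal(ch1$gene_states$state[1], "ACTIVE")
  expect_equal(ch1$gene_states$activation_time[1], 2)
  expect_equal(ch1$gene_states$state[2:3], c("SILENT", "SILENT"))
  # Monte-Carlo firing probability over one window vs 1 - exp(-r dt)
  set.seed(202)
  dt <- 0.5
  fired <- vapply(1:10000, function(i) {
    ch <- wnt_activation(ch0, loc, 3, tp, dt = dt)
    ch$gene_states$state[1] == "ACTIVE"
  }, TRUE)
  expect_lt(abs(mean(fired) - (1 - exp(-0.5 * dt))), 0.02 * 1)
})

test_that("loading weights track the active gene set monotonically", {
  loc <- hoxd_locus()
  lat <- discretize(loc, 2000)
  sp <- sim_params(w_active = 10, w_background = 0.1)
  ch <- init_chromatin(loc, lat)
  w0 <- loading_profile(ch, loc, lat, sp)
  cl <- lat$regions[lat$regions$name == "cluster", ]
  expect_true(all(w0$values[cl$start_bin:lat$n_bins] == 0.1))
  expect_true(all(w0$values[seq_len(cl$start_bin - 1)] == 0))
  ch1 <- hoxtimer:::fire_gene(ch, "Hoxd9", 100)
  w1 <- loading_profile(ch1, loc, lat, sp)
  g <- lat$genes[lat$genes$name == "Hoxd9", ]
  expect_true(all(w1$values[g$start_bin:g$end_bin] == 10))
  expect_equal(sum(w1$values == 10), g$end_bin - g$start_bin + 1)
  expect_true(all(w1$values >= w0$values))
})

test_that("contact-driven firing matches the exponential waiting-time quantile", {
  loc <- toy_locus()
  lat <- discretize(loc, 2000)
  ch0 <- init_chromatin(loc, lat)
  ch0 <- hoxtimer:::fire_gene(ch0, "gA", 0)   # erase gB downstream of gA
  tp <- timer_params(t_enh = 0, k_act = 0.4, polycomb_factor = 1,
                     erasure_velocity = 1e9)
  # zero contact: silent forever
  up <- activation_update(ch0, c(gB = 0, gC = 0), tp, dt = 5, t = 10,
                          anterior = "gA")
  expect_equal(up$chromatin$gene_states$state[2], "SILENT")
  # infinite hazard: fires this step
  up2 <- activation_update(ch0, c(gB = Inf), tp, dt = 0.1, t = 10,
                           anterior = "gA")
  expect_equal(up2$chromatin$gene_states$state[2], "ACTIVE")
  # constant contact c: median waiting time = ln 2 / (k c)
  set.seed(7)
  k <- 0.4; cc <- 2; dt <- 0.25
  waits <- vapply(1:10000, function(i) {
    ch <- ch0; t <- 0
    repeat {
      t <- t + dt
      up <- activation_update(ch, c(gB = cc, gC = 0), tp, dt, t,
                              anterior = "gA")
      ch <- up$chromatin
      if ("gB" %in% up$fired) return(t)
      if (t > 60) return(Inf)
    }
  }, 0)
  theory <- log(2) / (k * cc)
  # discrete-time median of the geometric approximation, within 5% after
  # accounting for the dt grid (compare on the continuous quantile)
  expect_lt(abs(median(waits) - theory) / theory, 0.05 + dt / theory)
})

test_that("repressive-mark erasure follows the front at its bp velocity", {
  loc <- hoxd_locus()
  tp <- timer_params(erasure_velocity = 300)
  lags <- hoxtimer:::erasure_lags(loc, tp)
  # the pre-looped CBS1 element removes the d4-d8 gap from the path
  expect_equal(unname(lags["Hoxd8"]), 0)
  # lag equals gap / velocity elsewhere
  g <- loc$genes
  gap <- g$start[g$name == "Hoxd9"] - g$end[g$name == "Hoxd10"]
  expect_equal(unname(lags["Hoxd10"]), gap / 300)
  # closely spaced posterior genes erase much faster than central ones
  expect_lt(lags["Hoxd13"], lags["Hoxd10"] / 3)
  # erasure_update respects the lag
  lat <- discretize(loc, 2000)
  ch <- init_chromatin(loc, lat)
  ch <- hoxtimer:::fire_gene(ch, "Hoxd9", 100)
  d10 <- lat$genes[lat$genes$name == "Hoxd10", ]
  ch1 <- hoxtimer:::erasure_update(ch, lags, 100 + lags["Hoxd10"] - 0.1)
  expect_true(any(ch1$k27me3$values[d10$start_bin:d10$end_bin] > 0))
  ch2 <- hoxtimer:::erasure_update(ch, lags, 100 + lags["Hoxd10"] + 0.1)
  expect_true(all(ch2$k27me3$values[d10$start_bin:d10$end_bin] == 0))
})

test_that("run_timer is reproducible and respects its gating structure", {
  loc <- hoxd_locus()
  r1 <- run_timer(loc, seed = 3, t_end = 100, keep_trajectory = FALSE)
  r2 <- run_timer(loc, seed = 3, t_end = 100, keep_trajectory = FALSE)
  expect_identical(r1$schedule, r2$schedule)
  expect_identical(r1$contact_haz, r2$contact_haz)
  # cluster genes never activate before the Wnt pulse
  expect_true(all(r1$schedule >= timer_params()$t_wnt))
  # chromatin mutual exclusion at every sampled state
  r3 <- run_timer(loc, seed = 5, t_end = 168, keep_trajectory = FALSE)
  for (s in r3$chromatin_timecourse)
    expect_true(all(s$k27me3$values * s$k27ac$values == 0))
  # k_act = 0: only the anterior CTCF-free genes ever fire
  tp0 <- timer_params(k_act = 0)
  r0 <- run_timer(loc, timer_p = tp0, seed = 2, keep_trajectory = FALSE)
  fired <- names(r0$schedule)[is.finite(r0$schedule)]
  expect_setequal(fired, c("Hoxd1", "Hoxd3", "Hoxd4"))
})

test_that("without CTCF barriers a compressed 3'-to-5' bias persists", {
  loc <- hoxd_locus()
  sp <- sim_params(p_stall = 0)
  runs <- run_replicates(loc, 1:20, sim_p = sp, keep_trajectory = FALSE)
  ot <- onset_table(runs)
  cs <- apply(ot, 1, colinearity_score, locus = loc)
  expect_gt(median(cs), 0)
  # compressed relative to wild type: the posterior genes come much earlier
  wt <- cached("wt_runs", run_replicates(hoxd_locus(), 1:50,
                                         keep_trajectory = FALSE))
  expect_lt(median(ot$Hoxd13), median(onset_table(wt)$Hoxd13))
})

test_that("expression proxy combines activation, contact and dilution", {
  tp <- timer_params(dilution_half_life = 2, expression_scale = 10)
  genes <- c("gA", "gB")
  fake <- structure(list(
    schedule = c(gA = 10, gB = Inf),
    contact_times = c(5, 15, 25),
    contact_maint = matrix(2, 3, 2, dimnames = list(NULL, genes)),
    timer_params = tp), class = "timer_result")
  e <- expression_proxy(fake, c(5, 15, 25), tp)
  # silent gene is zero at all timepoints
  expect_true(all(e$value[e$gene == "gB"] == 0))
  # active gene: step at activation, then scale * contact * dilution
  va <- e$value[e$gene == "gA"]
  expect_equal(va, c(0, 20, 20))
  # a later-ranking gene with equal contact is strictly diluted
  fake2 <- fake; fake2$schedule <- c(gA = 10, gB = 10)
  e2 <- expression_proxy(fake2, 15, tp)
  expect_equal(e2$value[e2$gene == "gB"], 20 * 2^(-1 / 2))
  expect_lt(e2$value[e2$gene == "gB"], e2$value[e2$gene == "gA"])
})

test_that("grid calibration returns the objective-minimizing point", {
  loc <- toy_locus()
  sp <- sim_params(bin_size = 2000, load_rate = 40, p_bypass = 2e-3)
  tp <- timer_params(t_wnt = 2, t_enh = 4, anterior_activation_rate = 2,
                     k_act = 0.3, erasure_velocity = 5000,
                     contact_window = 1)
  targets <- c(gB = 8, gC = 14)
  # a one-point grid returns that point
  one <- calibrate_defaults(list(k_act = 0.3), targets, locus = loc,
                            sim_p = sp, timer_p = tp, n_rep = 3,
                            t_start = 0, t_end = 20)
  expect_equal(one$timer_params$k_act, 0.3)
  expect_equal(nrow(one$grid), 1L)
  # argmin property over a small grid
  cal <- calibrate_defaults(list(k_act = c(0.05, 0.3), p_bypass = c(2e-4, 2e-3)),
                            targets, locus = loc, sim_p = sp, timer_p = tp,
                            n_rep = 4, t_start = 0, t_end = 20)
  expect_equal(cal$objective, min(cal$grid$objective))
  expect_error(calibrate_defaults(list(), targets), "empty|at least")
  expect_error(calibrate_defaults(list(nonsense = 1), targets, locus = loc,
                                  sim_p = sp, timer_p = tp, n_rep = 2,
                                  t_start = 0, t_end = 4),
               "unknown search parameters")
})
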