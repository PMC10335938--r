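# Gene-activation layer coupled to the extrusion engine: Wnt pulse on the
# CTCF-free domain, contact-driven activation of the rest of the cluster,
# transcription-coupled loading feedback, chromatin proxies, expression.

#' Timer parameters
#'
#' @param t_wnt model-hour the Wnt (Chiron) window ends and the CTCF-free
#'   anterior genes begin firing.
#' @param anterior_activation_rate per-hour firing rate of each silent
#'   anterior gene after `t_wnt` (quasi-simultaneous activation).
#' @param k_act activation rate per unit gene-enhancer contact per hour for
#'   central/posterior genes.
#' @param contact_window model-hours of trailing averaging applied to the
#'   instantaneous gene-enhancer contact signal.
#' @param t_enh model-hour the sub-TAD1 enhancer elements become active
#'   (no contact-driven activation before this).
#' @param polycomb_factor multiplicative hazard attenuation while a gene
#'   still carries the repressive proxy over its body; 1 = off.
#' @param erasure_velocity speed, in bp per model-hour, of the repressive-
#'   mark retraction front: after a gene's 3'-side neighbor activates, the
#'   front crosses the intergenic gap (minus any pre-looped element, which
#'   is already depleted) and the gene's mark is erased `gap / velocity`
#'   hours later.
#' @param dilution_half_life gene ranks over which the measured-signal
#'   dilution factor halves (posterior restriction of expressing cells).
#' @param expression_scale scalar applied to the expression proxy.
#' @param maintenance_halo bins added on the 5' (C-DOM) side of each gene
#'   body for the maintenance/expression contact zone, so that cohesin
#'   stalled at the gene's 5'-flanking CBS counts as anchoring contact.
#' @param update_dt model-hours between gene-state updates (the engine runs
#'   `update_dt / dt` steps between updates).
#' @return a validated `timer_params` list.
#' @export
timer_params <- function(t_wnt = 72, anterior_activation_rate = 0.15,
                         k_act = 0.15, contact_window = 2, t_enh = 96,
                         polycomb_factor = 0.002, erasure_velocity = 300,
                         dilution_half_life = 3,
                         expression_scale = 100, maintenance_halo = 1L,
                         update_dt = 0.1) {
  p <- list(t_wnt = t_wnt,
            anterior_activation_rate = anterior_activation_rate,
            k_act = k_act, contact_window = contact_window, t_enh = t_enh,
            polycomb_factor = polycomb_factor, erasure_velocity = erasure_velocity,
            dilution_half_life = dilution_half_life,
            expression_scale = expression_scale,
            maintenance_halo = as.integer(maintenance_halo),
            update_dt = update_dt)
  if (p$anterior_activation_rate < 0 || p$k_act < 0 || p$erasure_velocity <= 0)
    stop("rates must be >= 0")
  if (p$contact_window <= 0 || p$update_dt <= 0)
    stop("contact_window and update_dt must be > 0")
  structure(p, class = "timer_params")
}

#' Initial chromatin state
#'
#' All cluster genes silent, the repressive proxy (H3K27me3) at 1 over every
#' cluster bin and the active proxy (H3K27ac) at 0 everywhere: the condensed,
#' polycomb-covered ground state of the cluster.
#'
#' @param locus a `hox_locus`.
#' @param lattice the matching `hox_lattice`.
#' @return a `chromatin_state`.
#' @export
init_chromatin <- function(locus, lattice) {
  gs <- data.frame(name = lattice$genes$name, state = "SILENT",
                   activation_time = Inf, stringsAsFactors = FALSE)
  me3 <- numeric(lattice$n_bins)
  cl <- lattice$regions[lattice$regions$name == "cluster", , drop = FALSE]
  if (nrow(cl) == 1L) me3[cl$start_bin:cl$end_bin] <- 1
  else for (i in seq_len(nrow(lattice$genes)))
    me3[lattice$genes$start_bin[i]:lattice$genes$end_bin[i]] <- 1
  structure(list(gene_states = gs,
                 k27me3 = track_like(lattice, me3),
                 k27ac = track_like(lattice, numeric(lattice$n_bins)),
                 lattice = lattice),
            class = "chromatin_state")
}

#' @export
print.chromatin_state <- function(x, ...) {
  n_act <- sum(x$gene_states$state == "ACTIVE")
  cat(sprintf("<chromatin_state> %d/%d genes active\n", n_act,
              nrow(x$gene_states)))
  invisible(x)
}

fire_gene <- function(chromatin, gene, time) {
  i <- match(gene, chromatin$gene_states$name)
  chromatin$gene_states$state[i] <- "ACTIVE"
  chromatin$gene_states$activation_time[i] <- time
  gb <- chromatin$lattice$genes
  bins <- gb$start_bin[i]:gb$end_bin[i]
  chromatin$k27me3$values[bins] <- 0
  chromatin$k27ac$values[bins] <- 1
  chromatin
}

# Per-gene erasure lags: the retraction front starts at the 3'-side
# neighbor's body and travels the intergenic gap at erasure_velocity;
# pre-looped elements (regions named *_element, looped out of the negative
# micro-TAD before activation) are already depleted and subtract from the
# path length.
erasure_lags <- function(locus, params) {
  g <- locus$genes
  lag <- numeric(nrow(g))
  elements <- locus$regions[grepl("_element$", locus$regions$name), , drop = FALSE]
  for (i in seq_len(nrow(g))[-1L]) {
    gap_lo <- g$end[i]          # gene's 5'-side gap runs from its end ...
    gap_hi <- g$start[i - 1L]   # ... up to the 3'-neighbor's start
    gap <- max(0, gap_hi - gap_lo)
    if (nrow(elements)) {
      ov <- pmax(0, pmin(elements$end, gap_hi) - pmax(elements$start, gap_lo))
      gap <- max(0, gap - sum(ov))
    }
    lag[i] <- gap / params$erasure_velocity
  }
  names(lag) <- g$name
  lag
}

# The repressive-mark erasure front advances with transcription: the mark
# over a still-silent gene's body is erased once the front launched by its
# 3'-side neighbor's activation has crossed the intergenic gap.
erasure_update <- function(chromatin, lags, t) {
  gs <- chromatin$gene_states
  gb <- chromatin$lattice$genes
  for (i in seq_len(nrow(gs))[-1L]) {
    if (gs$state[i] != "SILENT" || gs$state[i - 1L] != "ACTIVE") next
    if (t < gs$activation_time[i - 1L] + lags[i]) next
    bins <- gb$start_bin[i]:gb$end_bin[i]
    chromatin$k27me3$values[bins] <- 0
  }
  chromatin
}

# a silent gene "retains the repressive proxy" while any of its body bins
# still carries the mark; its activation hazard is then attenuated
polycomb_attenuation <- function(chromatin, genes, pf) {
  gb <- chromatin$lattice$genes
  vapply(genes, function(g) {
    i <- match(g, gb$name)
    marked <- any(chromatin$k27me3$values[gb$start_bin[i]:gb$end_bin[i]] > 0)
    if (marked) pf else 1
  }, 0)
}

#' Wnt-pulse activation of the CTCF-free domain
#'
#' After `t_wnt`, each silent anterior (CTCF-free, 3' of CBS1) gene fires
#' independently at rate `anterior_activation_rate` per hour; over a window
#' of `dt` hours each fires with probability `1 - exp(-rate * dt)`. Firing
#' switches the gene to ACTIVE, records the activation time and swaps the
#' chromatin proxies over its body.
#'
#' @param chromatin a `chromatin_state`.
#' @param locus the `hox_locus`.
#' @param t current model-hour (end of the window).
#' @param params a `timer_params`.
#' @param dt window length in model-hours (default `params$update_dt`).
#' @return the updated `chromatin_state`.
#' @export
wnt_activation <- function(chromatin, locus, t, params, dt = params$update_dt) {
  if (t < params$t_wnt) return(chromatin)
  dt <- min(dt, t - params$t_wnt)  # clip the first window at t_wnt
  gs <- chromatin$gene_states
  ant <- locus$genes$name[locus$genes$domain == "anterior"]
  idx <- which(gs$state == "SILENT" & gs$name %in% ant)
  if (!length(idx)) return(chromatin)
  r <- params$anterior_activation_rate
  p <- if (is.infinite(r)) 1 else 1 - exp(-r * dt)
  fire <- runif(length(idx)) < p
  for (g in gs$name[idx[fire]]) chromatin <- fire_gene(chromatin, g, t)
  chromatin
}

#' Transcription-coupled loading profile
#'
#' Per-bin cohesin loading weights: `w_active` over every bin of an ACTIVE
#' gene body, `w_background` over every other bin of the cluster-plus-T-DOM
#' span (cluster start to axis end), 0 outside it.
#'
#' @param chromatin a `chromatin_state`.
#' @param locus the `hox_locus`.
#' @param lattice the `hox_lattice`.
#' @param params a `sim_params` (for `w_active`, `w_background`).
#' @return a `hox_track` of loading weights.
#' @export
loading_profile <- function(chromatin, locus, lattice, params) {
  w <- numeric(lattice$n_bins)
  cl <- lattice$regions[lattice$regions$name == "cluster", , drop = FALSE]
  span_start <- if (nrow(cl) == 1L) cl$start_bin else 1L
  w[span_start:lattice$n_bins] <- params$w_background
  act <- chromatin$gene_states$name[chromatin$gene_states$state == "ACTIVE"]
  gb <- lattice$genes
  for (g in act) {
    i <- match(g, gb$name)
    w[gb$start_bin[i]:gb$end_bin[i]] <- params$w_active
  }
  track_like(lattice, w)
}

#' Contact-driven activation update
#'
#' Each silent non-anterior gene `g` fires during a window of `dt` hours
#' with probability `1 - exp(-k_act * C_gE * att * dt)`, where `C_gE` is the
#' trailing-window mean gene-enhancer contact from the extrusion engine (the
#' number of extruded loops spanning both the gene body and the first
#' enhancer element - the gene has fallen into the positive loop domain -
#' plus the distance-decay background) and `att` is the polycomb attenuation
#' while the gene retains the repressive mark. The hazard is zero before the
#' enhancers are active (`t < t_enh`).
#'
#' @param chromatin a `chromatin_state`.
#' @param contact_signal named per-gene trailing-mean contact values.
#' @param params a `timer_params`.
#' @param dt window length in model-hours.
#' @param t current model-hour.
#' @param anterior character vector of anterior gene names (excluded here).
#' @return list with the updated `chromatin` and a character vector
#'   `fired` of genes that activated.
#' @export
activation_update <- function(chromatin, contact_signal, params, dt, t,
                              anterior = character(0)) {
  fired <- character(0)
  if (t < params$t_enh)
    return(list(chromatin = chromatin, fired = fired))
  gs <- chromatin$gene_states
  idx <- which(gs$state == "SILENT" & !(gs$name %in% anterior))
  if (!length(idx)) return(list(chromatin = chromatin, fired = fired))
  C <- contact_signal[gs$name[idx]]
  C[is.na(C)] <- 0
  if (any(C < 0)) stop("contact signal must be non-negative")
  att <- polycomb_attenuation(chromatin, gs$name[idx], params$polycomb_factor)
  haz <- params$k_act * C * att
  p <- ifelse(is.infinite(haz) & haz > 0, 1, 1 - exp(-haz * dt))
  fire <- runif(length(idx)) < p
  for (g in gs$name[idx[fire]]) {
    chromatin <- fire_gene(chromatin, g, t)
    fired <- c(fired, g)
  }
  list(chromatin = chromatin, fired = fired)
}

timer_zones <- function(lattice, timer_p) {
  gb <- lattice$genes
  enh <- lattice$regions[!is.na(lattice$regions$active_from), , drop = FALSE]
  mask <- rep(FALSE, lattice$n_bins)
  for (i in seq_len(nrow(enh))) mask[enh$start_bin[i]:enh$end_bin[i]] <- TRUE
  list(gene_lo = as.integer(gb$start_bin - 1L),
       gene_hi = as.integer(gb$end_bin - 1L),
       maint_lo = as.integer(pmax(0L, gb$start_bin - 1L - timer_p$maintenance_halo)),
       maint_hi = as.integer(gb$end_bin - 1L),
       enh_mask = mask,
       enh_first = if (any(mask)) min(which(mask)) - 1L else lattice$n_bins,
       genes = gb$name,
       t_enh = if (nrow(enh)) min(enh$active_from) else Inf)
}

# mean background contact between each gene's body bins and the enhancer bins
background_gene_contact <- function(lattice, zones, sim_p) {
  enh_bins <- which(zones$enh_mask)
  vapply(seq_along(zones$genes), function(g) {
    gb <- (zones$gene_lo[g] + 1L):(zones$gene_hi[g] + 1L)
    d <- abs(outer(gb, enh_bins, "-"))
    mean(sim_p$c0 * pmax(d, 1)^(-sim_p$alpha))
  }, 0)
}

#' Run the full Hox-timer simulation
#'
#' Orchestrates one replicate of the three-phase timer over
#' `[t_start, t_end]`: the cluster starts condensed (repressive proxy over
#' all cluster bins); after `t_wnt` the CTCF-free anterior genes fire
#' quasi-simultaneously and become cohesin loading sites; loop extrusion
#' from the transcribed segment stalls at the oriented CBS series and
#' stochastically bypasses it, extending contacts with the sub-TAD1
#' enhancers step by step toward the posterior end; each silent gene fires
#' at a rate proportional to its trailing-window enhancer contact once the
#' enhancers are active; every newly fired gene becomes a loading site in
#' turn (the self-propagating relay).
#'
#' @param locus a `hox_locus`.
#' @param sim_p a `sim_params`.
#' @param timer_p a `timer_params`.
#' @param t_start,t_end simulation window in model-hours (protocol clock:
#'   48 h is aggregate formation + pre-Chiron culture).
#' @param seed integer RNG seed for the replicate.
#' @param snapshot_every trajectory snapshot cadence (model-hours).
#' @param sample_every chromatin-state sampling cadence (model-hours).
#' @param keep_trajectory set `FALSE` to drop snapshots/events (faster,
#'   schedule and contact timecourse only).
#' @return a `timer_result` with the activation schedule, trajectory,
#'   sampled chromatin states and the per-gene contact timecourse.
#' @export
run_timer <- function(locus, sim_p = sim_params(), timer_p = timer_params(),
                      t_start = 48, t_end = 168, seed = sim_p$seed,
                      snapshot_every = 1, sample_every = 12,
                      keep_trajectory = TRUE) {
  stopifnot(t_end > t_start)
  lattice <- discretize(locus, sim_p$bin_size)
  zones <- timer_zones(lattice, timer_p)
  t_enh <- max(timer_p$t_enh, zones$t_enh, na.rm = TRUE)
  bg <- background_gene_contact(lattice, zones, sim_p)
  names(bg) <- zones$genes
  anterior <- locus$genes$name[locus$genes$domain == "anterior"]
  er_lags <- erasure_lags(locus, timer_p)

  state <- init_lattice(lattice, sim_p, seed = seed, t0 = t_start)
  chromatin <- init_chromatin(locus, lattice)

  n_sub <- max(1L, round(timer_p$update_dt / sim_p$dt))
  dt_chunk <- n_sub * sim_p$dt
  n_chunks <- ceiling((t_end - t_start) / dt_chunk - 1e-9)
  W <- max(1L, round(timer_p$contact_window / dt_chunk))
  ng <- length(zones$genes)
  haz_buf <- matrix(0, ng, W)
  maint_buf <- matrix(0, ng, W)
  bufpos <- 0L

  snap_every_chunks <- max(1L, round(snapshot_every / dt_chunk))
  sample_every_chunks <- max(1L, round(sample_every / dt_chunk))

  times <- state$time
  snaps <- if (keep_trajectory) list(cbind(left = state$left, right = state$right)) else list()
  ev <- list()
  chrom_samples <- list()
  chrom_sample_times <- numeric(0)
  ct_time <- numeric(n_chunks)
  ct_haz <- matrix(0, n_chunks, ng, dimnames = list(NULL, zones$genes))
  ct_maint <- matrix(0, n_chunks, ng, dimnames = list(NULL, zones$genes))

  profile <- loading_profile(chromatin, locus, lattice, sim_p)
  n_active_prev <- 0L
  # cohesin loading scales with the transcribed (NIPBL-positive) surface:
  # the reference mass is the profile with the anterior domain active, so
  # load_rate is the post-Wnt total loading rate
  ref_chrom <- init_chromatin(locus, lattice)
  for (g in anterior) ref_chrom <- fire_gene(ref_chrom, g, t_start)
  w_ref <- sum(loading_profile(ref_chrom, locus, lattice, sim_p)$values)
  sim_eff <- sim_p
  sim_eff$load_rate <- sim_p$load_rate * sum(profile$values) / w_ref

  for (chunk in seq_len(n_chunks)) {
    t_now <- state$time
    # 1. Wnt pulse on the CTCF-free domain
    chromatin <- wnt_activation(chromatin, locus, t_now + dt_chunk, timer_p,
                                dt = dt_chunk)
    # 2. refresh loading profile when the active set changed
    n_active <- sum(chromatin$gene_states$state == "ACTIVE")
    if (n_active != n_active_prev) {
      profile <- loading_profile(chromatin, locus, lattice, sim_p)
      n_active_prev <- n_active
      sim_eff$load_rate <- sim_p$load_rate * sum(profile$values) / w_ref
    }
    # 3. advance the extrusion engine
    res <- run_kernel(state, n_sub, sim_eff, profile$values, zones,
                      log_events = keep_trajectory)
    state <- state_from_cpp(res, lattice)
    # 4. trailing-window contact signal (instantaneous = chunk mean counts
    #    of bridging anchor pairs, plus the distance-decay background)
    bufpos <- bufpos %% W + 1L
    haz_buf[, bufpos] <- res$haz_contact / n_sub + bg
    maint_buf[, bufpos] <- res$maint_contact / n_sub + bg
    C_haz <- rowMeans(haz_buf)
    C_maint <- rowMeans(maint_buf)
    names(C_haz) <- names(C_maint) <- zones$genes
    ct_time[chunk] <- state$time
    ct_haz[chunk, ] <- C_haz
    ct_maint[chunk, ] <- C_maint
    # 5. repressive-mark retraction front, then contact-driven activation
    chromatin <- erasure_update(chromatin, er_lags, state$time)
    if (state$time >= t_enh) {
      up <- activation_update(chromatin, C_haz, timer_p, dt_chunk,
                              state$time, anterior = anterior)
      chromatin <- up$chromatin
    }
    # 6. records
    if (keep_trajectory && chunk %% snap_every_chunks == 0L) {
      times <- c(times, state$time)
      snaps[[length(snaps) + 1L]] <- cbind(left = state$left, right = state$right)
      if (length(res$ev_time))
        ev[[length(ev) + 1L]] <- data.frame(
          time = res$ev_time,
          kind = c("load", "unload", "stall", "bypass")[res$ev_kind],
          position = res$ev_pos + 1L)
    }
    if (chunk %% sample_every_chunks == 0L) {
      chrom_sample_times <- c(chrom_sample_times, state$time)
      chrom_samples[[length(chrom_samples) + 1L]] <-
        list(time = state$time, gene_states = chromatin$gene_states,
             k27me3 = chromatin$k27me3, k27ac = chromatin$k27ac)
    }
  }

  schedule <- chromatin$gene_states$activation_time
  names(schedule) <- chromatin$gene_states$name
  traj <- if (keep_trajectory) {
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(time = numeric(0), kind = character(0), position = integer(0))
    new_trajectory(times, snaps, events, lattice)
  } else NULL

  structure(list(schedule = schedule, trajectory = traj,
                 chromatin_timecourse = chrom_samples,
                 contact_times = ct_time, contact_haz = ct_haz,
                 contact_maint = ct_maint,
                 locus = locus, lattice = lattice,
                 sim_params = sim_p, timer_params = timer_p, seed = seed),
            class = "timer_result")
}

#' @export
print.timer_result <- function(x, ...) {
  cat(sprintf("<timer_result> genotype %s, seed %d\n", x$locus$genotype, x$seed))
  on <- x$schedule[is.finite(x$schedule)]
  cat("  onsets (h): ", paste(sprintf("%s=%.1f", names(on), on), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Run replicate timer simulations
#'
#' @param locus a `hox_locus`.
#' @param seeds integer vector of replicate seeds.
#' @param ... passed to [run_timer()].
#' @return list of `timer_result`s.
#' @export
run_replicates <- function(locus, seeds, ...) {
  lapply(seeds, function(s) run_timer(locus, seed = s, ...))
}

#' Activation-onset table across replicates
#'
#' @param results list of `timer_result`s.
#' @return data.frame with one row per replicate, one column per gene
#'   (activation model-hour; `Inf` if never activated).
#' @export
onset_table <- function(results) {
  as.data.frame(do.call(rbind, lapply(results, function(r) r$schedule)))
}

#' Expression proxy table
#'
#' FPKM-like per-gene, per-timepoint expression proxy
#' `E_g(t) = scale * 1[g active by t] * C_gE(t) * D_g`, where `C_gE` is the
#' trailing-window maintenance contact (gene body plus 5'-side anchoring
#' halo) and `D_g = 2^-(rank_g - 1) / dilution_half_life)` is the constant
#' posterior-dilution factor: only progressively fewer (more posterior)
#' cells of the population express later-ranking genes, which dilutes any
#' population-averaged signal.
#'
#' @param result a `timer_result` or list of them (replicates; values are
#'   averaged per replicate into separate columns).
#' @param timepoints model-hours at which to evaluate the proxy.
#' @param timer_p a `timer_params` (scale, dilution).
#' @return a long data.frame `gene, timepoint, replicate, value`
#'   (class `hox_expr`).
#' @export
expression_proxy <- function(result, timepoints, timer_p = NULL) {
  results <- if (inherits(result, "timer_result")) list(result) else result
  if (is.null(timer_p)) timer_p <- results[[1L]]$timer_params
  out <- list()
  for (r in seq_along(results)) {
    res <- results[[r]]
    genes <- names(res$schedule)
    rank <- seq_along(genes)
    D <- 2^(-(rank - 1) / timer_p$dilution_half_life)
    for (tp in timepoints) {
      i <- which.min(abs(res$contact_times - tp))
      C <- res$contact_maint[i, genes]
      active <- res$schedule[genes] <= tp
      val <- timer_p$expression_scale * as.numeric(active) * C * D
      out[[length(out) + 1L]] <- data.frame(
        gene = genes, timepoint = tp, replicate = r, value = val,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  structure(do.call(rbind, out), class = c("hox_expr", "data.frame"))
}

#' Grid-search calibration of timer defaults
#'
#' Minimizes the squared distance between median simulated activation times
#' and target onset hours over a finite grid of simulation/timer parameters.
#'
#' @param search_space named list of candidate values; names may be any of
#'   `k_act`, `p_bypass`, `v`, `unload_prob`, `load_rate`,
#'   `anterior_activation_rate`.
#' @param schedule_targets named numeric vector of target onset model-hours
#'   per gene.
#' @param locus locus to calibrate on (default [hoxd_locus()]).
#' @param sim_p,timer_p base parameter sets that grid values override.
#' @param n_rep replicates per grid point (>= 20 for the shipped defaults).
#' @param seeds replicate seeds (default `1:n_rep`).
#' @param t_start,t_end simulation window.
#' @param never_penalty onset hour substituted for never-activated genes in
#'   the objective.
#' @return list with `sim_params`, `timer_params` (best point), `objective`,
#'   and the full `grid` data.frame of evaluated objectives.
#' @export
calibrate_defaults <- function(search_space, schedule_targets,
                               locus = hoxd_locus(), sim_p = sim_params(),
                               timer_p = timer_params(), n_rep = 20,
                               seeds = seq_len(n_rep), t_start = 48,
                               t_end = 168, never_penalty = t_end + 24) {
  if (length(search_space) < 1L || !length(schedule_targets))
    stop("empty parameter grid or targets")
  grid <- expand.grid(search_space, KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty parameter grid")
  sim_keys <- c("p_bypass", "v", "unload_prob", "load_rate")
  timer_keys <- c("k_act", "anterior_activation_rate")
  bad <- setdiff(names(grid), c(sim_keys, timer_keys))
  if (length(bad)) stop("unknown search parameters: ", paste(bad, collapse = ", "))
  obj <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- sim_p; tp <- timer_p
    for (k in names(grid)) {
      if (k %in% sim_keys) sp[[k]] <- if (k == "v") as.integer(grid[i, k]) else grid[i, k]
      else tp[[k]] <- grid[i, k]
    }
    runs <- lapply(seeds, function(s)
      run_timer(locus, sp, tp, t_start = t_start, t_end = t_end, seed = s,
                keep_trajectory = FALSE))
    med <- apply(onset_table(runs), 2, median)
    med <- pmin(med, never_penalty)
    tg <- schedule_targets[names(schedule_targets) %in% names(med)]
    obj[i] <- sum((med[names(tg)] - tg)^2)
  }
  best <- which.min(obj)
  sp <- sim_p; tp <- timer_p
  for (k in names(grid)) {
    if (k %in% sim_keys) sp[[k]] <- if (k == "v") as.integer(grid[best, k]) else grid[best, k]
    else tp[[k]] <- grid[best, k]
  }
  list(sim_params = sp, timer_params = tp, objective = obj[best],
       grid = cbind(grid, objective = obj))
}
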