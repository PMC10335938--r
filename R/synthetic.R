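# Synthetic-data generators with known ground truth: spreading activation
# waves with posterior dilution, structured contact matrices (blocks,
# stripe, loops), replicate expression tables, valid-pair samples.

#' Wave generator parameters
#'
#' @param front_start front position (bp) at the first timepoint.
#' @param velocity front speed in bp per model-hour (> 0; positive moves
#'   toward increasing coordinates).
#' @param front_width sigmoid front width in bp.
#' @param amplitude plateau signal level behind the front.
#' @param dilution_rate per-hour-of-onset-lateness exponential (base-2)
#'   decay of the plateau (posterior dilution of the measured signal).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return a `wave_params` list.
#' @export
wave_params <- function(front_start, velocity, front_width = 2000,
                        amplitude = 1, dilution_rate = 0, noise_sd = 0,
                        seed = 1L) {
  stopifnot(velocity > 0, noise_sd >= 0, front_width > 0, amplitude > 0)
  structure(list(front_start = front_start, velocity = velocity,
                 front_width = front_width, amplitude = amplitude,
                 dilution_rate = dilution_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "wave_params")
}

#' Generate a spreading activation wave timecourse
#'
#' Per-bin signal at time `t`:
#' `amplitude * sigmoid((front_start + velocity*(t - t0) - x) / front_width)
#'  * 2^(-max(0, lateness_x) * dilution_rate)` plus Gaussian noise, clipped
#' at 0, where `lateness_x = max(0, x - front_start) / velocity` is the
#' model-hour at which the front reached bin midpoint `x`. Emulates the
#' progressive 3'-to-5' spreading of an activation mark whose
#' population-averaged amplitude dilutes for late-activating positions.
#'
#' @param axis list with `n_bins`, `bin_size`, `axis_start` (and optionally
#'   `chrom`), or a `hox_lattice`.
#' @param timepoints model-hours of the series; `t0 = timepoints[1]`.
#' @param params a `wave_params`.
#' @return a `hox_series`; deterministic given `params$seed`.
#' @export
gen_wave_tracks <- function(axis, timepoints, params) {
  chrom <- if (!is.null(axis$chrom)) axis$chrom else "chr"
  x <- axis$axis_start + (seq_len(axis$n_bins) - 0.5) * axis$bin_size
  set.seed(params$seed)
  t0 <- timepoints[1L]
  lateness <- pmax(0, x - params$front_start) / params$velocity
  dil <- 2^(-lateness * params$dilution_rate)
  tracks <- lapply(timepoints, function(t) {
    front <- params$front_start + params$velocity * (t - t0)
    sig <- params$amplitude * stats::plogis((front - x) / params$front_width) * dil
    if (params$noise_sd > 0) sig <- sig + rnorm(length(sig), 0, params$noise_sd)
    track(pmax(0, sig), chrom = chrom, axis_start = axis$axis_start,
          bin_size = axis$bin_size)
  })
  track_series(timepoints, tracks)
}

#' Recover the wave-front velocity from a timecourse
#'
#' Detects the half-maximum front position at each timepoint (linear
#' interpolation of the last crossing of half the track maximum) and
#' returns the least-squares slope of front position versus time.
#'
#' @param series a `hox_series` with >= 3 timepoints.
#' @return list with `velocity` (bp per model-hour) and the per-timepoint
#'   `fronts` (bp; `NA` where no front was detectable).
#' @export
recover_front_velocity <- function(series) {
  if (length(series$times) < 3L) stop("need >= 3 timepoints")
  tr0 <- series$tracks[[1L]]
  x <- tr0$axis_start + (seq_along(tr0$values) - 0.5) * tr0$bin_size
  fronts <- vapply(series$tracks, function(tr) {
    v <- tr$values
    thr <- max(v) / 2
    if (max(v) <= 0 || min(v) >= thr) return(NA_real_)
    above <- v >= thr
    if (!any(above) || all(above)) return(NA_real_)
    i <- max(which(above))             # last bin above threshold
    if (i == length(v)) return(x[i])
    # interpolate the downward crossing between bins i and i+1
    x[i] + (thr - v[i]) / (v[i + 1L] - v[i]) * (x[i + 1L] - x[i])
  }, 0)
  ok <- is.finite(fronts)
  if (sum(ok) < 2L) stop("front not detectable at >= 2 timepoints")
  fit <- lm(fronts[ok] ~ series$times[ok])
  list(velocity = unname(coef(fit)[2L]), fronts = fronts)
}

#' Synthetic contact-map parameters
#'
#' @param n_bins matrix size.
#' @param tad_blocks list of `list(range =, enrichment =)` self-interacting
#'   blocks.
#' @param stripe `list(x_range =, y_range =, enrichment =)` or `NULL`.
#' @param loops list of `list(bin1 =, bin2 =, enrichment =)` point loops.
#' @param alpha,c0 distance-decay background exponent and amplitude.
#' @param noise_sd multiplicative log-normal noise (SD of log signal).
#' @param seed RNG seed.
#' @return a `synth_map_params` list.
#' @export
synth_map_params <- function(n_bins, tad_blocks = list(), stripe = NULL,
                             loops = list(), alpha = 1, c0 = 1,
                             noise_sd = 0, seed = 1L) {
  enr <- c(vapply(tad_blocks, function(b) b$enrichment, 0),
           if (!is.null(stripe)) stripe$enrichment,
           vapply(loops, function(l) l$enrichment, 0))
  if (length(enr) && any(enr < 0)) stop("enrichments must be >= 0")
  structure(list(n_bins = as.integer(n_bins), tad_blocks = tad_blocks,
                 stripe = stripe, loops = loops, alpha = alpha, c0 = c0,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_map_params")
}

#' Generate a structured synthetic contact matrix
#'
#' Power-law distance-decay background multiplied by `1 + sum(enrichments)`
#' over block, stripe and loop features (overlapping features add), with
#' multiplicative log-normal noise, symmetrized. Emulates contact maps with
#' two micro-TADs and a stripe of preferential enhancer interactions.
#'
#' @param params a `synth_map_params`.
#' @return a `hox_map`; deterministic given `params$seed`.
#' @export
gen_contact_matrix <- function(params) {
  n <- params$n_bins
  set.seed(params$seed)
  m <- power_law_background(n, params$alpha, params$c0)
  fac <- matrix(1, n, n)
  for (b in params$tad_blocks)
    fac[b$range, b$range] <- fac[b$range, b$range] + b$enrichment
  if (!is.null(params$stripe)) {
    s <- params$stripe
    fac[s$x_range, s$y_range] <- fac[s$x_range, s$y_range] + s$enrichment
    fac[s$y_range, s$x_range] <- fac[s$y_range, s$x_range] + s$enrichment
  }
  for (l in params$loops) {
    fac[l$bin1, l$bin2] <- fac[l$bin1, l$bin2] + l$enrichment
    fac[l$bin2, l$bin1] <- fac[l$bin2, l$bin1] + l$enrichment
  }
  m <- m * fac
  if (params$noise_sd > 0) {
    noise <- matrix(exp(rnorm(n * n, 0, params$noise_sd)), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    m <- m * noise
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  new_contact_map(m)
}

#' Generate a replicate expression table with known onsets
#'
#' Per gene, timepoint and replicate:
#' `scale * 1[t >= onset_g] * 2^(-(rank_g - 1) * dilution)` with
#' multiplicative log-normal noise. Ground truth (onsets, dilution) is
#' returned in the attributes for recovery tests.
#'
#' @param locus a `hox_locus` (gene order gives the ranks).
#' @param onsets named onset model-hours per gene.
#' @param timepoints model-hours sampled.
#' @param dilution per-rank base-2 dilution exponent.
#' @param noise_sd SD of the log-normal noise (0 = noiseless).
#' @param n_replicates replicates per timepoint.
#' @param seed RNG seed.
#' @param scale expression scale.
#' @return a `hox_expr` long table.
#' @export
gen_expression_table <- function(locus, onsets, timepoints, dilution = 0,
                                 noise_sd = 0, n_replicates = 2, seed = 1L,
                                 scale = 100) {
  genes <- locus$genes$name
  if (!all(genes %in% names(onsets))) stop("onsets must cover all genes")
  set.seed(seed)
  rank <- seq_along(genes)
  rows <- expand.grid(gene = genes, timepoint = timepoints,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- scale * as.numeric(rows$timepoint >= onsets[rows$gene]) *
    2^(-(rank[match(rows$gene, genes)] - 1) * dilution)
  noise <- if (noise_sd > 0) exp(rnorm(nrow(rows), 0, noise_sd)) else 1
  rows$value <- base * noise
  structure(rows, class = c("hox_expr", "data.frame"),
            onsets = onsets, dilution = dilution)
}

#' Sample valid pairs from a contact map
#'
#' Draws `n` interaction pairs with probability proportional to the matrix
#' entries (upper triangle plus diagonal of the symmetric map).
#'
#' @param map a `hox_map` with positive sum.
#' @param n number of pairs (> 0).
#' @param seed RNG seed.
#' @return data.frame `bin1, bin2` with `bin1 <= bin2`.
#' @export
sample_pairs <- function(map, n, seed = 1L) {
  if (n <= 0) stop("n must be > 0")
  m <- map$matrix
  nb <- nrow(m)
  ut <- which(upper.tri(m, diag = TRUE))
  w <- m[ut]
  if (sum(w) <= 0) stop("map must have positive sum")
  set.seed(seed)
  cells <- sample(ut, n, replace = TRUE, prob = w)
  data.frame(bin1 = ((cells - 1L) %% nb) + 1L,
             bin2 = ((cells - 1L) %/% nb) + 1L)
}
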