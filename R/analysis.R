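# Bespoke quantifications: virtual 4C, mean-contact curves and centroid,
# micro-TAD split score, cumulative/interpolated timecourses, cross-cluster
# normalization, genotype comparison, colinearity, occupancy shares.
# All operations run identically on simulated and synthetic inputs.

#' Virtual 4C profile
#'
#' Extracts one viewpoint's interaction profile from a contact map or a
#' valid-pair list: the mean over the viewpoint rows (or the tally of pair
#' partners), with an exclusion zone of `exclusion` bins on both sides of
#' the viewpoint masked to zero, normalized to sum 1 over unmasked bins.
#'
#' @param source a `hox_map`, or a data.frame of pairs with columns
#'   `bin1`, `bin2`.
#' @param viewpoint integer bin range of the viewpoint.
#' @param exclusion number of bins masked on each side of the viewpoint
#'   (the viewpoint itself is always masked).
#' @param n_bins number of bins (required for pair-list input).
#' @return a `hox_track` summing to 1 over unmasked bins.
#' @export
virtual_4c <- function(source, viewpoint, exclusion = 2L, n_bins = NULL) {
  if (inherits(source, "hox_map")) {
    n <- nrow(source$matrix)
    if (any(viewpoint < 1) || any(viewpoint > n)) stop("viewpoint outside axis")
    prof <- colMeans(source$matrix[viewpoint, , drop = FALSE])
    chrom <- source$chrom; a0 <- source$axis_start; bs <- source$bin_size
  } else {
    if (is.null(n_bins)) stop("n_bins required for pair-list input")
    n <- n_bins
    p <- source
    hit1 <- p$bin1 %in% viewpoint
    hit2 <- p$bin2 %in% viewpoint
    other <- c(p$bin2[hit1], p$bin1[hit2 & !hit1])
    prof <- tabulate(other, nbins = n)
    chrom <- "chr"; a0 <- 0; bs <- 1
  }
  mask <- seq(max(1L, min(viewpoint) - exclusion),
              min(n, max(viewpoint) + exclusion))
  prof[mask] <- 0
  s <- sum(prof)
  if (s <= 0) stop("viewpoint profile empty after masking")
  track(prof / s, chrom = chrom, axis_start = a0, bin_size = bs)
}

#' Mean-contact curve of a region against a reference region
#'
#' For each bin `i` of `x_region`, the mean contact with all bins of
#' `y_region` (e.g. each cluster bin against the CS38-40 region). Returned
#' as a track on the `x_region` sub-axis.
#'
#' @param map a `hox_map`.
#' @param x_region,y_region integer bin ranges.
#' @return a `hox_track` over `x_region` (attribute `"bins"` holds the bin
#'   indices).
#' @export
mean_contact_curve <- function(map, x_region, y_region) {
  if (!length(x_region) || !length(y_region)) stop("empty region")
  n <- nrow(map$matrix)
  if (any(c(x_region, y_region) < 1) || any(c(x_region, y_region) > n))
    stop("region outside axis")
  vals <- rowMeans(map$matrix[x_region, y_region, drop = FALSE])
  out <- track(vals, chrom = map$chrom,
               axis_start = map$axis_start + (min(x_region) - 1) * map$bin_size,
               bin_size = map$bin_size)
  attr(out, "bins") <- x_region
  out
}

#' Signal-weighted centroid of a curve
#'
#' @param curve a `hox_track` (non-negative, positive sum).
#' @return centroid position in bp (bin-midpoint weighted mean).
#' @export
contact_centroid <- function(curve) {
  v <- curve$values
  if (any(v < 0)) stop("curve must be non-negative")
  s <- sum(v)
  if (s <= 0) stop("zero-sum curve has no centroid")
  mids <- curve$axis_start + (seq_along(v) - 0.5) * curve$bin_size
  sum(mids * v) / s
}

#' Micro-TAD split score
#'
#' Quantifies how strongly a boundary bin separates a span of the map into
#' two self-interacting blocks:
#' `(mean within-left + mean within-right) / (2 * mean cross)`, where the
#' within-block means exclude the diagonal. 1 for a uniform matrix; larger
#' values indicate a stronger two-domain split.
#'
#' @param map a `hox_map`.
#' @param boundary bin index; left block is `span` bins `<= boundary`.
#' @param span integer bin range to score over (e.g. the cluster bins);
#'   default: the whole map.
#' @return scalar split score.
#' @export
split_score <- function(map, boundary, span = NULL) {
  n <- nrow(map$matrix)
  if (is.null(span)) span <- seq_len(n)
  left <- span[span <= boundary]
  right <- span[span > boundary]
  if (length(left) < 2L || length(right) < 2L)
    stop("degenerate sides: boundary must lie strictly inside the span")
  block_mean <- function(b) {
    m <- map$matrix[b, b, drop = FALSE]
    (sum(m) - sum(diag(m))) / (length(b)^2 - length(b))
  }
  cross <- mean(map$matrix[left, right, drop = FALSE])
  if (cross <= 0) stop("zero cross-contact: split score undefined")
  (block_mean(left) + block_mean(right)) / (2 * cross)
}

#' Cumulative signal profiles
#'
#' Running per-bin sum over the timepoints of a series (the stacked
#' cumulative representation used for acetylation timecourses): output `k`
#' is the per-bin sum of all tracks up to and including timepoint `k`.
#'
#' @param series a `hox_series`.
#' @return a `hox_series` of cumulative tracks (same times).
#' @export
cumulative_signal <- function(series) {
  m <- series_matrix(series)
  cm <- t(apply(m, 1, cumsum))
  if (length(series$times) == 1L) cm <- m
  tracks <- lapply(seq_along(series$times), function(k) {
    tr <- series$tracks[[k]]
    track(cm[, k], chrom = tr$chrom, axis_start = tr$axis_start,
          bin_size = tr$bin_size)
  })
  track_series(series$times, tracks)
}

#' Hour-wise interpolation of a timecourse
#'
#' Per-bin linear interpolation between adjacent measured timepoints at a
#' regular cadence (used to render smooth "movies" from coarse
#' timecourses). Queries at measured times return the measured track
#' exactly.
#'
#' @param series a `hox_series` with at least two timepoints.
#' @param step output cadence in model-hours.
#' @return a `hox_series` sampled at `seq(min(times), max(times), by=step)`,
#'   with measured times included exactly.
#' @export
interpolate_timecourse <- function(series, step = 1) {
  if (step <= 0) stop("step must be > 0")
  if (length(series$times) < 2L) stop("need >= 2 timepoints to interpolate")
  tq <- sort(unique(c(seq(min(series$times), max(series$times), by = step),
                      series$times)))
  m <- series_matrix(series)
  out <- matrix(0, nrow(m), length(tq))
  for (b in seq_len(nrow(m)))
    out[b, ] <- approx(series$times, m[b, ], xout = tq)$y
  tr0 <- series$tracks[[1L]]
  tracks <- lapply(seq_along(tq), function(k)
    track(out[, k], chrom = tr0$chrom, axis_start = tr0$axis_start,
          bin_size = tr0$bin_size))
  track_series(tq, tracks)
}

#' Cross-cluster expression normalization
#'
#' Rescales target-gene values per sample by the sample's normalizer-gene
#' level: the scale factor of a sample is its normalizer mean divided by the
#' grand mean of the per-sample normalizer means, and target values are
#' divided by it. Normalizer rows are returned unchanged. This mirrors
#' normalizing one cluster's FPKM values against genes of the other,
#' unperturbed Hox clusters.
#'
#' @param expr a `hox_expr` long table (`gene, timepoint, replicate, value`).
#'   A sample is one `(timepoint, replicate)` combination.
#' @param target_genes,normalizer_genes character vectors of gene names.
#' @return a `hox_expr` with normalized target values.
#' @export
normalize_cross_cluster <- function(expr, target_genes, normalizer_genes) {
  stopifnot(all(c("gene", "timepoint", "replicate", "value") %in% names(expr)))
  sample_id <- interaction(expr$timepoint, expr$replicate, drop = TRUE)
  norm_rows <- expr$gene %in% normalizer_genes
  if (!all(vapply(split(norm_rows, sample_id), any, TRUE)))
    stop("normalizer genes missing from some samples")
  per_sample <- tapply(expr$value[norm_rows], sample_id[norm_rows], mean)
  if (any(per_sample <= 0)) stop("zero normalizer mean in some sample")
  grand <- mean(per_sample)
  s <- per_sample[as.character(sample_id)] / grand
  out <- expr
  tgt <- expr$gene %in% target_genes
  out$value[tgt] <- expr$value[tgt] / s[tgt]
  out
}

#' Welch comparison of two genotypes
#'
#' Per gene and timepoint: mean log2 ratio (mutant over wild type) of
#' replicate values and a two-sided Welch unequal-variances t-test on the
#' replicates, with significance stars at 0.05 and 0.01. With zero variance
#' in both groups and equal means, the p-value is reported as 1; with zero
#' variance and unequal means, as 0.
#'
#' @param wt,mut `hox_expr` tables with >= 2 replicates each.
#' @param pseudo pseudocount added inside the log ratio.
#' @return data.frame `gene, timepoint, log2_ratio, t, df, p, stars`.
#' @export
compare_genotypes <- function(wt, mut, pseudo = 1e-9) {
  keys <- unique(rbind(wt[c("gene", "timepoint")], mut[c("gene", "timepoint")]))
  out <- lapply(seq_len(nrow(keys)), function(i) {
    g <- keys$gene[i]; tp <- keys$timepoint[i]
    x <- wt$value[wt$gene == g & wt$timepoint == tp]
    y <- mut$value[mut$gene == g & mut$timepoint == tp]
    if (length(x) < 2L || length(y) < 2L) stop("need >= 2 replicates per group")
    lr <- log2((mean(y) + pseudo) / (mean(x) + pseudo))
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      tt <- list(statistic = c(t = if (p == 1) 0 else Inf), parameter = c(df = NA_real_))
    } else {
      tt <- stats::t.test(y, x, var.equal = FALSE)
      p <- tt$p.value
    }
    data.frame(gene = g, timepoint = tp, log2_ratio = lr,
               t = unname(tt$statistic), df = unname(tt$parameter), p = p,
               stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Colinearity score of an activation schedule
#'
#' Spearman rank correlation between the 3'-to-5' positional rank of the
#' genes and their activation times. Never-activated genes (infinite onset)
#' share the maximal rank with average-tie handling.
#'
#' @param schedule named numeric vector of activation model-hours (or a
#'   one-row slice of [onset_table()]).
#' @param locus the `hox_locus` giving the positional order.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
colinearity_score <- function(schedule, locus) {
  schedule <- unlist(schedule)
  genes <- intersect(locus$genes$name, names(schedule))
  if (sum(is.finite(schedule[genes])) < 3L)
    stop("need >= 3 finite onsets")
  onset <- schedule[genes]
  onset[!is.finite(onset)] <- max(onset[is.finite(onset)]) + 1
  pos_rank <- seq_along(genes)          # locus$genes is in 3'->5' order
  stats::cor(pos_rank, rank(onset, ties.method = "average"),
             method = "spearman")
}

#' Occupancy share shift across CBSs
#'
#' For each timepoint of an occupancy series, the fraction of total
#' labeled-CBS occupancy found at each CBS (rows sum to 1). Used to follow
#' the redistribution of cohesin from the first gating CBS toward more
#' posterior sites over time.
#'
#' @param occupancy_series a `hox_series` of occupancy tracks.
#' @param cbs_bins named integer vector of CBS bin indices.
#' @return matrix timepoints x CBSs of shares; timepoints with zero total
#'   occupancy are `NA` (flagged via attribute `"undefined"`).
#' @export
occupancy_share_shift <- function(occupancy_series, cbs_bins) {
  n <- length(occupancy_series$tracks[[1L]]$values)
  if (any(cbs_bins < 1) || any(cbs_bins > n)) stop("labeled bins outside axis")
  m <- vapply(occupancy_series$tracks,
              function(tr) tr$values[cbs_bins], numeric(length(cbs_bins)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  m <- t(m)
  colnames(m) <- names(cbs_bins)
  rownames(m) <- occupancy_series$times
  tot <- rowSums(m)
  undef <- tot <= 0
  shares <- m / tot
  shares[undef, ] <- NA_real_
  attr(shares, "undefined") <- which(undef)
  shares
}
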