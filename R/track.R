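# Per-bin signal tracks and time-indexed track series.

#' Per-bin signal track
#'
#' A `hox_track` is a per-bin signal vector with genomic-axis metadata
#' (chromosome, axis start, bin size); it maps directly to bedGraph.
#'
#' @param values numeric per-bin values.
#' @param chrom chromosome label.
#' @param axis_start axis start in bp (0-based).
#' @param bin_size bin width in bp.
#' @return a `hox_track`.
#' @export
track <- function(values, chrom = "chr", axis_start = 0, bin_size = 1) {
  stopifnot(is.numeric(values), bin_size > 0, axis_start >= 0)
  structure(list(values = as.numeric(values), chrom = chrom,
                 axis_start = as.numeric(axis_start),
                 bin_size = as.numeric(bin_size)),
            class = "hox_track")
}

track_like <- function(lattice, values) {
  track(values, chrom = lattice$chrom, axis_start = lattice$axis_start,
        bin_size = lattice$bin_size)
}

#' @export
print.hox_track <- function(x, ...) {
  cat(sprintf("<hox_track> %s: %d bins x %g bp, sum = %.4g\n", x$chrom,
              length(x$values), x$bin_size, sum(x$values)))
  invisible(x)
}

#' @export
length.hox_track <- function(x) length(x$values)

same_axis <- function(a, b) {
  isTRUE(a$chrom == b$chrom) && a$axis_start == b$axis_start &&
    a$bin_size == b$bin_size && length(a$values) == length(b$values)
}

#' Time-indexed series of tracks
#'
#' @param times strictly increasing numeric times (model-hours).
#' @param tracks list of `hox_track` objects on a shared axis.
#' @return a `hox_series`.
#' @export
track_series <- function(times, tracks) {
  stopifnot(length(times) == length(tracks), !is.unsorted(times, strictly = TRUE))
  if (length(tracks) > 1L)
    for (i in 2:length(tracks))
      if (!same_axis(tracks[[1L]], tracks[[i]])) stop("axis mismatch in series")
  structure(list(times = as.numeric(times), tracks = tracks),
            class = "hox_series")
}

#' @export
print.hox_series <- function(x, ...) {
  cat(sprintf("<hox_series> %d timepoints (%.4g..%.4g h), %d bins\n",
              length(x$times), min(x$times), max(x$times),
              length(x$tracks[[1L]]$values)))
  invisible(x)
}

series_matrix <- function(series) {
  do.call(cbind, lapply(series$tracks, function(t) t$values))
}
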