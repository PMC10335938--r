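# File formats and reproducibility plumbing: bedGraph tracks, BED6 locus
# annotations, dense/triplet contact matrices, key = value config files,
# JSON run manifests.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a track as bedGraph
#'
#' Four-column bedGraph (0-based, half-open, no header), one row per bin,
#' values at full double precision; write-then-read is lossless. Reading
#' rejects negative coordinates and empty or overlapping intervals, sorts
#' unsorted input with a warning, and requires uniform bin widths.
#'
#' @param path file path.
#' @param track a `hox_track`.
#' @return `read_track` returns a `hox_track`; `write_track` returns the
#'   path invisibly.
#' @export
write_track <- function(path, track) {
  n <- length(track$values)
  start <- track$axis_start + (seq_len(n) - 1) * track$bin_size
  df <- data.frame(chrom = track$chrom, start = fmt_num(start),
                   end = fmt_num(start + track$bin_size),
                   value = fmt_num(track$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  if (!nrow(df)) stop("empty bedGraph")
  if (any(df$start < 0)) stop("negative coordinate in bedGraph")
  if (any(df$start >= df$end)) stop("empty or inverted interval in bedGraph")
  if (is.unsorted(df$start)) {
    warning("unsorted bedGraph; sorting")
    df <- df[order(df$start), , drop = FALSE]
  }
  if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)]))
    stop("overlapping intervals in bedGraph")
  widths <- df$end - df$start
  if (length(unique(widths)) != 1L)
    stop("non-uniform bin widths; not a binned track")
  track(df$value, chrom = df$chrom[1L], axis_start = df$start[1L],
        bin_size = widths[1L])
}

#' Write / read a contact map
#'
#' `dense`: whitespace-separated full matrix (must be symmetric on read).
#' `triplet`: three columns `bin1 bin2 value` (1-based bins), upper
#' triangle plus diagonal only; the reader symmetrizes. Round trips are
#' lossless in both formats.
#'
#' @param path file path.
#' @param map a `hox_map`.
#' @param format `"dense"` or `"triplet"`.
#' @param n_bins matrix size (triplet reads only; default: max bin index).
#' @return `read_map` returns a `hox_map`; `write_map` the path, invisibly.
#' @export
write_map <- function(path, map, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    write.table(matrix(fmt_num(map$matrix), nrow(map$matrix)), path,
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(map$matrix, diag = TRUE) & map$matrix != 0,
                 arr.ind = TRUE)
    df <- data.frame(bin1 = idx[, 1L], bin2 = idx[, 2L],
                     value = fmt_num(map$matrix[idx]))
    df <- df[order(df$bin1, df$bin2), , drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path, format = c("dense", "triplet"), n_bins = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) stop("dense map must be square")
    if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
      stop("asymmetric dense map")
    m <- (m + t(m)) / 2
  } else {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("bin1", "bin2", "value"))
    if (any(df$bin1 > df$bin2))
      stop("triplet map must store the upper triangle only (bin1 <= bin2)")
    n <- if (is.null(n_bins)) max(df$bin1, df$bin2) else n_bins
    m <- matrix(0, n, n)
    m[cbind(df$bin1, df$bin2)] <- df$value
    m[cbind(df$bin2, df$bin1)] <- df$value
  }
  new_contact_map(m)
}

# ---- BED6 locus annotations -------------------------------------------------

read_bed6 <- function(source, what) {
  df <- if (is.data.frame(source)) source else {
    out <- tryCatch(
      read.table(source, sep = "\t", header = FALSE, comment.char = "#",
                 stringsAsFactors = FALSE),
      error = function(e) stop("malformed ", what, " BED: ", conditionMessage(e)))
    out
  }
  if (ncol(df) < 4L) stop("malformed ", what, " BED: need >= 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  if (ncol(df) >= 5L) names(df)[5L] <- "score"
  if (ncol(df) >= 6L) names(df)[6L] <- "strand"
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start < 0 |
                 df$start >= df$end)
  if (length(bad))
    stop("malformed ", what, " BED record at line ",
         paste(bad, collapse = ", "))
  df
}

#' Load a locus annotation from BED records
#'
#' Builds a `hox_locus` from three BED6 sources: genes (name column =
#' gene name, score column = domain code 1/2/3 for
#' anterior/central/posterior), CBSs (strand `+` = TOWARD_TDOM, `-` =
#' TOWARD_CDOM; score column 1 = occupied, 0 = unoccupied) and regions
#' (score column = enhancer `active_from` model-hours, 0 or `.` = none).
#' Gene order is taken as 3' to 5' in decreasing coordinate order.
#'
#' @param genes_source,cbs_source,regions_source file paths or data.frames
#'   of BED records.
#' @param axis `c(start, end)` of the modeled axis; default: span of the
#'   records.
#' @param genotype genotype label.
#' @return a validated `hox_locus`.
#' @export
load_annotation <- function(genes_source, cbs_source, regions_source,
                            axis = NULL, genotype = "custom") {
  g <- read_bed6(genes_source, "gene")
  if (!nrow(g)) stop("at least one gene required")
  s <- read_bed6(cbs_source, "CBS")
  r <- read_bed6(regions_source, "region")
  if (is.null(axis)) axis <- c(min(g$start, s$start, r$start),
                               max(g$end, s$end, r$end))
  genes <- data.frame(name = g$name, start = g$start, end = g$end,
                      domain = DOMAINS[as.integer(g$score)],
                      stringsAsFactors = FALSE)
  genes <- genes[order(-genes$start), , drop = FALSE]   # 3' -> 5'
  rownames(genes) <- NULL
  cluster_span <- r[r$name == "cluster", , drop = FALSE]
  pos <- floor((s$start + s$end) / 2)
  ctcf <- data.frame(
    id = s$name, pos = pos,
    orientation = ifelse(s$strand == "+", "TOWARD_TDOM", "TOWARD_CDOM"),
    occupied = if ("score" %in% names(s)) s$score != 0 else TRUE,
    in_cluster = if (nrow(cluster_span) == 1L)
      pos >= cluster_span$start & pos < cluster_span$end else TRUE,
    stringsAsFactors = FALSE)
  ctcf <- ctcf[order(ctcf$pos), , drop = FALSE]
  rownames(ctcf) <- NULL
  score <- suppressWarnings(as.numeric(r$score))
  regions <- data.frame(name = r$name, start = r$start, end = r$end,
                        active_from = ifelse(is.na(score) | score == 0,
                                             NA_real_, score),
                        stringsAsFactors = FALSE)
  hox_locus(g$chrom[1L], axis[1L], axis[2L], genes, ctcf, regions,
            genotype = genotype)
}

#' Serialize a locus annotation to BED files
#'
#' Writes `genes.bed`, `cbs.bed` and `regions.bed` under `dir`, in the
#' dialect read by [load_annotation()] (round-trip safe).
#'
#' @param locus a `hox_locus`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- locus$genes
  write.table(data.frame(locus$chrom, g$start, g$end, g$name,
                         match(g$domain, DOMAINS), "+"),
              file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  s <- locus$ctcf
  write.table(data.frame(locus$chrom, s$pos, s$pos + 1L, s$id,
                         as.integer(s$occupied),
                         ifelse(s$orientation == "TOWARD_TDOM", "+", "-")),
              file.path(dir, "cbs.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  r <- locus$regions
  write.table(data.frame(locus$chrom, r$start, r$end, r$name,
                         ifelse(is.na(r$active_from), 0, r$active_from), "+"),
              file.path(dir, "regions.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a locus previously written with [write_locus()]
#' @param dir directory holding `genes.bed`, `cbs.bed`, `regions.bed`.
#' @param axis,genotype passed to [load_annotation()].
#' @return a `hox_locus`.
#' @export
read_locus <- function(dir, axis = NULL, genotype = "custom") {
  load_annotation(file.path(dir, "genes.bed"), file.path(dir, "cbs.bed"),
                  file.path(dir, "regions.bed"), axis = axis,
                  genotype = genotype)
}

# ---- run configuration ------------------------------------------------------

config_schema <- function() {
  list(sim = names(unclass(sim_params())),
       timer = names(unclass(timer_params())),
       run = c("t_start", "t_end", "seeds", "snapshot_every", "sample_every"))
}

#' Read / write a run configuration
#'
#' Plain `[section]` / `key = value` text with sections `[sim]`, `[timer]`
#' and `[run]`. Keys are validated against the known parameter names;
#' unknown sections or keys are rejected.
#'
#' @param path file path.
#' @param config nested named list `list(sim =, timer =, run =)`.
#' @return `read_config` returns the nested list with numeric values
#'   parsed; `write_config` the path, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  schema <- config_schema()
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(schema)) stop("unknown config section: ", section)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("key outside any section: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      if (!key %in% schema[[section]])
        stop("unknown key '", key, "' in section [", section, "]")
      val <- trimws(paste(kv[-1L], collapse = "="))
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))
      out[[section]][[key]] <- if (any(is.na(num))) val else num
    } else stop("unparseable config line: ", ln)
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(path, config) {
  schema <- config_schema()
  lines <- character(0)
  for (sec in names(config)) {
    if (!sec %in% names(schema)) stop("unknown config section: ", sec)
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad)) stop("unknown key in [", sec, "]: ",
                          paste(bad, collapse = ", "))
    lines <- c(lines, paste0("[", sec, "]"))
    for (k in names(config[[sec]]))
      lines <- c(lines, paste0(k, " = ",
                               paste(fmt_num(config[[sec]][[k]]), collapse = ",")))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build parameter objects from a configuration
#'
#' @param config nested list from [read_config()].
#' @return list with `sim_params`, `timer_params` and the `run` section.
#' @export
config_params <- function(config) {
  sp <- do.call(sim_params, config$sim %||% list())
  tp <- do.call(timer_params, config$timer %||% list())
  list(sim_params = sp, timer_params = tp, run = config$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reproducibility manifest
#'
#' JSON record of the configuration, seeds and package version written
#' alongside run outputs; manifest + config + seed reproduce any output.
#'
#' @param path output path.
#' @param config nested configuration list.
#' @param seeds integer seeds used.
#' @param outputs character vector of output file names.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config, seeds, outputs = character(0)) {
  manifest <- list(
    package = "hoxtimer",
    version = as.character(utils::packageVersion("hoxtimer")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    seeds = seeds,
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
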