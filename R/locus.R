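#' @useDynLib hoxtimer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rbinom quantile approx coef lm rpois
#' @importFrom utils read.table write.table
NULL

ORIENTATIONS <- c("TOWARD_TDOM", "TOWARD_CDOM")
DOMAINS <- c("anterior", "central", "posterior")

#' Construct a locus annotation
#'
#' A `hox_locus` holds genes, oriented CTCF-binding sites (CBSs) and
#' regulatory regions on a single genomic axis (0-based, half-open
#' coordinates). It is the substrate for discretization, genotype editing and
#' simulation.
#'
#' @param chrom chromosome label.
#' @param axis_start,axis_end span of the modeled axis in bp.
#' @param genes data.frame with columns `name`, `start`, `end`, `domain`
#'   (one of `"anterior"`, `"central"`, `"posterior"`), ordered 3' to 5'.
#' @param ctcf data.frame with columns `id`, `pos`, `orientation`
#'   (`"TOWARD_TDOM"` or `"TOWARD_CDOM"`), `occupied`, `in_cluster`.
#' @param regions data.frame with columns `name`, `start`, `end`,
#'   `active_from` (model-hours; `NA` for non-enhancer regions).
#' @param genotype genotype label.
#' @return a validated `hox_locus` object.
#' @export
hox_locus <- function(chrom, axis_start, axis_end, genes, ctcf, regions,
                      genotype = "WT") {
  loc <- structure(
    list(chrom = chrom, axis_start = as.numeric(axis_start),
         axis_end = as.numeric(axis_end),
         genes = as.data.frame(genes, stringsAsFactors = FALSE),
         ctcf = {
           s <- as.data.frame(ctcf, stringsAsFactors = FALSE)
           s <- s[order(s$pos), , drop = FALSE]
           rownames(s) <- NULL
           s
         },
         regions = as.data.frame(regions, stringsAsFactors = FALSE),
         genotype = genotype),
    class = "hox_locus")
  validate_locus(loc)
  loc
}

#' Validate a locus annotation
#'
#' Checks the structural invariants: all features inside the axis, gene
#' intervals pairwise non-overlapping with unique names, CBS ids unique and
#' sorted output, and no occupied in-cluster CBS in the anterior (CTCF-free)
#' domain 3' of CBS1.
#'
#' @param loc a `hox_locus`.
#' @return `loc`, invisibly; errors listing offending features otherwise.
#' @export
validate_locus <- function(loc) {
  g <- loc$genes; s <- loc$ctcf; r <- loc$regions
  if (nrow(g) < 1L) stop("at least one gene required")
  if (anyDuplicated(g$name)) stop("duplicated gene names: ",
                                  paste(g$name[duplicated(g$name)], collapse = ", "))
  if (any(g$start >= g$end)) stop("gene with start >= end: ",
                                  paste(g$name[g$start >= g$end], collapse = ", "))
  bad <- g$start < loc$axis_start | g$end > loc$axis_end
  if (any(bad)) stop("gene outside axis: ", paste(g$name[bad], collapse = ", "))
  og <- g[order(g$start), , drop = FALSE]
  if (nrow(og) > 1L && any(og$start[-1L] < og$end[-nrow(og)]))
    stop("overlapping gene intervals")
  if (!all(g$domain %in% DOMAINS)) stop("unknown gene domain")
  if (nrow(s)) {
    if (anyDuplicated(s$id)) stop("duplicated CBS ids")
    if (!all(s$orientation %in% ORIENTATIONS)) stop("unknown CBS orientation")
    bad <- s$pos < loc$axis_start | s$pos >= loc$axis_end
    if (any(bad)) stop("CBS outside axis: ", paste(s$id[bad], collapse = ", "))
    cl <- r[r$name == "cluster", , drop = FALSE]
    if (nrow(cl) == 1L) {
      inc <- s$in_cluster
      out <- inc & (s$pos < cl$start | s$pos >= cl$end)
      if (any(out)) stop("in-cluster CBS outside cluster span: ",
                         paste(s$id[out], collapse = ", "))
      # anterior domain = 3' (T-DOM side, higher coordinates) of CBS1
      if ("CBS1" %in% s$id) {
        cbs1 <- s$pos[s$id == "CBS1"]
        ant <- inc & s$occupied & s$pos > cbs1
        if (any(ant)) stop("occupied in-cluster CBS in the CTCF-free domain: ",
                           paste(s$id[ant], collapse = ", "))
      }
    }
  }
  if (nrow(r)) {
    bad <- r$start < loc$axis_start | r$end > loc$axis_end | r$start >= r$end
    if (any(bad)) stop("invalid region: ", paste(r$name[bad], collapse = ", "))
  }
  invisible(loc)
}

#' @export
print.hox_locus <- function(x, ...) {
  cat(sprintf("<hox_locus> %s:%d-%d [%s]\n", x$chrom, x$axis_start, x$axis_end,
              x$genotype))
  cat(sprintf("  %d genes, %d CTCF sites (%d in-cluster), %d regions\n",
              nrow(x$genes), nrow(x$ctcf), sum(x$ctcf$in_cluster),
              nrow(x$regions)))
  invisible(x)
}

#' Default wild-type HoxD locus annotation
#'
#' Builds the wild-type fixture of the mouse HoxD locus on chr2 (mm10-like
#' labels, treated as an abstract axis): the full modeled span
#' chr2:73,900,037-75,621,560; the gene cluster chr2:74,667,374-74,767,842
#' holding ten genes in canonical 3'-to-5' order (Hoxd1 ... Hoxd13, Evx2);
#' nine in-cluster CBSs with the published orientations (CBS1, CBS2, CBS4 and
#' CBS5 toward T-DOM; CBS3 and CBS6-CBS9 toward C-DOM); five T-DOM CBSs in
#' sub-TAD1 oriented toward the cluster (convergent with the in-cluster
#' series); the CBS-rich CS38-40 region chr2:75,105,000-75,190,000; three
#' enhancer elements in sub-TAD1 becoming active at 96 model-hours; and the
#' 20-kb pre-looped element containing CBS1 between Hoxd4 and Hoxd8.
#'
#' Exact CBS base-pair positions are not published; the fixture interleaves
#' them with the genes in the order implied by the mutant phenotypes (CBS1
#' between Hoxd4 and Hoxd8, CBS2 between Hoxd8 and Hoxd9, CBS3 near Hoxd9,
#' CBS4 between Hoxd10 and Hoxd11, CBS5 between Hoxd11 and Hoxd12, CBS6-CBS9
#' spanning Hoxd12 to Evx2). All positions can be overridden via
#' [load_annotation()].
#'
#' @return a `hox_locus` describing the wild-type locus.
#' @export
hoxd_locus <- function() {
  genes <- data.frame(
    name = c("Hoxd1", "Hoxd3", "Hoxd4", "Hoxd8", "Hoxd9", "Hoxd10",
             "Hoxd11", "Hoxd12", "Hoxd13", "Evx2"),
    start = c(74748000, 74735000, 74719000, 74700500, 74694000, 74687000,
              74682000, 74676000, 74672600, 74669000),
    end   = c(74750500, 74740000, 74722500, 74704000, 74697500, 74690500,
              74684000, 74678000, 74675300, 74672000),
    domain = c("anterior", "anterior", "anterior", "central", "central",
               "central", "central", "posterior", "posterior", "posterior"),
    stringsAsFactors = FALSE)
  ctcf <- data.frame(
    id = c(paste0("CBS", 1:9), paste0("TD-CBS", 1:5)),
    pos = c(74716500, 74699000, 74693000, 74686000, 74679000,
            74675650, 74672300, 74670500, 74668000,
            74840000, 74930000, 75015000, 75110000, 75170000),
    orientation = c("TOWARD_TDOM", "TOWARD_TDOM", "TOWARD_CDOM",
                    "TOWARD_TDOM", "TOWARD_TDOM",
                    rep("TOWARD_CDOM", 4), rep("TOWARD_CDOM", 5)),
    occupied = TRUE,
    in_cluster = c(rep(TRUE, 9), rep(FALSE, 5)),
    stringsAsFactors = FALSE)
  regions <- data.frame(
    name = c("cluster", "subTAD1", "subTAD2", "CS38_40", "CDOM",
             "CBS1_element", "E1", "E2", "E3"),
    start = c(74667374, 74767842, 75190000, 75105000, 73900037,
              74704000, 74835000, 74925000, 75010000),
    end   = c(74767842, 75190000, 75621560, 75190000, 74667374,
              74724000, 74845000, 74935000, 75020000),
    active_from = c(NA, NA, NA, NA, NA, NA, 96, 96, 96),
    stringsAsFactors = FALSE)
  hox_locus("chr2", 73900037, 75621560, genes, ctcf, regions, genotype = "WT")
}

#' Minimal three-gene toy locus
#'
#' A small locus used for fast parameter-recovery studies: three genes on a
#' 200-kb axis, a single T-DOM-oriented CBS gating each of the two
#' non-anterior genes, one convergent downstream CBS and one enhancer
#' element. Useful wherever a full HoxD simulation would be needlessly slow.
#'
#' @param t_enh model-hour at which the toy enhancer becomes active.
#' @return a `hox_locus`.
#' @export
toy_locus <- function(t_enh = 4) {
  genes <- data.frame(
    name = c("gA", "gB", "gC"),
    start = c(120000, 96000, 72000),
    end = c(126000, 102000, 78000),
    domain = c("anterior", "central", "central"),
    stringsAsFactors = FALSE)
  ctcf <- data.frame(
    id = c("CBS1", "CBS2", "TD-CBS1"),
    pos = c(110000, 86000, 160000),
    orientation = c("TOWARD_TDOM", "TOWARD_TDOM", "TOWARD_CDOM"),
    occupied = TRUE,
    in_cluster = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  regions <- data.frame(
    name = c("cluster", "E1"),
    start = c(60000, 155000),
    end = c(140000, 165000),
    active_from = c(NA, t_enh),
    stringsAsFactors = FALSE)
  hox_locus("toy", 0, 200000, genes, ctcf, regions, genotype = "toy")
}

#' Discretize a locus to a lattice
#'
#' Maps base-pair features to lattice bins of width `bin_size`. Bin `i`
#' (1-based) covers `[axis_start + (i-1)*bin_size, axis_start + i*bin_size)`,
#' so the mapping is deterministic and invertible to bin intervals.
#'
#' @param locus a `hox_locus`.
#' @param bin_size bin width in bp.
#' @param merge_cbs if `TRUE`, CBSs falling in the same bin are merged
#'   (strongest blocking semantics retained); if `FALSE` (default) a bin
#'   shared by two same-orientation CBSs is an error.
#' @return a `hox_lattice` with `n_bins`, per-gene bin ranges, per-CBS bin
#'   indices and per-region bin ranges (all 1-based).
#' @export
discretize <- function(locus, bin_size = 2000, merge_cbs = FALSE) {
  stopifnot(bin_size > 0)
  axis_len <- locus$axis_end - locus$axis_start
  n_bins <- as.integer(ceiling(axis_len / bin_size))
  bp2bin <- function(p) pmin(n_bins, as.integer(floor((p - locus$axis_start) / bin_size)) + 1L)
  g <- locus$genes
  if (any(g$end - g$start < bin_size))
    warning("bin_size larger than smallest gene; gene bodies span single bins")
  gene_bins <- data.frame(name = g$name,
                          start_bin = bp2bin(g$start),
                          end_bin = bp2bin(g$end - 1),
                          domain = g$domain,
                          stringsAsFactors = FALSE)
  s <- locus$ctcf
  cbs_bins <- data.frame(id = s$id, bin = bp2bin(s$pos),
                         orientation = s$orientation,
                         occupied = s$occupied, in_cluster = s$in_cluster,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(cbs_bins$bin)) {
    if (!merge_cbs) stop("CBS bin collision: ", paste(
      cbs_bins$id[cbs_bins$bin %in% cbs_bins$bin[duplicated(cbs_bins$bin)]],
      collapse = ", "))
    cbs_bins <- cbs_bins[!duplicated(cbs_bins[c("bin", "orientation")]), , drop = FALSE]
  }
  r <- locus$regions
  region_bins <- data.frame(name = r$name,
                            start_bin = bp2bin(r$start),
                            end_bin = bp2bin(r$end - 1),
                            active_from = r$active_from,
                            stringsAsFactors = FALSE)
  structure(list(chrom = locus$chrom, axis_start = locus$axis_start,
                 axis_end = locus$axis_end, bin_size = bin_size,
                 n_bins = n_bins, genes = gene_bins, cbs = cbs_bins,
                 regions = region_bins, genotype = locus$genotype),
            class = "hox_lattice")
}

#' Bin interval in bp for lattice bins
#'
#' Inverse of the [discretize()] mapping: returns, for each 1-based bin
#' index, the half-open bp interval it covers.
#'
#' @param lattice a `hox_lattice`.
#' @param bins integer bin indices.
#' @return data.frame with `start` and `end` in bp.
#' @export
bin_interval <- function(lattice, bins) {
  stopifnot(all(bins >= 1L), all(bins <= lattice$n_bins))
  data.frame(start = lattice$axis_start + (bins - 1) * lattice$bin_size,
             end = pmin(lattice$axis_end,
                        lattice$axis_start + bins * lattice$bin_size))
}

#' Midpoint coordinates of lattice bins
#' @param lattice a `hox_lattice`.
#' @param bins integer bin indices.
#' @return numeric bp midpoints.
#' @export
bin_mid <- function(lattice, bins) {
  iv <- bin_interval(lattice, bins)
  (iv$start + iv$end) / 2
}
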