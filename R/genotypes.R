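# Genotype edits: CBS deletions, interval deletions, cassette insertions.

#' Genotype edit constructors
#'
#' `edit_delete_cbs()` inactivates/removes named CBSs (coordinates of other
#' features are unchanged: the deleted segments are ~1 kb against a 1.7-Mb
#' axis, so a deletion is modeled as removal of the barrier only).
#' `edit_delete_interval()` removes a genomic interval and shifts all
#' downstream coordinates, for large engineered deletions.
#' `edit_insert_cassette()` adds CBSs at `anchor + offset` positions, as for
#' the 2xCBS cassette inserted next to CBS1.
#'
#' @param ids character vector of CBS ids to delete.
#' @param start,end interval to delete (bp).
#' @param anchor insertion anchor position (bp).
#' @param offsets strictly increasing bp offsets relative to `anchor`.
#' @param orientations orientation for each inserted site.
#' @param id_prefix prefix for the inserted site ids.
#' @return a `genotype_edit` object.
#' @export
edit_delete_cbs <- function(ids) {
  structure(list(kind = "DELETE_CBS", targets = as.character(ids)),
            class = "genotype_edit")
}

#' @rdname edit_delete_cbs
#' @export
edit_delete_interval <- function(start, end) {
  stopifnot(start < end)
  structure(list(kind = "DELETE_INTERVAL", start = start, end = end),
            class = "genotype_edit")
}

#' @rdname edit_delete_cbs
#' @export
edit_insert_cassette <- function(anchor, offsets, orientations,
                                 id_prefix = "insCBS") {
  stopifnot(length(offsets) == length(orientations),
            all(orientations %in% ORIENTATIONS))
  if (length(offsets) > 1 && any(diff(offsets) <= 0))
    stop("cassette offsets must be strictly increasing")
  structure(list(kind = "INSERT_CBS_CASSETTE", anchor = anchor,
                 offsets = offsets, orientations = orientations,
                 id_prefix = id_prefix),
            class = "genotype_edit")
}

#' Apply genotype edits to a locus
#'
#' Applies edits in order and returns a new annotation; the input is never
#' modified. CBS deletions remove the site only; interval deletions remove
#' features inside the interval and shift downstream coordinates; cassette
#' insertions add oriented sites at `anchor + offset`.
#'
#' @param locus a `hox_locus`.
#' @param edits a single `genotype_edit` or list of them.
#' @param label genotype label for the edited annotation.
#' @return a new, validated `hox_locus`.
#' @export
apply_genotype <- function(locus, edits, label = NULL) {
  if (inherits(edits, "genotype_edit")) edits <- list(edits)
  loc <- locus
  for (e in edits) loc <- apply_one_edit(loc, e)
  loc$genotype <- if (is.null(label)) {
    paste0(locus$genotype, "+", paste(vapply(edits, edit_label, ""), collapse = "+"))
  } else label
  validate_locus(loc)
  loc
}

edit_label <- function(e) {
  switch(e$kind,
         DELETE_CBS = paste0("Del(", paste(e$targets, collapse = ","), ")"),
         DELETE_INTERVAL = sprintf("Del(%d-%d)", e$start, e$end),
         INSERT_CBS_CASSETTE = sprintf("Ins(%dxCBS)", length(e$offsets)))
}

apply_one_edit <- function(loc, e) {
  if (e$kind == "DELETE_CBS") {
    missing_ids <- setdiff(e$targets, loc$ctcf$id)
    if (length(missing_ids))
      stop("unknown CBS id: ", paste(missing_ids, collapse = ", "))
    loc$ctcf <- loc$ctcf[!(loc$ctcf$id %in% e$targets), , drop = FALSE]
    rownames(loc$ctcf) <- NULL
  } else if (e$kind == "INSERT_CBS_CASSETTE") {
    pos <- e$anchor + e$offsets
    if (any(pos %in% loc$ctcf$pos))
      stop("insertion collides with an existing CBS position")
    cl <- loc$regions[loc$regions$name == "cluster", , drop = FALSE]
    in_cl <- if (nrow(cl) == 1L) pos >= cl$start & pos < cl$end else rep(TRUE, length(pos))
    add <- data.frame(id = paste0(e$id_prefix, seq_along(pos)),
                      pos = pos, orientation = e$orientations,
                      occupied = TRUE, in_cluster = in_cl,
                      stringsAsFactors = FALSE)
    loc$ctcf <- rbind(loc$ctcf, add)
  } else if (e$kind == "DELETE_INTERVAL") {
    d <- e$end - e$start
    shift <- function(p) ifelse(p >= e$end, p - d, p)
    g <- loc$genes
    drop <- g$start >= e$start & g$end <= e$end
    g <- g[!drop, , drop = FALSE]
    if (any(g$start < e$end & g$end > e$start))
      stop("DELETE_INTERVAL partially overlaps a gene: ",
           paste(g$name[g$start < e$end & g$end > e$start], collapse = ", "))
    g$start <- shift(g$start); g$end <- shift(g$end)
    s <- loc$ctcf
    s <- s[!(s$pos >= e$start & s$pos < e$end), , drop = FALSE]
    s$pos <- shift(s$pos)
    r <- loc$regions
    r$start <- shift(pmax(r$start, ifelse(r$start >= e$start & r$start < e$end, e$end, r$start)))
    r$end <- shift(pmin(r$end, ifelse(r$end > e$start & r$end <= e$end, e$start, r$end)))
    r <- r[r$end > r$start, , drop = FALSE]
    loc$genes <- g; loc$ctcf <- s; loc$regions <- r
    loc$axis_end <- loc$axis_end - d
  } else stop("unknown edit kind: ", e$kind)
  # keep ctcf sorted by position
  loc$ctcf <- loc$ctcf[order(loc$ctcf$pos), , drop = FALSE]
  rownames(loc$ctcf) <- NULL
  loc
}

#' The engineered CBS genotypes
#'
#' Returns the edit lists for the CBS perturbation genotypes analyzed with
#' this model: single deletions Del(CBS1), Del(CBS2), Del(CBS4), the double
#' deletion Del(CBS1-2), the full anterior/central series deletion
#' Del(CBS1-5), and the cassette insertion Ins(2xCBS-d4d8) that places two
#' extra T-DOM-oriented sites 2-3 kb 5' of CBS1, so that three sites instead
#' of one open the series between Hoxd4 and Hoxd8.
#'
#' @return named list of `genotype_edit` lists.
#' @export
hoxd_mutants <- function() {
  cbs1 <- hoxd_locus()$ctcf$pos[hoxd_locus()$ctcf$id == "CBS1"]
  list(
    "Del(CBS1)"   = list(edit_delete_cbs("CBS1")),
    "Del(CBS2)"   = list(edit_delete_cbs("CBS2")),
    "Del(CBS4)"   = list(edit_delete_cbs("CBS4")),
    "Del(CBS1-2)" = list(edit_delete_cbs(c("CBS1", "CBS2"))),
    "Del(CBS1-5)" = list(edit_delete_cbs(paste0("CBS", 1:5))),
    "Ins(2xCBS-d4d8)" = list(edit_insert_cassette(
      anchor = cbs1, offsets = c(-3000, -2000),
      orientations = c("TOWARD_TDOM", "TOWARD_TDOM"),
      id_prefix = "CBS-d4d8-"))
  )
}
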