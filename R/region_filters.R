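## Region exclusion filters: remove AS-SNP candidates falling inside padded
## unreliable regions — assembly gaps (padded +/- 1 Mb, covering centromeric
## and telomeric neighbourhoods), blacklisted regions (+/- 100 bp) and CNVs
## (no padding). Intervals are held as GRanges (1-based closed); BED's
## 0-based half-open convention is converted once, by rtracklayer, at the
## file boundary.

default_paddings <- c(gap = 1e6, blacklist = 100, cnv = 0)

#' Construct an exclusion track
#'
#' @param label one of `"gap"`, `"blacklist"`, `"cnv"`; determines the default
#'   padding (1 Mb, 100 bp, 0 respectively).
#' @param intervals a `GRanges`, or a data.frame with columns
#'   `contig, start, end` in BED convention (0-based half-open).
#' @param padding padding in bases applied to each side before filtering;
#'   `NULL` uses the label's default.
#' @return an `exclusion_track` list with elements `label, intervals, padding`.
#' @export
exclusion_track <- function(label, intervals, padding = NULL) {
  label <- match.arg(label, c("gap", "blacklist", "cnv"))
  if (is.null(padding)) padding <- unname(default_paddings[label])
  assert_scalar_number(padding, "padding", lower = 0)
  if (is.data.frame(intervals)) {
    if (!all(c("contig", "start", "end") %in% names(intervals)))
      stopf("interval data.frame needs columns contig, start, end (BED convention)")
    if (nrow(intervals) && any(intervals$end <= intervals$start))
      stopf("degenerate interval (end <= start)")
    intervals <- GenomicRanges::GRanges(
      intervals$contig,
      IRanges::IRanges(intervals$start + 1L, intervals$end))
  }
  if (!methods::is(intervals, "GRanges"))
    stopf("intervals must be a GRanges or a BED-like data.frame")
  structure(list(label = label, intervals = intervals, padding = padding),
            class = "exclusion_track")
}

#' @export
print.exclusion_track <- function(x, ...) {
  cat(sprintf("exclusion_track '%s': %d interval(s), padding %g bp\n",
              x$label, length(x$intervals), x$padding))
  invisible(x)
}

#' Pad and merge an exclusion track's intervals
#'
#' Expands every interval by the track's padding on both sides (clipped at
#' the contig start), then merges overlapping or adjacent intervals into a
#' sorted, disjoint set.
#'
#' @param track an [exclusion_track()].
#' @return a `GRanges` of disjoint padded intervals.
#' @export
pad_and_merge <- function(track) {
  stopifnot(inherits(track, "exclusion_track"))
  gr <- track$intervals
  if (!length(gr)) return(gr)
  GenomicRanges::start(gr) <- pmax(1L, GenomicRanges::start(gr) - track$padding)
  GenomicRanges::end(gr) <- GenomicRanges::end(gr) + track$padding
  GenomicRanges::reduce(sort(gr))
}

#' Remove SNPs inside padded exclusion tracks
#'
#' A SNP is removed iff its position lies inside any padded interval of any
#' track; removed records carry the triggering track label(s). SNPs on
#' contigs absent from every track are retained (the tracks are
#' exclusion-only). Retained and removed always partition the input.
#'
#' @param snps data.frame with at least `snp_id, contig, pos` (1-based).
#' @param tracks a list of [exclusion_track()] objects.
#' @return list with `retained` (input rows kept) and `removed` (input rows
#'   plus a `excluded_by` column of comma-joined track labels).
#' @export
apply_exclusions <- function(snps, tracks) {
  if (inherits(tracks, "exclusion_track")) tracks <- list(tracks)
  n <- nrow(snps)
  reason <- rep("", n)
  if (n > 0L) {
    snp_gr <- GenomicRanges::GRanges(snps$contig,
                                     IRanges::IRanges(snps$pos, width = 1L))
    for (tr in tracks) {
      padded <- pad_and_merge(tr)
      if (!length(padded)) next
      hit <- IRanges::overlapsAny(snp_gr, padded)
      reason[hit] <- ifelse(reason[hit] == "", tr$label,
                            paste(reason[hit], tr$label, sep = ","))
    }
  }
  removed <- snps[reason != "", , drop = FALSE]
  if (nrow(removed)) removed$excluded_by <- reason[reason != ""]
  retained <- snps[reason == "", , drop = FALSE]
  rownames(retained) <- rownames(removed) <- NULL
  list(retained = retained, removed = removed)
}
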