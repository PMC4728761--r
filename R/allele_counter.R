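## Allelic read counting: assign each aligned read overlapping a heterozygous
## SNP to the G1 (reference) or G2 (alternative) allele by the observed base,
## gated on mapping and base quality. Because G2 is built by SNV substitution,
## G1 and G2 alignments share coordinates and a read's base at the SNP is the
## same in both; the dual-genome alignment acts as a mask (a read must map
## over the site in at least one genome to be counted).

#' Counting policy for [count_alleles()]
#'
#' @param min_mapq minimum mapping quality for a read to qualify.
#' @param min_baseq minimum base quality at the SNP for an informative call.
#' @param skip_duplicates drop duplicate-marked reads (SAM flag 0x400).
#' @param skip_secondary drop secondary/supplementary records (0x100/0x800).
#' @return a `counting_policy` list.
#' @export
counting_policy <- function(min_mapq = 20L, min_baseq = 20L,
                            skip_duplicates = TRUE, skip_secondary = TRUE) {
  assert_scalar_number(min_mapq, "min_mapq", lower = 0)
  assert_scalar_number(min_baseq, "min_baseq", lower = 0)
  structure(list(min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 skip_duplicates = isTRUE(skip_duplicates),
                 skip_secondary = isTRUE(skip_secondary)),
            class = "counting_policy")
}

#' Assign one observed base to the G1 allele, the G2 allele, or OTHER
#'
#' The call is `"G1"` if the base equals the reference allele and its quality
#' passes the threshold, `"G2"` for the alternative allele, and `"OTHER"` for
#' a third base, a missing base (e.g. a deletion spanning the site) or a
#' quality failure. Vectorized over reads.
#'
#' @param read_base observed base(s) on the reference strand.
#' @param read_base_quality Phred quality of the base(s).
#' @param snp a single-row [het_snps()] table (or vectors recycled rowwise).
#' @param min_base_quality quality gate.
#' @return character vector over `{"G1", "G2", "OTHER"}`.
#' @export
assign_read_allele <- function(read_base, read_base_quality, snp,
                               min_base_quality = 20L) {
  ref <- snp$ref
  alt <- snp$alt
  ok <- !is.na(read_base) & read_base_quality >= min_base_quality
  out <- rep("OTHER", length(read_base))
  out[ok & read_base == ref] <- "G1"
  out[ok & read_base == alt] <- "G2"
  out
}

## reference-space width consumed by a CIGAR string (M/=/X/D/N)
cigar_ref_width <- function(cigar) {
  simple <- grepl("^\\d+M$", cigar)
  w <- integer(length(cigar))
  w[simple] <- as.integer(sub("M$", "", cigar[simple]))
  if (any(!simple)) {
    w[!simple] <- vapply(cigar[!simple], function(cg) {
      ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
      len <- as.integer(sub("[A-Z=]$", "", ops))
      op <- sub("^\\d+", "", ops)
      sum(len[op %in% c("M", "=", "X", "D", "N")])
    }, integer(1L), USE.NAMES = FALSE)
  }
  w
}

## base and quality observed at reference position `at` for one read;
## returns list(base=..., qual=...) with NA base if the read has no aligned
## base there (deletion/ skipped region)
base_at_general <- function(at, pos, cigar, seq, qual) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  rcur <- pos
  qcur <- 1L
  for (i in seq_along(op)) {
    o <- op[i]
    l <- len[i]
    if (o %in% c("M", "=", "X")) {
      if (at >= rcur && at < rcur + l) {
        qi <- qcur + (at - rcur)
        return(list(base = substr(seq, qi, qi),
                    qual = utf8ToInt(substr(qual, qi, qi)) - 33L))
      }
      rcur <- rcur + l
      qcur <- qcur + l
    } else if (o %in% c("D", "N")) {
      if (at >= rcur && at < rcur + l) return(list(base = NA_character_, qual = 0L))
      rcur <- rcur + l
    } else if (o %in% c("I", "S")) {
      qcur <- qcur + l
    }
  }
  list(base = NA_character_, qual = 0L)
}

normalize_alignments <- function(x) {
  if (is.character(x) && length(x) == 1L) return(read_alignments(x))
  if (is.data.frame(x)) {
    need <- c("qname", "flag", "contig", "pos", "mapq", "cigar", "seq", "qual")
    miss <- setdiff(need, names(x))
    if (length(miss)) stopf("alignment table lacks column(s): %s",
                            paste(miss, collapse = ", "))
    return(x)
  }
  stopf("alignments must be a SAM/BAM path or an alignment data.frame")
}

qualifying_reads <- function(aln, policy) {
  keep <- bitwAnd(aln$flag, 4L) == 0L & aln$mapq >= policy$min_mapq
  if (policy$skip_secondary)
    keep <- keep & bitwAnd(aln$flag, 256L) == 0L & bitwAnd(aln$flag, 2048L) == 0L
  if (policy$skip_duplicates) keep <- keep & bitwAnd(aln$flag, 1024L) == 0L
  aln[keep, , drop = FALSE]
}

#' Count G1/G2 allele support at heterozygous SNPs
#'
#' Reads qualifying in at least one of the two alignments (mapped over the
#' site with mapping quality at or above the policy threshold) vote once per
#' overlapped SNP, by the base they carry at the SNP position. Emits one
#' record per SNP with any coverage; SNPs with no overlapping reads produce
#' no record, which feeds the downstream discard rule.
#'
#' @param alignments_g1 SAM/BAM path or alignment data.frame (reference
#'   genome alignment).
#' @param alignments_g2 optional second alignment (alternative genome); when
#'   `NULL` the single alignment is used alone (`single_genome` mode).
#' @param snps a [het_snps()] table.
#' @param policy a [counting_policy()].
#' @return data.frame with class `allele_counts`: columns `snp_id, contig,
#'   pos, ref, alt, n_g1, n_g2, n_other, n_total_informative`.
#' @export
count_alleles <- function(alignments_g1, alignments_g2 = NULL, snps,
                          policy = counting_policy()) {
  a1 <- normalize_alignments(alignments_g1)
  known <- attr(a1, "contigs")
  q1 <- qualifying_reads(a1, policy)
  if (!is.null(alignments_g2)) {
    a2 <- normalize_alignments(alignments_g2)
    known <- unique(c(known, attr(a2, "contigs")))
    q2 <- qualifying_reads(a2, policy)
    extra <- q2[!(q2$qname %in% q1$qname), , drop = FALSE]
    reads <- rbind(q1[, c("qname", "contig", "pos", "cigar", "seq", "qual")],
                   extra[, c("qname", "contig", "pos", "cigar", "seq", "qual")])
  } else {
    reads <- q1[, c("qname", "contig", "pos", "cigar", "seq", "qual")]
  }
  if (!is.null(known)) {
    bad <- setdiff(unique(snps$contig), known)
    if (length(bad)) stopf("SNP(s) on contig(s) unknown to the alignments: %s",
                           paste(bad, collapse = ", "))
  }
  empty <- data.frame(snp_id = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      n_g1 = integer(), n_g2 = integer(), n_other = integer(),
                      n_total_informative = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("allele_counts", "data.frame")
  if (nrow(reads) == 0L || nrow(snps) == 0L) return(empty)

  out <- list()
  for (ctg in unique(snps$contig)) {
    s <- snps[snps$contig == ctg, , drop = FALSE]
    r <- reads[reads$contig == ctg, , drop = FALSE]
    if (nrow(r) == 0L) next
    rw <- cigar_ref_width(r$cigar)
    ov <- IRanges::findOverlaps(IRanges::IRanges(r$pos, width = rw),
                                IRanges::IRanges(s$pos, width = 1L))
    if (!length(ov)) next
    ri <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    simple <- grepl("^\\d+M$", r$cigar[ri])
    base <- character(length(ri))
    qualv <- integer(length(ri))
    if (any(simple)) {
      off <- s$pos[si[simple]] - r$pos[ri[simple]] + 1L
      base[simple] <- substr(r$seq[ri[simple]], off, off)
      qualv[simple] <- utf8ToInt(paste0(substr(r$qual[ri[simple]], off, off),
                                        collapse = ""))[seq_len(sum(simple))] - 33L
      ## substr on vectors returns per-element strings; concat+utf8ToInt keeps
      ## the per-read order because each extracted quality is one character
    }
    if (any(!simple)) {
      gi <- which(!simple)
      for (j in gi) {
        ba <- base_at_general(s$pos[si[j]], r$pos[ri[j]], r$cigar[ri[j]],
                              r$seq[ri[j]], r$qual[ri[j]])
        base[j] <- if (is.na(ba$base)) NA_character_ else ba$base
        qualv[j] <- ba$qual
      }
    }
    call <- assign_read_allele(base, qualv,
                               list(ref = s$ref[si], alt = s$alt[si]),
                               policy$min_baseq)
    sf <- factor(si, levels = seq_len(nrow(s)))
    n_g1 <- as.integer(table(sf[call == "G1"]))
    n_g2 <- as.integer(table(sf[call == "G2"]))
    n_other <- as.integer(table(sf[call == "OTHER"]))
    covered <- (n_g1 + n_g2 + n_other) > 0L
    out[[ctg]] <- data.frame(
      snp_id = s$snp_id[covered], contig = s$contig[covered],
      pos = s$pos[covered], ref = s$ref[covered], alt = s$alt[covered],
      n_g1 = n_g1[covered], n_g2 = n_g2[covered], n_other = n_other[covered],
      n_total_informative = (n_g1 + n_g2)[covered], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("allele_counts", "data.frame")
  res
}

#' Discard SNPs without informative coverage
#'
#' Implements the rule that sites with no reads assigned to either allele are
#' removed before testing; `min_total` raises the bar to a minimum informative
#' depth.
#'
#' @param records an `allele_counts` table from [count_alleles()].
#' @param min_total minimum `n_g1 + n_g2` to retain a site (>= 1).
#' @return the retained records.
#' @export
discard_uncovered <- function(records, min_total = 1L) {
  assert_scalar_number(min_total, "min_total", lower = 1)
  records[records$n_total_informative >= min_total, , drop = FALSE]
}

#' Write / read allele-count tables
#'
#' @param records an `allele_counts` table.
#' @param path TSV path.
#' @export
write_counts <- function(records, path) write_tsv_file(records, path)

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_tsv_file(path)
  class(df) <- c("allele_counts", "data.frame")
  df
}
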