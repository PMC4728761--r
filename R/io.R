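## File-format boundaries. All external formats go through the standard
## Bioconductor readers (Biostrings, Rsamtools, rtracklayer, vcfR); the only
## hand-rolled writer is the minimal 8-column VCF body (plain text).

#' Construct a table of heterozygous SNPs
#'
#' The unit record of the pipeline: a biallelic heterozygous single-nucleotide
#' site. The reference allele is the G1 allele; the alternative allele is the
#' one substituted into the alternative genome G2.
#'
#' @param snp_id character identifiers (e.g. rsIDs), unique.
#' @param contig contig names.
#' @param pos 1-based positions.
#' @param ref,alt single bases in `A/C/G/T`, `ref != alt` rowwise.
#' @return a `data.frame` with class `het_snps`.
#' @export
het_snps <- function(snp_id, contig, pos, ref, alt) {
  n <- length(snp_id)
  if (n == 0L) {
    df <- data.frame(snp_id = character(), contig = character(),
                     pos = integer(), ref = character(), alt = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("het_snps", "data.frame")
    return(df)
  }
  if (anyDuplicated(snp_id)) stopf("snp_id values must be unique")
  if (!all(is_dna_base(ref)) || !all(is_dna_base(alt)))
    stopf("ref and alt alleles must be single bases in A/C/G/T (SNVs only)")
  if (any(ref == alt)) stopf("ref and alt alleles must differ at every site")
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) stopf("positions must be 1-based positive integers")
  df <- data.frame(snp_id = as.character(snp_id), contig = as.character(contig),
                   pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
  class(df) <- c("het_snps", "data.frame")
  df
}

as_dnastringset <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    return(Biostrings::readDNAStringSet(reference))
  if (is.character(reference)) {
    if (is.null(names(reference))) names(reference) <- paste0("contig", seq_along(reference))
    return(Biostrings::DNAStringSet(reference))
  }
  stopf("reference must be a DNAStringSet, a (named) character vector, or a FASTA path")
}

#' Read and write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#'
#' @param x named character vector or `DNAStringSet`.
#' @param path file path.
#' @return `read_fasta` returns a `DNAStringSet`; `write_fasta` the path.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(as_dnastringset(x), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write simulated reads as FASTQ (Phred+33)
#'
#' Reads flagged as reverse strand are written as sequenced, i.e.
#' reverse-complemented relative to the reference-strand sequence stored in
#' the alignment table.
#'
#' @param alignments alignment table as produced by [simulate_reads()].
#' @param path output path.
#' @export
write_fastq <- function(alignments, path) {
  if (nrow(alignments) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(alignments$seq)
  names(seqs) <- alignments$qname
  quals <- Biostrings::BStringSet(alignments$qual)
  rev <- bitwAnd(alignments$flag, 16L) != 0L
  if (any(rev)) {
    seqs[rev] <- Biostrings::reverseComplement(seqs[rev])
    quals[rev] <- Biostrings::BStringSet(vapply(as.character(quals[rev]), function(q)
      intToUtf8(rev(utf8ToInt(q))), ""))
  }
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write heterozygous SNPs as a minimal VCF
#'
#' Emits a plain-text VCFv4.2 body with the standard 8 columns and 1-based
#' positions.
#'
#' @param snps a [het_snps()] table.
#' @param path output path.
#' @param contig_lengths optional named integer vector for `##contig` header lines.
#' @export
write_het_vcf <- function(snps, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps)) paste(snps$contig, snps$pos, snps$snp_id, snps$ref,
                                snps$alt, ".", ".", ".", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read heterozygous SNVs from a VCF
#'
#' Parses a VCF with [vcfR::read.vcfR()] and keeps biallelic SNVs only
#' (single-base REF and ALT). Records without an ID get `contig:pos`.
#'
#' @param path VCF path.
#' @return a [het_snps()] table.
#' @export
read_het_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(het_snps(character(), character(), integer(), character(), character()))
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES
  fix <- fix[keep, , drop = FALSE]
  id <- fix$ID
  missing_id <- is.na(id) | id == "." | id == ""
  id[missing_id] <- paste0(fix$CHROM[missing_id], ":", fix$POS[missing_id])
  het_snps(id, fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT)
}

#' Write an alignment table as SAM
#'
#' @param alignments data.frame with columns `qname, flag, contig, pos, mapq,
#'   cigar, seq, qual` (reference-strand `seq`, as in SAM).
#' @param contig_lengths named integer vector for the `@SQ` header lines.
#' @param path output path (`.sam`).
#' @export
write_sam <- function(alignments, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  body <- if (nrow(alignments))
    paste(alignments$qname, alignments$flag, alignments$contig, alignments$pos,
          alignments$mapq, alignments$cigar, "*", 0L, 0L,
          alignments$seq, alignments$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM into the internal table
#'
#' SAM input is converted (sorted, indexed) with [Rsamtools::asBam()]; records
#' are then loaded with [Rsamtools::scanBam()]. Unmapped records are dropped.
#' The known contigs of the file header are attached as attribute `contigs`.
#'
#' @param path SAM or BAM path.
#' @return data.frame with columns `qname, flag, contig, pos, mapq, cigar,
#'   seq, qual`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(path, ".bai"))) Rsamtools::indexBam(path)
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                            "mapq", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  df <- data.frame(qname = res$qname, flag = res$flag,
                   contig = as.character(res$rname), pos = res$pos,
                   mapq = res$mapq, cigar = res$cigar,
                   seq = as.character(res$seq), qual = as.character(res$qual),
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$pos) & bitwAnd(df$flag, 4L) == 0L, , drop = FALSE]
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  attr(df, "contigs") <- names(hdr)
  df
}

#' Read and write GWAS catalogs
#'
#' A GWAS catalog is a TSV with columns `gwas_snp_id, trait, contig, position`
#' (1-based). `(gwas_snp_id, trait)` pairs must be unique.
#'
#' @param catalog catalog data.frame (see [generate_gwas_catalog()]).
#' @param path file path.
#' @export
write_gwas_catalog <- function(catalog, path) write_tsv_file(catalog, path)

#' @rdname write_gwas_catalog
#' @export
read_gwas_catalog <- function(path) {
  df <- read_tsv_file(path)
  generate_gwas_catalog(df)
}

#' Read an allele-frequency table
#'
#' Accepts either a TSV with columns `snp_id, af`, or a VCF whose INFO field
#' carries `AF=`.
#'
#' @param path file path.
#' @return data.frame with columns `snp_id, af`.
#' @export
read_af_table <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    af <- as.numeric(sub(".*AF=([0-9.eE+-]+).*", "\\1", fix$INFO))
    return(data.frame(snp_id = fix$ID, af = af, stringsAsFactors = FALSE))
  }
  df <- read_tsv_file(path)
  if (!all(c("snp_id", "af") %in% names(df)))
    stopf("AF table must have columns 'snp_id' and 'af'")
  df[, c("snp_id", "af")]
}

#' Read and write a phased haplotype panel
#'
#' The panel is a 0/1 matrix, one row per haplotype, one named column per SNP,
#' serialized as TSV with a header row.
#'
#' @param panel 0/1 matrix with column names.
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' Read an exclusion track from BED
#'
#' BED's 0-based half-open intervals are converted by
#' [rtracklayer::import()]; padding defaults by label (gap 1 Mb,
#' blacklist 100 bp, cnv 0).
#'
#' @param path BED path.
#' @param label one of `"gap"`, `"blacklist"`, `"cnv"`.
#' @param padding override the label's default padding (bases).
#' @return an [exclusion_track()].
#' @export
read_track_bed <- function(path, label, padding = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  exclusion_track(label, gr, padding = padding)
}

#' Write an exclusion track's raw intervals as BED
#'
#' @param track an [exclusion_track()].
#' @param path output path.
#' @export
write_track_bed <- function(track, path) {
  gr <- track$intervals
  S4Vectors::mcols(gr) <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
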