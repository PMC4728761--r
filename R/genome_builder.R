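## Alternative-genome construction: substitute the sample's alternative
## alleles into the reference (G1) to obtain the personalized genome (G2).
## SNV-only substitution keeps G1 and G2 on the same coordinate system, which
## the per-position allele counting downstream silently relies on.

#' Build the alternative genome G2 from the reference and a SNP set
#'
#' Replaces the reference base with the alternative allele at every
#' heterozygous SNV. Indels and multi-base alleles are rejected: they would
#' shift coordinates and break the shared G1/G2 coordinate system that the
#' allele counter assumes. A SNP whose stated reference allele does not match
#' the reference sequence is a fatal error — it signals a VCF/reference
#' mismatch that would silently corrupt every downstream count.
#'
#' @param reference `DNAStringSet`, named character vector, or FASTA path.
#' @param snps a [het_snps()] table (SNVs only).
#' @return an object of class `GenomeBuild`: list with elements `g1`, `g2`
#'   (both `DNAStringSet`) and `substitutions` (data.frame `snp_id, contig,
#'   pos, ref, alt`).
#' @examples
#' b <- build_alternative_genome(c(chr1 = "AAAA"),
#'                               het_snps("s1", "chr1", 2, "A", "G"))
#' as.character(b$g2) # "AGAA"
#' @export
build_alternative_genome <- function(reference, snps) {
  g1 <- as_dnastringset(reference)
  if (!inherits(snps, "het_snps"))
    snps <- het_snps(snps$snp_id, snps$contig, snps$pos, snps$ref, snps$alt)
  bad_contig <- setdiff(unique(snps$contig), names(g1))
  if (length(bad_contig))
    stopf("SNP contig(s) absent from the reference: %s",
          paste(bad_contig, collapse = ", "))
  g2 <- g1
  if (nrow(snps)) {
    for (ctg in unique(snps$contig)) {
      s <- snps[snps$contig == ctg, , drop = FALSE]
      if (any(s$pos > Biostrings::width(g1[ctg])))
        stopf("SNP position beyond the end of contig %s", ctg)
      seq1 <- g1[[ctg]]
      have <- as.character(Biostrings::extractAt(
        seq1, IRanges::IRanges(s$pos, width = 1L)))
      mism <- have != s$ref
      if (any(mism))
        stopf("reference allele mismatch at %s (%s:%d): VCF says %s, reference has %s",
              s$snp_id[which(mism)[1L]], ctg, s$pos[which(mism)[1L]],
              s$ref[which(mism)[1L]], have[which(mism)[1L]])
      g2[[ctg]] <- Biostrings::replaceLetterAt(seq1, s$pos, s$alt)
    }
  }
  structure(list(g1 = g1, g2 = g2,
                 substitutions = data.frame(
                   snp_id = snps$snp_id, contig = snps$contig, pos = snps$pos,
                   ref = snps$ref, alt = snps$alt, stringsAsFactors = FALSE)),
            class = "GenomeBuild")
}

#' @export
print.GenomeBuild <- function(x, ...) {
  cat("GenomeBuild:", length(x$g1), "contig(s),",
      nrow(x$substitutions), "substitution(s)\n")
  invisible(x)
}

#' List all positions at which G1 and G2 differ
#'
#' Base-by-base comparison of the two genomes, used to validate a build: the
#' differing positions must equal the substitution set exactly, and their
#' count is the Hamming distance between G1 and G2.
#'
#' @param build a `GenomeBuild`.
#' @return data.frame `contig, pos, g1_base, g2_base`, sorted by contig then
#'   position.
#' @export
diff_genomes <- function(build) {
  if (!inherits(build, "GenomeBuild")) stopf("'build' must be a GenomeBuild")
  if (!identical(names(build$g1), names(build$g2)) ||
      !all(Biostrings::width(build$g1) == Biostrings::width(build$g2)))
    stopf("corrupted build: G1 and G2 contig names/lengths differ")
  out <- lapply(names(build$g1), function(ctg) {
    a <- charToRaw(as.character(build$g1[[ctg]]))
    b <- charToRaw(as.character(build$g2[[ctg]]))
    pos <- which(a != b)
    data.frame(contig = rep(ctg, length(pos)), pos = pos,
               g1_base = rawToChar(a[pos], multiple = TRUE),
               g2_base = rawToChar(b[pos], multiple = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a GenomeBuild to disk
#'
#' @param build a `GenomeBuild`.
#' @param fasta_path output FASTA path for G2.
#' @param log_path optional TSV path for the substitution log.
#' @export
write_genome_build <- function(build, fasta_path, log_path = NULL) {
  write_fasta(build$g2, fasta_path)
  if (!is.null(log_path)) write_tsv_file(build$substitutions, log_path)
  invisible(fasta_path)
}
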