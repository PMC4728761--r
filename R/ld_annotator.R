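## Allele-frequency annotation and LD proxy linking: intersect AS-SNPs with a
## population allele-frequency table, then link them to GWAS catalog SNPs via
## linkage disequilibrium computed on a phased haplotype panel
## (r^2 = D^2 / (pA (1-pA) pB (1-pB)), D = pAB - pA pB).

#' Annotate SNPs with population allele frequencies
#'
#' With `require_present` (the default, matching intersect semantics), SNPs
#' absent from the table are dropped; the dropped rows are attached as
#' attribute `"dropped"`. Duplicated table entries with conflicting
#' frequencies are an error; exact duplicates are tolerated.
#'
#' @param snps data.frame with a `snp_id` column.
#' @param af_table data.frame with columns `snp_id, af` (alternative-allele
#'   frequency in `[0, 1]`).
#' @param require_present drop SNPs missing from the table (default `TRUE`).
#' @return `snps` with an `af` column added (and possibly rows dropped);
#'   attribute `"dropped"` holds the removed rows.
#' @export
annotate_af <- function(snps, af_table, require_present = TRUE) {
  if (!all(c("snp_id", "af") %in% names(af_table)))
    stopf("af_table needs columns 'snp_id' and 'af'")
  if (nrow(af_table) && (any(is.na(af_table$af)) ||
                         any(af_table$af < 0 | af_table$af > 1)))
    stopf("allele frequencies must lie in [0, 1]")
  if (anyDuplicated(af_table$snp_id)) {
    per_id <- tapply(af_table$af, af_table$snp_id,
                     function(v) length(unique(v)))
    if (any(per_id > 1))
      stopf("conflicting allele frequencies for: %s",
            paste(names(per_id)[per_id > 1], collapse = ", "))
    af_table <- af_table[!duplicated(af_table$snp_id), , drop = FALSE]
  }
  snps <- as.data.frame(snps)
  snps$af <- af_table$af[match(snps$snp_id, af_table$snp_id)]
  missing <- is.na(snps$af)
  dropped <- snps[FALSE, , drop = FALSE]
  if (require_present && any(missing)) {
    dropped <- snps[missing, , drop = FALSE]
    snps <- snps[!missing, , drop = FALSE]
    rownames(snps) <- NULL
  }
  attr(snps, "dropped") <- dropped
  snps
}

#' Squared allelic correlation (LD r-squared) between two loci
#'
#' Computed from phased 0/1 haplotype vectors as
#' `r^2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB`. Symmetric in
#' its arguments and invariant to relabeling alleles at either locus.
#'
#' @param hap_a,hap_b 0/1 vectors of equal length (>= 2), one entry per
#'   haplotype.
#' @return r-squared in `[0, 1]`.
#' @examples
#' compute_r2(c(1, 1, 0, 0), c(1, 1, 0, 0)) # 1
#' @export
compute_r2 <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b)) stopf("haplotype vectors differ in length")
  if (length(hap_a) < 2L) stopf("need at least 2 haplotypes")
  if (!all(hap_a %in% c(0, 1)) || !all(hap_b %in% c(0, 1)))
    stopf("haplotype vectors must be 0/1")
  pa <- mean(hap_a)
  pb <- mean(hap_b)
  if (pa == 0 || pa == 1 || pb == 0 || pb == 1)
    stopf("monomorphic locus: LD is undefined on this panel")
  pab <- mean(hap_a == 1 & hap_b == 1)
  D <- pab - pa * pb
  ## per-locus variances grouped first so the result is exactly symmetric
  (D * D) / ((pa * (1 - pa)) * (pb * (1 - pb)))
}

#' Link AS-SNPs to GWAS catalog SNPs through LD proxies
#'
#' For every (AS-SNP, catalog entry) pair, computes r-squared on the phased
#' panel and keeps pairs at or above `r2_min` (strictly above with
#' `strict = TRUE`). An AS-SNP identical to a catalog SNP links with
#' r-squared 1 without consulting the panel. Pairs for which either SNP is
#' absent from the panel produce no link; their ids are attached as attribute
#' `"missing_from_panel"` and reported in one consolidated warning unless
#' `quiet`.
#'
#' @param as_snps data.frame with a `snp_id` column (or a character vector of
#'   ids).
#' @param catalog a `gwas_catalog` (see [generate_gwas_catalog()]).
#' @param panel phased 0/1 matrix with SNP-id column names.
#' @param r2_min LD threshold in `[0, 1]`, default 0.8.
#' @param strict require r-squared strictly above the threshold.
#' @param quiet suppress the missing-from-panel warning.
#' @return data.frame `as_snp_id, gwas_snp_id, trait, r2`, sorted by AS-SNP
#'   then decreasing r-squared.
#' @export
find_proxies <- function(as_snps, catalog, panel, r2_min = 0.8,
                         strict = FALSE, quiet = FALSE) {
  assert_scalar_number(r2_min, "r2_min", lower = 0, upper = 1)
  ids <- if (is.data.frame(as_snps)) as_snps$snp_id else as.character(as_snps)
  empty <- data.frame(as_snp_id = character(), gwas_snp_id = character(),
                      trait = character(), r2 = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(ids) || nrow(catalog) == 0L) return(empty)
  have <- colnames(panel)
  missing <- character(0)
  rows <- vector("list", length(ids) * nrow(catalog))
  kk <- 0L
  for (a in ids) {
    for (gi in seq_len(nrow(catalog))) {
      g <- catalog$gwas_snp_id[gi]
      if (a == g) {
        r2 <- 1
      } else if (a %in% have && g %in% have) {
        r2 <- tryCatch(compute_r2(panel[, a], panel[, g]),
                       error = function(e) NA_real_)
        if (is.na(r2)) next  # monomorphic column: unusable panel entry
      } else {
        missing <- c(missing, setdiff(c(a, g), have))
        next
      }
      keep <- if (strict) r2 > r2_min else r2 >= r2_min
      if (keep) {
        kk <- kk + 1L
        rows[[kk]] <- data.frame(as_snp_id = a, gwas_snp_id = g,
                                 trait = catalog$trait[gi], r2 = r2,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (kk) do.call(rbind, rows[seq_len(kk)]) else empty
  if (nrow(links)) {
    links <- links[order(links$as_snp_id, -links$r2), , drop = FALSE]
    rownames(links) <- NULL
  }
  missing <- unique(missing)
  if (length(missing) && !quiet)
    warnf("%d SNP id(s) absent from the haplotype panel (no LD link computed): %s%s",
          length(missing), paste(utils::head(missing, 5L), collapse = ", "),
          if (length(missing) > 5L) ", ..." else "")
  attr(links, "missing_from_panel") <- missing
  links
}
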