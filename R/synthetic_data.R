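## Synthetic-data generator: every input the pipeline consumes — reference
## contig, planted heterozygous SNVs, allelically imbalanced reads, exclusion
## tracks, allele frequencies, GWAS catalog, phased haplotype panel — with a
## ground-truth table, so each downstream stage has an exact oracle.

#' Generate a random reference contig
#'
#' @param length contig length in bases (>= 1).
#' @param seed RNG seed; identical (length, seed) gives identical sequence.
#' @return a character string over A/C/G/T.
#' @export
generate_reference <- function(length, seed) {
  assert_scalar_number(length, "length", lower = 1)
  withr::with_seed(as.integer(seed),
                   paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""))
}

#' Plant heterozygous SNVs on a reference sequence
#'
#' Positions are drawn without replacement, at least `read_length` bases from
#' either contig end (so every simulated read overlapping a site fits on the
#' contig), and at least `min_spacing` bases apart (default one read length,
#' so no read overlaps two sites and per-site read draws stay independent).
#' The reference allele is the reference base at the position; the alternative
#' allele is drawn uniformly from the other three bases.
#'
#' @param reference character string (the contig sequence).
#' @param n number of sites to plant.
#' @param seed RNG seed.
#' @param read_length margin kept free at contig ends (bases).
#' @param min_spacing minimum distance between planted sites (bases).
#' @param contig contig name recorded in the output.
#' @return a [het_snps()] table with strictly increasing positions.
#' @export
plant_het_snps <- function(reference, n, seed, read_length = 50L,
                           min_spacing = read_length, contig = "chrS") {
  L <- nchar(reference)
  if (n == 0L) return(het_snps(character(), character(), integer(),
                               character(), character()))
  lo <- read_length + 1L
  hi <- L - read_length
  if (hi < lo || n > (hi - lo + 1L))
    stopf("cannot place %d SNPs on a %d-base contig with a %d-base end margin",
          n, L, read_length)
  withr::with_seed(as.integer(seed), {
    cand <- sample(lo:hi)
    pos <- integer(0)
    for (p in cand) {
      if (!length(pos) || min(abs(p - pos)) >= min_spacing) {
        pos <- c(pos, p)
        if (length(pos) == n) break
      }
    }
    if (length(pos) < n)
      stopf("cannot place %d SNPs with min spacing %d on a %d-base contig",
            n, min_spacing, L)
    pos <- sort(pos)
    ref <- substring(reference, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "",
                  USE.NAMES = FALSE)
    het_snps(sprintf("snp%05d", seq_len(n)), contig, pos, ref, alt)
  })
}

#' Configuration for the read simulator
#'
#' @param contig_length contig length (bases), must exceed `read_length`.
#' @param n_het_snps number of planted heterozygous sites.
#' @param read_length read length (bases).
#' @param mean_depth mean reads per site (Poisson mean; 0 allowed, gives an
#'   empty run and exercises the zero-coverage discard rule downstream).
#' @param error_rate per-base substitution error probability, in `[0, 0.25)`.
#' @param imbalance named numeric vector, SNP id -> probability that a read
#'   overlapping the site carries the G1 (reference) allele; sites not named
#'   default to 0.5 (no imbalance). Values must be strictly inside (0, 1)
#'   unless `allow_degenerate`.
#' @param seed RNG seed; identical config + seed gives byte-identical outputs.
#' @param contig contig name.
#' @param base_quality Phred quality written for every simulated base.
#' @param allow_degenerate allow imbalance 0 or 1 (validation runs only).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(contig_length = 120000L, n_het_snps = 500L,
                              read_length = 36L, mean_depth = 60,
                              error_rate = 0.001, imbalance = NULL,
                              seed = 1L, contig = "chrS",
                              base_quality = 37L, allow_degenerate = FALSE) {
  assert_scalar_number(contig_length, "contig_length", lower = 1)
  assert_scalar_number(read_length, "read_length", lower = 1)
  if (contig_length <= read_length)
    stopf("contig_length must exceed read_length")
  assert_scalar_number(mean_depth, "mean_depth", lower = 0)
  assert_scalar_number(error_rate, "error_rate", lower = 0, upper = 0.25,
                       open_upper = TRUE)
  assert_scalar_number(seed, "seed")
  if (!is.null(imbalance)) {
    if (is.null(names(imbalance)) || any(names(imbalance) == ""))
      stopf("'imbalance' must be a named vector keyed by snp_id")
    lo_ok <- if (allow_degenerate) all(imbalance >= 0 & imbalance <= 1)
             else all(imbalance > 0 & imbalance < 1)
    if (!lo_ok) stopf("imbalance values must lie strictly in (0, 1)")
  }
  structure(list(contig_length = as.integer(contig_length),
                 n_het_snps = as.integer(n_het_snps),
                 read_length = as.integer(read_length),
                 mean_depth = mean_depth, error_rate = error_rate,
                 imbalance = imbalance, seed = as.integer(seed),
                 contig = contig, base_quality = as.integer(base_quality)),
            class = "simulation_config")
}

## apply per-base substitution errors, uniform over the 3 non-original bases
apply_sequencing_errors <- function(seqs, read_length, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  n <- length(seqs)
  hit <- which(runif(n * read_length) < error_rate)
  if (!length(hit)) return(seqs)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = read_length)
  cur <- match(mat[hit], DNA_BASES)
  off <- sample.int(3L, length(hit), replace = TRUE)
  mat[hit] <- DNA_BASES[((cur - 1L + off) %% 4L) + 1L]
  do.call(paste0, lapply(seq_len(read_length), function(r) mat[r, ]))
}

#' Simulate allelically imbalanced ChIP-seq reads over planted SNPs
#'
#' For each site, a Poisson(`mean_depth`) number of single-end reads is placed
#' uniformly over the windows covering the site. Each read is drawn from the
#' G1 (reference) haplotype with probability `imbalance[snp_id]`, otherwise
#' from the G2 haplotype (all alternative alleles); per-base sequencing errors
#' are applied afterwards. Reads are returned as an alignment table (their
#' placement is known by construction, so no aligner is involved); the truth
#' table records the exact pre-error haplotype of origin per read, aggregated
#' per site.
#'
#' @param config a [simulation_config()].
#' @param reference contig sequence (character string).
#' @param snps a [het_snps()] table (see [plant_het_snps()]).
#' @param fastq_path optional path; if given, reads are also written as FASTQ.
#' @return list with elements:
#'   * `alignments`: data.frame `qname, flag, contig, pos, mapq, cigar, seq,
#'     qual` plus simulation-only columns `origin_g1` (pre-error haplotype)
#'     and `snp_idx`;
#'   * `truth`: data.frame `snp_id, contig, pos, imbalance, n_g1_true,
#'     n_g2_true, n_reads, is_planted_as` (counts are pre-error reads
#'     overlapping each site; `n_g1_true + n_g2_true == n_reads`).
#' @export
simulate_reads <- function(config, reference, snps, fastq_path = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (nchar(reference) != config$contig_length)
    stopf("reference length (%d) disagrees with config contig_length (%d)",
          nchar(reference), config$contig_length)
  imb <- rep(0.5, nrow(snps))
  names(imb) <- snps$snp_id
  if (!is.null(config$imbalance)) {
    unknown <- setdiff(names(config$imbalance), snps$snp_id)
    if (length(unknown))
      stopf("imbalance requested for unknown SNP id(s): %s",
            paste(unknown, collapse = ", "))
    imb[names(config$imbalance)] <- config$imbalance
  }
  rl <- config$read_length
  g2seq <- if (nrow(snps))
    as.character(build_alternative_genome(
      stats::setNames(reference, config$contig), snps)$g2[[1L]])
  else reference

  res <- withr::with_seed(config$seed, {
    depth <- rpois(nrow(snps), config$mean_depth)
    N <- sum(depth)
    if (N == 0L) {
      aln <- data.frame(qname = character(), flag = integer(),
                        contig = character(), pos = integer(),
                        mapq = integer(), cigar = character(),
                        seq = character(), qual = character(),
                        origin_g1 = logical(), snp_idx = integer(),
                        stringsAsFactors = FALSE)
      list(aln = aln, depth = depth, ng1 = integer(nrow(snps)),
           nreads = integer(nrow(snps)))
    } else {
      snp_of <- rep(seq_len(nrow(snps)), depth)
      start <- snps$pos[snp_of] - sample.int(rl, N, replace = TRUE) + 1L
      g1_origin <- runif(N) < imb[snp_of]
      seqs <- character(N)
      if (any(g1_origin))
        seqs[g1_origin] <- substring(reference, start[g1_origin],
                                     start[g1_origin] + rl - 1L)
      if (any(!g1_origin))
        seqs[!g1_origin] <- substring(g2seq, start[!g1_origin],
                                      start[!g1_origin] + rl - 1L)
      ## truth counts: every read overlapping a site votes with its haplotype
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start, width = rl),
        IRanges::IRanges(snps$pos, width = 1L))
      ng1 <- nreads <- integer(nrow(snps))
      tot <- table(factor(S4Vectors::subjectHits(ov), levels = seq_len(nrow(snps))))
      g1t <- table(factor(S4Vectors::subjectHits(ov)[g1_origin[S4Vectors::queryHits(ov)]],
                          levels = seq_len(nrow(snps))))
      nreads <- as.integer(tot)
      ng1 <- as.integer(g1t)
      seqs <- apply_sequencing_errors(seqs, rl, config$error_rate)
      aln <- data.frame(
        qname = sprintf("read%07d", seq_len(N)),
        flag = 16L * rbinom(N, 1L, 0.5),
        contig = config$contig, pos = start, mapq = 60L,
        cigar = paste0(rl, "M"), seq = seqs,
        qual = strrep(intToUtf8(config$base_quality + 33L), rl),
        origin_g1 = g1_origin, snp_idx = snp_of,
        stringsAsFactors = FALSE)
      list(aln = aln, depth = depth, ng1 = ng1, nreads = nreads)
    }
  })
  truth <- data.frame(snp_id = snps$snp_id, contig = snps$contig,
                      pos = snps$pos, imbalance = unname(imb),
                      n_g1_true = res$ng1,
                      n_g2_true = res$nreads - res$ng1,
                      n_reads = res$nreads,
                      is_planted_as = unname(imb) != 0.5,
                      stringsAsFactors = FALSE)
  if (!is.null(fastq_path)) write_fastq(res$aln, fastq_path)
  list(alignments = res$aln, truth = truth)
}

#' Generate exclusion tracks overlapping a fraction of planted SNPs
#'
#' Picks `round(fraction_masked * n)` sites, assigns each to one of the three
#' track labels (gap, blacklist, cnv) uniformly, and places a short raw
#' interval over it. Membership of every SNP in each padded track is
#' recomputed arithmetically from the raw intervals and the paddings and
#' returned as the mask ground truth; because padded intervals can reach
#' neighbouring sites, the realized masked fraction can slightly exceed the
#' requested one.
#'
#' @param snps a [het_snps()] table.
#' @param fraction_masked fraction of sites to cover, in `[0, 1]`.
#' @param seed RNG seed.
#' @param contig_length contig length (intervals are clipped to it).
#' @param paddings named vector of paddings (bases) for `gap`, `blacklist`,
#'   `cnv`; defaults are the production values (1 Mb, 100 bp, 0).
#' @param interval_halfwidth half-width of each raw interval (bases).
#' @return list with `tracks` (named list of [exclusion_track()]) and
#'   `membership` (data.frame `snp_id, in_gap, in_blacklist, in_cnv, masked`).
#' @export
generate_exclusion_tracks <- function(snps, fraction_masked, seed,
                                      contig_length,
                                      paddings = c(gap = 1e6, blacklist = 100,
                                                   cnv = 0),
                                      interval_halfwidth = 60L) {
  assert_scalar_number(fraction_masked, "fraction_masked", lower = 0, upper = 1)
  labels <- c("gap", "blacklist", "cnv")
  stopifnot(all(labels %in% names(paddings)))
  n <- nrow(snps)
  k <- round(n * fraction_masked)
  assign <- withr::with_seed(as.integer(seed), {
    idx <- if (k > 0L) sample.int(n, k) else integer(0)
    lab <- if (k > 0L) sample(labels, k, replace = TRUE) else character(0)
    list(idx = idx, lab = lab)
  })
  tracks <- lapply(labels, function(lb) {
    sel <- assign$idx[assign$lab == lb]
    if (length(sel)) {
      st <- pmax(1L, snps$pos[sel] - interval_halfwidth)
      en <- pmin(as.integer(contig_length), snps$pos[sel] + interval_halfwidth)
      gr <- GenomicRanges::GRanges(snps$contig[sel], IRanges::IRanges(st, en))
    } else {
      gr <- GenomicRanges::GRanges()
    }
    exclusion_track(lb, gr, padding = unname(paddings[lb]))
  })
  names(tracks) <- labels
  ## membership truth by direct arithmetic on raw intervals + padding
  member <- sapply(labels, function(lb) {
    tr <- tracks[[lb]]
    if (!length(tr$intervals)) return(rep(FALSE, n))
    st <- GenomicRanges::start(tr$intervals) - tr$padding
    en <- GenomicRanges::end(tr$intervals) + tr$padding
    ctg <- as.character(GenomicRanges::seqnames(tr$intervals))
    vapply(seq_len(n), function(i)
      any(ctg == snps$contig[i] & st <= snps$pos[i] & snps$pos[i] <= en),
      logical(1L))
  })
  member <- matrix(member, nrow = n,
                   dimnames = list(NULL, paste0("in_", labels)))
  membership <- data.frame(snp_id = snps$snp_id, member,
                           masked = rowSums(member) > 0,
                           stringsAsFactors = FALSE)
  list(tracks = tracks, membership = membership)
}

#' Generate a phased haplotype panel with controlled pairwise LD
#'
#' The index SNP's allele column is Bernoulli(`maf`). Each partner column
#' copies the index allele with probability `sqrt(target_r2)` and draws a
#' fresh Bernoulli(`maf`) allele otherwise, which makes the expected
#' correlation `sqrt(target_r2)` and hence the expected r-squared equal to
#' `target_r2`; the realized r-squared converges to the target as the panel
#' grows. The realized value (computed with [compute_r2()]) is reported per
#' partner.
#'
#' @param index_snp index SNP id (character) or a single-row [het_snps()].
#' @param partners named numeric vector `snp_id -> target_r2` (each in
#'   `[0, 1]`), or a data.frame with columns `snp_id, target_r2`.
#' @param n_haplotypes number of phased haplotypes (even, >= 20).
#' @param seed RNG seed.
#' @param maf allele frequency used for all columns.
#' @return list with `panel` (0/1 matrix, columns = index then partners) and
#'   `realized` (data.frame `snp_id, target_r2, realized_r2`).
#' @export
generate_haplotype_panel <- function(index_snp, partners, n_haplotypes, seed,
                                     maf = 0.5) {
  index_id <- if (is.data.frame(index_snp)) index_snp$snp_id[1L] else index_snp
  if (is.data.frame(partners))
    partners <- stats::setNames(partners$target_r2, partners$snp_id)
  if (any(partners < 0 | partners > 1)) stopf("target_r2 values must be in [0, 1]")
  if (n_haplotypes < 20L || n_haplotypes %% 2L != 0L)
    stopf("n_haplotypes must be even and at least 20")
  withr::with_seed(as.integer(seed), {
    draw_poly <- function() {
      for (i in 1:1000) {
        x <- rbinom(n_haplotypes, 1L, maf)
        if (var(x) > 0) return(x)
      }
      stopf("could not draw a polymorphic column (maf too extreme?)")
    }
    x <- draw_poly()
    cols <- lapply(partners, function(r2t) {
      if (r2t == 1) return(x)
      cc <- sqrt(r2t)
      for (i in 1:1000) {
        y <- ifelse(runif(n_haplotypes) < cc, x, rbinom(n_haplotypes, 1L, maf))
        if (var(y) > 0) return(y)
      }
      stopf("could not draw a polymorphic partner column")
    })
    panel <- cbind(x, do.call(cbind, cols))
    colnames(panel) <- c(index_id, names(partners))
    realized <- vapply(seq_along(partners), function(j)
      compute_r2(x, panel[, j + 1L]), numeric(1L))
    list(panel = panel,
         realized = data.frame(snp_id = names(partners),
                               target_r2 = unname(partners),
                               realized_r2 = realized,
                               stringsAsFactors = FALSE))
  })
}

#' Construct (and validate) a GWAS catalog
#'
#' @param entries data.frame with columns `gwas_snp_id, trait, contig,
#'   position`; `(gwas_snp_id, trait)` pairs must be unique.
#' @return the validated catalog data.frame, class `gwas_catalog`.
#' @export
generate_gwas_catalog <- function(entries) {
  required <- c("gwas_snp_id", "trait", "contig", "position")
  if (nrow(entries) == 0L && !all(required %in% names(entries))) {
    entries <- data.frame(gwas_snp_id = character(), trait = character(),
                          contig = character(), position = integer(),
                          stringsAsFactors = FALSE)
  }
  if (!all(required %in% names(entries)))
    stopf("catalog needs columns: %s", paste(required, collapse = ", "))
  if (anyDuplicated(entries[, c("gwas_snp_id", "trait")]))
    stopf("duplicate (gwas_snp_id, trait) rows in the catalog")
  entries <- entries[, required]
  entries$position <- as.integer(entries$position)
  class(entries) <- c("gwas_catalog", "data.frame")
  entries
}

#' The GALNT2-locus GWAS catalog used in the worked example
#'
#' The four GWAS lead SNPs reported in high LD with the AS-SNP rs4846913 in
#' the first intron of GALNT2 (chr1), with their associated plasma-lipid
#' traits: rs2144300 and rs4846914 (HDL-C, TG), rs10489615 (HDL-C) and
#' rs10127775 (metabolite levels). Positions are illustrative placeholders
#' near the locus (the LD proxy logic uses the haplotype panel, not
#' coordinates).
#'
#' @return a `gwas_catalog` with 4 rows.
#' @export
galnt2_gwas_catalog <- function() {
  generate_gwas_catalog(data.frame(
    gwas_snp_id = c("rs2144300", "rs4846914", "rs10489615", "rs10127775"),
    trait = c("HDL-C, TG", "HDL-C, TG", "HDL-C", "metabolite levels"),
    contig = "chr1",
    position = c(230295000L, 230295500L, 230296000L, 230296500L),
    stringsAsFactors = FALSE))
}
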