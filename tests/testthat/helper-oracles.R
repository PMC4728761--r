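# Independent oracles used across the suite. Each recomputes the quantity
# under test from its definition, avoiding the package's code paths.

# Exact two-sided binomial p by direct enumeration of all n+1 outcomes.
oracle_binom_p <- function(k, n, p0 = 0.5) {
  d <- dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

# BH step-up from the definition: q_i = min over ranks j >= rank(i) of
# p_(j) * m / j, capped at 1, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  quot <- p[o] * m / seq_len(m)
  qs <- rev(cummin(rev(quot)))
  q <- numeric(m)
  q[o] <- pmin(1, qs)
  q
}

# Literal O(m^2) double-loop version of the same definition (small m only).
oracle_bh_slow <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(j)
    min(1, min(ps[j:m] * m / (j:m))), numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}

# LD r^2 by counting the four haplotype classes.
oracle_r2 <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1)
  pA <- sum(a == 1) / n
  pB <- sum(b == 1) / n
  D <- n11 / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Brute-force point-in-padded-interval scan over raw track intervals
# (1-based SNP positions against GRanges raw intervals +/- padding).
oracle_masked <- function(snps, tracks) {
  vapply(seq_len(nrow(snps)), function(i) {
    any(vapply(tracks, function(tr) {
      if (!length(tr$intervals)) return(FALSE)
      st <- GenomicRanges::start(tr$intervals) - tr$padding
      en <- GenomicRanges::end(tr$intervals) + tr$padding
      ctg <- as.character(GenomicRanges::seqnames(tr$intervals))
      any(ctg == snps$contig[i] & st <= snps$pos[i] & snps$pos[i] <= en)
    }, logical(1)))
  }, logical(1))
}

# Tiny deterministic simulated dataset shared by several tests.
tiny_sim <- function(seed = 3L, n_sites = 40L, mean_depth = 25,
                     error_rate = 0, contig_length = 12000L,
                     read_length = 30L, imbalance = NULL) {
  ref <- generate_reference(contig_length, seed)
  snps <- plant_het_snps(ref, n_sites, seed + 1L, read_length = read_length)
  cfg <- simulation_config(contig_length = contig_length,
                           n_het_snps = n_sites, read_length = read_length,
                           mean_depth = mean_depth, error_rate = error_rate,
                           imbalance = imbalance, seed = seed + 2L)
  sim <- simulate_reads(cfg, ref, snps)
  list(ref = ref, snps = snps, cfg = cfg, aln = sim$alignments,
       truth = sim$truth)
}
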