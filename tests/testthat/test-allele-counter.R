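test_that("assign_read_allele follows the base/quality definition", {
  snp <- het_snps("s", "chr1", 10, "C", "A")
  expect_equal(assign_read_allele("C", 30, snp, 20), "G1")
  expect_equal(assign_read_allele("A", 30, snp, 20), "G2")
  expect_equal(assign_read_allele("G", 30, snp, 20), "OTHER")  # third allele
  expect_equal(assign_read_allele("A", 10, snp, 20), "OTHER")  # quality gate
  expect_equal(assign_read_allele(NA_character_, 30, snp, 20), "OTHER")
  expect_equal(assign_read_allele(c("C", "A", "T"), c(30, 30, 30), snp, 20),
               c("G1", "G2", "OTHER"))
})

test_that("counts equal the simulator truth exactly when error_rate = 0", {
  sim <- tiny_sim(seed = 70, n_sites = 50, mean_depth = 20, error_rate = 0)
  rec <- count_alleles(sim$aln, snps = sim$snps)
  tr <- sim$truth
  covered <- tr[tr$n_reads > 0, ]
  expect_setequal(rec$snp_id, covered$snp_id)
  m <- match(rec$snp_id, covered$snp_id)
  expect_equal(rec$n_g1, covered$n_g1_true[m])
  expect_equal(rec$n_g2, covered$n_g2_true[m])
  expect_equal(rec$n_other, rep(0L, nrow(rec)))
  expect_equal(rec$n_total_informative, rec$n_g1 + rec$n_g2)
  # determinism
  expect_identical(rec, count_alleles(sim$aln, snps = sim$snps))
})

test_that("zero-coverage SNPs yield no record and feed the discard rule", {
  sim <- tiny_sim(seed = 71, n_sites = 30, mean_depth = 1.5, error_rate = 0)
  rec <- count_alleles(sim$aln, snps = sim$snps)
  uncovered <- sim$truth$snp_id[sim$truth$n_reads == 0]
  expect_gt(length(uncovered), 0)  # depth 1.5 leaves some sites empty
  expect_false(any(rec$snp_id %in% uncovered))

  kept <- discard_uncovered(rec, min_total = 1)
  expect_true(all(kept$n_total_informative >= 1))
  r <- rec[1, ]
  r$n_g1 <- 1L; r$n_g2 <- 0L; r$n_total_informative <- 1L
  expect_equal(nrow(discard_uncovered(r, 1)), 1)   # (1,0) retained at 1
  r$n_g1 <- 0L; r$n_total_informative <- 0L
  expect_equal(nrow(discard_uncovered(r, 1)), 0)   # (0,0) removed
  expect_error(discard_uncovered(rec, 0))
})

test_that("strand flags do not alter counts", {
  sim <- tiny_sim(seed = 72, n_sites = 25, mean_depth = 15, error_rate = 0)
  flipped <- sim$aln
  flipped$flag <- bitwXor(flipped$flag, 16L)
  expect_equal(count_alleles(sim$aln, snps = sim$snps)[, -(1:5)],
               count_alleles(flipped, snps = sim$snps)[, -(1:5)])
})

test_that("SAM/BAM file input matches in-memory counting", {
  sim <- tiny_sim(seed = 73, n_sites = 20, mean_depth = 12, error_rate = 0)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$aln, c(chrS = sim$cfg$contig_length), sam)
  from_file <- count_alleles(sam, snps = sim$snps)
  in_mem <- count_alleles(sim$aln, snps = sim$snps)
  expect_equal(from_file[order(from_file$snp_id), ],
               in_mem[order(in_mem$snp_id), ], ignore_attr = TRUE)
  # a SNP on a contig unknown to the file header is an error
  bad <- het_snps("x", "chrZ", 5, "A", "C")
  expect_error(count_alleles(sam, snps = bad), "unknown")
})

test_that("dual-genome mode counts reads qualifying in either alignment once", {
  snps <- het_snps("s", "chrS", 100, "A", "C")
  mk <- function(qname, mapq, base) data.frame(
    qname = qname, flag = 0L, contig = "chrS", pos = 96L, mapq = mapq,
    cigar = "10M", seq = paste0("GGGG", base, "GGGGG"),
    qual = strrep("I", 10), stringsAsFactors = FALSE)
  g1 <- rbind(mk("r1", 60, "A"), mk("r2", 0, "C"), mk("r3", 0, "C"))
  g2 <- rbind(mk("r1", 60, "A"), mk("r2", 60, "C"), mk("r3", 0, "C"))
  rec <- count_alleles(g1, g2, snps)
  # r1 qualifies in both (counted once), r2 only in G2, r3 in neither
  expect_equal(rec$n_g1, 1L)
  expect_equal(rec$n_g2, 1L)
})

test_that("duplicate/secondary records and low base quality are excluded", {
  snps <- het_snps("s", "chrS", 100, "A", "C")
  base_read <- data.frame(qname = "r", flag = 0L, contig = "chrS", pos = 96L,
                          mapq = 60L, cigar = "10M",
                          seq = paste0("GGGG", "A", "GGGGG"),
                          qual = strrep("I", 10), stringsAsFactors = FALSE)
  dupe <- transform(base_read, qname = "d", flag = 1024L)
  secondary <- transform(base_read, qname = "s2", flag = 256L)
  lowq <- transform(base_read, qname = "lq",
                    qual = paste0(strrep("I", 4), "#", strrep("I", 5)))
  rec <- count_alleles(rbind(base_read, dupe, secondary, lowq), snps = snps)
  expect_equal(rec$n_g1, 1L)     # only the primary, good-quality read
  expect_equal(rec$n_other, 1L)  # low-baseq observation
})

test_that("soft clips and deletions are walked correctly", {
  # read at pos 10, CIGAR 3S5M2D5M: covers ref 10-14 and 17-21, deletion 15-16
  snps <- het_snps(c("a", "b", "c"), "chrS", c(12, 15, 17), rep("A", 3),
                   rep("C", 3))
  seqchars <- c("T", "T", "T",  "G", "G", "A", "G", "G",  "C", "G", "G", "G", "G")
  aln <- data.frame(qname = "r", flag = 0L, contig = "chrS", pos = 10L,
                    mapq = 60L, cigar = "3S5M2D5M",
                    seq = paste(seqchars, collapse = ""),
                    qual = strrep("I", 13), stringsAsFactors = FALSE)
  rec <- count_alleles(aln, snps = snps)
  rec <- rec[order(rec$snp_id), ]
  expect_equal(rec$snp_id, c("a", "b", "c"))
  expect_equal(rec$n_g1, c(1L, 0L, 0L))      # ref allele observed at 12
  expect_equal(rec$n_g2, c(0L, 0L, 1L))      # alt allele observed at 17
  expect_equal(rec$n_other, c(0L, 1L, 0L))   # deletion spans 15
})
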