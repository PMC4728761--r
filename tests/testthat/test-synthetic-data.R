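test_that("generate_reference honours length, alphabet and determinism", {
  s <- generate_reference(10, seed = 1)
  expect_equal(nchar(s), 10)
  expect_true(all(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T")))
  expect_equal(nchar(generate_reference(1, seed = 7)), 1)
  expect_identical(generate_reference(500, seed = 5),
                   generate_reference(500, seed = 5))
  expect_error(generate_reference(0, seed = 1))
})

test_that("plant_het_snps plants consistent, collision-free, ordered sites", {
  ref <- strrep("ACGT", 25)
  expect_equal(nrow(plant_het_snps(ref, 0, seed = 1)), 0)
  long_ref <- generate_reference(60000, seed = 2)
  snps <- plant_het_snps(long_ref, 1000, seed = 3, read_length = 20,
                         min_spacing = 1)
  expect_equal(nrow(snps), 1000)
  expect_equal(anyDuplicated(snps$pos), 0)          # zero collisions
  expect_true(all(diff(snps$pos) > 0))              # strictly increasing
  expect_identical(snps$ref, substring(long_ref, snps$pos, snps$pos))
  expect_true(all(snps$alt != snps$ref))
  expect_true(all(snps$pos > 20 & snps$pos <= 60000 - 20))
  expect_error(plant_het_snps("ACGTACGT", 100, seed = 1, read_length = 2))
})

test_that("planted sites respect the minimum spacing", {
  ref <- generate_reference(20000, seed = 9)
  snps <- plant_het_snps(ref, 100, seed = 4, read_length = 36)
  expect_true(all(diff(snps$pos) >= 36))
})

test_that("simulate_reads: empty, degenerate and conservation contracts", {
  ref <- generate_reference(5000, seed = 1)
  snps <- plant_het_snps(ref, 10, seed = 2, read_length = 30)

  cfg0 <- simulation_config(contig_length = 5000, n_het_snps = 10,
                            read_length = 30, mean_depth = 0,
                            error_rate = 0, seed = 5)
  sim0 <- simulate_reads(cfg0, ref, snps)
  expect_equal(nrow(sim0$alignments), 0)
  expect_true(all(sim0$truth$n_g1_true == 0 & sim0$truth$n_g2_true == 0))
  fq <- tempfile(fileext = ".fastq")
  simulate_reads(cfg0, ref, snps, fastq_path = fq)
  expect_equal(file.size(fq), 0)

  # degenerate imbalance 1: every overlapping read carries the ref allele
  imb1 <- stats::setNames(rep(1, 10), snps$snp_id)
  cfg1 <- simulation_config(contig_length = 5000, n_het_snps = 10,
                            read_length = 30, mean_depth = 20,
                            error_rate = 0, imbalance = imb1, seed = 6,
                            allow_degenerate = TRUE)
  sim1 <- simulate_reads(cfg1, ref, snps)
  expect_true(all(sim1$alignments$origin_g1))
  expect_true(all(sim1$truth$n_g2_true == 0))
  # conservation: counts sum to reads overlapping each site
  expect_equal(sim1$truth$n_g1_true + sim1$truth$n_g2_true, sim1$truth$n_reads)

  # imbalance outside (0,1) rejected unless degenerate mode
  expect_error(simulation_config(imbalance = stats::setNames(1, "snp00001")),
               "strictly")
  # unknown SNP id rejected
  cfg_bad <- simulation_config(contig_length = 5000, n_het_snps = 10,
                               read_length = 30, mean_depth = 5,
                               imbalance = c(nosuch = 0.7), seed = 1)
  expect_error(simulate_reads(cfg_bad, ref, snps), "unknown SNP id")
})

test_that("simulate_reads is calibrated: allele ratio matches the imbalance", {
  ref <- generate_reference(4000, seed = 11)
  snps <- plant_het_snps(ref, 3, seed = 12, read_length = 30)
  imb <- stats::setNames(c(0.5, 0.3, 0.8), snps$snp_id)
  cfg <- simulation_config(contig_length = 4000, n_het_snps = 3,
                           read_length = 30, mean_depth = 10000,
                           error_rate = 0, imbalance = imb, seed = 13)
  sim <- simulate_reads(cfg, ref, snps)
  tr <- sim$truth
  ratio <- tr$n_g1_true / tr$n_reads
  se <- sqrt(tr$imbalance * (1 - tr$imbalance) / tr$n_reads)
  expect_true(all(abs(ratio - tr$imbalance) <= 3 * se))
  expect_identical(tr$is_planted_as, tr$imbalance != 0.5)
})

test_that("simulator output is byte-identical for identical config and seed", {
  ref <- generate_reference(4000, seed = 21)
  snps <- plant_het_snps(ref, 8, seed = 22, read_length = 30)
  cfg <- simulation_config(contig_length = 4000, n_het_snps = 8,
                           read_length = 30, mean_depth = 15,
                           error_rate = 0.01, seed = 23)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  s1 <- simulate_reads(cfg, ref, snps, fastq_path = f1)
  s2 <- simulate_reads(cfg, ref, snps, fastq_path = f2)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("exclusion-track generation matches an independent membership scan", {
  ref <- generate_reference(30000, seed = 31)
  snps <- plant_het_snps(ref, 100, seed = 32, read_length = 25)

  tr0 <- generate_exclusion_tracks(snps, 0, seed = 33, contig_length = 30000)
  expect_true(all(vapply(tr0$tracks, function(t) length(t$intervals) == 0,
                         logical(1))))
  expect_false(any(tr0$membership$masked))

  tr1 <- generate_exclusion_tracks(snps, 1, seed = 34, contig_length = 30000,
                                   paddings = c(gap = 50, blacklist = 10, cnv = 0))
  expect_true(all(tr1$membership$masked))

  tr <- generate_exclusion_tracks(snps, 0.3, seed = 35, contig_length = 30000,
                                  paddings = c(gap = 40, blacklist = 10, cnv = 0),
                                  interval_halfwidth = 5)
  expect_identical(tr$membership$masked, oracle_masked(snps, tr$tracks))
  expect_gte(mean(tr$membership$masked), 0.3)  # padding can reach neighbours
})

test_that("haplotype panel realizes its target r2", {
  p1 <- generate_haplotype_panel("idx", c(prt = 1), 100, seed = 41)
  expect_identical(p1$panel[, "prt"], p1$panel[, "idx"])
  expect_equal(p1$realized$realized_r2, 1)

  p0 <- generate_haplotype_panel("idx", c(prt = 0), 10000, seed = 42)
  expect_lt(p0$realized$realized_r2, 0.01)

  p9 <- generate_haplotype_panel("idx", c(prt = 0.9), 10000, seed = 43)
  expect_lt(abs(p9$realized$realized_r2 - 0.9), 0.05)

  # recorded realized r2 equals what the LD module computes on the panel
  expect_equal(compute_r2(p9$panel[, "idx"], p9$panel[, "prt"]),
               p9$realized$realized_r2, tolerance = 1e-12)

  expect_error(generate_haplotype_panel("idx", c(prt = 0.5), 10, seed = 1))
  expect_error(generate_haplotype_panel("idx", c(prt = 0.5), 21, seed = 1))
  expect_error(generate_haplotype_panel("idx", c(prt = 1.2), 100, seed = 1))
})

test_that("GWAS catalog construction validates and round-trips", {
  empty <- generate_gwas_catalog(data.frame())
  expect_equal(nrow(empty), 0)

  catg <- galnt2_gwas_catalog()
  expect_equal(nrow(catg), 4)
  expect_setequal(catg$gwas_snp_id,
                  c("rs2144300", "rs4846914", "rs10489615", "rs10127775"))

  dup <- rbind(catg, catg[1, ])
  expect_error(generate_gwas_catalog(dup), "duplicate")

  path <- tempfile(fileext = ".tsv")
  write_gwas_catalog(catg, path)
  back <- read_gwas_catalog(path)
  expect_equal(as.data.frame(back), as.data.frame(catg))
})
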