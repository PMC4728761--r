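test_that("AF annotation intersects, drops and validates", {
  snps <- data.frame(snp_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  af <- data.frame(snp_id = c("a", "c"), af = c(0.37, 0.8),
                   stringsAsFactors = FALSE)
  ann <- annotate_af(snps, af)
  expect_equal(ann$snp_id, c("a", "c"))
  expect_equal(ann$af, c(0.37, 0.8))
  expect_equal(attr(ann, "dropped")$snp_id, "b")

  keep <- annotate_af(snps, af, require_present = FALSE)
  expect_equal(nrow(keep), 3)
  expect_true(is.na(keep$af[keep$snp_id == "b"]))

  expect_error(annotate_af(snps, data.frame(snp_id = c("a", "a"),
                                            af = c(0.3, 0.4))), "conflicting")
  # exact duplicates tolerated
  ok <- annotate_af(snps, data.frame(snp_id = c("a", "a", "c"),
                                     af = c(0.3, 0.3, 0.8)))
  expect_equal(ok$af, c(0.3, 0.8))
  expect_error(annotate_af(snps, data.frame(snp_id = "a", af = 1.2)))
})

test_that("AF intersection scales: 44 of 50 present leaves 44", {
  snps <- data.frame(snp_id = sprintf("s%02d", 1:50), stringsAsFactors = FALSE)
  af <- data.frame(snp_id = sprintf("s%02d", 1:44), af = runif(44))
  ann <- annotate_af(snps, af)
  expect_equal(nrow(ann), 44)
  expect_equal(nrow(attr(ann, "dropped")), 6)
})

test_that("r2 matches its definition, is symmetric and relabel-invariant", {
  a <- c(rep(1, 50), rep(0, 50))
  expect_equal(compute_r2(a, a), 1)
  expect_equal(compute_r2(a, 1 - a), 1)        # complement: |D| unchanged
  # haplotype counts AB=40, Ab=10, aB=10, ab=40 -> D = 0.15, r2 = 0.36
  b <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(compute_r2(a, b), 0.36, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:200) {
    n <- sample(seq(10, 80, by = 2), 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (var(x) == 0 || var(y) == 0) next
    r2 <- compute_r2(x, y)
    expect_equal(r2, oracle_r2(x, y), tolerance = 1e-12)
    expect_identical(r2, compute_r2(y, x))               # symmetry
    expect_equal(compute_r2(1 - x, y), r2, tolerance = 1e-12)
    expect_equal(r2, suppressWarnings(stats::cor(x, y))^2, tolerance = 1e-12)
    expect_true(r2 >= 0 && r2 <= 1 + 1e-12)
  }
  expect_error(compute_r2(c(1, 1, 1), c(0, 1, 0)), "monomorphic")
  expect_error(compute_r2(c(1, 0), c(0, 1, 1)), "length")
  expect_error(compute_r2(c(1, 2), c(0, 1)), "0/1")
})

test_that("proxy search links by panel LD with threshold semantics", {
  catg <- galnt2_gwas_catalog()
  hp <- generate_haplotype_panel("rs4846913",
                                 stats::setNames(rep(0.95, 4),
                                                 catg$gwas_snp_id),
                                 1000, seed = 101)
  links <- find_proxies("rs4846913", catg, hp$panel, r2_min = 0.8)
  expect_equal(nrow(links), 4)
  expect_true(all(links$r2 >= 0.8))
  expect_true(all(c("HDL-C", "TG") %in%
                    unlist(strsplit(links$trait, ", "))))
  expect_true("metabolite levels" %in% links$trait)
  # sorted by AS-SNP then descending r2
  expect_true(all(diff(links$r2) <= 0))

  # empty catalog -> no links
  expect_equal(nrow(find_proxies("rs4846913",
                                 generate_gwas_catalog(data.frame()),
                                 hp$panel)), 0)

  # a realized r2 ~ 0.5 partner is excluded at 0.8
  hp2 <- generate_haplotype_panel("idx", c(gw = 0.5), 2000, seed = 102)
  cat2 <- generate_gwas_catalog(data.frame(gwas_snp_id = "gw", trait = "t",
                                           contig = "c1", position = 1L))
  expect_equal(nrow(find_proxies("idx", cat2, hp2$panel, r2_min = 0.8)), 0)
  # and included once the threshold drops below the realized value
  r2v <- compute_r2(hp2$panel[, "idx"], hp2$panel[, "gw"])
  expect_equal(nrow(find_proxies("idx", cat2, hp2$panel, r2_min = r2v)), 1)
  expect_equal(nrow(find_proxies("idx", cat2, hp2$panel, r2_min = r2v,
                                 strict = TRUE)), 0)

  # self-link without a panel column; missing ids raise one warning
  cat3 <- generate_gwas_catalog(data.frame(gwas_snp_id = "idx", trait = "t",
                                           contig = "c1", position = 1L))
  self <- find_proxies("idx", cat3, hp2$panel[, "gw", drop = FALSE])
  expect_equal(self$r2, 1)
  expect_warning(find_proxies("absent", cat2, hp2$panel), "absent from")

  # monotone filtering: raising r2_min never adds links
  l0 <- find_proxies("idx", cat2, hp2$panel, r2_min = 0)
  expect_true(nrow(find_proxies("idx", cat2, hp2$panel, r2_min = 0.9)) <=
                nrow(l0))
  expect_equal(nrow(l0), 1)  # every polymorphic pairing at r2_min = 0
})
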