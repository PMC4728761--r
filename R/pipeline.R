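## End-to-end orchestration of the discovery pipeline:
## count -> discard -> binomial test -> FDR selection -> AF intersection ->
## region exclusion -> LD proxy linking, with telescoping stage accounting.
## Exclusion filters run after selection (they prune the selected AS-SNPs;
## reordering them before the test would change the multiple-testing
## universe); a flag allows pre-test filtering for sensitivity analysis.

#' Assemble a pipeline configuration
#'
#' Every input can be an in-memory object (the containers produced by the
#' readers and the synthetic generator) or a file path (FASTA / VCF / SAM /
#' BAM / BED / TSV), resolved at run time by the package readers.
#' Alternatively, `simulate` may hold a list of [simulate_study()] arguments;
#' the study is then generated from `seed` and its truth tables are attached
#' to the run report.
#'
#' @param snps heterozygous SNPs ([het_snps()] table or VCF path).
#' @param alignments_g1,alignments_g2 alignments against the reference and
#'   the alternative genome (tables or SAM/BAM paths); `alignments_g2` may be
#'   `NULL` for single-genome counting.
#' @param reference optional reference (used only to rebuild/validate G2).
#' @param tracks list of [exclusion_track()] objects, or a named list/vector
#'   of BED paths (`gap`, `blacklist`, `cnv`); `NULL` skips the stage.
#' @param af_table allele-frequency table (data.frame or TSV/VCF path);
#'   `NULL` skips the stage.
#' @param gwas_catalog GWAS catalog (data.frame or TSV path).
#' @param panel phased haplotype panel (0/1 matrix or TSV path). Required
#'   when a catalog is given.
#' @param simulate optional list of [simulate_study()] arguments.
#' @param alpha selection threshold on the BH q-value, in `(0, 1]`.
#' @param r2_min LD proxy threshold, in `[0, 1]`.
#' @param min_mapq,min_baseq counting quality gates (Phred).
#' @param min_total minimum informative reads to keep a site.
#' @param select_on `"q"` (select on adjusted values; default) or `"p"`.
#' @param strict_r2 require r-squared strictly above `r2_min`.
#' @param require_af drop SNPs absent from the AF table (intersect semantics).
#' @param filter_before_test run the region filters before testing instead of
#'   after selection (sensitivity analysis only).
#' @param seed master seed for all randomness of the run.
#' @param out_dir optional output directory for the per-stage TSVs, the final
#'   report and the run metadata.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(snps = NULL, alignments_g1 = NULL,
                            alignments_g2 = NULL, reference = NULL,
                            tracks = NULL, af_table = NULL,
                            gwas_catalog = NULL, panel = NULL,
                            simulate = NULL,
                            alpha = 0.05, r2_min = 0.8, min_mapq = 20L,
                            min_baseq = 20L, min_total = 1L,
                            select_on = "q", strict_r2 = FALSE,
                            require_af = TRUE, filter_before_test = FALSE,
                            seed = 1L, out_dir = NULL) {
  structure(list(snps = snps, alignments_g1 = alignments_g1,
                 alignments_g2 = alignments_g2, reference = reference,
                 tracks = tracks, af_table = af_table,
                 gwas_catalog = gwas_catalog, panel = panel,
                 simulate = simulate, alpha = alpha, r2_min = r2_min,
                 min_mapq = min_mapq, min_baseq = min_baseq,
                 min_total = min_total, select_on = select_on,
                 strict_r2 = strict_r2, require_af = require_af,
                 filter_before_test = filter_before_test,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks threshold ranges and that every path-valued input resolves;
#' problems are returned as a character vector (empty when the configuration
#' is valid), not raised.
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  chk_num <- function(x, name, lower, upper, open_lower = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
      (if (open_lower) x > lower else x >= lower) && x <= upper
    if (!ok) problems <<- c(problems,
                            sprintf("'%s' must be in %s%g, %g]", name,
                                    if (open_lower) "(" else "[", lower, upper))
  }
  chk_num(config$alpha, "alpha", 0, 1, open_lower = TRUE)
  chk_num(config$r2_min, "r2_min", 0, 1)
  chk_num(config$min_total, "min_total", 1, Inf)
  chk_path <- function(x, name) {
    if (is.character(x) && length(x) == 1L && !file.exists(x))
      problems <<- c(problems, sprintf("'%s' path does not resolve: %s", name, x))
  }
  for (nm in c("snps", "alignments_g1", "alignments_g2", "reference",
               "af_table", "gwas_catalog", "panel"))
    chk_path(config[[nm]], nm)
  if (is.list(config$tracks) || is.character(config$tracks)) {
    for (i in seq_along(config$tracks))
      if (is.character(config$tracks[[i]])) chk_path(config$tracks[[i]], "tracks")
  }
  if (is.null(config$simulate)) {
    if (is.null(config$snps)) problems <- c(problems, "'snps' is required")
    if (is.null(config$alignments_g1))
      problems <- c(problems, "'alignments_g1' is required")
  }
  if (!is.null(config$gwas_catalog) && is.null(config$panel))
    problems <- c(problems, "'panel' is required when a GWAS catalog is given")
  problems
}

resolve_tracks <- function(tracks) {
  if (is.null(tracks)) return(NULL)
  if (inherits(tracks, "exclusion_track")) return(list(tracks))
  out <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    if (inherits(tr, "exclusion_track")) return(tr)
    if (is.character(tr)) {
      lb <- names(tracks)[i]
      if (is.null(lb) || lb == "") stopf("track paths must be named gap/blacklist/cnv")
      return(read_track_bed(tr, lb))
    }
    stopf("tracks must be exclusion_track objects or named BED paths")
  })
  out
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  keep <- config[setdiff(names(config), "out_dir")]
  writeLines(deparse(keep), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the AS-SNP discovery pipeline end to end
#'
#' Executes the stages in order: allele counting, zero-coverage discard,
#' exact binomial test with BH correction, AS-SNP selection, allele-frequency
#' intersection, region exclusion, and LD proxy linking; asserts that the
#' stage counts telescope (each stage's input equals the previous stage's
#' retained output) and, if `out_dir` is set, writes per-stage TSVs, the
#' final report and a JSON metadata file. Identical configuration and seed
#' give an identical report.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`: list with `stage_counts`,
#'   `results` (all scored sites), `final` (the reported AS-SNP table with
#'   counts, p, q, AF and proxy links), `links`, `truth` (simulation ground
#'   truth, when simulated) and `provenance`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stopf("invalid configuration:\n- %s", paste(problems, collapse = "\n- "))
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  truth <- NULL
  if (!is.null(config$simulate)) {
    study <- do.call(simulate_study,
                     c(config$simulate, list(seed = config$seed)))
    config$snps <- study$snps
    config$alignments_g1 <- study$alignments
    config$tracks <- study$tracks
    config$af_table <- study$af_table
    config$gwas_catalog <- study$catalog
    config$panel <- study$panel
    truth <- study$truth
    note("simulated study: %d sites, %d planted AS", nrow(study$snps),
         sum(study$truth$sites$is_planted_as))
  }
  snps <- if (is.character(config$snps)) read_het_vcf(config$snps) else config$snps
  af_table <- if (is.character(config$af_table)) read_af_table(config$af_table)
              else config$af_table
  catalog <- if (is.character(config$gwas_catalog))
    read_gwas_catalog(config$gwas_catalog) else config$gwas_catalog
  panel <- if (is.character(config$panel)) read_panel(config$panel) else config$panel
  tracks <- resolve_tracks(config$tracks)

  policy <- counting_policy(min_mapq = config$min_mapq,
                            min_baseq = config$min_baseq)
  stage <- function(name, n_in, n_out)
    data.frame(stage = name, n_in = n_in, n_removed = n_in - n_out,
               n_out = n_out, stringsAsFactors = FALSE)
  stages <- list()

  ## optional pre-test region filtering (sensitivity analysis)
  if (isTRUE(config$filter_before_test) && !is.null(tracks)) {
    fl <- apply_exclusions(snps, tracks)
    stages[[length(stages) + 1L]] <- stage("pre_filter", nrow(snps),
                                           nrow(fl$retained))
    snps <- fl$retained
    note("pre-test region filter removed %d site(s)", nrow(fl$removed))
  }

  counts <- count_alleles(config$alignments_g1, config$alignments_g2, snps,
                          policy)
  stages[[length(stages) + 1L]] <- stage("count", nrow(snps), nrow(counts))
  covered <- discard_uncovered(counts, config$min_total)
  stages[[length(stages) + 1L]] <- stage("discard_uncovered", nrow(counts),
                                         nrow(covered))
  results <- as_binomial_test(covered, alpha = config$alpha,
                              select_on = config$select_on)
  stages[[length(stages) + 1L]] <- stage("test", nrow(covered), nrow(results))
  selected <- select_as_snps(results, alpha = config$alpha,
                             on = config$select_on)
  stages[[length(stages) + 1L]] <- stage("select", nrow(results),
                                         nrow(selected))

  if (!is.null(af_table)) {
    selected <- annotate_af(selected, af_table,
                            require_present = config$require_af)
    dropped <- attr(selected, "dropped")
    stages[[length(stages) + 1L]] <- stage("af_intersect",
                                           nrow(selected) + nrow(dropped),
                                           nrow(selected))
    if (nrow(dropped)) note("AF intersection dropped: %s",
                            paste(dropped$snp_id, collapse = ", "))
  }

  removed <- selected[FALSE, , drop = FALSE]
  if (!is.null(tracks) && !isTRUE(config$filter_before_test)) {
    fl <- apply_exclusions(selected, tracks)
    stages[[length(stages) + 1L]] <- stage("region_filter", nrow(selected),
                                           nrow(fl$retained))
    removed <- fl$removed
    selected <- fl$retained
    if (nrow(removed)) note("region filter removed: %s",
                            paste(removed$snp_id, collapse = ", "))
  }

  links <- NULL
  final <- as.data.frame(selected)
  if (!is.null(catalog) && nrow(final)) {
    links <- find_proxies(final, catalog, panel, r2_min = config$r2_min,
                          strict = config$strict_r2, quiet = TRUE)
    miss <- attr(links, "missing_from_panel")
    if (length(miss)) note("%d id(s) absent from the haplotype panel", length(miss))
    agg <- if (nrow(links))
      do.call(rbind, lapply(split(links, links$as_snp_id), function(d)
        data.frame(snp_id = d$as_snp_id[1L], n_proxies = nrow(d),
                   proxy_gwas_snps = paste(d$gwas_snp_id, collapse = ","),
                   proxy_traits = paste(unique(d$trait), collapse = "; "),
                   best_r2 = max(d$r2), stringsAsFactors = FALSE)))
    else data.frame(snp_id = character(), n_proxies = integer(),
                    proxy_gwas_snps = character(), proxy_traits = character(),
                    best_r2 = numeric(), stringsAsFactors = FALSE)
    final <- merge(final, agg, by = "snp_id", all.x = TRUE, sort = FALSE)
    final$n_proxies[is.na(final$n_proxies)] <- 0L
  } else if (!is.null(catalog)) {
    links <- find_proxies(character(0), catalog, panel, quiet = TRUE)
  }
  if (nrow(final))
    final <- final[order(final$q_value, -abs(final$allelic_ratio - 0.5)), ,
                   drop = FALSE]
  rownames(final) <- NULL

  stage_counts <- do.call(rbind, stages)
  ## telescoping invariant: each stage consumes the previous stage's output
  if (nrow(stage_counts) > 1L) {
    same_thread <- stage_counts$stage != "af_intersect"
    lag_ok <- stage_counts$n_in[-1L] == stage_counts$n_out[-nrow(stage_counts)]
    if (!all(lag_ok[same_thread[-1L]]))
      stopf("internal error: stage counts do not telescope")
  }

  report <- structure(list(stage_counts = stage_counts, results = results,
                           final = final, links = links, removed = removed,
                           truth = truth, log = log,
                           provenance = list(seed = config$seed,
                                             alpha = config$alpha,
                                             r2_min = config$r2_min,
                                             select_on = config$select_on,
                                             config_hash = config_hash(config),
                                             package_version =
                                               as.character(packageVersion("asbscan")))),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write a run report to disk
#'
#' Emits the per-stage TSVs (`results.tsv`, `final_report.tsv`, `links.tsv`,
#' `removed.tsv`, `stage_counts.tsv`), the JSON run metadata and a plain-text
#' log. File contents are a pure function of the configuration and seed;
#' the wall-clock timestamp goes only to the log.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(report$stage_counts, file.path(out_dir, "stage_counts.tsv"))
  write_tsv_file(report$results, file.path(out_dir, "results.tsv"))
  write_tsv_file(report$final, file.path(out_dir, "final_report.tsv"))
  if (!is.null(report$links))
    write_tsv_file(report$links, file.path(out_dir, "links.tsv"))
  if (nrow(report$removed))
    write_tsv_file(report$removed, file.path(out_dir, "removed.tsv"))
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(format(Sys.time()), report$log), file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("AS-SNP discovery run (seed", x$provenance$seed, ")\n")
  print(x$stage_counts, row.names = FALSE)
  cat(nrow(x$final), "AS-SNP(s) in the final report\n")
  if (!is.null(x$links)) cat(nrow(x$links), "proxy link(s)\n")
  invisible(x)
}

#' Generate a complete synthetic study with ground truth
#'
#' Produces every input of one pipeline run: a random reference contig,
#' planted heterozygous SNVs (a subset with allelic imbalance), simulated
#' reads, exclusion tracks covering a fraction of sites, an allele-frequency
#' table, a GWAS catalog with one entry per planted AS site, and a phased
#' haplotype panel realizing high LD between each planted AS-SNP and its
#' catalog partner. The defaults are the package's standard validation
#' scenario: 500 sites of which 20 carry an allelic imbalance of magnitude
#' 0.75-0.9 (either direction), mean depth 60, and about 30% of sites masked
#' by exclusion tracks.
#'
#' @param seed master seed; all substreams derive from it.
#' @param n_sites total heterozygous sites.
#' @param n_as planted allele-specific sites.
#' @param mean_depth Poisson mean reads per site.
#' @param imbalance_range magnitude range of the planted G1-read probability.
#' @param fraction_masked fraction of sites covered by exclusion tracks.
#' @param error_rate per-base sequencing error rate.
#' @param contig_length,read_length contig and read lengths (bases).
#' @param n_haplotypes phased haplotypes in the LD panel.
#' @param target_r2 target LD between each planted AS-SNP and its GWAS
#'   partner.
#' @param paddings per-track paddings used both to generate the synthetic
#'   tracks and to filter; scaled to the synthetic contig (the production
#'   defaults of [exclusion_track()] assume genome-scale input).
#' @return list with `reference, snps, alignments, tracks, af_table, catalog,
#'   panel` (pipeline inputs) and `truth` (list `sites`, `mask`, `ld`).
#' @export
simulate_study <- function(seed = 1L, n_sites = 500L, n_as = 20L,
                           mean_depth = 60, imbalance_range = c(0.75, 0.9),
                           fraction_masked = 0.3, error_rate = 0.001,
                           contig_length = 120000L, read_length = 36L,
                           n_haplotypes = 2000L, target_r2 = 0.95,
                           paddings = c(gap = 20, blacklist = 10, cnv = 0)) {
  seeds <- derive_seeds(seed, 7L)
  reference <- generate_reference(contig_length, seeds[1L])
  snps <- plant_het_snps(reference, n_sites, seeds[2L],
                         read_length = read_length)
  imb <- withr::with_seed(seeds[3L], {
    as_idx <- sample.int(n_sites, n_as)
    mag <- runif(n_as, imbalance_range[1L], imbalance_range[2L])
    flip <- runif(n_as) < 0.5
    stats::setNames(ifelse(flip, 1 - mag, mag), snps$snp_id[as_idx])
  })
  cfg <- simulation_config(contig_length = contig_length,
                           n_het_snps = n_sites, read_length = read_length,
                           mean_depth = mean_depth, error_rate = error_rate,
                           imbalance = imb, seed = seeds[4L])
  sim <- simulate_reads(cfg, reference, snps)
  tr <- generate_exclusion_tracks(snps, fraction_masked, seeds[5L],
                                  contig_length = contig_length,
                                  paddings = paddings,
                                  interval_halfwidth = 5L)
  af_table <- withr::with_seed(seeds[6L],
    data.frame(snp_id = snps$snp_id,
               af = round(runif(n_sites, 0.05, 0.95), 4L),
               stringsAsFactors = FALSE))
  as_ids <- names(imb)
  catalog <- generate_gwas_catalog(data.frame(
    gwas_snp_id = paste0("gwas_", as_ids),
    trait = paste0("trait_", seq_along(as_ids)),
    contig = snps$contig[match(as_ids, snps$snp_id)],
    position = snps$pos[match(as_ids, snps$snp_id)] + 11L,
    stringsAsFactors = FALSE))
  panel_seeds <- derive_seeds(seeds[7L], length(as_ids))
  panels <- lapply(seq_along(as_ids), function(i)
    generate_haplotype_panel(as_ids[i],
                             stats::setNames(target_r2, paste0("gwas_", as_ids[i])),
                             n_haplotypes, panel_seeds[i]))
  panel <- do.call(cbind, lapply(panels, `[[`, "panel"))
  ld_truth <- do.call(rbind, lapply(seq_along(panels), function(i) {
    d <- panels[[i]]$realized
    d$as_snp_id <- as_ids[i]
    d
  }))
  sites <- merge(sim$truth, tr$membership, by = "snp_id", sort = FALSE)
  list(reference = stats::setNames(reference, cfg$contig), snps = snps,
       alignments = sim$alignments, tracks = tr$tracks, af_table = af_table,
       catalog = catalog, panel = panel,
       truth = list(sites = sites, mask = tr$membership, ld = ld_truth))
}
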