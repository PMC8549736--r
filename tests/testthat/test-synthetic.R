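test_that("catalog generation honors ranges and is deterministic", {
  cfg <- synth_config(n_genomes = 10, bgc_per_genome_range = c(1, 1),
                      samples_per_site = 2, seed = 1)
  out <- generate_catalog(cfg)
  expect_equal(length(unique(out$catalog$bgc_id)), 10)

  out2 <- generate_catalog(cfg)
  expect_identical(out$orf_fasta, out2$orf_fasta)
  expect_identical(out$catalog, out2$catalog)

  # empirical mean of per-genome BGC counts approaches the uniform mean
  cfg2 <- synth_config(n_genomes = 200, bgc_per_genome_range = c(1, 4),
                       samples_per_site = 2, seed = 7)
  cat2 <- generate_catalog(cfg2)$catalog
  per_genome <- dplyr::count(dplyr::distinct(cat2, genome_id, bgc_id),
                             genome_id)
  expect_lt(abs(mean(per_genome$n) - 2.5), 0.2)
})

test_that("inverted ranges are rejected as configuration errors", {
  expect_error(synth_config(bgc_per_genome_range = c(4, 1)),
               "configuration error")
  expect_error(synth_config(substitution_error_rate = 1.2),
               "probability")
  expect_error(synth_config(planted_fold = 0.5), "fold")
})

test_that("community generation gives normalized, site-structured taxa", {
  cfg <- tiny_config()
  cat_obj <- generate_catalog(cfg)
  comm <- generate_communities(cfg, cat_obj$catalog)
  m <- adtbgc:::taxa_matrix(comm$taxa)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  prof <- as.matrix(comm$truth$site_profiles[, -1])
  expect_true(all(abs(rowSums(prof) - 1) < 1e-9))
  expect_true(all(comm$truth$planted_bgcs$bgc_id %in%
                    cat_obj$catalog$bgc_id))

  # very large Dirichlet concentration: samples converge on the profile
  cfg_big <- tiny_config(dirichlet_concentration = 1e8)
  comm_big <- generate_communities(cfg_big, cat_obj$catalog)
  mb <- adtbgc:::taxa_matrix(comm_big$taxa)
  profile_of <- as.matrix(comm_big$truth$site_profiles[, -1])
  rownames(profile_of) <- comm_big$truth$site_profiles$site
  for (i in seq_len(nrow(mb))) {
    site <- comm_big$metadata$site[i]
    expect_true(max(abs(mb[i, ] - profile_of[site, colnames(mb)])) < 1e-3)
  }
})

test_that("strong site effects separate sites in Bray-Curtis space", {
  cfg <- tiny_config(site_effect_max_fold = 50,
                     dirichlet_concentration = 500, n_genomes = 6)
  cat_obj <- generate_catalog(cfg)
  comm <- generate_communities(cfg, cat_obj$catalog)
  d <- as.matrix(bray_curtis(comm$taxa))
  same <- outer(comm$metadata$site, comm$metadata$site, "==")
  diag(same) <- NA
  expect_gt(min(d[!same & !is.na(same)]), max(d[same & !is.na(same)]))
})

test_that("a single dominant species gives zero Shannon diversity", {
  profile <- c(5, 0, 0)
  res <- shannon_metrics(profile)
  expect_equal(res$shannon, 0)
  expect_equal(res$richness, 1)
  expect_true(is.na(res$equitability))
})

test_that("read simulation conserves reads and respects error-free mode", {
  cfg <- tiny_config()
  study <- simulate_study(cfg)
  counts <- study$truth$orf_read_counts
  expect_true(all(colSums(counts) + study$truth$background_reads ==
                    cfg$reads_per_sample))

  # error-free, background-free: every read is an exact (possibly
  # reverse-complemented) substring of an eligible ORF
  sid <- study$metadata$sample_id[1]
  sim <- suppressWarnings(simulate_sample_reads(
    sid, study$catalog, study$orf_fasta, study$taxa, study$metadata,
    study$truth, cfg))
  expect_equal(length(sim$reads), cfg$reads_per_sample)
  genome_seqs <- paste(study$orf_fasta, collapse = "|")
  hits <- vapply(sim$reads[1:50], function(r) {
    grepl(r, genome_seqs, fixed = TRUE) ||
      grepl(adtbgc:::revcomp(r), genome_seqs, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
})

test_that("identical config and seed reproduce identical reads", {
  cfg <- tiny_config(substitution_error_rate = 0.01,
                     background_fraction = 0.3)
  study <- simulate_study(cfg, simulate_reads = FALSE)
  sid <- study$metadata$sample_id[2]
  s1 <- suppressWarnings(simulate_sample_reads(
    sid, study$catalog, study$orf_fasta, study$taxa, study$metadata,
    study$truth, cfg))
  s2 <- suppressWarnings(simulate_sample_reads(
    sid, study$catalog, study$orf_fasta, study$taxa, study$metadata,
    study$truth, cfg))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$orf_counts, s2$orf_counts)

  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1, f1)
  write_fastq(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(read_fastq(f1)), s1$reads)
})

test_that("planted enrichment shifts true read counts by about the fold", {
  # two sites, generous depth, no errors; the planted BGC is a small BGC
  # of a BGC-rich genome with site-neutral abundance, so the true-count
  # ratio between sites approximates the nominal 8-fold
  base_cfg <- synth_config(n_sites = 2, samples_per_site = 20,
                           n_genomes = 8,
                           bgc_per_genome_range = c(10, 14),
                           orf_per_bgc_range = c(3, 5),
                           orf_length_range = c(150, 900),
                           reads_per_sample = 5000, read_length = 50,
                           substitution_error_rate = 0,
                           background_fraction = 0,
                           planted_per_site = 1, planted_fold = 8,
                           planted_species_fold = 1,
                           site_effect_max_fold = 1,
                           dirichlet_concentration = 1e5, seed = 11)
  cat0 <- generate_catalog(base_cfg)$catalog
  shares <- cat0 |>
    dplyr::group_by(genome_id, bgc_id) |>
    dplyr::summarise(w = sum(length_nt), .groups = "drop") |>
    dplyr::group_by(genome_id) |>
    dplyr::mutate(q = w / sum(w)) |>
    dplyr::ungroup() |>
    dplyr::arrange(q)
  b <- shares$bgc_id[1] # smallest weight share: realized fold ~ nominal
  cfg <- synth_config(n_sites = 2, samples_per_site = 20, n_genomes = 8,
                      bgc_per_genome_range = c(10, 14),
                      orf_per_bgc_range = c(3, 5),
                      orf_length_range = c(150, 900),
                      reads_per_sample = 5000, read_length = 50,
                      substitution_error_rate = 0, background_fraction = 0,
                      planted_enrichment = tibble::tibble(
                        site = "buccal_mucosa", bgc_id = b, fold = 8),
                      planted_species_fold = 1,
                      site_effect_max_fold = 1,
                      dirichlet_concentration = 1e5, seed = 11)
  study <- simulate_study(cfg)
  orfs <- study$catalog$orf_id[study$catalog$bgc_id == b]
  site_of <- study$metadata$site[match(colnames(study$truth$orf_read_counts),
                                       study$metadata$sample_id)]
  per_sample <- colSums(study$truth$orf_read_counts[orfs, , drop = FALSE])
  ratio <- mean(per_sample[site_of == "buccal_mucosa"]) /
    mean(per_sample[site_of != "buccal_mucosa"])
  expect_gte(ratio, 6)
  expect_lte(ratio, 10)
})
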