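# End-to-end orchestration: synthetic -> catalog -> quantify -> diversity
# -> community -> enrichment -> ancom -> networks, file-based, with a JSON
# run manifest.

PIPELINE_STAGES <- c("simulate", "catalog", "quantify", "diversity",
                     "community", "enrichment", "ancom", "networks")

#' Pipeline configuration
#'
#' @param synthetic A [synth_config()] describing the synthetic study.
#' @param stages Stages to run (subset of simulate, catalog, quantify,
#'   diversity, community, enrichment, ancom, networks).
#' @param seed Global seed; each stage derives its own stream via
#'   [derive_seed()]. Defaults to the synthetic config's seed.
#' @param write_reads Write per-sample FASTQ files during simulation (and
#'   read them back during quantification). Off by default: reads are
#'   regenerated deterministically from per-sample seeds instead, which
#'   avoids serializing multi-gigabyte FASTQ at study scale.
#' @param k k-mer length for the index.
#' @param min_fold,max_padj Enrichment calling thresholds.
#' @param min_site_samples Minimum samples for a site to be tested.
#' @param anosim_permutations Permutations for ANOSIM.
#' @param nmds_max_samples NMDS is run on a stratified subsample of at
#'   most this many samples (ordination cost grows quadratically).
#' @param nmds_trymax Maximum NMDS starts.
#' @param network_cutoff BGC network distance cutoff.
#' @param identity_threshold Core-peptide identity threshold (percent).
#' @param abundance_min_total Heat-map abundance filter threshold.
#' @param ancom_min_sample_total,ancom_min_prevalence,ancom_min_taxon_total
#'   ANCOM input filters (see [ancom_filter()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synth_config(),
                            stages = PIPELINE_STAGES,
                            seed = synthetic$seed,
                            write_reads = FALSE,
                            k = 31,
                            min_fold = 4,
                            max_padj = 1e-8,
                            min_site_samples = 200,
                            anosim_permutations = 10000,
                            nmds_max_samples = 160,
                            nmds_trymax = 20,
                            network_cutoff = 0.3,
                            identity_threshold = 75,
                            abundance_min_total = 100,
                            ancom_min_sample_total = 10000,
                            ancom_min_prevalence = 10,
                            ancom_min_taxon_total = 1000) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(synthetic = synthetic, stages = stages,
                 seed = as.integer(seed), write_reads = write_reads,
                 k = k, min_fold = min_fold, max_padj = max_padj,
                 min_site_samples = min_site_samples,
                 anosim_permutations = anosim_permutations,
                 nmds_max_samples = nmds_max_samples,
                 nmds_trymax = nmds_trymax,
                 network_cutoff = network_cutoff,
                 identity_threshold = identity_threshold,
                 abundance_min_total = abundance_min_total,
                 ancom_min_sample_total = ancom_min_sample_total,
                 ancom_min_prevalence = ancom_min_prevalence,
                 ancom_min_taxon_total = ancom_min_taxon_total),
            class = "pipeline_config")
}

plog <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

need_artifact <- function(outdir, file, stage) {
  path <- file.path(outdir, file)
  if (!file.exists(path)) {
    stop("stage '", stage, "' requires missing artifact: ", file,
         call. = FALSE)
  }
  path
}

read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)),
                         tibble::as_tibble(m))
  readr::write_tsv(df, path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order, each stage reading its
#' inputs from and writing its outputs to `outdir` (stages communicate
#' only through files). A JSON manifest records stages, parameters, seed
#' and package version. Rerunning with the same configuration reproduces
#' byte-identical TSV outputs.
#'
#' Because stages consume only files, real (non-synthetic) data can be
#' analyzed by placing `catalog.tsv`, `taxa.tsv`, `metadata.tsv` and a
#' `reads/` directory of per-sample FASTQ files into `outdir` and running
#' the stages from `"catalog"` onward.
#'
#' @param config A [pipeline_config()].
#' @param outdir Run directory (created if needed).
#' @return `outdir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  for (stage in PIPELINE_STAGES) {
    if (!stage %in% config$stages) next
    plog(stage, "started")
    switch(stage,
           simulate = stage_simulate(config, outdir),
           catalog = stage_catalog(config, outdir),
           quantify = stage_quantify(config, outdir),
           diversity = stage_diversity(config, outdir),
           community = stage_community(config, outdir),
           enrichment = stage_enrichment(config, outdir),
           ancom = stage_ancom(config, outdir),
           networks = stage_networks(config, outdir))
    plog(stage, "done")
  }
  manifest <- list(
    stages = as.list(intersect(PIPELINE_STAGES, config$stages)),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("synthetic", "stages"))],
    synthetic = config$synthetic[setdiff(names(config$synthetic),
                                         "planted_enrichment")],
    package_version = as.character(utils::packageVersion("adtbgc")),
    r_version = R.version.string,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

stage_simulate <- function(config, outdir) {
  fq <- if (config$write_reads) file.path(outdir, "reads") else NULL
  study <- simulate_study(config$synthetic, fastq_dir = fq)
  write_catalog(study$catalog, file.path(outdir, "catalog.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(study$orf_fasta),
                              file.path(outdir, "orfs.fasta"))
  readr::write_tsv(study$metadata, file.path(outdir, "metadata.tsv"))
  readr::write_tsv(study$taxa, file.path(outdir, "taxa.tsv"))
  readr::write_tsv(study$truth$planted_bgcs,
                   file.path(outdir, "truth_planted_bgcs.tsv"))
  readr::write_tsv(study$truth$site_profiles,
                   file.path(outdir, "truth_site_profiles.tsv"))
  write_matrix_tsv(study$truth$orf_read_counts,
                   file.path(outdir, "truth_orf_counts.tsv"), "orf_id")
  jsonlite::write_json(
    list(planted_species = study$truth$planted_species,
         background_reads = as.list(study$truth$background_reads)),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_catalog <- function(config, outdir) {
  cat_path <- need_artifact(outdir, "catalog.tsv", "catalog")
  catalog <- load_catalog(cat_path)
  readr::write_tsv(summarize_categories(catalog),
                   file.path(outdir, "category_summary.tsv"))
  filtered <- suppressMessages(filter_nonbiosynthetic_orfs(catalog))
  write_catalog(filtered, file.path(outdir, "catalog_filtered.tsv"))
  invisible(NULL)
}

stage_quantify <- function(config, outdir) {
  catalog <- load_catalog(need_artifact(outdir, "catalog_filtered.tsv",
                                        "quantify"))
  fasta <- Biostrings::readDNAStringSet(
    need_artifact(outdir, "orfs.fasta", "quantify"))
  orf_fasta <- setNames(as.character(fasta), names(fasta))
  metadata <- readr::read_tsv(need_artifact(outdir, "metadata.tsv",
                                            "quantify"),
                              show_col_types = FALSE)

  seqs <- sanitize_sequences(orf_fasta[catalog$orf_id],
                             seed = derive_seed(config$seed, "sanitize"))
  index <- suppressWarnings(build_index(seqs, k = config$k))
  plog("quantify", sprintf("index: %s k-mers, %s classes",
                           format(index$n_kmers, big.mark = ","),
                           format(index$n_classes, big.mark = ",")))

  reads_dir <- file.path(outdir, "reads")
  if (dir.exists(reads_dir)) {
    q <- quantify_samples(catalog, index, metadata, fastq_dir = reads_dir)
  } else {
    taxa <- readr::read_tsv(need_artifact(outdir, "taxa.tsv", "quantify"),
                            show_col_types = FALSE)
    planted <- readr::read_tsv(
      need_artifact(outdir, "truth_planted_bgcs.tsv", "quantify"),
      show_col_types = FALSE)
    full_catalog <- load_catalog(need_artifact(outdir, "catalog.tsv",
                                               "quantify"))
    q <- quantify_samples(catalog, index, metadata, taxa = taxa,
                          truth = list(planted_bgcs = planted),
                          config = config$synthetic,
                          full_catalog = full_catalog,
                          orf_fasta = orf_fasta)
  }
  counts <- suppressMessages(finalize_counts(q$bgc_counts))
  counts <- size_factor_normalize(counts)
  write_matrix_tsv(counts$counts, file.path(outdir, "counts.tsv"), "bgc_id")
  write_matrix_tsv(counts$counts - 1, file.path(outdir, "counts_raw.tsv"),
                   "bgc_id")
  write_matrix_tsv(counts$normalized, file.path(outdir, "normalized.tsv"),
                   "bgc_id")
  readr::write_tsv(tibble::tibble(sample_id = names(counts$size_factors),
                                  size_factor = counts$size_factors,
                                  unassigned_reads = q$unassigned[
                                    names(counts$size_factors)]),
                   file.path(outdir, "size_factors.tsv"))
  invisible(NULL)
}

stage_diversity <- function(config, outdir) {
  taxa <- readr::read_tsv(need_artifact(outdir, "taxa.tsv", "diversity"),
                          show_col_types = FALSE)
  metadata <- readr::read_tsv(need_artifact(outdir, "metadata.tsv",
                                            "diversity"),
                              show_col_types = FALSE)
  raw <- read_matrix_tsv(need_artifact(outdir, "counts_raw.tsv",
                                       "diversity"))
  div_sp <- shannon_metrics(taxa)
  div_bgc <- shannon_metrics(t(raw))
  div <- dplyr::inner_join(div_sp, div_bgc, by = "sample_id",
                           suffix = c("_species", "_bgc")) |>
    dplyr::left_join(metadata[, c("sample_id", "site")], by = "sample_id")
  readr::write_tsv(div, file.path(outdir, "diversity.tsv"))

  kw_sp <- kruskal_dunn(div$shannon_species, div$site)
  kw_bgc <- kruskal_dunn(div$shannon_bgc, div$site)
  st <- sign_test(div$shannon_bgc, div$shannon_species)
  tests <- dplyr::bind_rows(
    tibble::tibble(test = "kruskal_species", statistic = kw_sp$statistic,
                   p_value = kw_sp$p_value, effect = kw_sp$epsilon_sq),
    tibble::tibble(test = "kruskal_bgc", statistic = kw_bgc$statistic,
                   p_value = kw_bgc$p_value, effect = kw_bgc$epsilon_sq),
    tibble::tibble(test = "sign_bgc_gt_species", statistic = st$S,
                   p_value = st$p_value, effect = st$S / st$n))
  readr::write_tsv(tests, file.path(outdir, "diversity_tests.tsv"))

  reg <- suppressWarnings(diversity_regression(
    tibble::tibble(h_species = div$shannon_species,
                   h_bgc = div$shannon_bgc, site = div$site)))
  readr::write_tsv(reg, file.path(outdir, "diversity_regression.tsv"))
  invisible(NULL)
}

stage_community <- function(config, outdir) {
  taxa <- readr::read_tsv(need_artifact(outdir, "taxa.tsv", "community"),
                          show_col_types = FALSE)
  metadata <- readr::read_tsv(need_artifact(outdir, "metadata.tsv",
                                            "community"),
                              show_col_types = FALSE)
  norm <- read_matrix_tsv(need_artifact(outdir, "normalized.tsv",
                                        "community"))
  norm <- norm[, taxa$sample_id, drop = FALSE]
  site_of <- metadata$site[match(taxa$sample_id, metadata$sample_id)]

  ft <- species_filter(taxa)
  d_sp <- bray_curtis(ft)
  bgc_prop <- t(sweep(norm, 2, colSums(norm), "/"))
  d_bgc <- bray_curtis(bgc_prop)

  an_sp <- anosim(d_sp, site_of, n_perm = config$anosim_permutations,
                  seed = derive_seed(config$seed, "anosim_species"))
  an_bgc <- anosim(d_bgc, site_of, n_perm = config$anosim_permutations,
                   seed = derive_seed(config$seed, "anosim_bgc"))

  # NMDS on a stratified subsample (quadratic cost in n)
  sub <- stratified_subsample(metadata$sample_id, site_of,
                              config$nmds_max_samples,
                              derive_seed(config$seed, "nmds_subsample"))
  keep <- taxa$sample_id %in% sub
  sub_ids <- taxa$sample_id[keep]
  mds_sp <- nmds(bray_curtis(ft[ft$sample_id %in% sub_ids, ]), k = 2,
                 trymax = config$nmds_trymax,
                 seed = derive_seed(config$seed, "nmds_species"))
  mds_bgc <- nmds(bray_curtis(bgc_prop[sub_ids, ]), k = 2,
                  trymax = config$nmds_trymax,
                  seed = derive_seed(config$seed, "nmds_bgc"))

  wc_bgc <- ward_cluster(t(norm), sites = site_of)
  # species RA enters on a log scale with a 0.1% detection floor so rare
  # species do not dominate the squared-Euclidean distances
  wc_sp <- ward_cluster(ft, sites = site_of,
                        transform = function(x) log10(x + 1e-3))
  jac <- clustering_jaccard(wc_bgc$labels, wc_sp$labels)

  stats <- tibble::tibble(
    statistic = c("anosim_r_species", "anosim_p_species", "anosim_r_bgc",
                  "anosim_p_bgc", "nmds_stress_species", "nmds_stress_bgc",
                  "ward_min_purity_bgc", "clustering_jaccard"),
    value = c(an_sp$R, an_sp$p_value, an_bgc$R, an_bgc$p_value,
              mds_sp$stress, mds_bgc$stress, min(wc_bgc$purity$purity), jac))
  readr::write_tsv(stats, file.path(outdir, "community_stats.tsv"))
  coords <- dplyr::bind_rows(
    tibble::as_tibble(mds_sp$points, rownames = "sample_id") |>
      dplyr::mutate(level = "species"),
    tibble::as_tibble(mds_bgc$points, rownames = "sample_id") |>
      dplyr::mutate(level = "bgc"))
  readr::write_tsv(coords, file.path(outdir, "nmds_coords.tsv"))
  readr::write_tsv(dplyr::bind_rows(
    dplyr::mutate(wc_bgc$purity, level = "bgc"),
    dplyr::mutate(wc_sp$purity, level = "species")),
    file.path(outdir, "ward_purity.tsv"))
  write_dendrogram_newick(wc_bgc, file.path(outdir, "ward_bgc.nwk"))
  invisible(NULL)
}

stratified_subsample <- function(sample_ids, sites, max_n, seed) {
  if (length(sample_ids) <= max_n) return(sample_ids)
  set.seed(seed)
  per_site <- split(sample_ids, sites)
  n_each <- ceiling(max_n / length(per_site))
  unlist(lapply(per_site, function(s) {
    if (length(s) <= n_each) s else sample(s, n_each)
  }), use.names = FALSE)
}

stage_enrichment <- function(config, outdir) {
  norm <- read_matrix_tsv(need_artifact(outdir, "normalized.tsv",
                                        "enrichment"))
  counts <- read_matrix_tsv(need_artifact(outdir, "counts.tsv",
                                          "enrichment"))
  sf <- readr::read_tsv(need_artifact(outdir, "size_factors.tsv",
                                      "enrichment"), show_col_types = FALSE)
  metadata <- readr::read_tsv(need_artifact(outdir, "metadata.tsv",
                                            "enrichment"),
                              show_col_types = FALSE)
  m <- structure(list(counts = counts,
                      size_factors = setNames(sf$size_factor, sf$sample_id),
                      normalized = norm, state = "normalized"),
                 class = "bgc_counts")
  enr <- enrichment_all_sites(m, metadata,
                              min_samples = config$min_site_samples,
                              min_fold = config$min_fold,
                              max_padj = config$max_padj)
  readr::write_tsv(enr, file.path(outdir, "enrichment.tsv"))
  invisible(NULL)
}

stage_ancom <- function(config, outdir) {
  taxa <- readr::read_tsv(need_artifact(outdir, "taxa.tsv", "ancom"),
                          show_col_types = FALSE)
  metadata <- readr::read_tsv(need_artifact(outdir, "metadata.tsv",
                                            "ancom"), show_col_types = FALSE)
  counts <- estimated_taxon_counts(taxa, metadata)
  counts <- ancom_filter(counts,
                         min_sample_total = config$ancom_min_sample_total,
                         min_prevalence = config$ancom_min_prevalence,
                         min_taxon_total = config$ancom_min_taxon_total)
  res <- ancom_pairwise(counts, metadata,
                        sites = select_enrichment_sites(
                          metadata, config$min_site_samples))
  readr::write_tsv(res, file.path(outdir, "ancom.tsv"))
  invisible(NULL)
}

stage_networks <- function(config, outdir) {
  catalog <- load_catalog(need_artifact(outdir, "catalog_filtered.tsv",
                                        "networks"))
  norm <- read_matrix_tsv(need_artifact(outdir, "normalized.tsv",
                                        "networks"))
  enr_path <- file.path(outdir, "enrichment.tsv")
  enr <- if (file.exists(enr_path)) {
    readr::read_tsv(enr_path, show_col_types = FALSE)
  } else NULL

  m <- structure(list(counts = norm, size_factors = NULL, normalized = norm,
                      state = "normalized"), class = "bgc_counts")
  dmat <- bgc_distance_matrix(catalog)
  net <- build_bgc_network(catalog, dmat, cutoff = config$network_cutoff,
                           enrichment = enr, counts = m)
  readr::write_tsv(net$nodes, file.path(outdir, "bgc_network_nodes.tsv"))
  readr::write_tsv(net$edges, file.path(outdir, "bgc_network_edges.tsv"))
  export_network(net, graphml = file.path(outdir, "bgc_network.graphml"))

  fasta <- Biostrings::readDNAStringSet(
    need_artifact(outdir, "orfs.fasta", "networks"))
  orf_fasta <- setNames(as.character(fasta), names(fasta))
  pep <- suppressWarnings(extract_precursor_orfs(catalog, orf_fasta))
  if (nrow(pep)) {
    pep <- classify_precursor(pep)
    pep <- pep[pep$passes, ]
  }
  if (nrow(pep)) {
    pep <- dplyr::bind_cols(pep, cleave_leader(pep$precursor))
    pnet <- suppressWarnings(build_peptide_network(
      pep, threshold = config$identity_threshold))
    readr::write_tsv(pnet$nodes, file.path(outdir, "peptide_nodes.tsv"))
    readr::write_tsv(pnet$edges, file.path(outdir, "peptide_edges.tsv"))
    export_network(pnet, graphml = file.path(outdir,
                                             "peptide_network.graphml"))
  } else {
    readr::write_tsv(tibble::tibble(orf_id = character()),
                     file.path(outdir, "peptide_nodes.tsv"))
  }
  invisible(NULL)
}
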