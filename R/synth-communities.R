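# Synthetic community structure: site profiles, per-sample abundances,
# metadata, ground truth.

#' Generate site-structured communities, sample metadata and ground truth
#'
#' Site mean profiles are built from one shared log-normal(0, 1) species
#' magnitude vector times a bounded per-site effect, log-uniform on
#' `[1/f, f]` with `f = site_effect_max_fold`, then renormalized. Bounding
#' the site effect keeps incidental between-site fold changes of unplanted
#' features below the enrichment-calling threshold, so planted signals stay
#' identifiable while sites remain compositionally distinct. Per-sample
#' abundances are Dirichlet draws centered on the site profile with
#' concentration `dirichlet_concentration`.
#'
#' Planted ground truth: unless `config$planted_enrichment` is given,
#' `planted_per_site` BGCs per site are chosen from BGC-rich genomes (the
#' smallest BGC of each chosen genome, so the within-genome weight
#' redistribution approximates the nominal fold), and one low-BGC species
#' is boosted `planted_species_fold`-fold in the first site. Host genomes
#' of planted signals get a neutral site effect so the planted fold is
#' attributable to the plant alone.
#'
#' @param config A [synth_config()].
#' @param catalog Catalog tibble from [generate_catalog()].
#' @return A list with `metadata` (tibble: sample_id, subject_id, visit,
#'   site, total_reads), `taxa` (wide tibble: sample_id + one column per
#'   species, rows summing to 1) and `truth` (list with
#'   `site_profiles`, `planted_bgcs`, `planted_species`,
#'   `orf_read_counts` — the last filled by read simulation).
#' @export
generate_communities <- function(config, catalog) {
  validate_synth_config(config)
  if (nrow(catalog) == 0) stop("catalog is empty", call. = FALSE)
  genomes <- dplyr::distinct(catalog, .data$genome_id, .data$species)
  G <- nrow(genomes)
  if (G == 0) stop("catalog contains zero species", call. = FALSE)
  set.seed(derive_seed(config$seed, "communities"))

  sites <- site_names(config$n_sites)
  mag <- rlnorm(G, 0, 1)
  f <- config$site_effect_max_fold
  eff <- matrix(exp(runif(G * config$n_sites, -log(f), log(f))),
                nrow = G, ncol = config$n_sites)

  planted <- resolve_planting(config, catalog, sites, genomes, mag)
  host_idx <- match(unique(planted$genome_id), genomes$genome_id)
  host_idx <- host_idx[!is.na(host_idx)]
  if (length(host_idx)) eff[host_idx, ] <- 1

  planted_species <- NULL
  if (config$planted_species_fold > 1 && G >= 2) {
    bgc_per_genome <- catalog |>
      dplyr::distinct(.data$genome_id, .data$bgc_id) |>
      dplyr::count(.data$genome_id)
    n_bgc <- bgc_per_genome$n[match(genomes$genome_id, bgc_per_genome$genome_id)]
    cand <- setdiff(order(n_bgc, seq_len(G)), host_idx)
    sp_idx <- cand[1]
    eff[sp_idx, ] <- 1
    eff[sp_idx, 1] <- config$planted_species_fold
    planted_species <- list(species = genomes$species[sp_idx],
                            genome_id = genomes$genome_id[sp_idx],
                            site = sites[1],
                            fold = config$planted_species_fold)
  }

  profiles <- sweep(mag * eff, 2, colSums(mag * eff), "/")
  dimnames(profiles) <- list(genomes$species, sites)

  n <- config$n_sites * config$samples_per_site
  site_of <- rep(sites, each = config$samples_per_site)
  idx_in_site <- rep(seq_len(config$samples_per_site), times = config$n_sites)
  sample_id <- sprintf("%s_%03d", abbrev_site(site_of), idx_in_site)
  metadata <- tibble::tibble(
    sample_id = sample_id,
    subject_id = sprintf("subj_%s_%03d", abbrev_site(site_of),
                         ceiling(idx_in_site / 2)),
    visit = 2L - idx_in_site %% 2L,
    site = site_of,
    total_reads = config$reads_per_sample
  )

  conc <- config$dirichlet_concentration
  ra <- matrix(0, nrow = n, ncol = G,
               dimnames = list(sample_id, genomes$species))
  for (i in seq_len(n)) {
    shape <- conc * profiles[, site_of[i]]
    x <- stats::rgamma(G, shape = shape)
    if (sum(x) == 0) x <- profiles[, site_of[i]] # degenerate draw guard
    ra[i, ] <- x / sum(x)
  }

  truth <- list(
    site_profiles = matrix_to_taxa(t(profiles)) |>
      dplyr::rename(site = "sample_id"),
    planted_bgcs = planted,
    planted_species = planted_species,
    orf_read_counts = NULL
  )
  list(metadata = metadata, taxa = matrix_to_taxa(ra), truth = truth)
}

abbrev_site <- function(site) {
  vapply(strsplit(site, "_", fixed = TRUE), function(p) {
    paste(substr(p, 1, 3), collapse = "")
  }, character(1))
}

# choose planted site-enriched BGCs: one per donor genome. Donors are
# chosen for identifiability at the configured depth: the planted BGC is
# the one with the smallest share q of its genome's read-eligible
# ORF-sampling weight (an s-fold weight multiplier realizes a marginal
# fold of s / (1 + (s-1) q), so small q keeps the realized fold near the
# nominal one), and donors are drawn from the abundant half of the
# community so the planted signal is observable.
resolve_planting <- function(config, catalog, sites, genomes = NULL,
                             mag = NULL) {
  if (!is.null(config$planted_enrichment)) {
    pe <- tibble::as_tibble(config$planted_enrichment)
    missing <- setdiff(pe$bgc_id, catalog$bgc_id)
    if (length(missing)) {
      stop("planted BGC ids not in catalog: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    bg <- dplyr::distinct(catalog, .data$bgc_id, .data$genome_id)
    pe$genome_id <- bg$genome_id[match(pe$bgc_id, bg$bgc_id)]
    return(pe)
  }
  n_need <- config$planted_per_site * length(sites)
  if (n_need == 0) {
    return(tibble::tibble(site = character(), bgc_id = character(),
                          fold = numeric(), genome_id = character()))
  }
  eligible <- catalog[catalog$length_nt >= config$read_length, ]
  bgc_info <- eligible |>
    dplyr::group_by(.data$genome_id, .data$bgc_id) |>
    dplyr::summarise(weight = sum(.data$length_nt), .groups = "drop") |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::mutate(q = .data$weight / sum(.data$weight),
                  n_bgc = dplyr::n()) |>
    dplyr::ungroup()
  best <- bgc_info |>
    dplyr::filter(.data$n_bgc >= 2) |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::slice_min(.data$q, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (!is.null(mag)) {
    host_mag <- mag[match(best$genome_id, genomes$genome_id)]
    abundant <- best[host_mag >= median(mag), ]
    if (nrow(abundant) >= n_need) best <- abundant
  }
  best <- dplyr::arrange(best, .data$q)
  donors <- head(best, n_need)
  if (nrow(donors) < n_need) {
    stop("not enough genomes to plant ", n_need, " BGCs", call. = FALSE)
  }
  ord <- sample(n_need) # assign donors to sites at random
  tibble::tibble(
    site = rep(sites, each = config$planted_per_site),
    bgc_id = donors$bgc_id[ord],
    fold = config$planted_fold,
    genome_id = donors$genome_id[ord]
  )
}
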