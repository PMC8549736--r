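#' Configuration for the synthetic ADT study generator
#'
#' Bundles every knob of the synthetic-study generator: catalog shape
#' (genomes, BGCs per genome, ORFs per BGC, ORF lengths), community
#' structure (sites, samples per site, Dirichlet concentration), sequencing
#' (reads per sample, read length, substitution error rate, background
#' fraction) and the planted ground-truth signals used to validate the
#' downstream statistics.
#'
#' The defaults describe the study conditions used throughout the package's
#' validation: 4 body sites x 250 samples, 40 single-species genomes
#' carrying 1-18 BGCs each, 10,000 reads of 100 nt per sample with a 0.5%
#' substitution rate, 25% of reads drawn from non-BGC genome background,
#' three BGCs per site planted at 8-fold enrichment and one species planted
#' at 10-fold differential abundance in the first site.
#'
#' @param n_sites Number of body sites.
#' @param samples_per_site Metagenome samples simulated per site.
#' @param n_genomes Number of genomes (one species each).
#' @param bgc_per_genome_range Integer pair; BGC count per genome is drawn
#'   uniformly from this range.
#' @param orf_per_bgc_range Integer pair; ORFs per BGC.
#' @param orf_length_range Integer pair, nucleotides; ORF lengths are drawn
#'   uniformly and rounded to a multiple of 3.
#' @param reads_per_sample Reads emitted per sample.
#' @param read_length Read length in nt (must be >= 31 for alignment).
#' @param substitution_error_rate Per-base substitution probability.
#' @param background_fraction Probability a read comes from non-BGC genome
#'   background sequence rather than a BGC ORF.
#' @param planted_enrichment Optional tibble with columns `site`, `bgc_id`,
#'   `fold` naming explicit planted site-enriched BGCs. When `NULL`,
#'   `planted_per_site` BGCs per site are chosen automatically at
#'   `planted_fold` during community generation.
#' @param planted_per_site,planted_fold Automatic planting: number of BGCs
#'   per site and their fold enrichment.
#' @param planted_species_fold Fold by which one species is boosted in the
#'   first site (ground truth for compositional testing); set to 1 to
#'   disable.
#' @param dirichlet_concentration Concentration of the per-sample Dirichlet
#'   draw around the site mean profile; larger = less within-site noise.
#' @param site_effect_max_fold Per-site species effects are log-uniform on
#'   `[1/f, f]`; bounds the incidental between-site fold change of
#'   unplanted features.
#' @param background_length Length (nt) of the per-genome background
#'   sequence generated once per genome.
#' @param prob_nonbiosynthetic Probability that a non-precursor ORF is
#'   flagged nonbiosynthetic.
#' @param seed Integer master seed; all stage and sample seeds derive from
#'   it via [derive_seed()].
#' @return A `synth_config` object (named list, validated).
#' @examples
#' cfg <- synth_config(n_genomes = 5, samples_per_site = 4,
#'                     reads_per_sample = 200)
#' @export
synth_config <- function(n_sites = 4,
                         samples_per_site = 250,
                         n_genomes = 40,
                         bgc_per_genome_range = c(1L, 18L),
                         orf_per_bgc_range = c(3L, 8L),
                         orf_length_range = c(300L, 1500L),
                         reads_per_sample = 10000,
                         read_length = 100,
                         substitution_error_rate = 0.005,
                         background_fraction = 0.25,
                         planted_enrichment = NULL,
                         planted_per_site = 3,
                         planted_fold = 8,
                         planted_species_fold = 10,
                         dirichlet_concentration = 300,
                         site_effect_max_fold = 2,
                         background_length = 20000,
                         prob_nonbiosynthetic = 0.1,
                         seed = 1) {
  cfg <- list(
    n_sites = as.integer(n_sites),
    samples_per_site = as.integer(samples_per_site),
    n_genomes = as.integer(n_genomes),
    bgc_per_genome_range = as.integer(bgc_per_genome_range),
    orf_per_bgc_range = as.integer(orf_per_bgc_range),
    orf_length_range = as.integer(orf_length_range),
    reads_per_sample = as.integer(reads_per_sample),
    read_length = as.integer(read_length),
    substitution_error_rate = substitution_error_rate,
    background_fraction = background_fraction,
    planted_enrichment = planted_enrichment,
    planted_per_site = as.integer(planted_per_site),
    planted_fold = planted_fold,
    planted_species_fold = planted_species_fold,
    dirichlet_concentration = dirichlet_concentration,
    site_effect_max_fold = site_effect_max_fold,
    background_length = as.integer(background_length),
    prob_nonbiosynthetic = prob_nonbiosynthetic,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  chk_range <- function(r, name) {
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2] || r[1] <= 0) {
      stop("configuration error: `", name,
           "` must be a positive, non-inverted integer pair", call. = FALSE)
    }
  }
  chk_range(cfg$bgc_per_genome_range, "bgc_per_genome_range")
  chk_range(cfg$orf_per_bgc_range, "orf_per_bgc_range")
  chk_range(cfg$orf_length_range, "orf_length_range")
  chk_prob <- function(p, name) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop("configuration error: `", name, "` must be a probability in [0,1]",
           call. = FALSE)
    }
  }
  chk_prob(cfg$substitution_error_rate, "substitution_error_rate")
  chk_prob(cfg$background_fraction, "background_fraction")
  chk_prob(cfg$prob_nonbiosynthetic, "prob_nonbiosynthetic")
  for (nm in c("n_sites", "samples_per_site", "n_genomes", "reads_per_sample",
               "read_length", "background_length")) {
    if (cfg[[nm]] < 1) stop("configuration error: `", nm, "` must be >= 1",
                            call. = FALSE)
  }
  if (cfg$planted_fold < 1 || cfg$planted_species_fold < 1) {
    stop("configuration error: planted folds must be >= 1", call. = FALSE)
  }
  if (!is.null(cfg$planted_enrichment)) {
    pe <- cfg$planted_enrichment
    if (!all(c("site", "bgc_id", "fold") %in% names(pe))) {
      stop("configuration error: `planted_enrichment` needs columns ",
           "site, bgc_id, fold", call. = FALSE)
    }
    if (any(pe$fold < 1)) {
      stop("configuration error: planted fold must be >= 1", call. = FALSE)
    }
  }
  if (cfg$dirichlet_concentration <= 0) {
    stop("configuration error: `dirichlet_concentration` must be positive",
         call. = FALSE)
  }
  if (cfg$site_effect_max_fold < 1) {
    stop("configuration error: `site_effect_max_fold` must be >= 1",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d sites x %d samples, %d genomes, %s BGCs/genome\n",
              x$n_sites, x$samples_per_site, x$n_genomes,
              paste(x$bgc_per_genome_range, collapse = "-")))
  cat(sprintf("  %d reads/sample of %d nt, error %.3g, background %.2g\n",
              x$reads_per_sample, x$read_length,
              x$substitution_error_rate, x$background_fraction))
  cat(sprintf("  planted: %d BGCs/site at %gx, species at %gx; seed %d\n",
              x$planted_per_site, x$planted_fold, x$planted_species_fold,
              x$seed))
  invisible(x)
}

# default site naming: the four deeply-sampled ADT sites first
site_names <- function(n) {
  base <- c("buccal_mucosa", "tongue_dorsum", "external_naris", "gingiva")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("site", seq_len(n - length(base)) + length(base)))
}
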