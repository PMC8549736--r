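# Ground-truth evaluation of a pipeline run directory.

#' Recovery metrics for a synthetic-study pipeline run
#'
#' Reads the artifacts of a [run_pipeline()] directory and scores the
#' pipeline against the generator's ground truth: sensitivity and
#' false-positive rate of planted BGC enrichment recovery, recovery of the
#' planted differential species by the compositional test, the
#' community-structure statistics (ANOSIM R, Ward purity, clustering
#' agreement) and the BGC-vs-species diversity sign test.
#'
#' @param outdir A pipeline run directory.
#' @return Named list of metrics.
#' @export
recovery_metrics <- function(outdir) {
  rd <- function(f) readr::read_tsv(file.path(outdir, f),
                                    show_col_types = FALSE)
  enr <- rd("enrichment.tsv")
  planted <- rd("truth_planted_bgcs.tsv")
  stats <- rd("community_stats.tsv")
  tests <- rd("diversity_tests.tsv")
  truth_json <- jsonlite::read_json(file.path(outdir, "truth.json"),
                                    simplifyVector = TRUE)

  key <- function(b, s) paste(b, s, sep = "@")
  planted_keys <- key(planted$bgc_id, planted$site)
  tested_sites <- unique(enr$site)
  planted_tested <- planted[planted$site %in% tested_sites, ]
  called <- key(enr$bgc_id[enr$enriched], enr$site[enr$enriched])
  sens <- if (nrow(planted_tested)) {
    mean(key(planted_tested$bgc_id, planted_tested$site) %in% called)
  } else NA_real_
  all_keys <- key(enr$bgc_id, enr$site)
  negatives <- setdiff(all_keys, planted_keys)
  fpr <- if (length(negatives)) {
    mean(negatives %in% called)
  } else NA_real_

  ancom_path <- file.path(outdir, "ancom.tsv")
  sp_frac <- NA_real_
  if (file.exists(ancom_path) && !is.null(truth_json$planted_species)) {
    an <- rd("ancom.tsv")
    ps <- truth_json$planted_species
    rel <- an[an$species == ps$species &
                (an$group_a == ps$site | an$group_b == ps$site), ]
    sp_frac <- if (nrow(rel)) mean(rel$differential) else NA_real_
  }

  sval <- function(s) stats$value[stats$statistic == s]
  sign_row <- tests[tests$test == "sign_bgc_gt_species", ]
  list(
    enrichment_sensitivity = sens,
    enrichment_fpr = fpr,
    n_planted = nrow(planted_tested),
    n_negative = length(negatives),
    ancom_planted_species_frac = sp_frac,
    anosim_r_species = sval("anosim_r_species"),
    anosim_r_bgc = sval("anosim_r_bgc"),
    nmds_stress_species = sval("nmds_stress_species"),
    nmds_stress_bgc = sval("nmds_stress_bgc"),
    ward_min_purity_bgc = sval("ward_min_purity_bgc"),
    clustering_jaccard = sval("clustering_jaccard"),
    sign_test_S = sign_row$statistic,
    sign_test_p = sign_row$p_value
  )
}
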