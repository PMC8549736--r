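# ANCOM-style compositional differential abundance of species between
# sites: estimated counts, the study filters, and the W statistic with the
# CLR decision rule.

#' Estimate per-taxon read counts from relative abundances
#'
#' count = round(RA x total post-QC reads), per sample.
#'
#' @param taxa Wide taxa tibble (`sample_id` + species columns).
#' @param metadata Metadata tibble with `sample_id` and `total_reads`.
#' @return Wide tibble of estimated integer counts.
#' @export
estimated_taxon_counts <- function(taxa, metadata) {
  m <- taxa_matrix(taxa)
  total <- metadata$total_reads[match(rownames(m), metadata$sample_id)]
  if (anyNA(total)) {
    stop("total_reads missing for sample(s): ",
         paste(head(rownames(m)[is.na(total)], 5), collapse = ", "),
         call. = FALSE)
  }
  matrix_to_taxa(round(m * total))
}

#' ANCOM input filters
#'
#' Drops samples with fewer than `min_sample_total` total estimated reads,
#' then taxa present in fewer than `min_prevalence` samples or represented
#' by fewer than `min_taxon_total` estimated reads in total.
#'
#' @param counts Wide estimated-count tibble from
#'   [estimated_taxon_counts()].
#' @param min_sample_total Sample total-read floor (default 10,000).
#' @param min_prevalence Taxon prevalence floor (default 10 samples).
#' @param min_taxon_total Taxon grand-total floor (default 1,000 reads).
#' @return Filtered count tibble.
#' @export
ancom_filter <- function(counts, min_sample_total = 10000,
                         min_prevalence = 10, min_taxon_total = 1000) {
  m <- taxa_matrix(counts)
  m <- m[rowSums(m) >= min_sample_total, , drop = FALSE]
  if (nrow(m) == 0) stop("every sample filtered out", call. = FALSE)
  keep <- colSums(m > 0) >= min_prevalence & colSums(m) >= min_taxon_total
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0) stop("every taxon filtered out", call. = FALSE)
  matrix_to_taxa(m)
}

#' ANCOM W statistic between two groups of samples
#'
#' Zeros are replaced by a pseudocount of 1. For each taxon i, the log
#' ratio log(count_i / count_j) is tested against every other taxon j by a
#' two-sided Wilcoxon rank-sum test between the groups, with
#' Benjamini-Hochberg correction within taxon i's m - 1 tests; W_i is the
#' number of rejections at `alpha`. The CLR value of a taxon in a sample
#' is log(count / geometric mean over retained taxa);
#' `clr_diff` is the difference of group means (group a minus group b). A
#' taxon is flagged differential when |clr_diff| > `clr_cut` and W_i is at
#' or above the empirical 90th percentile of the W distribution.
#'
#' @param counts Filtered wide count tibble (see [ancom_filter()]).
#' @param groups Two-level group label per sample (site pair).
#' @param alpha Per-ratio rejection level. Default 0.05.
#' @param clr_cut CLR mean-difference cutoff. Default 0.5.
#' @param w_quantile Percentile of the W distribution. Default 0.9.
#' @return Tibble: `species`, `group_a`, `group_b`, `W`, `clr_diff`,
#'   `differential`.
#' @export
ancom_w <- function(counts, groups, alpha = 0.05, clr_cut = 0.5,
                    w_quantile = 0.9) {
  m <- taxa_matrix(counts)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("ANCOM contrast needs exactly two groups",
                             call. = FALSE)
  if (length(groups) != nrow(m)) {
    stop("groups must match the samples", call. = FALSE)
  }
  if (min(table(groups)) < 2) stop("each group needs >= 2 samples",
                                   call. = FALSE)
  if (ncol(m) < 2) stop("need at least two taxa", call. = FALSE)
  m[m == 0] <- 1
  lg <- log(m)
  ntax <- ncol(lg)
  ga <- groups == lev[1]

  w <- integer(ntax)
  for (i in seq_len(ntax)) {
    lr <- lg[, i] - lg[, -i, drop = FALSE]
    pv <- vapply(seq_len(ncol(lr)), function(j) {
      suppressWarnings(stats::wilcox.test(lr[ga, j], lr[!ga, j],
                                          exact = FALSE)$p.value)
    }, numeric(1))
    w[i] <- sum(stats::p.adjust(pv, method = "BH") < alpha)
  }

  clr <- lg - rowMeans(lg)
  clr_diff <- colMeans(clr[ga, , drop = FALSE]) -
    colMeans(clr[!ga, , drop = FALSE])
  w_cut <- quantile(w, w_quantile)
  tibble::tibble(species = colnames(m), group_a = lev[1], group_b = lev[2],
                 W = w, clr_diff = unname(clr_diff),
                 differential = abs(clr_diff) > clr_cut & w >= w_cut)
}

#' Pairwise ANCOM contrasts between sites
#'
#' Runs [ancom_w()] for every pair of the named sites (or all site pairs).
#'
#' @param counts Filtered wide count tibble.
#' @param metadata Metadata with `sample_id` and `site`.
#' @param sites Sites to contrast (default: all present among the counts).
#' @inheritParams ancom_w
#' @return Row-bound result tibble over site pairs.
#' @export
ancom_pairwise <- function(counts, metadata, sites = NULL, alpha = 0.05,
                           clr_cut = 0.5, w_quantile = 0.9) {
  site_of <- metadata$site[match(counts$sample_id, metadata$sample_id)]
  sites <- sites %||% sort(unique(site_of))
  pairs <- utils::combn(sites, 2)
  dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    sel <- site_of %in% c(a, b)
    sub <- counts[sel, , drop = FALSE]
    grp <- factor(site_of[sel], levels = c(a, b))
    ancom_w(sub, as.character(grp), alpha = alpha, clr_cut = clr_cut,
            w_quantile = w_quantile)
  }))
}
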