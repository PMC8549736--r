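# One-vs-rest differential BGC abundance: simplified negative-binomial
# Wald test on size-factor-normalized counts.

#' Sites with enough samples for enrichment testing
#'
#' @param metadata Sample metadata tibble with a `site` column.
#' @param min_samples Minimum samples per site. Default 200.
#' @return Character vector of qualifying sites (may be empty).
#' @export
select_enrichment_sites <- function(metadata, min_samples = 200) {
  tab <- table(metadata$site)
  names(tab)[tab >= min_samples]
}

#' One-vs-rest negative-binomial Wald enrichment test
#'
#' For each BGC, compares its mean normalized count in the focal site
#' (mu_F) against all other sites pooled (mu_R). The log2 fold change is
#' log2(mu_F / mu_R); a per-BGC dispersion is estimated by method of
#' moments pooled within groups, alpha = max(alpha_min,
#' (s^2 - mu) / mu^2); the standard error of the LFC follows from the NB
#' variance mu + alpha mu^2 by the delta method; Wald z = LFC / SE with a
#' two-sided normal p value and Benjamini-Hochberg adjustment across BGCs
#' within the contrast. A BGC is called enriched when LFC >=
#' log2(min_fold) (inclusive) and the adjusted p value is below
#' `max_padj`.
#'
#' @param m A normalized `bgc_counts` object.
#' @param metadata Sample metadata (sample_id, site).
#' @param focal_site Site to contrast against the rest.
#' @param min_fold Fold-change threshold (default 4).
#' @param max_padj Adjusted-p threshold (default 1e-8).
#' @param alpha_min Dispersion floor (default 1e-8).
#' @return Tibble: `bgc_id`, `site`, `lfc`, `se`, `p`, `padj`, `enriched`.
#' @export
nb_wald_one_vs_rest <- function(m, metadata, focal_site, min_fold = 4,
                                max_padj = 1e-8, alpha_min = 1e-8) {
  stopifnot(inherits(m, "bgc_counts"))
  if (m$state != "normalized") {
    stop("counts must be size-factor normalized", call. = FALSE)
  }
  x <- m$normalized
  site_of <- metadata$site[match(colnames(x), metadata$sample_id)]
  if (anyNA(site_of)) stop("samples missing from metadata", call. = FALSE)
  focal <- site_of == focal_site
  if (!any(focal)) stop("focal group is empty: ", focal_site, call. = FALSE)
  if (all(focal)) stop("rest group is empty", call. = FALSE)

  xf <- x[, focal, drop = FALSE]
  xr <- x[, !focal, drop = FALSE]
  nf <- ncol(xf); nr <- ncol(xr)
  mu_f <- rowMeans(xf)
  mu_r <- rowMeans(xr)
  v_f <- apply(xf, 1, var)
  v_r <- apply(xr, 1, var)
  s2 <- ((nf - 1) * v_f + (nr - 1) * v_r) / (nf + nr - 2)
  mu_bar <- (nf * mu_f + nr * mu_r) / (nf + nr)
  alpha <- pmax(alpha_min, (s2 - mu_bar) / mu_bar^2)

  lfc <- log2(mu_f / mu_r)
  se <- sqrt((mu_f + alpha * mu_f^2) / (nf * mu_f^2) +
               (mu_r + alpha * mu_r^2) / (nr * mu_r^2)) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(bgc_id = rownames(x), site = focal_site,
                 lfc = unname(lfc), se = unname(se), p = unname(p),
                 padj = unname(padj),
                 enriched = unname(lfc >= log2(min_fold) & padj < max_padj))
}

#' Run the one-vs-rest enrichment test for every qualifying site
#'
#' @inheritParams nb_wald_one_vs_rest
#' @param min_samples Passed to [select_enrichment_sites()].
#' @return Row-bound enrichment tibble over all qualifying sites.
#' @export
enrichment_all_sites <- function(m, metadata, min_samples = 200,
                                 min_fold = 4, max_padj = 1e-8,
                                 alpha_min = 1e-8) {
  sites <- select_enrichment_sites(metadata, min_samples)
  if (length(sites) == 0) {
    warning("no site reaches ", min_samples, " samples", call. = FALSE)
    return(tibble::tibble(bgc_id = character(), site = character(),
                          lfc = numeric(), se = numeric(), p = numeric(),
                          padj = numeric(), enriched = logical()))
  }
  dplyr::bind_rows(lapply(sites, function(s) {
    nb_wald_one_vs_rest(m, metadata, s, min_fold = min_fold,
                        max_padj = max_padj, alpha_min = alpha_min)
  }))
}
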