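# Alpha diversity (Shannon H', richness, equitability) and supporting
# univariate statistics.

#' Shannon diversity metrics for abundance profiles
#'
#' Proportions are taken over the positive entries of each profile;
#' H' = -sum p_i ln p_i (natural log), richness S is the number of
#' positive entries, and equitability E_H = H'/ln(S) for S >= 2 (undefined,
#' `NA`, when S <= 1).
#'
#' @param x Nonnegative numeric vector, or a matrix / wide tibble (rows =
#'   samples; a `sample_id` column is honored).
#' @return One-row tibble (vector input) or one row per sample, with
#'   columns `shannon`, `richness`, `equitability` (and `sample_id` for
#'   multi-sample input).
#' @export
shannon_metrics <- function(x) {
  if (is.data.frame(x)) {
    m <- taxa_matrix(x)
    res <- t(apply(m, 1, shannon_one))
    return(dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                            tibble::as_tibble(res)))
  }
  if (is.matrix(x)) {
    res <- t(apply(x, 1, shannon_one))
    out <- tibble::as_tibble(res)
    if (!is.null(rownames(x))) {
      out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), out)
    }
    return(out)
  }
  tibble::as_tibble(as.list(shannon_one(x)))
}

shannon_one <- function(x) {
  if (any(x < 0) || all(x == 0)) {
    stop("profile must be nonnegative with positive sum", call. = FALSE)
  }
  p <- x[x > 0] / sum(x)
  h <- -sum(p * log(p))
  s <- length(p)
  c(shannon = h, richness = s,
    equitability = if (s >= 2) h / log(s) else NA_real_)
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Computes the tie-corrected Kruskal-Wallis H across groups, the epsilon
#' squared effect size H/(n-1), Dunn's pairwise z tests with
#' Benjamini-Hochberg adjustment across all pairs jointly, and a compact
#' letter display (groups sharing a letter are not significantly different
#' at `alpha`), built greedily over groups sorted by decreasing median.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (same length).
#' @param alpha Significance level for the letter display. Default 0.05.
#' @return A `kruskal_dunn` object with elements `statistic` (H), `df`,
#'   `p_value`, `epsilon_sq`, `pairwise` (tibble: group_a, group_b, z, p,
#'   p_adj), `letters` (tibble: group, median, letters).
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups", call. = FALSE)
  if (any(tab == 0)) stop("empty group", call. = FALSE)
  kw <- stats::kruskal.test(values, factor(groups))
  n <- length(values)
  eps2 <- unname(kw$statistic) / (n - 1)

  # Dunn z statistics on joint midranks, tie-corrected
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  gl <- names(tab)
  mean_r <- tapply(r, groups, mean)
  pairs <- utils::combn(gl, 2)
  z <- apply(pairs, 2, function(p) {
    ni <- tab[[p[1]]]; nj <- tab[[p[2]]]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    (mean_r[[p[1]]] - mean_r[[p[2]]]) / se
  })
  pw <- tibble::tibble(group_a = pairs[1, ], group_b = pairs[2, ],
                       z = z, p = 2 * stats::pnorm(-abs(z)))
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")

  med <- sort(tapply(values, groups, median), decreasing = TRUE)
  ns_pair <- function(a, b) {
    hit <- (pw$group_a == a & pw$group_b == b) |
      (pw$group_a == b & pw$group_b == a)
    pw$p_adj[hit] >= alpha
  }
  letter_sets <- list()
  for (g in names(med)) {
    placed <- FALSE
    for (i in seq_along(letter_sets)) {
      if (all(vapply(letter_sets[[i]], ns_pair, logical(1), b = g))) {
        letter_sets[[i]] <- c(letter_sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) letter_sets[[length(letter_sets) + 1]] <- g
  }
  lets <- vapply(names(med), function(g) {
    paste(letters[which(vapply(letter_sets, function(s) g %in% s,
                               logical(1)))], collapse = "")
  }, character(1))

  structure(list(statistic = unname(kw$statistic),
                 df = unname(kw$parameter),
                 p_value = kw$p.value,
                 epsilon_sq = eps2,
                 n = n,
                 pairwise = pw,
                 letters = tibble::tibble(group = names(med),
                                          median = as.numeric(med),
                                          letters = unname(lets))),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g (df = %d), p = %.3g, eps^2 = %.3g\n",
              x$statistic, x$df, x$p_value, x$epsilon_sq))
  print(x$letters)
  invisible(x)
}

#' Paired sign test
#'
#' Ties are dropped; S counts pairs with `a > b`; the p value is the
#' two-sided exact binomial probability under p = 1/2.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return Tibble with `S`, `n` (pairs after tie removal) and `p_value`.
#' @export
sign_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length",
                                   call. = FALSE)
  keep <- a != b
  if (!any(keep)) stop("all pairs are tied", call. = FALSE)
  s <- sum(a[keep] > b[keep])
  n <- sum(keep)
  tibble::tibble(S = s, n = n,
                 p_value = stats::binom.test(s, n, 0.5)$p.value)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected tau_B with the standard normal approximation for the p
#' value.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Tibble with `tau_b` and `p_value`.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("tau_B undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  tibble::tibble(tau_b = unname(ct$estimate), p_value = ct$p.value)
}

#' Per-site linear models of BGC diversity on species diversity
#'
#' Pairs with species-level H' of 0 are removed; for each site (and
#' pooled, as `"overall"`), ordinary least squares of `h_bgc` on
#' `h_species` yields R^2 and the slope F-test p value. Sites left with
#' fewer than 3 pairs are skipped with a warning.
#'
#' @param data Tibble with columns `h_species`, `h_bgc`, `site`.
#' @return Tibble with `site`, `n`, `r_squared`, `p_value`, `slope`,
#'   `intercept`.
#' @export
diversity_regression <- function(data) {
  stopifnot(all(c("h_species", "h_bgc", "site") %in% names(data)))
  data <- data[data$h_species > 0, ]
  fit_one <- function(d, label) {
    if (nrow(d) < 3) {
      warning("site ", label, " skipped: fewer than 3 pairs", call. = FALSE)
      return(NULL)
    }
    m <- stats::lm(h_bgc ~ h_species, data = d)
    sm <- suppressWarnings(summary(m)) # exact fits trip a precision warning
    pv <- if (sm$fstatistic[["value"]] >= 0 && nrow(d) > 2) {
      stats::pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
                sm$fstatistic[["dendf"]], lower.tail = FALSE)
    } else NA_real_
    tibble::tibble(site = label, n = nrow(d), r_squared = sm$r.squared,
                   p_value = pv, slope = stats::coef(m)[["h_species"]],
                   intercept = stats::coef(m)[["(Intercept)"]])
  }
  per_site <- dplyr::bind_rows(lapply(split(data, data$site), function(d) {
    fit_one(d, d$site[1])
  }))
  dplyr::bind_rows(per_site, fit_one(data, "overall"))
}
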