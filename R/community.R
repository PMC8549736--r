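# Beta diversity and clustering: Bray-Curtis, ANOSIM, NMDS, Ward
# dendrograms, cluster purity, clustering-agreement Jaccard.

#' Filter a species relative-abundance table before ordination
#'
#' Entries below `min_ra` are zeroed; species observed at relative
#' abundance 1.0 in any sample are removed; species with nonzero entries
#' in fewer than `min_prevalence` samples are removed.
#'
#' @param taxa Wide taxa tibble (`sample_id` + one column per species).
#' @param min_ra Minimum within-sample relative abundance (default 0.001,
#'   i.e. 0.1%).
#' @param min_prevalence Minimum number of samples a species must occur in
#'   (default 25).
#' @return Filtered taxa tibble.
#' @export
species_filter <- function(taxa, min_ra = 0.001, min_prevalence = 25) {
  m <- taxa_matrix(taxa)
  m[m < min_ra] <- 0
  mono <- apply(m, 2, function(x) any(x >= 1 - 1e-12))
  m <- m[, !mono, drop = FALSE]
  prev <- colSums(m > 0)
  m <- m[, prev >= min_prevalence, drop = FALSE]
  if (ncol(m) == 0) stop("species filter removed every species", call. = FALSE)
  matrix_to_taxa(m)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(u, v) = sum |u_i - v_i| / sum (u_i + v_i) over nonnegative profiles.
#'
#' @param profiles Samples x features matrix, or wide tibble with a
#'   `sample_id` column.
#' @return A `dist` object with sample labels; attribute `metric` is
#'   `"bray"`.
#' @export
bray_curtis <- function(profiles) {
  m <- if (is.data.frame(profiles)) taxa_matrix(profiles) else
    as.matrix(profiles)
  if (any(m < 0)) stop("profiles must be nonnegative", call. = FALSE)
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2) {
    stop("Bray-Curtis undefined between all-zero profiles: ",
         paste(head(rownames(m)[zero], 5), collapse = ", "), call. = FALSE)
  }
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "metric") <- "bray"
  d
}

# dist vector index for pairs in row-major (i < j) order
dist_rowmajor_index <- function(n) {
  i <- rep.int(seq_len(n - 1), rev(seq_len(n - 1)))
  j <- unlist(lapply(seq_len(n - 1), function(a) seq(a + 1, n)))
  n * (i - 1) - i * (i - 1) / 2 + (j - i)
}

#' Analysis of similarities (ANOSIM)
#'
#' All pairwise dissimilarities are ranked jointly (midranks for ties);
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4).
#' The p value is `(1 + #[R_perm >= R_obs]) / (1 + n_perm)` under random
#' relabeling of samples.
#'
#' @param d A `dist` object (e.g. from [bray_curtis()]).
#' @param groups Group labels, aligned with the rows of `d`.
#' @param n_perm Number of permutations. Default 10000.
#' @param seed Optional integer seed for the permutation stream.
#' @return An `adt_anosim` object with `R`, `p_value`, `n_perm`,
#'   `perm_r` (the permuted statistics).
#' @export
anosim <- function(d, groups, n_perm = 10000, seed = NULL) {
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must match the distance matrix",
                                call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2)) stop("every group needs at least two samples",
                         call. = FALSE)
  rk <- rank(as.numeric(d))[dist_rowmajor_index(n)]
  if (!is.null(seed)) set.seed(seed)
  res <- .cpp_anosim(rk, as.integer(factor(groups)) - 1L, n,
                     as.integer(n_perm))
  structure(list(R = res$r_obs,
                 p_value = (1 + sum(res$r_perm >= res$r_obs)) / (1 + n_perm),
                 n_perm = as.integer(n_perm),
                 perm_r = as.numeric(res$r_perm),
                 groups = groups),
            class = "adt_anosim")
}

#' @export
print.adt_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4g, p = %.4g (%d permutations)\n",
              x$R, x$p_value, x$n_perm))
  invisible(x)
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes stress-1 = sqrt(sum (d_config - d_hat)^2 / sum d_config^2),
#' where d_hat is the isotonic regression of configuration distances on
#' the rank order of the input dissimilarities (primary tie treatment),
#' by iterated Guttman transforms. The first start is classical scaling;
#' up to `trymax - 1` further random starts are tried, stopping early
#' after `no_improve` starts without improvement. The best configuration
#' is centered and rotated to its principal axes.
#'
#' @param d A `dist` object.
#' @param k Embedding dimension. Default 2.
#' @param trymax Maximum number of starts. Default 100.
#' @param seed Optional seed for the random starts.
#' @param maxit Majorization iterations per start. Default 300.
#' @param tol Relative stress-change convergence tolerance. Default 1e-7.
#' @param no_improve Early stop after this many non-improving starts.
#' @return An `adt_nmds` object with `points` (n x k), `stress`,
#'   `n_restarts`, `converged`.
#' @export
nmds <- function(d, k = 2, trymax = 100, seed = NULL, maxit = 300,
                 tol = 1e-7, no_improve = 10) {
  dv <- as.numeric(d)
  if (any(!is.finite(dv))) stop("non-finite dissimilarities", call. = FALSE)
  n <- attr(d, "Size")
  if (n < 4) stop("NMDS needs at least 4 points", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))

  run_one <- function(x0) {
    x <- x0
    dc <- as.numeric(stats::dist(x))
    stress_prev <- Inf
    converged <- FALSE
    for (it in seq_len(maxit)) {
      ord <- order(dv, dc)
      fit <- stats::isoreg(dc[ord])$yf
      dhat <- numeric(length(dc))
      dhat[ord] <- fit
      denom <- sum(dc^2)
      stress <- sqrt(sum((dc - dhat)^2) / denom)
      if (is.finite(stress_prev) &&
          abs(stress_prev - stress) < tol * max(stress, 1e-12)) {
        converged <- TRUE
        stress_prev <- stress
        break
      }
      stress_prev <- stress
      # Guttman transform with disparities dhat
      ratio <- ifelse(dc > 0, dhat / dc, 0)
      B <- matrix(0, n, n)
      B[lower.tri(B)] <- -ratio
      B <- B + t(B)
      diag(B) <- -rowSums(B)
      x <- (B %*% x) / n
      dc <- as.numeric(stats::dist(x))
    }
    list(x = x, stress = stress_prev, converged = converged)
  }

  # dist() fills lower triangle columnwise, matching as.numeric(d)
  best <- NULL
  n_runs <- 0L
  stale <- 0L
  x0 <- tryCatch(stats::cmdscale(d, k = k),
                 error = function(e) matrix(rnorm(n * k), n, k))
  if (ncol(x0) < k) x0 <- cbind(x0, matrix(0, n, k - ncol(x0)))
  repeat {
    n_runs <- n_runs + 1L
    run <- run_one(x0)
    if (is.null(best) || run$stress < best$stress - 1e-9) {
      best <- run
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (n_runs >= trymax || stale >= no_improve) break
    x0 <- matrix(rnorm(n * k), n, k)
  }

  x <- scale(best$x, center = TRUE, scale = FALSE)
  rot <- stats::prcomp(x, center = FALSE)$rotation
  x <- x %*% rot
  dimnames(x) <- list(labels, paste0("NMDS", seq_len(k)))
  structure(list(points = x, stress = best$stress, n_restarts = n_runs,
                 converged = best$converged),
            class = "adt_nmds")
}

#' @export
print.adt_nmds <- function(x, ...) {
  cat(sprintf("NMDS (%d points, k = %d): stress = %.4g after %d start(s)%s\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_restarts,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Ward clustering of samples with per-cluster site purity
#'
#' Agglomerates samples by Ward's minimum-variance method on squared
#' Euclidean distances of the (by default log10-transformed) profiles,
#' cuts the tree at `K` clusters, and reports each cluster's majority
#' site and purity (fraction of members from the majority site).
#'
#' @param x Samples x features matrix or wide tibble, or a normalized
#'   `bgc_counts` object (transposed and log10-transformed internally).
#' @param sites Site label per sample (required for purity).
#' @param K Number of flat clusters; defaults to the number of distinct
#'   sites.
#' @param transform Transform applied to the values before clustering
#'   (default `log10`; use `identity` for none).
#' @return An `adt_ward` object with `hclust`, `labels`, `purity`
#'   (tibble: cluster, size, majority_site, purity) and `K`.
#' @export
ward_cluster <- function(x, sites = NULL, K = NULL, transform = log10) {
  if (inherits(x, "bgc_counts")) {
    if (x$state != "normalized") stop("normalize counts first", call. = FALSE)
    m <- t(x$normalized)
  } else if (is.data.frame(x)) {
    m <- taxa_matrix(x)
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) < 2) stop("need at least two samples", call. = FALSE)
  m <- transform(m)
  d2 <- stats::dist(m)^2
  hc <- stats::hclust(d2, method = "ward.D")
  if (is.null(K)) {
    if (is.null(sites)) stop("supply K or sites", call. = FALSE)
    K <- length(unique(sites))
  }
  if (K > nrow(m)) stop("K exceeds the number of samples", call. = FALSE)
  labels <- stats::cutree(hc, k = K)
  purity <- NULL
  if (!is.null(sites)) {
    purity <- dplyr::bind_rows(lapply(sort(unique(labels)), function(cl) {
      s <- sites[labels == cl]
      tab <- sort(table(s), decreasing = TRUE)
      tibble::tibble(cluster = cl, size = length(s),
                     majority_site = names(tab)[1],
                     purity = as.numeric(tab[1]) / length(s))
    }))
  }
  structure(list(hclust = hc, labels = labels, purity = purity, K = K),
            class = "adt_ward")
}

#' @export
print.adt_ward <- function(x, ...) {
  cat(sprintf("Ward clustering: %d samples cut at K = %d\n",
              length(x$labels), x$K))
  if (!is.null(x$purity)) print(x$purity)
  invisible(x)
}

#' Export a Ward dendrogram as Newick
#'
#' @param ward An `adt_ward` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(ward, path) {
  ape::write.tree(ape::as.phylo(ward$hclust), file = path)
  invisible(path)
}

#' Pair-counting Jaccard agreement between two clusterings
#'
#' Over all unordered sample pairs, J = n11 / (n11 + n10 + n01), where
#' n11 counts pairs co-clustered in both partitions and n10/n01 pairs
#' co-clustered in exactly one.
#'
#' @param labels_a,labels_b Cluster labels over the same samples.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
clustering_jaccard <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(labels_a) < 2) stop("need at least two samples", call. = FALSE)
  ut <- upper.tri(matrix(0, length(labels_a), length(labels_a)))
  ca <- outer(labels_a, labels_a, "==")[ut]
  cb <- outer(labels_b, labels_b, "==")[ut]
  union <- sum(ca | cb)
  if (union == 0) return(1) # both all-singleton partitions agree trivially
  sum(ca & cb) / union
}
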