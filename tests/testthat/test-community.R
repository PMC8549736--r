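test_that("species filter zeroes rare entries and drops listed species", {
  taxa <- matrix_to_taxa_helper(rbind(
    s1 = c(sub = 9e-4, mono = 1.0, keep = 0.02, rare = 0.05),
    s2 = c(sub = 9e-4, mono = 0.2, keep = 0.03, rare = 0),
    s3 = c(sub = 9e-4, mono = 0.1, keep = 0.04, rare = 0)))
  out <- species_filter(taxa, min_ra = 0.001, min_prevalence = 2)
  expect_false("sub" %in% names(out))   # always below threshold
  expect_false("mono" %in% names(out))  # hits RA 1.0 once
  expect_true("keep" %in% names(out))
  expect_false("rare" %in% names(out))  # prevalence 1 < 2
  expect_error(species_filter(taxa, min_ra = 0.5, min_prevalence = 4),
               "every species")
})

test_that("Bray-Curtis matches its closed form", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0),
             d = c(2, 0, 0), e = c(0, 0, 3))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["d", "e"], 1)
  expect_equal(d["a", "b"], 0.5)
  expect_error(bray_curtis(rbind(x = c(0, 0), y = c(0, 0))), "all-zero")
})

test_that("ANOSIM equals exhaustive relabeling on a 6-sample fixture", {
  set.seed(5)
  x <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 4), 3, 2))
  rownames(x) <- paste0("s", 1:6)
  d <- stats::dist(x)
  grp <- rep(c("g1", "g2"), each = 3)
  res <- anosim(d, grp, n_perm = 10000, seed = 1)

  # oracle: R for every distinct 3/3 relabeling
  rk <- matrix(0, 6, 6)
  rk[lower.tri(rk)] <- rank(as.numeric(d))
  rk <- rk + t(rk)
  r_for <- function(lab) {
    within <- outer(lab, lab, "==")
    ut <- upper.tri(rk)
    (mean(rk[ut & !within]) - mean(rk[ut & within])) / (6 * 5 / 4)
  }
  combos <- utils::combn(6, 3)
  r_all <- apply(combos, 2, function(ix) {
    lab <- rep("b", 6); lab[ix] <- "a"; r_for(lab)
  })
  expect_equal(res$R, r_for(grp), tolerance = 1e-12)
  p_exact <- mean(r_all >= res$R - 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.02)

  # cross-check against the reference ecology implementation
  ref <- vegan::anosim(d, grouping = factor(grp), permutations = 99)
  expect_equal(res$R, unname(ref$statistic), tolerance = 1e-12)
})

test_that("ANOSIM reaches 1 under full separation and 0 on noise", {
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 50, 0.1), 5, 2))
  d <- stats::dist(x)
  res <- anosim(d, rep(c("a", "b"), each = 5), n_perm = 500, seed = 2)
  expect_equal(res$R, 1)

  set.seed(9)
  dn <- stats::dist(matrix(rnorm(40), 20, 2))
  null <- anosim(dn, sample(rep(c("a", "b"), each = 10)), n_perm = 2000,
                 seed = 3)
  expect_lt(abs(mean(null$perm_r)), 0.05)
  # rank-based: invariant under monotone transforms of the distances
  labs <- sample(rep(c("a", "b"), each = 10))
  mono <- anosim(dn^2, labs, n_perm = 10, seed = 4)
  direct <- anosim(dn, labs, n_perm = 10, seed = 4)
  expect_equal(mono$R, direct$R)
})

test_that("NMDS recovers planar configurations and matches vegan", {
  set.seed(11)
  pts <- matrix(rnorm(20), 10, 2)
  d <- stats::dist(pts)
  fit <- nmds(d, k = 2, trymax = 10, seed = 1)
  expect_lt(fit$stress, 1e-3)

  # order invariance: permuting the input leaves the stress unchanged
  perm <- sample(10)
  dp <- stats::dist(pts[perm, ])
  fit_p <- nmds(dp, k = 2, trymax = 10, seed = 1)
  expect_lt(abs(fit$stress - fit_p$stress), 1e-6)

  # four-point fixture against an independent implementation
  d4 <- stats::dist(rbind(c(0, 0), c(1, 0.1), c(0.2, 1.2), c(1.1, 1)))
  ours <- nmds(d4, k = 2, trymax = 20, seed = 2)
  ref <- vegan::monoMDS(d4, k = 2, model = "global")
  expect_lt(abs(ours$stress - ref$stress), 1e-3)

  # stress is non-increasing in the embedding dimension
  set.seed(13)
  dd <- stats::dist(matrix(rnorm(24), 8, 3))
  s1 <- nmds(dd, k = 1, trymax = 15, seed = 3)$stress
  s2 <- nmds(dd, k = 2, trymax = 15, seed = 3)$stress
  expect_lte(s2, s1 + 1e-6)

  expect_error(nmds(stats::dist(rbind(c(0, 0), c(1, 1), c(2, 2))), k = 2),
               "4 points")
})

test_that("Ward clustering matches a brute-force criterion search", {
  set.seed(17)
  x <- matrix(rnorm(12), 6, 2)
  rownames(x) <- paste0("s", 1:6)
  wc <- ward_cluster(x, K = 2, transform = identity)

  # O(n^3) oracle: merge the pair minimizing the Ward cost
  clusters <- as.list(seq_len(6))
  merges <- list()
  for (step in 1:5) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(x[a, , drop = FALSE])
      cb <- colMeans(x[b, , drop = FALSE])
      cost <- length(a) * length(b) / (length(a) + length(b)) *
        sum((ca - cb)^2)
      if (is.null(best) || cost < best$cost) {
        best <- list(cost = cost, i = i, j = j)
      }
    }
    merges[[step]] <- sort(unlist(clusters[c(best$i, best$j)]))
    clusters[[best$j]] <- c(clusters[[best$j]], clusters[[best$i]])
    clusters[[best$i]] <- NULL
  }

  # reconstruct merged member sets from the hclust merge matrix
  hm <- wc$hclust$merge
  sets <- list()
  for (s in seq_len(nrow(hm))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(grab(hm[s, 1]), grab(hm[s, 2])))
  }
  expect_equal(sets, merges)
})

test_that("Ward purity is 1 for separated blobs and duplicates merge first", {
  x <- rbind(matrix(rnorm(10, 0, 0.05), 5, 2),
             matrix(rnorm(10, 10, 0.05), 5, 2))
  wc <- ward_cluster(x, sites = rep(c("a", "b"), each = 5),
                     transform = identity)
  expect_equal(wc$K, 2)
  expect_equal(wc$purity$purity, c(1, 1))

  y <- rbind(c(1, 1), c(5, 5), c(1, 1), c(9, 0))
  wcd <- ward_cluster(y, K = 2, transform = identity)
  expect_equal(sort(abs(wcd$hclust$merge[1, ])), c(1, 3))
  expect_equal(wcd$hclust$height[1], 0)

  expect_error(ward_cluster(y, K = 9, transform = identity), "K exceeds")
})

test_that("pair-counting Jaccard agrees with manual enumeration", {
  expect_equal(clustering_jaccard(c(1, 1, 2, 2), c(7, 7, 9, 9)), 1)
  expect_equal(clustering_jaccard(1:4, rep(1, 4)), 0)
  # 6-sample fixture: co-pairs a = {12,13,23,45}, b = {12,34,35,45}
  a <- c(1, 1, 1, 2, 2, 3)
  b <- c(1, 1, 2, 2, 2, 3)
  expect_equal(clustering_jaccard(a, b), 2 / 6)
  expect_error(clustering_jaccard(1, 1), "two samples")
})

test_that("dendrograms export as parseable Newick", {
  x <- matrix(rnorm(12), 6, 2)
  rownames(x) <- paste0("s", 1:6)
  wc <- ward_cluster(x, K = 2, transform = identity)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(wc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(x))
})
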