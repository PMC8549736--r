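test_that("sequence sanitization replaces exactly the ambiguity codes", {
  clean <- sanitize_sequences(c(a = "ACGT"), seed = 1)
  expect_equal(unname(clean["a"]), "ACGT")
  expect_equal(attr(clean, "n_replaced"), 0L)

  s <- sanitize_sequences(c(x = "ACNT"), seed = 1)
  expect_equal(nchar(s[["x"]]), 4)
  expect_equal(substr(s[["x"]], 1, 2), "AC")
  expect_equal(substr(s[["x"]], 4, 4), "T")
  expect_true(substr(s[["x"]], 3, 3) %in% c("A", "C", "G", "T"))
  expect_equal(attr(s, "n_replaced"), 1L)

  messy <- c(m = "ANNRYACGTSWK") # seven ambiguity codes
  expect_equal(attr(sanitize_sequences(messy, seed = 3), "n_replaced"), 7L)
  expect_error(sanitize_sequences(c(ok = "ACGT", bad = "")), "bad")
})

test_that("index construction builds canonical k-mer classes", {
  one <- c(t1 = random_dna(31, seed = 5))
  idx <- build_index(one, k = 31)
  expect_equal(idx$n_kmers, 1)
  expect_equal(index_classes(idx), list("t1"))
  expect_equal(unname(idx$effective_length), 1)

  two <- c(a = random_dna(60, seed = 6))
  two <- c(two, b = unname(two))
  idx2 <- build_index(two, k = 31)
  expect_true(all(vapply(index_classes(idx2), identical, logical(1),
                         c("a", "b"))))

  expect_warning(build_index(c(short = "ACGT", long = random_dna(40, 1)),
                             k = 31), "skipped")
})

test_that("index classes agree with brute-force k-mer enumeration", {
  set.seed(8)
  shared <- random_dna(40)
  seqs <- c(s1 = paste0(random_dna(25), shared),
            s2 = paste0(shared, random_dna(30)),
            s3 = paste0(random_dna(18), shared, random_dna(12)))
  k <- 31
  idx <- build_index(seqs, k = k)

  oracle <- list()
  for (nm in names(seqs)) {
    for (km in unique(oracle_kmers(seqs[[nm]], k))) {
      oracle[[km]] <- union(oracle[[km]], nm)
    }
  }
  oracle_classes <- table(vapply(oracle, function(x)
    paste(sort(x), collapse = ","), character(1)))
  got <- index_classes(idx)
  got_sizes <- table(vapply(got, function(x)
    paste(sort(x), collapse = ","), character(1)))
  expect_equal(idx$n_kmers, length(oracle))
  # per-class k-mer counts must match the enumeration
  dump <- adtbgc:::.cpp_index_dump(idx$ptr)
  per_class <- table(dump$class_id)
  got_kmer_counts <- sort(as.integer(per_class))
  oracle_kmer_counts <- sort(as.integer(table(vapply(
    oracle, function(x) paste(sort(x), collapse = ","), character(1)))))
  expect_equal(got_kmer_counts, oracle_kmer_counts)
  expect_setequal(names(got_sizes), names(oracle_classes))
})

test_that("pseudoalignment assigns by k-mer intersection, strand-blind", {
  seqs <- c(u1 = random_dna(120, seed = 21), u2 = random_dna(120, seed = 22))
  idx <- build_index(seqs, k = 31)

  frag <- substr(seqs[["u1"]], 30, 90)
  aln <- pseudoalign(idx, frag)
  expect_equal(aln$ec_targets[[aln$read_ec[1]]], "u1")

  aln_rc <- pseudoalign(idx, adtbgc:::revcomp(frag))
  expect_equal(aln_rc$ec_targets[[aln_rc$read_ec[1]]], "u1")

  aln_miss <- pseudoalign(idx, random_dna(60, seed = 99))
  expect_equal(aln_miss$read_ec[1], 0L)
  expect_equal(aln_miss$n_unassigned, 1L)

  aln_short <- pseudoalign(idx, "ACGTACGT")
  expect_equal(aln_short$n_too_short, 1L)
})

test_that("all counts are invariant to reverse-complementing every read", {
  cfg <- tiny_config(substitution_error_rate = 0.01)
  study <- simulate_study(cfg, simulate_reads = FALSE)
  sim <- suppressWarnings(simulate_sample_reads(
    study$metadata$sample_id[1], study$catalog, study$orf_fasta,
    study$taxa, study$metadata, study$truth, cfg))
  idx <- suppressWarnings(build_index(study$orf_fasta, k = 31))
  est_f <- em_quantify(pseudoalign(idx, sim$reads), idx)
  est_r <- em_quantify(pseudoalign(idx, adtbgc:::revcomp(sim$reads)), idx)
  expect_equal(est_f, est_r)
})

test_that("EM matches direct counting, symmetry and a likelihood oracle", {
  # all singleton classes: EM is direct counting
  seqs <- c(a = random_dna(100, seed = 31), b = random_dna(100, seed = 32))
  idx <- build_index(seqs, k = 31)
  reads <- c(substr(seqs[["a"]], 1, 40), substr(seqs[["a"]], 20, 70),
             substr(seqs[["b"]], 10, 55))
  est <- em_quantify(pseudoalign(idx, reads), idx)
  expect_equal(unname(est[c("a", "b")]), c(2, 1), tolerance = 1e-9)

  # one shared class, equal lengths: symmetric split
  dup <- c(a = random_dna(80, seed = 33))
  dup <- c(dup, b = unname(dup))
  idx2 <- build_index(dup, k = 31)
  reads2 <- rep(substr(dup[["a"]], 5, 60), 10)
  est2 <- em_quantify(pseudoalign(idx2, reads2), idx2)
  expect_equal(unname(est2[c("a", "b")]), c(5, 5), tolerance = 1e-6)

  # two-class toy {A}:6, {A,B}:4 against a grid-search maximizer of the
  # same multinomial likelihood
  aln_toy <- structure(list(
    ec_target_idx = list(1L, c(1L, 2L)),
    ec_targets = list("A", c("A", "B")),
    ec_counts = c(6, 4), n_unassigned = 0L, n_too_short = 0L,
    n_reads = 10L), class = "pseudoalignment")
  idx_toy <- list(target_ids = c("A", "B"),
                  effective_length = c(A = 70, B = 70))
  est3 <- em_quantify(aln_toy, idx_toy, max_iter = 5000, tol = 1e-9)

  loglik <- function(tha) {
    thb <- 10 - tha
    w <- c(tha, thb) / 70
    denom <- c(w[1], w[1] + w[2])
    sum(c(6, 4) * log(denom / sum(w)))
  }
  grid <- seq(0.001, 9.999, by = 0.001)
  opt <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  expect_equal(unname(est3[["A"]]), opt, tolerance = 1e-3)

  ll <- attr(est3, "loglik")
  expect_true(all(diff(ll) > -1e-9)) # EM monotonicity
})

test_that("ORF counts aggregate to BGCs with orphan detection", {
  cat2 <- dplyr::bind_rows(
    catalog_row("B1", orf_id = c("o1", "o2")),
    catalog_row("B2", orf_id = "o3"))
  expect_equal(aggregate_to_bgc(c(o1 = 2.2, o2 = 3.3, o3 = 0), cat2),
               c(B1 = 5.5, B2 = 0))
  expect_error(aggregate_to_bgc(c(zz = 1), cat2), "not present")

  # three-BGC fixture against hand sums
  cat3 <- dplyr::bind_rows(cat2, catalog_row("B3", orf_id = c("p1", "p2")))
  counts <- c(o1 = 1, o2 = 0.5, o3 = 7, p1 = 2, p2 = 0.25)
  expect_equal(aggregate_to_bgc(counts, cat3),
               c(B1 = 1.5, B2 = 7, B3 = 2.25))
})

test_that("count finalization drops undetected BGCs, rounds and adds one", {
  sc <- list(s1 = c(B1 = 2.5, B2 = 0, B3 = 1.2),
             s2 = c(B1 = 0.4, B2 = 0, B3 = 2.51))
  expect_message(m <- finalize_counts(sc), "1 BGC")
  expect_equal(m$state, "pseudocounted")
  expect_equal(rownames(m$counts), c("B1", "B3"))
  expect_equal(m$counts["B1", "s1"], 4)  # 2.5 -> 3 -> 4
  expect_equal(m$counts["B1", "s2"], 1)  # 0.4 -> 0 -> 1
  expect_equal(m$counts["B3", "s2"], 4)  # 2.51 -> 3 -> 4
  expect_true(all(m$counts >= 1))
})

test_that("size factors follow the median-of-ratios definition", {
  m1 <- structure(list(counts = cbind(s1 = c(3, 5, 7), s2 = c(6, 10, 14)),
                       state = "pseudocounted"), class = "bgc_counts")
  rownames(m1$counts) <- paste0("B", 1:3)
  n1 <- size_factor_normalize(m1)
  expect_equal(unname(n1$size_factors[2] / n1$size_factors[1]), 2)
  expect_equal(n1$normalized[, 1], n1$normalized[, 2])

  m2 <- structure(list(counts = matrix(4, 3, 3,
                                       dimnames = list(paste0("B", 1:3),
                                                       paste0("s", 1:3))),
                       state = "pseudocounted"), class = "bgc_counts")
  expect_equal(unname(size_factor_normalize(m2)$size_factors), rep(1, 3))

  # hand-computed 3x3 fixture: row geometric means 2, 4, 8
  m3 <- structure(list(counts = cbind(s1 = c(1, 2, 4), s2 = c(2, 4, 8),
                                      s3 = c(4, 8, 16)),
                       state = "pseudocounted"), class = "bgc_counts")
  rownames(m3$counts) <- paste0("B", 1:3)
  expect_equal(unname(size_factor_normalize(m3)$size_factors),
               c(0.5, 1, 2))

  single <- structure(list(counts = matrix(2, 2, 1,
                                           dimnames = list(c("B1", "B2"),
                                                           "s1")),
                           state = "pseudocounted"), class = "bgc_counts")
  expect_warning(size_factor_normalize(single), "single sample")
})

test_that("abundance filter applies a strict less-than cutoff", {
  mk <- function(rows) {
    structure(list(counts = rows, normalized = rows, state = "normalized"),
              class = "bgc_counts")
  }
  m <- mk(rbind(low = rep(99.9 / 4, 4), edge = rep(25, 4),
                high = rep(50, 4)))
  out <- abundance_filter(m, min_total = 100)
  expect_equal(rownames(out$normalized), c("edge", "high"))
  expect_error(abundance_filter(mk(rbind(x = rep(1, 4))), min_total = 100),
               "every BGC")
})

test_that("duplicating a sample's reads scales its size factor only", {
  # deep enough that the +1 pseudocount is negligible, and enough samples
  # that the doubled sample barely moves the per-BGC geometric means
  cfg <- tiny_config(samples_per_site = 8, reads_per_sample = 2000,
                     n_genomes = 3, bgc_per_genome_range = c(2, 2))
  study <- simulate_study(cfg, simulate_reads = FALSE)
  idx <- suppressWarnings(build_index(study$orf_fasta, k = 31))
  sims <- lapply(study$metadata$sample_id, function(sid) {
    suppressWarnings(simulate_sample_reads(
      sid, study$catalog, study$orf_fasta, study$taxa, study$metadata,
      study$truth, cfg))
  })
  bgc <- lapply(sims, function(s) {
    aggregate_to_bgc(em_quantify(pseudoalign(idx, s$reads), idx),
                     study$catalog)
  })
  names(bgc) <- study$metadata$sample_id
  base <- size_factor_normalize(suppressMessages(finalize_counts(bgc)))

  bgc_dup <- bgc
  reads_dup <- c(sims[[2]]$reads, sims[[2]]$reads)
  bgc_dup[[2]] <- aggregate_to_bgc(
    em_quantify(pseudoalign(idx, reads_dup), idx), study$catalog)
  dup <- size_factor_normalize(suppressMessages(finalize_counts(bgc_dup)))

  common <- intersect(rownames(base$normalized), rownames(dup$normalized))
  ratio <- dup$size_factors[2] / base$size_factors[2]
  expect_equal(unname(ratio), 2, tolerance = 0.15)
  rel <- abs(dup$normalized[common, 2] - base$normalized[common, 2]) /
    pmax(base$normalized[common, 2], 1)
  expect_lt(stats::median(rel), 0.05)
})

test_that("error-free reads over unique ORFs are recovered exactly", {
  cfg <- tiny_config()
  study <- simulate_study(cfg)
  idx <- suppressWarnings(build_index(study$orf_fasta, k = 31))
  sid <- study$metadata$sample_id[1]
  sim <- suppressWarnings(simulate_sample_reads(
    sid, study$catalog, study$orf_fasta, study$taxa, study$metadata,
    study$truth, cfg))
  aln <- pseudoalign(idx, sim$reads)
  est <- em_quantify(aln, idx)
  expect_equal(aln$n_unassigned + sum(aln$ec_counts), length(sim$reads))
  truth <- study$truth$orf_read_counts[names(est), sid]
  expect_equal(as.numeric(round(est)), as.numeric(truth))
  expect_equal(sum(est), sum(truth), tolerance = 1e-6)
})

test_that("a k-mer index survives a JSON round trip", {
  seqs <- c(a = random_dna(80, seed = 41), b = random_dna(90, seed = 42))
  idx <- build_index(seqs, k = 31)
  path <- withr::local_tempfile(fileext = ".json")
  write_index_json(idx, path)
  idx2 <- read_index_json(path)
  expect_equal(idx2$k, idx$k)
  expect_equal(idx2$target_ids, idx$target_ids)
  expect_equal(idx2$n_kmers, idx$n_kmers)
  frag <- substr(seqs[["b"]], 10, 70)
  a1 <- pseudoalign(idx, frag)
  a2 <- pseudoalign(idx2, frag)
  expect_equal(a1$ec_targets[[a1$read_ec[1]]],
               a2$ec_targets[[a2$read_ec[1]]])
})
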