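test_that("BGC distance components combine as documented", {
  expect_equal(bgc_distance("A;B;C", "A;B;C"), 0)
  expect_equal(bgc_distance("A;B", "C;D"), 1)
  expect_equal(bgc_distance("", ""), 1)

  # J = 1/2, AI = 1/3, DSS = 2/3 with weights (0.2, 0.05, 0.75)
  d <- bgc_distance("A;B;C", "A;B;D")
  expect_equal(d, 1 - (0.2 * 0.5 + 0.05 / 3 + 0.75 * 2 / 3),
               tolerance = 1e-12)

  expect_error(bgc_distance("A", "B", weights = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("BGC distance is a symmetric [0,1] quantity with zero diagonal", {
  set.seed(41)
  pool <- c("KS", "AT", "ACP", "C", "A", "TE")
  for (i in 1:25) {
    a <- sample(pool, sample(1:5, 1), replace = TRUE)
    b <- sample(pool, sample(1:5, 1), replace = TRUE)
    d1 <- bgc_distance(a, b)
    expect_equal(d1, bgc_distance(b, a))
    expect_gte(d1, 0)
    expect_lte(d1, 1)
    expect_equal(bgc_distance(a, a), 0)
  }
})

test_that("network families equal brute-force connected components", {
  cat6 <- dplyr::bind_rows(lapply(1:6, function(i) {
    catalog_row(paste0("N", i), orf_id = paste0("N", i, "_o1"),
                domain_string = c("KS;AT;ACP", "KS;AT;ACP", "KS;AT;TE",
                                  "C;A;TE", "C;A;TE", "Terp")[i],
                raw_types = "t1pks")
  }))
  dm <- bgc_distance_matrix(cat6)
  net <- build_bgc_network(cat6, dm, cutoff = 0.3)

  ids <- unique(cat6$bgc_id)
  oracle <- oracle_components(ids, net$edges$from, net$edges$to)
  split_net <- unname(split(net$nodes$bgc_id, net$nodes$family))
  split_oracle <- unname(split(names(oracle), oracle))
  expect_setequal(lapply(split_net, sort), lapply(split_oracle, sort))

  # all distances above cutoff: all singletons
  net_tight <- build_bgc_network(cat6, dm, cutoff = -0.01)
  expect_equal(length(unique(net_tight$nodes$family)), 6)

  # clique at distance 0 collapses into one family
  expect_true(all(net$nodes$family[1:2] == net$nodes$family[1]))

  # raising the cutoff never splits families (monotone coarsening)
  net_loose <- build_bgc_network(cat6, dm, cutoff = 0.9)
  fam_tight <- net$nodes$family
  fam_loose <- net_loose$nodes$family
  for (f in unique(fam_tight)) {
    members <- net$nodes$bgc_id[fam_tight == f]
    expect_equal(length(unique(fam_loose[net_loose$nodes$bgc_id %in%
                                           members])), 1)
  }

  bad <- dm[1:5, 1:5]
  expect_error(build_bgc_network(cat6, bad, cutoff = 0.3), "match")
})

test_that("precursor extraction gates on category and length", {
  cat_mix <- dplyr::bind_rows(
    catalog_row("R1", raw_types = "lantipeptide",
                orf_id = c("R1_small", "R1_big"),
                length_nt = c(450L, 451L)),
    catalog_row("P1", raw_types = "nrps", orf_id = "P1_small",
                length_nt = 300L),
    catalog_row("H1", raw_types = "nrps;bacteriocin", orf_id = "H1_small",
                length_nt = 120L))
  pep <- paste0("M", strrep("A", 20))
  nt_ok <- paste0(adtbgc:::reverse_translate(pep), "TAA")
  fasta <- c(R1_small = paste0(adtbgc:::reverse_translate(
    paste0("M", strrep("A", 148))), "TAA"),
    R1_big = random_dna(451, seed = 51),
    P1_small = nt_ok, H1_small = nt_ok)
  fasta["R1_small"] <- substr(fasta["R1_small"], 1, 450)

  out <- suppressWarnings(extract_precursor_orfs(cat_mix, fasta))
  expect_true("H1_small" %in% out$orf_id)   # hybrid containing a RiPP type
  expect_false("P1_small" %in% out$orf_id)  # NRPS-only BGC
  expect_false("R1_big" %in% out$orf_id)    # 451 nt > 450
})

test_that("the rule-based classifier scores hallmark features", {
  # 25 aa, GG motif, 4 Cys in the C-terminal half
  good <- "MAKELAQGGITCSTCCWNSTIANCG"
  res <- classify_precursor(tibble::tibble(orf_id = "g", precursor = good))
  expect_gte(res$score, 0.75)
  expect_true(res$passes)
  expect_equal(res$ripp_class, "lanthipeptide")

  expect_error(classify_precursor(
    tibble::tibble(orf_id = "x", precursor = "MKKAGGIT")), "10 aa")
  expect_error(classify_precursor(
    tibble::tibble(orf_id = "x", precursor = "MKKAGGITXZZAAAA")),
    "amino-acid")

  ext <- classify_precursor(
    tibble::tibble(orf_id = "g", precursor = good),
    scores = tibble::tibble(orf_id = "g", score = 0.74, class = "lasso"))
  expect_false(ext$passes)
})

test_that("leader cleavage follows the GG rule with midpoint fallback", {
  res <- cleave_leader("MKKAGGITCSTCC")
  expect_equal(res$leader, "MKKAGG")
  expect_equal(res$core, "ITCSTCC")

  no_gg <- cleave_leader("MKAVLITCSW")  # length 10, no GG
  expect_equal(nchar(no_gg$leader), 5)

  late_gg <- cleave_leader("MKAVLITCSWGG")  # GG only in the final third
  expect_equal(nchar(late_gg$leader), 6)

  set.seed(53)
  for (i in 1:20) {
    p <- paste(sample(c("A", "G", "C", "S", "T", "K", "M"), 15,
                      replace = TRUE), collapse = "")
    cl <- cleave_leader(p)
    expect_equal(paste0(cl$leader, cl$core), p)
  }
})

test_that("peptide identity behaves like a global-alignment percent", {
  expect_equal(peptide_identity("MKTCSTCC", "MKTCSTCC"), 100)
  expect_equal(peptide_identity("AAAAAKAAAA", "AAAAAWAAAA"), 90)
  expect_lt(peptide_identity("WWHHWWHHWW", "PPGGPPGGPP"), 20)
  expect_equal(peptide_identity("MKTCSTAA", "MKTCSTAW"),
               peptide_identity("MKTCSTAW", "MKTCSTAA"))
  expect_error(peptide_identity("", "AAA"), "nonempty")
})

test_that("peptide networks respect the identity threshold", {
  peps <- tibble::tibble(
    orf_id = c("p1", "p2", "p3", "p4", "p5"),
    bgc_id = paste0("B", 1:5),
    core = c("ITCSTCCWNSTIAN", "ITCSTCCWNSTIAN", "ITCSTCCWNSTLAN",
             "GGGGAVVKKAAAGG", "WWHHPPWWHHPPWW"))
  net <- suppressWarnings(build_peptide_network(peps, threshold = 75))
  dup_edge <- net$edges[net$edges$from == "p1" & net$edges$to == "p2", ]
  expect_equal(dup_edge$identity, 100)

  # oracle component count from all-pairs alignment
  idm <- outer(seq_len(5), seq_len(5), Vectorize(function(i, j) {
    peptide_identity(peps$core[i], peps$core[j])
  }))
  sel <- which(upper.tri(idm) & idm >= 75, arr.ind = TRUE)
  oracle <- oracle_components(peps$orf_id, peps$orf_id[sel[, 1]],
                              peps$orf_id[sel[, 2]])
  expect_equal(length(unique(net$nodes$family)),
               length(unique(oracle)))

  # a stricter threshold removes sub-threshold edges
  id13 <- peptide_identity(peps$core[1], peps$core[3])
  net80 <- suppressWarnings(build_peptide_network(peps, threshold = 93))
  expect_true(id13 < 93)
  expect_false(any(net80$edges$from == "p1" & net80$edges$to == "p3"))

  refs <- c(known = "ITCSTCCWNSTIAN")
  net_ref <- build_peptide_network(peps, references = refs, threshold = 75)
  expect_true(all(c("p1", "p2") %in% net_ref$reference_matches$orf_id))
  expect_warning(build_peptide_network(peps, references = NULL),
                 "reference")
})
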