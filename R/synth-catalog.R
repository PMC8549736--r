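# Synthetic catalog generation: genomes, BGCs, ORF sequences.

GENUS_POOL <- c("Streptococcus", "Actinomyces", "Neisseria", "Corynebacterium",
                "Prevotella", "Fusobacterium", "Capnocytophaga", "Rothia",
                "Staphylococcus", "Veillonella", "Haemophilus", "Gemella")

# eHOMD-style habitat labels with sampling weights; the first three are the
# ADT-colonizer habitats, the rest mark environmental/transient strains
HABITAT_POOL <- c("Oral" = 0.35, "Nasal" = 0.15, "Nasal,Oral" = 0.10,
                  "NonOralRef" = 0.20, "Skin" = 0.10, "Unassigned" = 0.05,
                  "Vaginal" = 0.05)

# antiSMASH-style raw cluster types with sampling weights (single types;
# hybrids are drawn as two types)
RAW_TYPE_POOL <- c(
  bacteriocin = 0.24, lantipeptide = 0.06, lassopeptide = 0.03,
  thiopeptide = 0.03, sactipeptide = 0.02, nrps = 0.11, terpene = 0.11,
  arylpolyene = 0.08, t1pks = 0.03, t3pks = 0.03, resorcinol = 0.02,
  siderophore = 0.06, hserlactone = 0.03, ectoine = 0.02, phosphonate = 0.02,
  butyrolactone = 0.02, ladderane = 0.03, phenazine = 0.03, "acyl_amino" = 0.03
)

HYBRID_PROB <- 0.07

# small per-type domain vocabularies used to build domain strings; BGCs of
# the same type share vocabulary, so similarity networks group by type
DOMAIN_POOLS <- list(
  bacteriocin = c("DUF95", "ABC_tran", "Peptidase_C39", "HlyD", "TIGR01847"),
  ripp = c("LANC_like", "Lant_dehydr_N", "Lant_dehydr_C", "YcaO", "radical_SAM",
           "Peptidase_C39"),
  nrps = c("Condensation", "AMP-binding", "PP-binding", "Epimerase",
           "Thioesterase", "MT"),
  pks = c("PKS_KS", "PKS_AT", "PKS_DH", "PKS_ER", "PKS_KR", "ACP",
          "Thioesterase"),
  terpene = c("Terpene_synth_C", "SQS_PSY", "Lycopene_cycl", "polyprenyl_synt"),
  arylpolyene = c("APE_KS", "FabH", "ACP", "AMP-binding", "Glycos_transf"),
  other = c("p450", "Methyltransf", "FAD_binding", "Aminotran", "DegT",
            "Glycos_transf")
)

domain_pool_for <- function(raw_type) {
  ripp_sub <- c("cyanobactin", "glycocin", "lantipeptide", "lassopeptide",
                "linaridin", "microcin", "proteusin", "sactipeptide",
                "thiopeptide")
  pks_sub <- c("otherks", "resorcinol", "t1pks", "t2pks", "t3pks", "transatpks")
  if (raw_type == "bacteriocin") DOMAIN_POOLS$bacteriocin
  else if (raw_type %in% ripp_sub) DOMAIN_POOLS$ripp
  else if (raw_type == "nrps") DOMAIN_POOLS$nrps
  else if (raw_type %in% pks_sub) DOMAIN_POOLS$pks
  else if (raw_type == "terpene") DOMAIN_POOLS$terpene
  else if (raw_type == "arylpolyene") DOMAIN_POOLS$arylpolyene
  else DOMAIN_POOLS$other
}

# one deterministic codon per amino acid (reverse translation of designed
# precursor peptides)
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

reverse_translate <- function(aa) {
  paste(CODON_OF[strsplit(aa, "", fixed = TRUE)[[1]]], collapse = "")
}

# sample() treats a scalar first argument as 1:x; this keeps degenerate
# ranges (lo == hi) honest
sample_range <- function(lo, hi, n = 1) {
  x <- seq(lo, hi)
  x[sample.int(length(x), n, replace = TRUE)]
}

# design a RiPP-like precursor: Met + leader + GG + Cys/Ser/Thr-rich core
design_precursor_peptide <- function() {
  leader_len <- sample(9:15, 1)
  core_len <- sample(14:22, 1)
  leader <- paste(sample(strsplit("ALVIFEKQNSD", "")[[1]], leader_len,
                         replace = TRUE), collapse = "")
  core_pool <- c("C", "S", "T", "G", "A", "V", "I", "W", "N")
  core_w <- c(4, 3, 3, 2, 2, 1, 1, 1, 1)
  core <- paste(sample(core_pool, core_len, replace = TRUE, prob = core_w),
                collapse = "")
  paste0("M", leader, "GG", core)
}

#' Generate a synthetic BGC catalog with ORF sequences
#'
#' Draws `n_genomes` single-species genomes from a pool of common ADT
#' genera, assigns each an eHOMD-style habitat label (ADT or environmental),
#' and gives each genome a uniform number of BGCs in
#' `bgc_per_genome_range`. Each BGC carries an antiSMASH-style raw type (or
#' two, for hybrids), ordered ORFs with random ACGT sequence, per-ORF domain
#' strings drawn from a type-specific vocabulary, and biosynthetic flags.
#' BGCs of RiPP or bacteriocin character get a short designed precursor ORF
#' (leader + Gly-Gly + Cys/Ser/Thr-rich core) as their first ORF so the
#' peptide modules have realistic substrate.
#'
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `catalog` (tibble, one row per ORF; see
#'   [load_catalog()] for the schema) and `orf_fasta` (named character
#'   vector of ORF nucleotide sequences keyed by `orf_id`).
#' @export
generate_catalog <- function(config) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, "catalog"))

  rows <- vector("list", config$n_genomes)
  seqs <- list()
  bgc_counter <- 0L
  ripp_sub <- c("cyanobactin", "glycocin", "lantipeptide", "lassopeptide",
                "linaridin", "microcin", "proteusin", "sactipeptide",
                "thiopeptide")

  for (g in seq_len(config$n_genomes)) {
    genome_id <- sprintf("G%03d", g)
    genus <- sample(GENUS_POOL, 1)
    species <- paste0(genus, "_sp", g)
    habitat <- sample(names(HABITAT_POOL), 1, prob = HABITAT_POOL)
    n_bgc <- sample_range(config$bgc_per_genome_range[1],
                          config$bgc_per_genome_range[2])

    grows <- vector("list", n_bgc)
    for (b in seq_len(n_bgc)) {
      bgc_counter <- bgc_counter + 1L
      bgc_id <- sprintf("BGC%04d", bgc_counter)
      if (runif(1) < HYBRID_PROB) {
        raw_types <- sample(names(RAW_TYPE_POOL), 2, prob = RAW_TYPE_POOL)
      } else {
        raw_types <- sample(names(RAW_TYPE_POOL), 1, prob = RAW_TYPE_POOL)
      }
      contig_edge <- runif(1) < 0.1
      n_orf <- sample_range(config$orf_per_bgc_range[1],
                            config$orf_per_bgc_range[2])
      lens <- sample_range(config$orf_length_range[1],
                           config$orf_length_range[2], n_orf)
      lens <- pmax(3L * ceiling(lens / 3L), 3L)
      orf_ids <- sprintf("%s_orf%02d", bgc_id, seq_len(n_orf))
      orf_seq <- as.character(.cpp_random_dna(as.integer(lens)))

      is_ripp_like <- any(raw_types %in% c("bacteriocin", ripp_sub))
      if (is_ripp_like) {
        pep <- design_precursor_peptide()
        nt <- paste0(reverse_translate(pep), "TAA")
        orf_seq[1] <- nt
        lens[1] <- nchar(nt)
      }

      pool <- domain_pool_for(raw_types[1])
      dom <- vapply(seq_len(n_orf), function(i) {
        if (is_ripp_like && i == 1) return("") # precursors carry no domains
        nd <- sample(0:3, 1, prob = c(0.15, 0.35, 0.3, 0.2))
        if (nd == 0) "" else
          paste(sample(pool, nd, replace = TRUE), collapse = ";")
      }, character(1))

      bio <- runif(n_orf) >= config$prob_nonbiosynthetic
      bio[1] <- TRUE # every BGC keeps at least its lead ORF

      names(orf_seq) <- orf_ids
      seqs[[length(seqs) + 1L]] <- orf_seq
      grows[[b]] <- tibble::tibble(
        bgc_id = bgc_id, genome_id = genome_id, genus = genus,
        species = species, habitat = habitat,
        raw_types = paste(raw_types, collapse = ";"),
        contig_edge = contig_edge, orf_id = orf_ids,
        length_nt = as.integer(lens), biosynthetic = bio,
        domain_string = dom
      )
    }
    rows[[g]] <- dplyr::bind_rows(grows)
  }

  catalog <- dplyr::bind_rows(rows)
  list(catalog = catalog, orf_fasta = unlist(seqs))
}
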