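# Shared fixtures, all built in code.

# one catalog row per ORF
catalog_row <- function(bgc_id, genome_id = "G001", genus = "Streptococcus",
                        species = "Streptococcus_sp1", habitat = "Oral",
                        raw_types = "bacteriocin", contig_edge = FALSE,
                        orf_id, length_nt = 300L, biosynthetic = TRUE,
                        domain_string = "") {
  tibble::tibble(bgc_id = bgc_id, genome_id = genome_id, genus = genus,
                 species = species, habitat = habitat,
                 raw_types = raw_types, contig_edge = contig_edge,
                 orf_id = orf_id, length_nt = as.integer(length_nt),
                 biosynthetic = biosynthetic, domain_string = domain_string)
}

# catalog encoding the published per-category ADT/environment counts
# (one single-ORF BGC per record)
published_category_counts <- function() {
  tibble::tribble(
    ~category, ~raw, ~adt, ~env,
    "Bacteriocin", "bacteriocin", 610L, 252L,
    "RiPP", "lantipeptide", 241L, 202L,
    "NRPS", "nrps", 129L, 356L,
    "Terpene", "terpene", 150L, 296L,
    "Aryl Polyene", "arylpolyene", 211L, 99L,
    "PKS", "t1pks", 105L, 197L,
    "Siderophore", "siderophore", 100L, 138L,
    "HSL", "hserlactone", 11L, 106L,
    "Ectoine", "ectoine", 0L, 27L,
    "Phosphonate", "phosphonate", 0L, 18L,
    "Butyrolactone", "butyrolactone", 9L, 5L,
    "Hybrid", "t1pks;nrps", 60L, 213L,
    "Other", "ladderane", 106L, 254L
  )
}

table1_catalog <- function() {
  expected <- published_category_counts()
  rows <- lapply(seq_len(nrow(expected)), function(i) {
    n_adt <- expected$adt[i]; n_env <- expected$env[i]
    n <- n_adt + n_env
    if (n == 0) return(NULL)
    ids <- sprintf("T1_%s_%04d", gsub("[^A-Za-z]", "", expected$category[i]),
                   seq_len(n))
    catalog_row(bgc_id = ids,
                habitat = rep(c("Oral", "Skin"), c(n_adt, n_env)),
                raw_types = expected$raw[i],
                orf_id = paste0(ids, "_orf01"))
  })
  dplyr::bind_rows(rows)
}

# small fast synthetic config for unit tests; ... overrides any default
tiny_config <- function(...) {
  args <- list(n_sites = 2, samples_per_site = 3, n_genomes = 4,
               bgc_per_genome_range = c(2, 3), orf_per_bgc_range = c(2, 3),
               orf_length_range = c(150, 400), reads_per_sample = 300,
               read_length = 50, substitution_error_rate = 0,
               background_fraction = 0, planted_per_site = 1,
               planted_fold = 8, planted_species_fold = 1, seed = 42)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

matrix_to_taxa_helper <- function(m) adtbgc:::matrix_to_taxa(m)

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent canonicalization for k-mer oracles
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  vapply(km, function(x) min(x, oracle_revcomp(x)), character(1),
         USE.NAMES = FALSE)
}

# brute-force connected components over an edge list (DFS)
oracle_components <- function(ids, edges_from, edges_to) {
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  cur <- 0L
  for (s in ids) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- c(edges_to[edges_from == v], edges_from[edges_to == v])
      stack <- c(stack, nb[is.na(comp[nb])])
    }
  }
  comp
}
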