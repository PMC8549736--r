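# BGC family networks (domain-based distance, connected components at a
# cutoff) and RiPP core-peptide identity networks.

split_domains <- function(x) {
  d <- unlist(strsplit(x, ";", fixed = TRUE))
  d[nzchar(d)]
}

# ordered domain sequence of a BGC: concatenation of its ORFs' domain
# strings in ORF order
bgc_domain_seq <- function(catalog) {
  lapply(split(catalog$domain_string,
               factor(catalog$bgc_id, levels = unique(catalog$bgc_id))),
         split_domains)
}

#' Domain-content distance between two BGCs
#'
#' distance = 1 - (w_J * J + w_A * AI + w_D * DSS), where J is the Jaccard
#' index of the domain sets, AI the Jaccard index of adjacent ordered
#' domain pairs, and DSS = 1 - sum|a_d - b_d| / sum(a_d + b_d) over domain
#' copy-number vectors. Two BGCs with no domains at all are at distance 1.
#' This is a desk-scale simplification of profile-HMM-based cluster
#' distances: the sequence-similarity component is replaced by copy-number
#' similarity.
#'
#' @param dom_a,dom_b Ordered domain name vectors (possibly empty), or
#'   semicolon-joined strings.
#' @param weights Named or positional weights (J, AI, DSS) summing to 1.
#'   Default `c(0.2, 0.05, 0.75)`.
#' @return Distance in `[0, 1]`.
#' @export
bgc_distance <- function(dom_a, dom_b, weights = c(0.2, 0.05, 0.75)) {
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1", call. = FALSE)
  }
  if (is.character(dom_a) && length(dom_a) == 1) dom_a <- split_domains(dom_a)
  if (is.character(dom_b) && length(dom_b) == 1) dom_b <- split_domains(dom_b)
  if (length(dom_a) == 0 && length(dom_b) == 0) return(1)
  jacc <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0) return(1)
    length(intersect(a, b)) / length(u)
  }
  j <- jacc(unique(dom_a), unique(dom_b))
  pairs <- function(d) {
    if (length(d) < 2) character(0)
    else paste(d[-length(d)], d[-1], sep = "|")
  }
  ai <- jacc(unique(pairs(dom_a)), unique(pairs(dom_b)))
  doms <- union(dom_a, dom_b)
  ca <- table(factor(dom_a, levels = doms))
  cb <- table(factor(dom_b, levels = doms))
  dss <- 1 - sum(abs(ca - cb)) / sum(ca + cb)
  1 - (weights[1] * j + weights[2] * ai + weights[3] * dss)
}

#' All-pairs BGC distance matrix for a catalog
#'
#' @param catalog Catalog tibble.
#' @param weights Passed to [bgc_distance()].
#' @return Symmetric distance matrix with BGC ids as dimnames.
#' @export
bgc_distance_matrix <- function(catalog, weights = c(0.2, 0.05, 0.75)) {
  doms <- bgc_domain_seq(catalog)
  n <- length(doms)
  d <- matrix(0, n, n, dimnames = list(names(doms), names(doms)))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) {
        d[i, j] <- if (length(doms[[i]]) == 0) 1 else 0
        next
      }
      d[i, j] <- d[j, i] <- bgc_distance(doms[[i]], doms[[j]], weights)
    }
  }
  d
}

#' Build the BGC family network at a distance cutoff
#'
#' Edges connect BGC pairs at distance <= `cutoff`; families are the
#' connected components, singletons retained as their own family. Node
#' annotations (genus, category, enrichment, abundance) are joined when
#' supplied.
#'
#' @param catalog Catalog tibble.
#' @param distances Matrix from [bgc_distance_matrix()].
#' @param cutoff Edge cutoff (default 0.3).
#' @param enrichment Optional enrichment tibble (from
#'   [enrichment_all_sites()]); the site(s) where each BGC is enriched are
#'   annotated.
#' @param counts Optional normalized `bgc_counts`; the median log10
#'   normalized abundance is annotated.
#' @return A `bgc_network` object with `nodes`, `edges`, `graph`.
#' @export
build_bgc_network <- function(catalog, distances, cutoff = 0.3,
                              enrichment = NULL, counts = NULL) {
  ids <- unique(catalog$bgc_id)
  if (!setequal(rownames(distances), ids)) {
    stop("distance matrix ids do not match the catalog: ",
         paste(head(c(setdiff(ids, rownames(distances)),
                      setdiff(rownames(distances), ids)), 5),
               collapse = ", "), call. = FALSE)
  }
  distances <- distances[ids, ids]
  adj <- distances <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  fam <- igraph::components(g)$membership

  info <- catalog |>
    dplyr::distinct(.data$bgc_id, .data$genus, .data$raw_types)
  nodes <- tibble::tibble(bgc_id = ids,
                          genus = info$genus[match(ids, info$bgc_id)],
                          category = categorize_type(
                            info$raw_types[match(ids, info$bgc_id)]),
                          family = unname(fam[ids]))
  if (!is.null(enrichment)) {
    enr <- enrichment[enrichment$enriched, c("bgc_id", "site")]
    bad <- setdiff(enr$bgc_id, ids)
    if (length(bad)) {
      stop("enrichment ids absent from catalog: ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    enr <- enr |>
      dplyr::group_by(.data$bgc_id) |>
      dplyr::summarise(enriched_site = paste(.data$site, collapse = ";"),
                       .groups = "drop")
    nodes <- dplyr::left_join(nodes, enr, by = "bgc_id")
  }
  if (!is.null(counts)) {
    if (!inherits(counts, "bgc_counts") || counts$state != "normalized") {
      stop("counts must be a normalized bgc_counts", call. = FALSE)
    }
    med <- apply(counts$normalized, 1, function(x) median(log10(x)))
    nodes$median_log10_abundance <- unname(med[nodes$bgc_id])
  }
  ut <- which(upper.tri(distances) & distances <= cutoff, arr.ind = TRUE)
  edges <- tibble::tibble(from = rownames(distances)[ut[, 1]],
                          to = colnames(distances)[ut[, 2]],
                          distance = distances[ut])
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "bgc_network")
}

#' @export
print.bgc_network <- function(x, ...) {
  cat(sprintf("<bgc_network> %d BGCs, %d edges, %d families\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$family))))
  invisible(x)
}

#' Export a network as GraphML and an edge-list TSV
#'
#' @param network A `bgc_network` or `peptide_network`.
#' @param graphml,edges_tsv Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, graphml = NULL, edges_tsv = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
  }
  if (!is.null(edges_tsv)) readr::write_tsv(network$edges, edges_tsv)
  invisible(c(graphml = graphml, edges_tsv = edges_tsv))
}

#' Extract candidate RiPP precursor ORFs
#'
#' Takes all ORFs of length <= `max_nt` from BGCs categorized RiPP or
#' Bacteriocin (including hybrids containing such a raw type), translates
#' them in frame 1 and trims the trailing stop codon. Candidates with an
#' internal stop are dropped with a warning.
#'
#' @param catalog Catalog tibble.
#' @param orf_fasta Named ORF nucleotide sequences.
#' @param max_nt Maximum ORF length in nucleotides. Default 450.
#' @return Tibble: `orf_id`, `bgc_id`, `precursor` (amino-acid sequence).
#' @export
extract_precursor_orfs <- function(catalog, orf_fasta, max_nt = 450) {
  ripp_raw <- c("bacteriocin", RIPP_TYPES)
  per_bgc <- dplyr::distinct(catalog, .data$bgc_id, .data$raw_types)
  has_ripp <- vapply(strsplit(per_bgc$raw_types, ";", fixed = TRUE),
                     function(tt) any(tt %in% ripp_raw), logical(1))
  keep_bgc <- per_bgc$bgc_id[has_ripp]
  cand <- catalog[catalog$bgc_id %in% keep_bgc &
                    catalog$length_nt <= max_nt, ]
  if (nrow(cand) == 0) {
    return(tibble::tibble(orf_id = character(), bgc_id = character(),
                          precursor = character()))
  }
  nt <- orf_fasta[cand$orf_id]
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(nt),
                          if.fuzzy.codon = "solve")))
  aa <- sub("\\*$", "", aa)
  internal_stop <- grepl("*", aa, fixed = TRUE)
  if (any(internal_stop)) {
    warning(sum(internal_stop),
            " candidate(s) dropped: internal stop codon", call. = FALSE)
  }
  tibble::tibble(orf_id = cand$orf_id, bgc_id = cand$bgc_id,
                 precursor = unname(aa))[!internal_stop, ]
}

#' Rule-based RiPP precursor classification
#'
#' A deterministic stand-in for a learned precursor classifier, built from
#' hallmark features of published RiPP precursors: plausible length (20 to
#' 120 aa), Cys/Ser/Thr density in the C-terminal half, and a Gly-Gly
#' cleavage motif. The score is 0.4 x (length in range) + 0.25 x (GG
#' motif present) + 0.35 x min(1, density / 0.25). A peptide passes when
#' score >= `threshold`; passing peptides are classed lanthipeptide when
#' the C-terminal half has both Cys and Ser/Thr, class II bacteriocin when
#' a GG motif is present without that signature, ripp-like otherwise.
#' Externally computed scores can be supplied instead via `scores`
#' (tibble: orf_id, score, class) and take precedence.
#'
#' @param peptides Tibble from [extract_precursor_orfs()] (columns
#'   `orf_id`, `precursor`), or a single amino-acid string.
#' @param threshold Passing score. Default 0.75.
#' @param scores Optional external classifier-score table.
#' @return Input tibble with `score`, `ripp_class` (NA when failing) and
#'   `passes` columns.
#' @export
classify_precursor <- function(peptides, threshold = 0.75, scores = NULL) {
  if (is.character(peptides)) {
    peptides <- tibble::tibble(orf_id = names(peptides) %||%
                                 paste0("pep", seq_along(peptides)),
                               precursor = unname(peptides))
  }
  aa <- peptides$precursor
  if (any(nchar(aa) < 10)) {
    stop("precursor shorter than 10 aa", call. = FALSE)
  }
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", aa))) {
    stop("non-amino-acid characters in precursor", call. = FALSE)
  }
  n <- nchar(aa)
  chalf <- substr(aa, ceiling(n / 2) + 1, n)
  cst <- vapply(strsplit(chalf, "", fixed = TRUE), function(ch) {
    mean(ch %in% c("C", "S", "T"))
  }, numeric(1))
  has_gg <- grepl("GG", aa, fixed = TRUE)
  score <- 0.4 * (n >= 20 & n <= 120) + 0.25 * has_gg +
    0.35 * pmin(1, cst / 0.25)
  cls <- ifelse(
    grepl("C", chalf) & grepl("[ST]", chalf), "lanthipeptide",
    ifelse(has_gg, "class II bacteriocin", "ripp-like"))
  if (!is.null(scores)) {
    hit <- match(peptides$orf_id, scores$orf_id)
    score[!is.na(hit)] <- scores$score[hit[!is.na(hit)]]
    if ("class" %in% names(scores)) {
      cls[!is.na(hit)] <- scores$class[hit[!is.na(hit)]]
    }
  }
  passes <- score >= threshold
  peptides$score <- score
  peptides$ripp_class <- ifelse(passes, cls, NA_character_)
  peptides$passes <- passes
  peptides
}

#' Cleave a precursor into leader and core
#'
#' Cleaves immediately after the last Gly-Gly motif whose end falls within
#' the first two-thirds of the sequence; with no such motif, cleaves at
#' floor(length / 2). Leader + core always reconstructs the precursor.
#'
#' @param peptide Character vector of precursor sequences.
#' @return Tibble with `leader` and `core`.
#' @export
cleave_leader <- function(peptide) {
  out <- lapply(peptide, function(p) {
    n <- nchar(p)
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    gg_end <- which(ch[-n] == "G" & ch[-1] == "G") + 1L
    gg_end <- gg_end[gg_end <= floor(2 * n / 3)]
    cut <- if (length(gg_end)) max(gg_end) else floor(n / 2)
    c(leader = substr(p, 1, cut), core = substr(p, cut + 1, n))
  })
  tibble::tibble(leader = vapply(out, `[[`, character(1), "leader"),
                 core = vapply(out, `[[`, character(1), "core"))
}

#' Percent identity between two core peptides by global alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62, gap open 11 and gap
#' extend 1; identity = 100 x matches / alignment length. The full query
#' is aligned (global alignment leaves no unaligned termini).
#'
#' @param core_a,core_b Amino-acid strings.
#' @return Percent identity in `[0, 100]`.
#' @export
peptide_identity <- function(core_a, core_b) {
  if (!nzchar(core_a) || !nzchar(core_b)) {
    stop("cores must be nonempty", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(core_a), Biostrings::AAString(core_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Build the core-peptide identity network
#'
#' Edges connect core pairs at percent identity >= `threshold`; matches
#' against a reference core-peptide set are recorded separately.
#'
#' @param peptides Tibble with `orf_id`, `bgc_id` and `core` columns
#'   (classified and cleaved).
#' @param references Optional named character vector of reference core
#'   peptides (amino acid); when absent, reference matching is skipped
#'   with a warning.
#' @param threshold Percent-identity threshold (default 75; use 80 to
#'   reproduce the stricter figure rendering).
#' @param annotations Optional tibble keyed by `bgc_id` joined onto nodes.
#' @return A `peptide_network` object with `nodes`, `edges`,
#'   `reference_matches`, `graph`.
#' @export
build_peptide_network <- function(peptides, references = NULL,
                                  threshold = 75, annotations = NULL) {
  stopifnot(all(c("orf_id", "core") %in% names(peptides)))
  n <- nrow(peptides)
  edges <- tibble::tibble(from = character(), to = character(),
                          identity = numeric())
  if (n >= 2) {
    pr <- utils::combn(n, 2)
    idv <- vapply(seq_len(ncol(pr)), function(p) {
      peptide_identity(peptides$core[pr[1, p]], peptides$core[pr[2, p]])
    }, numeric(1))
    sel <- idv >= threshold
    edges <- tibble::tibble(from = peptides$orf_id[pr[1, sel]],
                            to = peptides$orf_id[pr[2, sel]],
                            identity = idv[sel])
  }
  ref_matches <- tibble::tibble(orf_id = character(),
                                reference = character(),
                                identity = numeric())
  if (is.null(references) || length(references) == 0) {
    warning("no reference peptides supplied: reference matching skipped",
            call. = FALSE)
  } else {
    grid <- expand.grid(i = seq_len(n), r = seq_along(references))
    idv <- vapply(seq_len(nrow(grid)), function(g) {
      peptide_identity(peptides$core[grid$i[g]], references[[grid$r[g]]])
    }, numeric(1))
    sel <- idv >= threshold
    ref_matches <- tibble::tibble(
      orf_id = peptides$orf_id[grid$i[sel]],
      reference = names(references)[grid$r[sel]],
      identity = idv[sel])
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = peptides$orf_id)
  fam <- igraph::components(g)$membership
  nodes <- peptides
  nodes$family <- unname(fam[nodes$orf_id])
  if (!is.null(annotations) && "bgc_id" %in% names(nodes)) {
    nodes <- dplyr::left_join(nodes, annotations, by = "bgc_id")
  }
  structure(list(nodes = nodes, edges = edges,
                 reference_matches = ref_matches, graph = g),
            class = "peptide_network")
}

#' @export
print.peptide_network <- function(x, ...) {
  cat(sprintf("<peptide_network> %d cores, %d edges, %d families, %d reference matches\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$family)), nrow(x$reference_matches)))
  invisible(x)
}
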