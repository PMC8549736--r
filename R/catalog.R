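# BGC catalog data model: loading, habitat-source classification, category
# taxonomy, Table-style summarization, nonbiosynthetic-ORF filtering.

ADT_HABITATS <- c("Nasal", "Nasal,Oral", "Oral")
ENV_HABITATS <- c("NonOralRef", "Skin", "Unassigned", "Vaginal")

RIPP_TYPES <- c("cyanobactin", "glycocin", "lantipeptide", "lassopeptide",
                "linaridin", "microcin", "proteusin", "sactipeptide",
                "thiopeptide")
PKS_TYPES <- c("otherks", "resorcinol", "t1pks", "t2pks", "t3pks",
               "transatpks")

# canonical category order used in summaries
CATEGORY_LEVELS <- c("Bacteriocin", "RiPP", "NRPS", "Terpene", "Aryl Polyene",
                     "PKS", "Siderophore", "HSL", "Ectoine", "Phosphonate",
                     "Butyrolactone", "Hybrid", "Other")

#' Load a BGC catalog from its TSV representation
#'
#' One row per ORF; columns: `bgc_id`, `genome_id`, `genus`, `species`,
#' `habitat`, `raw_types` (semicolon-joined), `contig_edge` (0/1),
#' `orf_id`, `length_nt`, `biosynthetic` (0/1), `domain_string`
#' (semicolon-joined, may be empty). ORF order within a BGC is the row
#' order.
#'
#' @param path TSV file path.
#' @return Catalog tibble.
#' @export
load_catalog <- function(path) {
  cat <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           bgc_id = "c", genome_id = "c", genus = "c",
                           species = "c", habitat = "c", raw_types = "c",
                           contig_edge = "i", orf_id = "c", length_nt = "i",
                           biosynthetic = "i", domain_string = "c"
                         ))
  cat$contig_edge <- cat$contig_edge == 1L
  cat$biosynthetic <- cat$biosynthetic == 1L
  cat$domain_string[is.na(cat$domain_string)] <- ""
  validate_catalog(cat)
  cat
}

validate_catalog <- function(cat) {
  if (nrow(cat) == 0) return(invisible(cat))
  bad <- !cat$habitat %in% c(ADT_HABITATS, ENV_HABITATS)
  if (any(bad)) {
    stop("unknown habitat value ", sQuote(cat$habitat[which(bad)[1]]),
         " in row ", which(bad)[1], call. = FALSE)
  }
  # a bgc_id must map to a single genome and appear as one contiguous block
  per_bgc <- dplyr::distinct(cat, .data$bgc_id, .data$genome_id)
  dup <- per_bgc$bgc_id[duplicated(per_bgc$bgc_id)]
  blocks <- rle(cat$bgc_id)$values
  dup <- unique(c(dup, blocks[duplicated(blocks)]))
  if (length(dup)) {
    stop("duplicate bgc_id in catalog: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cat$orf_id)) {
    stop("duplicate orf_id in catalog", call. = FALSE)
  }
  if (any(is.na(cat$raw_types) | cat$raw_types == "")) {
    stop("raw_types must be nonempty for every BGC", call. = FALSE)
  }
  invisible(cat)
}

#' Write a catalog tibble to TSV
#' @param catalog Catalog tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog
  out$contig_edge <- as.integer(out$contig_edge)
  out$biosynthetic <- as.integer(out$biosynthetic)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Classify a habitat label as ADT or Environment
#'
#' Strains whose habitat is "Nasal", "Nasal,Oral" or "Oral" are ADT
#' colonizers; "NonOralRef", "Skin", "Unassigned" and "Vaginal" mark
#' environmental strains found only transiently in the ADT.
#'
#' @param habitat Character vector of habitat labels.
#' @return Character vector, `"ADT"` or `"Environment"`.
#' @export
classify_source <- function(habitat) {
  out <- ifelse(habitat %in% ADT_HABITATS, "ADT",
                ifelse(habitat %in% ENV_HABITATS, "Environment", NA_character_))
  if (anyNA(out)) {
    stop("unknown habitat value: ",
         paste(unique(habitat[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Assign a BGC category from its raw cluster type(s)
#'
#' Composite (two or more) raw types are Hybrid. Single raw types map to
#' the 13-category taxonomy: bacteriocin -> Bacteriocin; the RiPP
#' subclasses (cyanobactin, glycocin, lantipeptide, lassopeptide,
#' linaridin, microcin, proteusin, sactipeptide, thiopeptide) -> RiPP;
#' nrps -> NRPS; terpene -> Terpene; arylpolyene -> Aryl Polyene; the PKS
#' subclasses (otherks, resorcinol, t1pks, t2pks, t3pks, transatpks) ->
#' PKS; siderophore -> Siderophore; hserlactone -> HSL; ectoine ->
#' Ectoine; phosphonate -> Phosphonate; butyrolactone -> Butyrolactone;
#' anything else -> Other.
#'
#' @param raw_types Character vector of semicolon-joined raw type strings.
#' @return Character vector of categories.
#' @export
categorize_type <- function(raw_types) {
  vapply(strsplit(raw_types, ";", fixed = TRUE), function(tt) {
    tt <- tt[nzchar(tt)]
    if (length(tt) >= 2) return("Hybrid")
    t1 <- tt[1]
    if (t1 == "bacteriocin") "Bacteriocin"
    else if (t1 %in% RIPP_TYPES) "RiPP"
    else if (t1 == "nrps") "NRPS"
    else if (t1 == "terpene") "Terpene"
    else if (t1 == "arylpolyene") "Aryl Polyene"
    else if (t1 %in% PKS_TYPES) "PKS"
    else if (t1 == "siderophore") "Siderophore"
    else if (t1 == "hserlactone") "HSL"
    else if (t1 == "ectoine") "Ectoine"
    else if (t1 == "phosphonate") "Phosphonate"
    else if (t1 == "butyrolactone") "Butyrolactone"
    else "Other"
  }, character(1))
}

#' Summarize a catalog by category and habitat source
#'
#' Counts BGCs per category split by ADT vs environmental source, with
#' total percents rounded half-up to one decimal, plus a Total row.
#'
#' @param catalog Catalog tibble (one row per ORF).
#' @return Tibble with columns `category`, `adt_count`,
#'   `environment_count`, `total_count`, `total_percent`.
#' @export
summarize_categories <- function(catalog) {
  if (nrow(catalog) == 0) stop("catalog is empty", call. = FALSE)
  bgcs <- dplyr::distinct(catalog, .data$bgc_id, .data$habitat,
                          .data$raw_types)
  bgcs$category <- categorize_type(bgcs$raw_types)
  bgcs$source <- classify_source(bgcs$habitat)
  n_total <- nrow(bgcs)
  tab <- bgcs |>
    dplyr::count(.data$category, .data$source) |>
    tidyr::pivot_wider(names_from = "source", values_from = "n",
                       values_fill = 0L)
  if (!"ADT" %in% names(tab)) tab$ADT <- 0L
  if (!"Environment" %in% names(tab)) tab$Environment <- 0L
  tab <- tab |>
    dplyr::transmute(category = .data$category,
                     adt_count = .data$ADT,
                     environment_count = .data$Environment,
                     total_count = .data$ADT + .data$Environment,
                     total_percent = round_half_up(
                       100 * .data$total_count / n_total, 1))
  tab <- tab[order(match(tab$category, CATEGORY_LEVELS)), ]
  total <- tibble::tibble(category = "Total",
                          adt_count = sum(tab$adt_count),
                          environment_count = sum(tab$environment_count),
                          total_count = sum(tab$total_count),
                          total_percent = 100)
  dplyr::bind_rows(tab, total)
}

#' Drop nonbiosynthetic ORFs (and BGCs left empty) from a catalog
#'
#' ORFs flagged `biosynthetic = FALSE` encode proteins not involved in
#' specialized-metabolite biosynthesis and are excluded before indexing.
#' BGCs whose every ORF is removed are dropped and reported.
#'
#' @param catalog Catalog tibble.
#' @return Filtered catalog; attribute `dropped_bgcs` lists BGC ids that
#'   lost all their ORFs.
#' @export
filter_nonbiosynthetic_orfs <- function(catalog) {
  keep <- catalog[catalog$biosynthetic, ]
  dropped <- setdiff(unique(catalog$bgc_id), unique(keep$bgc_id))
  if (length(dropped)) {
    message(length(dropped),
            " BGC(s) dropped: no biosynthetic ORFs remained")
  }
  attr(keep, "dropped_bgcs") <- dropped
  keep
}
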