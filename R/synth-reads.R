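# Shotgun read simulation with known per-ORF ground truth.

#' Simulate reads for one metagenome sample
#'
#' Each read is drawn by (i) choosing a genome proportional to the sample's
#' species relative abundances, (ii) with probability `background_fraction`
#' taking a uniformly placed substring of that genome's background
#' sequence, otherwise of one of its BGC ORFs (ORF chosen proportional to
#' length, times the planted fold for planted BGCs in the sample's site),
#' with strand chosen uniformly and per-base substitutions applied at
#' `substitution_error_rate`. ORFs shorter than the read length are skipped
#' with a warning. The per-sample RNG stream is seeded as
#' `derive_seed(config$seed, sample_id)`, so samples are reproducible
#' independently and in any order.
#'
#' @param sample_id Sample to simulate (must appear in `metadata`).
#' @param catalog,orf_fasta Catalog tibble and named ORF sequences from
#'   [generate_catalog()].
#' @param taxa Wide taxa tibble from [generate_communities()].
#' @param metadata Sample metadata tibble.
#' @param truth Ground-truth list (used for the planted-enrichment table);
#'   may be `NULL` for no planting.
#' @param config A [synth_config()].
#' @return A list with `reads` (character), `ids` (read names), `quality`
#'   (constant phred+33 quality string), `orf_counts` (named integer, true
#'   reads per ORF) and `n_background`.
#' @export
simulate_sample_reads <- function(sample_id, catalog, orf_fasta, taxa,
                                  metadata, truth, config) {
  if (config$read_length < 31) {
    stop("read_length must be >= 31", call. = FALSE)
  }
  meta_row <- metadata[metadata$sample_id == sample_id, ]
  if (nrow(meta_row) != 1) {
    stop("unknown sample_id: ", sample_id, call. = FALSE)
  }
  site <- meta_row$site

  genomes <- dplyr::distinct(catalog, .data$genome_id, .data$species)
  ra_row <- taxa[taxa$sample_id == sample_id, ]
  ra <- as.numeric(ra_row[1, genomes$species])

  orf_tab <- catalog[, c("orf_id", "bgc_id", "genome_id", "length_nt")]
  orf_seqs <- orf_fasta[orf_tab$orf_id]
  weights <- as.numeric(orf_tab$length_nt)

  planted <- truth$planted_bgcs
  if (!is.null(planted) && nrow(planted)) {
    here <- planted[planted$site == site, ]
    if (nrow(here)) {
      for (i in seq_len(nrow(here))) {
        sel <- orf_tab$bgc_id == here$bgc_id[i]
        weights[sel] <- weights[sel] * here$fold[i]
      }
    }
  }

  eligible <- orf_tab$length_nt >= config$read_length & weights > 0
  n_skip <- sum(!eligible & weights > 0)
  if (n_skip > 0) {
    warning(n_skip, " ORFs shorter than the read length were skipped",
            call. = FALSE)
  }
  genome_orfs <- lapply(genomes$genome_id, function(g) {
    which(orf_tab$genome_id == g & eligible)
  })

  set.seed(derive_seed(config$seed, sample_id))
  bg <- genome_backgrounds(config, genomes$genome_id)
  sim <- .cpp_sim_reads(unname(orf_seqs), weights, genome_orfs, ra, bg,
                        config$reads_per_sample, config$read_length,
                        config$substitution_error_rate,
                        config$background_fraction)
  orf_counts <- as.integer(sim$orf_counts)
  names(orf_counts) <- orf_tab$orf_id
  list(reads = as.character(sim$reads),
       ids = sprintf("%s.%d", sample_id, seq_len(config$reads_per_sample)),
       quality = strrep("I", config$read_length),
       orf_counts = orf_counts,
       n_background = sim$n_background)
}

# genome-specific background DNA, generated once per genome from a seed
# derived from the master seed (independent of sample order); cached so
# per-sample calls do not regenerate it
.bg_cache <- new.env(parent = emptyenv())

genome_backgrounds <- function(config, genome_ids) {
  key <- paste(config$seed, config$background_length,
               paste(genome_ids, collapse = ","), sep = "|")
  hit <- .bg_cache[[key]]
  if (!is.null(hit)) return(hit)
  seed_keep <- get0(".Random.seed", envir = globalenv())
  set.seed(derive_seed(config$seed, "background"))
  bg <- as.character(.cpp_random_dna(rep(config$background_length,
                                         length(genome_ids))))
  names(bg) <- genome_ids
  if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, envir = globalenv())
  .bg_cache[[key]] <- bg
  bg
}

#' Write reads as FASTQ (Sanger phred+33, constant quality)
#'
#' @param sim Result of [simulate_sample_reads()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  n <- length(sim$reads)
  out <- character(4L * n)
  out[seq(1, by = 4, length.out = n)] <- paste0("@", sim$ids)
  out[seq(2, by = 4, length.out = n)] <- sim$reads
  out[seq(3, by = 4, length.out = n)] <- "+"
  out[seq(4, by = 4, length.out = n)] <- sim$quality
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file into a character vector of sequences
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Generate a complete synthetic study
#'
#' Runs [generate_catalog()], [generate_communities()] and
#' [simulate_sample_reads()] for every sample, recording the true per-ORF
#' read counts in the ground truth. Reads themselves are only retained on
#' disk when `fastq_dir` is given; otherwise they are discarded after
#' counting and can be regenerated deterministically from the per-sample
#' seeds (see [quantify_samples()]).
#'
#' @param config A [synth_config()].
#' @param fastq_dir Optional directory to write per-sample FASTQ files.
#' @param simulate_reads Set `FALSE` to skip read simulation entirely
#'   (catalog + communities only).
#' @return A list with `catalog`, `orf_fasta`, `metadata`, `taxa`, `truth`;
#'   `truth$orf_read_counts` is an ORF x sample integer matrix and
#'   `truth$background_reads` a named integer vector.
#' @export
simulate_study <- function(config, fastq_dir = NULL, simulate_reads = TRUE) {
  cat_obj <- generate_catalog(config)
  comm <- generate_communities(config, cat_obj$catalog)
  study <- list(catalog = cat_obj$catalog, orf_fasta = cat_obj$orf_fasta,
                metadata = comm$metadata, taxa = comm$taxa,
                truth = comm$truth)
  if (!simulate_reads) return(study)

  orf_ids <- cat_obj$catalog$orf_id
  counts <- matrix(0L, nrow = length(orf_ids), ncol = nrow(comm$metadata),
                   dimnames = list(orf_ids, comm$metadata$sample_id))
  bg <- integer(nrow(comm$metadata))
  names(bg) <- comm$metadata$sample_id
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, recursive = TRUE, showWarnings = FALSE)
  }
  for (sid in comm$metadata$sample_id) {
    sim <- withCallingHandlers(
      simulate_sample_reads(sid, cat_obj$catalog, cat_obj$orf_fasta,
                            comm$taxa, comm$metadata, comm$truth, config),
      warning = function(w) invokeRestart("muffleWarning"))
    counts[, sid] <- sim$orf_counts
    bg[sid] <- sim$n_background
    if (!is.null(fastq_dir)) {
      write_fastq(sim, file.path(fastq_dir, paste0(sid, ".fastq")))
    }
  }
  study$truth$orf_read_counts <- counts
  study$truth$background_reads <- bg
  study
}
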