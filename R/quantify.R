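# Metagenome-to-BGC quantification: k-mer index over biosynthetic ORFs,
# pseudoalignment, EM resolution of multi-mapping reads, aggregation and
# median-of-ratios normalization.

#' Replace IUPAC ambiguity codes by seeded pseudorandom bases
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param seed Integer seed for the replacement draw.
#' @return Sequences with every non-ACGT character replaced by a random
#'   base; attribute `n_replaced` reports the replacement count.
#' @export
sanitize_sequences <- function(seqs, seed = 1) {
  empty <- !nzchar(seqs)
  if (any(empty)) {
    nm <- names(seqs)[which(empty)[1]] %||% as.character(which(empty)[1])
    stop("empty sequence for record ", nm, call. = FALSE)
  }
  set.seed(seed)
  n_replaced <- 0L
  hits <- gregexpr("[^ACGT]", seqs)
  for (i in seq_along(seqs)) {
    pos <- hits[[i]]
    if (pos[1] == -1L) next
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    chars[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    seqs[[i]] <- paste(chars, collapse = "")
    n_replaced <- n_replaced + length(pos)
  }
  attr(seqs, "n_replaced") <- n_replaced
  seqs
}

#' Build a canonical k-mer index over target sequences
#'
#' Every k-mer is stored under the lexicographic minimum of itself and its
#' reverse complement, mapped to an equivalence class: the set of targets
#' containing it. Sequences shorter than `k` are skipped with a warning.
#'
#' @param seqs Named character vector of ACGT sequences (run
#'   [sanitize_sequences()] first if ambiguity codes may be present).
#' @param k k-mer length, at most 31. Default 31.
#' @return A `kmer_index` object.
#' @export
build_index <- function(seqs, k = 31) {
  if (is.null(names(seqs))) names(seqs) <- paste0("target", seq_along(seqs))
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than k = ", k, " skipped",
            call. = FALSE)
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0) stop("no sequences of length >= k", call. = FALSE)
  ptr <- .cpp_build_index(unname(seqs), as.integer(k))
  st <- .cpp_index_stats(ptr)
  structure(list(ptr = ptr, k = as.integer(k), target_ids = names(seqs),
                 effective_length = setNames(st$effective_length, names(seqs)),
                 n_kmers = st$n_kmers, n_classes = st$n_classes),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d, %d targets, %s k-mers, %s classes\n",
              x$k, length(x$target_ids), format(x$n_kmers, big.mark = ","),
              format(x$n_classes, big.mark = ",")))
  invisible(x)
}

#' Equivalence classes of a k-mer index
#'
#' @param index A `kmer_index`.
#' @return List of character vectors: the target ids of each class.
#' @export
index_classes <- function(index) {
  lapply(.cpp_index_classes(index$ptr), function(i) index$target_ids[i])
}

#' Serialize / restore a k-mer index as JSON
#'
#' Intended for desk-scale indexes; stores k, target ids, effective
#' lengths, equivalence classes and the full k-mer table (encoded codes).
#'
#' @param index A `kmer_index`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored `kmer_index`.
#' @export
write_index_json <- function(index, path) {
  dump <- .cpp_index_dump(index$ptr)
  obj <- list(k = index$k, target_ids = index$target_ids,
              effective_length = unname(index$effective_length),
              classes = .cpp_index_classes(index$ptr),
              kmer_code = dump$kmer_code, class_id = dump$class_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index_json
#' @export
read_index_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ptr <- .cpp_index_restore(obj$k, length(obj$target_ids),
                            as.integer(obj$effective_length),
                            as.character(obj$kmer_code),
                            as.integer(obj$class_id),
                            lapply(obj$classes, as.integer))
  st <- .cpp_index_stats(ptr)
  structure(list(ptr = ptr, k = as.integer(obj$k),
                 target_ids = obj$target_ids,
                 effective_length = setNames(st$effective_length,
                                             obj$target_ids),
                 n_kmers = st$n_kmers, n_classes = st$n_classes),
            class = "kmer_index")
}

#' Pseudoalign reads against a k-mer index
#'
#' A read's equivalence class is the intersection of the classes of its
#' canonical k-mers; k-mers absent from the index are ignored (tolerating
#' substitution errors). A read is unassigned iff none of its k-mers hits
#' the index or the intersection is empty; reads shorter than `k` are
#' unassigned and counted in `n_too_short`.
#'
#' @param index A `kmer_index`.
#' @param reads Character vector of reads.
#' @return A `pseudoalignment` object: `read_ec` (per-read class index, 0 =
#'   unassigned), `ec_targets` (list of target-id vectors per class),
#'   `ec_counts` (reads per class), `n_unassigned`, `n_too_short`.
#' @export
pseudoalign <- function(index, reads) {
  res <- .cpp_pseudoalign(index$ptr, reads)
  structure(list(
    read_ec = res$read_ec,
    ec_targets = lapply(res$ec_targets, function(i) index$target_ids[i]),
    ec_target_idx = res$ec_targets,
    ec_counts = res$ec_counts,
    n_unassigned = res$n_unassigned,
    n_too_short = res$n_too_short,
    n_reads = length(reads)
  ), class = "pseudoalignment")
}

#' @export
print.pseudoalignment <- function(x, ...) {
  cat(sprintf("<pseudoalignment> %d reads: %d assigned (%d classes), %d unassigned\n",
              x$n_reads, x$n_reads - x$n_unassigned,
              length(x$ec_counts), x$n_unassigned))
  invisible(x)
}

#' Resolve multi-mapping reads by multinomial EM
#'
#' Maximizes the multinomial likelihood of the observed equivalence-class
#' counts over per-target abundances, with class weights proportional to
#' abundance over effective length (`length - k + 1`). Iterates until the
#' maximum absolute change in estimated counts drops below `tol` or
#' `max_iter` is reached. Estimated counts sum to the number of assigned
#' reads.
#'
#' @param aln A `pseudoalignment`.
#' @param index The `kmer_index` the reads were aligned to.
#' @param max_iter,tol Stopping rule (default 200 iterations, 1e-3 counts).
#' @return Named numeric vector of estimated counts per target; attributes
#'   `n_iter`, `converged` and `loglik` (trace, non-decreasing).
#' @export
em_quantify <- function(aln, index, max_iter = 200, tol = 1e-3) {
  n_t <- length(index$target_ids)
  out <- setNames(numeric(n_t), index$target_ids)
  if (length(aln$ec_counts) == 0) {
    attr(out, "n_iter") <- 0L
    attr(out, "converged") <- TRUE
    attr(out, "loglik") <- numeric(0)
    return(out)
  }
  cls <- aln$ec_target_idx
  cnt <- as.numeric(aln$ec_counts)
  total <- sum(cnt)
  A <- Matrix::sparseMatrix(
    i = rep(seq_along(cls), lengths(cls)),
    j = unlist(cls),
    x = 1,
    dims = c(length(cls), n_t)
  )
  eff <- pmax(as.numeric(index$effective_length), 1)
  theta <- rep(total / n_t, n_t)
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- theta / eff
    denom <- as.numeric(A %*% w)
    ll <- c(ll, sum(cnt * log(denom / sum(w))))
    est <- w * as.numeric(Matrix::crossprod(A, cnt / denom))
    if (max(abs(est - theta)) < tol) {
      theta <- est
      converged <- TRUE
      break
    }
    theta <- est
  }
  out[] <- theta
  attr(out, "n_iter") <- it
  attr(out, "converged") <- converged
  attr(out, "loglik") <- ll
  out
}

#' Aggregate per-ORF estimated counts to per-BGC counts
#'
#' @param orf_counts Named numeric vector of per-ORF counts.
#' @param catalog Catalog tibble mapping `orf_id` to `bgc_id`.
#' @return Named numeric vector of per-BGC counts (every catalog BGC,
#'   zeros included).
#' @export
aggregate_to_bgc <- function(orf_counts, catalog) {
  map <- setNames(catalog$bgc_id, catalog$orf_id)
  orphan <- setdiff(names(orf_counts), names(map))
  if (length(orphan)) {
    stop("ORF id(s) not present in catalog: ",
         paste(head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  bgc_ids <- unique(catalog$bgc_id)
  sums <- tapply(orf_counts, factor(map[names(orf_counts)], levels = bgc_ids),
                 sum, default = 0)
  setNames(as.numeric(sums), bgc_ids)
}

#' Assemble per-sample BGC counts into a count matrix
#'
#' Drops BGCs with zero estimated counts in every sample (reported),
#' rounds estimates to the nearest integer (halves away from zero) and
#' adds one pseudocount to every cell.
#'
#' @param sample_counts Named list (by sample id) of named per-BGC count
#'   vectors over a common BGC universe, or a BGC x sample numeric matrix.
#' @return A `bgc_counts` object in state `"pseudocounted"`; attribute
#'   `n_dropped` reports undetected BGCs removed.
#' @export
finalize_counts <- function(sample_counts) {
  if (is.list(sample_counts) && !is.matrix(sample_counts)) {
    bgc_ids <- names(sample_counts[[1]])
    m <- vapply(sample_counts, function(x) x[bgc_ids], numeric(length(bgc_ids)))
    rownames(m) <- bgc_ids
  } else {
    m <- as.matrix(sample_counts)
  }
  detected <- rowSums(m) > 0
  n_dropped <- sum(!detected)
  if (n_dropped > 0) {
    message(n_dropped, " BGC(s) not detected in any sample removed")
  }
  m <- m[detected, , drop = FALSE]
  m <- round_half_away(m) + 1
  structure(list(counts = m, size_factors = NULL, normalized = NULL,
                 state = "pseudocounted", n_dropped = n_dropped),
            class = "bgc_counts")
}

#' @export
print.bgc_counts <- function(x, ...) {
  cat(sprintf("<bgc_counts> %d BGCs x %d samples, state: %s\n",
              nrow(x$counts), ncol(x$counts), x$state))
  invisible(x)
}

#' Median-of-ratios size-factor normalization
#'
#' For each sample j, the size factor s_j is the median over BGCs of the
#' ratio of its count to the BGC's geometric mean across samples;
#' normalized counts are counts divided by s_j.
#'
#' @param m A `bgc_counts` in state `"pseudocounted"` (every entry >= 1,
#'   so geometric means are positive).
#' @return The object with `size_factors`, `normalized` and state
#'   `"normalized"`.
#' @export
size_factor_normalize <- function(m) {
  stopifnot(inherits(m, "bgc_counts"))
  if (m$state != "pseudocounted") {
    stop("size_factor_normalize expects a pseudocounted matrix", call. = FALSE)
  }
  cnt <- m$counts
  if (ncol(cnt) == 1) {
    warning("single sample: size factor set to 1", call. = FALSE)
    s <- 1
  } else {
    gm <- exp(rowMeans(log(cnt)))
    s <- apply(cnt / gm, 2, median)
  }
  m$size_factors <- setNames(as.numeric(s), colnames(cnt))
  m$normalized <- sweep(cnt, 2, s, "/")
  m$state <- "normalized"
  m
}

#' Remove low-abundance BGCs from a normalized count matrix
#'
#' BGCs whose total normalized count across all samples is strictly below
#' `min_total` are removed.
#'
#' @param m A normalized `bgc_counts`.
#' @param min_total Threshold (default 100 normalized reads).
#' @return The filtered object.
#' @export
abundance_filter <- function(m, min_total = 100) {
  stopifnot(inherits(m, "bgc_counts"))
  if (m$state != "normalized") {
    stop("abundance_filter expects a normalized matrix", call. = FALSE)
  }
  keep <- rowSums(m$normalized) >= min_total
  if (!any(keep)) stop("abundance filter removed every BGC", call. = FALSE)
  m$counts <- m$counts[keep, , drop = FALSE]
  m$normalized <- m$normalized[keep, , drop = FALSE]
  m
}

#' Quantify a set of samples against a k-mer index
#'
#' For each sample, obtains reads either from `fastq_dir` (files named
#' `<sample_id>.fastq`) or by deterministic re-simulation from the
#' per-sample seed, pseudoaligns them, runs [em_quantify()] and aggregates
#' to BGC counts.
#'
#' @param catalog Catalog tibble (after [filter_nonbiosynthetic_orfs()] if
#'   desired); aggregation uses its ORF-to-BGC map.
#' @param index `kmer_index` built over the catalog's ORFs.
#' @param metadata,taxa,truth,config Study pieces from [simulate_study()];
#'   only needed when `fastq_dir` is `NULL`.
#' @param fastq_dir Optional directory of per-sample FASTQ files.
#' @param full_catalog Catalog used for read simulation (defaults to
#'   `catalog`); pass the unfiltered catalog so simulated reads include
#'   nonbiosynthetic ORFs.
#' @param orf_fasta Named ORF sequences for re-simulation (full catalog).
#' @return List with `bgc_counts` (named list of per-sample BGC count
#'   vectors), `orf_counts` (ORF x sample matrix of EM estimates) and
#'   `unassigned` (named integer).
#' @export
quantify_samples <- function(catalog, index, metadata, taxa = NULL,
                             truth = NULL, config = NULL, fastq_dir = NULL,
                             full_catalog = catalog, orf_fasta = NULL) {
  samples <- metadata$sample_id
  orf_mat <- matrix(0, nrow = length(index$target_ids),
                    ncol = length(samples),
                    dimnames = list(index$target_ids, samples))
  unassigned <- setNames(integer(length(samples)), samples)
  bgc_counts <- vector("list", length(samples))
  names(bgc_counts) <- samples
  for (sid in samples) {
    if (!is.null(fastq_dir)) {
      reads <- unname(read_fastq(file.path(fastq_dir, paste0(sid, ".fastq"))))
    } else {
      if (is.null(config) || is.null(orf_fasta)) {
        stop("either fastq_dir or (taxa, truth, config, orf_fasta) must ",
             "be supplied", call. = FALSE)
      }
      sim <- withCallingHandlers(
        simulate_sample_reads(sid, full_catalog, orf_fasta,
                              taxa, metadata, truth, config),
        warning = function(w) invokeRestart("muffleWarning"))
      reads <- sim$reads
    }
    aln <- pseudoalign(index, reads)
    est <- em_quantify(aln, index)
    orf_mat[, sid] <- est
    unassigned[sid] <- aln$n_unassigned
    bgc_counts[[sid]] <- aggregate_to_bgc(est, catalog)
  }
  list(bgc_counts = bgc_counts, orf_counts = orf_mat, unassigned = unassigned)
}
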