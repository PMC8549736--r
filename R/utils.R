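#' Derive a reproducible integer seed from a base seed and a label
#'
#' Stage- and sample-level randomness is driven by seeds derived from one
#' global seed plus a string label (stage name or sample id), so any stage
#' or sample can be re-simulated independently and in any order.
#'
#' @param seed Integer base seed.
#' @param id Character label (e.g. a sample id or stage name).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, id) {
  bytes <- utf8ToInt(paste0(seed, "/", id))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

# round to one decimal, half-up (printed-percent convention)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# round to integer, halves away from zero
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# reverse complement of ACGT strings (no ambiguity codes)
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

geomean <- function(x) exp(mean(log(x)))

# taxa tables are wide tibbles: sample_id column + one column per species
taxa_matrix <- function(taxa) {
  stopifnot("sample_id" %in% names(taxa))
  m <- as.matrix(taxa[setdiff(names(taxa), "sample_id")])
  rownames(m) <- taxa$sample_id
  m
}

matrix_to_taxa <- function(m) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}
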