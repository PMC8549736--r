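# broom-style tidiers for the package's result objects.

#' @export
tidy.adt_anosim <- function(x, ...) {
  tibble::tibble(statistic = x$R, p.value = x$p_value,
                 n.permutations = x$n_perm)
}

#' @export
glance.adt_anosim <- function(x, ...) tidy.adt_anosim(x)

#' @export
tidy.adt_nmds <- function(x, ...) {
  tibble::as_tibble(x$points, rownames = "sample_id")
}

#' @export
glance.adt_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, n.restarts = x$n_restarts,
                 converged = x$converged)
}

#' @export
tidy.adt_ward <- function(x, ...) {
  out <- tibble::tibble(sample_id = names(x$labels) %||%
                          as.character(seq_along(x$labels)),
                        cluster = unname(x$labels))
  if (!is.null(x$purity)) {
    out <- dplyr::left_join(out, x$purity[, c("cluster", "majority_site")],
                            by = "cluster")
  }
  out
}

#' @export
glance.adt_ward <- function(x, ...) {
  tibble::tibble(K = x$K,
                 min.purity = if (is.null(x$purity)) NA_real_ else
                   min(x$purity$purity),
                 mean.purity = if (is.null(x$purity)) NA_real_ else
                   mean(x$purity$purity))
}

#' @export
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 epsilon.sq = x$epsilon_sq, n = x$n)
}

#' Long tibble view of a count matrix
#' @param x A `bgc_counts` object.
#' @param ... Unused.
#' @export
tidy.bgc_counts <- function(x, ...) {
  out <- tibble::as_tibble(x$counts, rownames = "bgc_id") |>
    tidyr::pivot_longer(-"bgc_id", names_to = "sample_id",
                        values_to = "count")
  if (!is.null(x$normalized)) {
    nrm <- tibble::as_tibble(x$normalized, rownames = "bgc_id") |>
      tidyr::pivot_longer(-"bgc_id", names_to = "sample_id",
                          values_to = "normalized")
    out <- dplyr::left_join(out, nrm, by = c("bgc_id", "sample_id"))
  }
  out
}

#' @export
glance.bgc_counts <- function(x, ...) {
  tibble::tibble(n.bgcs = nrow(x$counts), n.samples = ncol(x$counts),
                 state = x$state)
}
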