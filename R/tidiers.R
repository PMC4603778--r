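#' Tidy a per-population count table
#'
#' @param x A `del_counts` from [count_reads()].
#' @param ... Unused.
#' @return Long tibble: trisynthon columns, `population`, `count`.
#' @exportS3Method generics::tidy
tidy.del_counts <- function(x, ...) {
  k <- sum(grepl("^code", names(x)))
  key_cols <- c(paste0("code", seq_len(k)), paste0("block", seq_len(k)))
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-dplyr::all_of(key_cols),
                        names_to = "population", values_to = "count")
}

#' @rdname tidy.del_counts
#' @return `glance()`: one row per population with read totals, decoded
#'   (`ok`) counts and the decode rate.
#' @exportS3Method generics::glance
glance.del_counts <- function(x, ...) {
  failures <- attr(x, "failures")
  totals <- attr(x, "totals")
  failures |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(total = unname(totals[.data$population]),
                  decode_rate = .data$ok / .data$total)
}

#' Tidy enrichment results
#' @param x A `del_enrichment` from [rank_enriched()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.del_enrichment <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.del_enrichment
#' @exportS3Method generics::glance
glance.del_enrichment <- function(x, ...) {
  tibble::tibble(
    n_trisynthons = nrow(x),
    sel_total = attr(x, "sel_total"),
    naive_total = attr(x, "naive_total"),
    diversity = attr(x, "diversity"),
    max_fold_enrichment = if (nrow(x)) max(x$fold_enrichment) else NA_real_
  )
}

#' Tidy detected families
#' @param x A `del_families` from [detect_planes()].
#' @param ... Unused.
#' @return The plane table.
#' @exportS3Method generics::tidy
tidy.del_families <- function(x, ...) x$planes

#' @rdname tidy.del_families
#' @exportS3Method generics::glance
glance.del_families <- function(x, ...) {
  tibble::tibble(
    n_planes = nrow(x$planes),
    n_member_trisynthons = if (nrow(x$members))
      nrow(dplyr::distinct(x$members[grep("^code", names(x$members))])) else 0L,
    min_members = x$params$min_members,
    tail_threshold = x$params$tail_threshold,
    min_coverage = x$params$min_coverage
  )
}
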