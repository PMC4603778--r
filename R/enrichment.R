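#' Fold enrichment of a trisynthon over the naive library
#'
#' Observed selected frequency divided by the naive baseline. The baseline
#' is the trisynthon's naive frequency when it was observed in the naive
#' sequencing, and otherwise the naive-library average `1 / diversity` -
#' the comparison used to report enrichment for binders never sampled in
#' the naive pool. No pseudocounts are applied. Vectorised.
#'
#' @param sel_count,sel_total Selected-population count and total reads.
#' @param naive_count,naive_total Naive-population count and total reads.
#' @param diversity Library diversity (distinct products), the baseline
#'   denominator for naive dropouts; see [library_diversity()].
#' @return Fold enrichment (>= 0).
#' @examples
#' # a trisynthon seen 13x among 147,885 selected reads and never among
#' # 2,037,412 naive reads of a 334-million-member library:
#' fold_enrichment(13, 147885, 0, 2037412, 2259 * 222 * 667)  # ~29,400
#' @export
fold_enrichment <- function(sel_count, sel_total, naive_count, naive_total,
                            diversity) {
  if (any(sel_total <= 0)) abort("sel_total must be positive")
  if (any(diversity <= 0)) abort("diversity must be positive")
  if (any(naive_total <= 0)) abort("naive_total must be positive")
  baseline <- ifelse(naive_count > 0, naive_count / naive_total, 1 / diversity)
  (sel_count / sel_total) / baseline
}

#' Rank trisynthons by fold enrichment
#'
#' Computes per-trisynthon fold enrichment ([fold_enrichment()]) and two
#' tail probabilities under the no-enrichment null. `poisson_tail` is the
#' chance of at least the observed selected count at
#' `rate = sel_total * baseline` (the baseline treated as a known rate).
#' `binom_tail` is the exact conditional test of the same null that also
#' accounts for naive-count sampling noise: given `sel_count + naive_count`
#' observations of the trisynthon, the selected share is
#' `Binomial(sel_count + naive_count, sel_total / (sel_total + naive_total))`,
#' which stays calibrated when naive counts are small (for a naive dropout
#' it reduces to `f^sel_count`). Family detection combines `binom_tail`;
#' ranking is descending by fold enrichment, ties broken by count then
#' lexicographic codes (stable).
#'
#' @param counts A `del_counts` from [count_reads()] (or any tibble with
#'   `code*`/`block*` columns and the two population count columns).
#' @param diversity Library diversity for the zero-naive baseline.
#' @param selected,naive Names of the count columns.
#' @param min_count Keep trisynthons with at least this selected count.
#' @return Tibble of class `del_enrichment` with columns `sel_count`,
#'   `naive_count`, `fold_enrichment`, `poisson_tail`, `log_poisson_tail`;
#'   attributes `sel_total`, `naive_total`, `diversity`, `cycle_sizes`.
#' @export
rank_enriched <- function(counts, diversity, selected = "selected",
                          naive = "naive", min_count = 1L) {
  for (col in c(selected, naive)) {
    if (!col %in% names(counts)) abort(sprintf("population column '%s' missing", col))
  }
  k <- sum(grepl("^code", names(counts)))
  sel_total <- sum(counts[[selected]])
  naive_total <- sum(counts[[naive]])
  code_cols <- paste0("code", seq_len(k))
  out <- counts |>
    tibble::as_tibble() |>
    dplyr::rename(sel_count = dplyr::all_of(selected),
                  naive_count = dplyr::all_of(naive)) |>
    dplyr::filter(.data$sel_count >= min_count) |>
    dplyr::mutate(
      fold_enrichment = fold_enrichment(.data$sel_count, sel_total,
                                        .data$naive_count, naive_total,
                                        diversity),
      baseline = ifelse(.data$naive_count > 0,
                        .data$naive_count / naive_total, 1 / diversity),
      log_poisson_tail = stats::ppois(.data$sel_count - 1L,
                                      sel_total * .data$baseline,
                                      lower.tail = FALSE, log.p = TRUE),
      poisson_tail = exp(.data$log_poisson_tail),
      log_binom_tail = stats::pbinom(.data$sel_count - 1L,
                                     .data$sel_count + .data$naive_count,
                                     sel_total / (sel_total + naive_total),
                                     lower.tail = FALSE, log.p = TRUE),
      binom_tail = exp(.data$log_binom_tail)
    ) |>
    dplyr::select(-"baseline") |>
    dplyr::arrange(dplyr::desc(.data$fold_enrichment),
                   dplyr::desc(.data$sel_count),
                   dplyr::across(dplyr::all_of(code_cols)))
  structure(out, class = c("del_enrichment", class(tibble::tibble())),
            sel_total = sel_total, naive_total = naive_total,
            diversity = diversity, cycle_sizes = attr(counts, "cycle_sizes"))
}

#' Detect building-block planes (compound families)
#'
#' A family in a three-cycle library appears as a plane of the cube: the
#' set of enriched trisynthons sharing one fixed building block in one
#' cycle. Candidate planes are every (cycle, block) among the enriched
#' results. Member evidence is combined with Fisher's method on the
#' per-trisynthon conditional tails (`-2 * sum(log p) ~ chi-squared(2k)`,
#' the calibrated null probability of a member-tail product as small as
#' observed), Bonferroni-adjusted across candidates. Because a strong plane
#' in one cycle induces apparently significant blocks in the other cycles
#' (each cuts a thin slice through the true plane, a fraction roughly one
#' over the fixed cycle's size), a reported plane must also cover at least
#' `min_coverage` of its possible member combinations; a genuine plane is
#' essentially fully populated while orthogonal slices are not.
#'
#' @param results A `del_enrichment` from [rank_enriched()].
#' @param min_members Minimum enriched members for a candidate plane.
#' @param tail_threshold Bonferroni-adjusted significance threshold.
#' @param min_coverage Minimum fraction of the block's possible trisynthons
#'   present among the enriched members.
#' @param cycle_sizes Named vector of tag wells per cycle; defaults to the
#'   attribute carried from [count_reads()].
#' @return Object of class `del_families`: `$planes` (cycle, block_id,
#'   n_members, coverage, fisher_stat, p_value, p_adjusted), `$members`
#'   (plane-tagged member trisynthons), `$params`.
#' @export
detect_planes <- function(results, min_members = 3L, tail_threshold = 0.01,
                          min_coverage = 0.5, cycle_sizes = NULL) {
  stopifnot(nrow(results) > 0)
  cycle_sizes <- cycle_sizes %||% attr(results, "cycle_sizes")
  if (is.null(cycle_sizes)) abort("supply `cycle_sizes` (tag wells per cycle)")
  k <- length(cycle_sizes)
  res <- tibble::as_tibble(results)

  cand <- purrr::map_dfr(seq_len(k), function(ci) {
    res |>
      dplyr::group_by(block_id = .data[[paste0("block", ci)]]) |>
      dplyr::summarise(
        n_members = dplyr::n(),
        fisher_stat = -2 * sum(.data$log_binom_tail),
        .groups = "drop"
      ) |>
      dplyr::mutate(cycle = ci, .before = 1) |>
      dplyr::mutate(coverage = .data$n_members / prod(cycle_sizes[-ci]))
  }) |>
    dplyr::filter(.data$n_members >= min_members)

  if (nrow(cand) == 0L) {
    planes <- tibble::tibble(cycle = integer(), block_id = character(),
                             n_members = integer(), coverage = double(),
                             fisher_stat = double(), p_value = double(),
                             p_adjusted = double())
  } else {
    planes <- cand |>
      dplyr::mutate(
        p_value = stats::pchisq(.data$fisher_stat, df = 2 * .data$n_members,
                                lower.tail = FALSE),
        p_adjusted = pmin(1, .data$p_value * dplyr::n())
      ) |>
      dplyr::filter(.data$p_adjusted < tail_threshold,
                    .data$coverage >= min_coverage) |>
      dplyr::arrange(.data$p_adjusted, dplyr::desc(.data$n_members))
  }

  members <- purrr::pmap_dfr(
    planes[c("cycle", "block_id")],
    function(cycle, block_id) {
      res |>
        dplyr::filter(.data[[paste0("block", cycle)]] == block_id) |>
        dplyr::mutate(plane_cycle = cycle, plane_block = block_id, .before = 1)
    }
  )

  structure(
    list(planes = planes, members = members,
         params = list(min_members = min_members,
                       tail_threshold = tail_threshold,
                       min_coverage = min_coverage,
                       cycle_sizes = cycle_sizes)),
    class = "del_families"
  )
}

#' @export
print.del_families <- function(x, ...) {
  cat("<del_families> ", nrow(x$planes), " plane(s) detected\n", sep = "")
  if (nrow(x$planes)) print(x$planes)
  invisible(x)
}

#' Building-block prevalence within a family
#'
#' Fraction of the family's member trisynthons carrying each building block
#' of one cycle. Denominators count member trisynthons (not reads);
#' fractions over the blocks present sum to 1.
#'
#' @param family A `del_families` object (members of all detected planes,
#'   distinct trisynthons) or a tibble of member trisynthons with `block*`
#'   columns.
#' @param cycle Cycle to tabulate.
#' @return Tibble `block_id`, `n`, `prevalence`, descending.
#' @export
prevalence_table <- function(family, cycle) {
  members <- if (inherits(family, "del_families")) family$members else
    tibble::as_tibble(family)
  if (nrow(members) == 0L) abort("family has no members")
  k <- sum(grepl("^code", names(members)))
  members <- dplyr::distinct(members,
                             dplyr::across(dplyr::all_of(paste0("code", seq_len(k)))),
                             .keep_all = TRUE)
  col <- paste0("block", cycle)
  members |>
    dplyr::count(block_id = .data[[col]], name = "n") |>
    dplyr::mutate(prevalence = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$prevalence), .data$block_id)
}

#' Cube-plot coordinates of a count table
#'
#' Maps each observed trisynthon to integer axis coordinates: the position
#' of its building block within the cycle's well order in the schema.
#' Members of a plane share one fixed coordinate.
#'
#' @param counts A `del_counts` (or tibble with `block*` columns and a
#'   count column).
#' @param schema The [del_schema()] defining block order.
#' @param population Count column to carry; defaults to the first count
#'   column.
#' @return Tibble `index1..indexK`, `block1..blockK`, `count`, one row per
#'   trisynthon with positive count.
#' @export
cube_coordinates <- function(counts, schema, population = NULL) {
  stopifnot(inherits(schema, "del_schema"))
  k <- n_cycles(schema)
  block_cols <- paste0("block", seq_len(k))
  count_cols <- setdiff(names(counts), c(block_cols, paste0("code", seq_len(k))))
  population <- population %||% count_cols[1]
  out <- tibble::as_tibble(counts)[c(block_cols, population)]
  names(out)[k + 1L] <- "count"
  out <- dplyr::filter(out, .data$count > 0)
  for (ci in seq_len(k)) {
    order_ci <- unique(schema$blocks$block_id[schema$blocks$cycle == ci])
    idx <- match(out[[paste0("block", ci)]], order_ci)
    if (anyNA(idx)) {
      abort(sprintf("block(s) not in schema cycle %d: %s", ci,
                    paste(unique(out[[paste0("block", ci)]][is.na(idx)]), collapse = ", ")))
    }
    out[[paste0("index", ci)]] <- idx
  }
  dplyr::relocate(out, dplyr::all_of(paste0("index", seq_len(k))))
}
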