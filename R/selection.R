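#' Affinity model for selection simulation
#'
#' Binding and capture of a library member during one selection round is
#' abstracted as an independent Bernoulli event per molecule copy. Every
#' trisynthon captures at the background probability unless it belongs to a
#' planted family (a fixed building block in one cycle, i.e. a plane of the
#' cube), in which case the planted capture probability applies; explicit
#' per-trisynthon overrides take final precedence.
#'
#' @param background Background capture probability.
#' @param planted Tibble with columns `cycle`, `block_id`, `capture_prob`
#'   (one row per planted plane), or `NULL`.
#' @param overrides Optional tibble with columns `code1..codeK`,
#'   `capture_prob`.
#' @return An object of class `del_affinity`.
#' @examples
#' affinity_model(0.001, planted = tibble::tibble(
#'   cycle = 3, block_id = "boronate3_001", capture_prob = 0.5))
#' @export
affinity_model <- function(background = 0.001, planted = NULL, overrides = NULL) {
  stopifnot(background >= 0, background <= 1)
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("cycle", "block_id", "capture_prob") %in% names(planted)),
              all(planted$capture_prob >= 0), all(planted$capture_prob <= 1))
    if (any(planted$capture_prob < background)) {
      abort("planted capture probabilities must be >= background")
    }
  }
  structure(list(background = background, planted = planted,
                 overrides = overrides),
            class = "del_affinity")
}

capture_probs <- function(affinity, tri) {
  p <- rep(affinity$background, nrow(tri))
  if (!is.null(affinity$planted)) {
    for (i in seq_len(nrow(affinity$planted))) {
      row <- affinity$planted[i, ]
      hit <- tri[[paste0("block", row$cycle)]] == row$block_id
      p[hit] <- pmax(p[hit], row$capture_prob)
    }
  }
  if (!is.null(affinity$overrides)) {
    keys <- intersect(names(affinity$overrides), names(tri))
    idx <- dplyr::left_join(
      tri[keys],
      dplyr::mutate(affinity$overrides, .row = dplyr::row_number()),
      by = keys
    )$.row
    p[!is.na(idx)] <- affinity$overrides$capture_prob[idx[!is.na(idx)]]
  }
  p
}

#' Simulate rounds of affinity selection
#'
#' Starts every trisynthon at `copies_per_member` molecules (optionally
#' Poisson-distributed around it) and, for each round, draws the surviving
#' copy number from `Binomial(count, capture_prob)`. No competition,
#' ligand depletion, or amplification bias is modelled: rounds are
#' independent thinning operations, so a member with capture probability
#' `p` retains an expected fraction `p^rounds` of its copies.
#'
#' @param schema A [del_schema()] with materialised tags.
#' @param affinity An [affinity_model()].
#' @param copies_per_member Starting copy number per trisynthon.
#' @param rounds Number of selection rounds (the reference workflow uses 2).
#' @param seed Optional seed.
#' @param poisson_start If `TRUE`, round-0 counts are
#'   `Poisson(copies_per_member)` instead of exact.
#' @return Tibble with the trisynthon columns of [trisynthons()], the
#'   per-member `capture_prob`, and counts `count_0` (input pool) through
#'   `count_<rounds>`.
#' @export
simulate_selection <- function(schema, affinity, copies_per_member = 1000L,
                               rounds = 2L, seed = NULL,
                               poisson_start = FALSE) {
  stopifnot(inherits(schema, "del_schema"), inherits(affinity, "del_affinity"),
            rounds >= 1, copies_per_member >= 0)
  set_seed_if(seed)
  tri <- trisynthons(schema)
  if (nrow(tri) == 0L) abort("schema enumerates an empty library")
  p <- capture_probs(affinity, tri)
  tri$capture_prob <- p
  n <- nrow(tri)
  count <- if (poisson_start) stats::rpois(n, copies_per_member)
           else rep(as.integer(copies_per_member), n)
  tri$count_0 <- count
  for (r in seq_len(rounds)) {
    count <- stats::rbinom(n, count, p)
    tri[[paste0("count_", r)]] <- count
  }
  tri
}

#' Emit synthetic sequencing reads for a selection population
#'
#' Samples reads multinomially in proportion to a count column, builds each
#' read from the schema's layout (hairpin constant, reverse-complemented
#' codes in cycle order K..1 separated by single-A junction gaps, the
#' faithful headpiece tail), optionally truncates reads at a simulated
#' polymerase stall (per-junction read-through, stall artifacts applied at
#' the read end), applies uniform per-base substitution errors, and writes
#' Phred+33 FASTQ with constant quality 30. Identical seeds reproduce
#' byte-identical FASTQ.
#'
#' @param counts Output of [simulate_selection()].
#' @param schema The [del_schema()] the counts came from.
#' @param n_reads Number of reads to emit.
#' @param fastq Output FASTQ path (".gz" suffix compresses).
#' @param round Count column to sample from; default the final round.
#' @param error_rate Per-base substitution probability.
#' @param enzyme A [enzyme_profile()] for stall truncation, or `NULL` to
#'   emit full-length reads only.
#' @param population Label recorded in read ids and the truth table.
#' @param seed Optional seed.
#' @param truth Optional path for the truth table TSV.
#' @param metadata Optional path for a run-metadata JSON (seed, parameters).
#' @return The truth tibble (`read_id`, trisynthon codes and blocks,
#'   `truncated`, `stopped_at`, `n_errors`, `population`), invisibly the
#'   paths as attributes.
#' @export
emit_reads <- function(counts, schema, n_reads, fastq,
                       round = NULL, error_rate = 0.005, enzyme = NULL,
                       population = "reads", seed = NULL,
                       truth = NULL, metadata = NULL) {
  stopifnot(inherits(schema, "del_schema"), n_reads >= 0)
  count_cols <- grep("^count_", names(counts), value = TRUE)
  if (length(count_cols) == 0L) abort("`counts` has no count_* columns")
  round_col <- if (is.null(round)) count_cols[length(count_cols)]
               else paste0("count_", round)
  stopifnot(round_col %in% names(counts))
  weights <- counts[[round_col]]
  if (n_reads > 0 && sum(weights) == 0) {
    abort(sprintf("cannot draw reads: all '%s' counts are zero", round_col))
  }
  set_seed_if(seed)

  k <- n_cycles(schema)
  layout <- read_layout(schema)
  prefix <- schema$hairpin_constant
  tail_const <- headpiece_read_tail(schema$headpiece)
  gap <- strrep("A", schema$junction_gap[1])  # deterministic single-A skip

  idx <- sample.int(nrow(counts), n_reads, replace = TRUE, prob = weights)
  rc <- lapply(seq_len(k), function(ci) reverse_complement(counts[[paste0("code", ci)]]))

  # segment list in read order: prefix, [gap, code_K] ... [gap, code_1], tail
  segs <- list(rep(prefix, n_reads))
  for (ci in rev(seq_len(k))) {
    segs[[length(segs) + 1]] <- rep(gap, n_reads)
    segs[[length(segs) + 1]] <- rc[[ci]][idx]
  }
  segs[[length(segs) + 1]] <- rep(tail_const, n_reads)

  stopped_at <- rep(NA_integer_, n_reads)
  if (!is.null(enzyme)) {
    stopifnot(inherits(enzyme, "del_enzyme"))
    p <- enzyme$read_through_prob
    # stop ordinal s in 1..k counted from the hairpin side, k+1 = full length
    probs <- c(p^(seq_len(k) - 1) * (1 - p), p^k)
    s <- sample.int(k + 1L, n_reads, replace = TRUE, prob = probs)
    stalled <- s <= k
    stopped_at[stalled] <- s[stalled]
    # a stall before gap s removes every segment from that gap onward
    for (j in seq_len(k)) {
      kill <- stalled & s <= j
      segs[[2 * j]][kill] <- ""       # gap before window for cycle k - j + 1
      segs[[2 * j + 1]][kill] <- ""   # that tag window
    }
    segs[[2 * k + 2]][stalled] <- ""  # tail constant
    reads <- do.call(paste0, segs)
    if (any(stalled)) {
      art <- sample(names(enzyme$stall_weights), sum(stalled), replace = TRUE,
                    prob = enzyme$stall_weights)
      w <- which(stalled)
      plus <- w[art == "plus_A"]
      reads[plus] <- paste0(reads[plus], "A")
      for (i in w[art == "minus_A"]) reads[i] <- apply_artifact(reads[i], "minus_A")
    }
  } else {
    reads <- do.call(paste0, segs)
  }

  # uniform substitution errors
  len <- nchar(reads)
  n_err <- stats::rbinom(n_reads, len, error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(len[i], n_err[i])
    for (p_i in pos) {
      old <- substr(reads[i], p_i, p_i)
      substr(reads[i], p_i, p_i) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }

  ids <- sprintf("%s_%07d", population, seq_len(max(n_reads, 0L)))
  write_fastq(reads, ids, fastq)

  truth_tbl <- tibble::tibble(read_id = ids)
  for (ci in seq_len(k)) {
    truth_tbl[[paste0("code", ci)]] <- counts[[paste0("code", ci)]][idx]
    truth_tbl[[paste0("block", ci)]] <- counts[[paste0("block", ci)]][idx]
  }
  truth_tbl$truncated <- !is.na(stopped_at)
  truth_tbl$stopped_at <- stopped_at
  truth_tbl$n_errors <- n_err
  truth_tbl$population <- population

  if (!is.null(truth)) readr::write_tsv(truth_tbl, truth)
  if (!is.null(metadata)) {
    jsonlite::write_json(
      list(population = population, n_reads = n_reads, round = round_col,
           error_rate = error_rate, seed = seed,
           enzyme = if (!is.null(enzyme)) enzyme$name,
           read_through_prob = if (!is.null(enzyme)) enzyme$read_through_prob,
           junction_gap = schema$junction_gap,
           layout_min_length = layout_min_length(layout)),
      metadata, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  attr(truth_tbl, "fastq") <- fastq
  truth_tbl
}

write_fastq <- function(reads, ids, path) {
  qual <- Biostrings::PhredQuality(vapply(nchar(reads), strrep, "", x = "?"))
  xs <- Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(reads), qual)
  names(xs) <- ids
  Biostrings::writeQualityScaledXStringSet(
    xs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

read_fastq <- function(path) {
  xs <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub(" .*", "", names(xs)),
                 sequence = as.character(xs))
}
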