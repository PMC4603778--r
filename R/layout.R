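#' Expected sequencing-read layout for a schema
#'
#' The library molecule is read by self-primed extension from the hairpin
#' end, so reads carry the hairpin constant first and the tag codes in
#' reverse cycle order (cycle K, ..., 1) as reverse complements. Each
#' `U^tr-T` junction contributes a run of adenosines whose length is
#' `junction_gap[1]` (single-A skip, the behaviour observed with Klenow)
#' up to `junction_gap[2]` (faithful copy of both junction bases). The
#' final `rG^tr-T` junction into the headpiece is copied faithfully, so the
#' read ends in a fixed constant: `A` (from the last tag's leading T), `C`
#' (from the ribo-G) and the reverse complement of the rest of the
#' headpiece.
#'
#' @param schema A [del_schema()].
#' @return A tibble of class `del_layout`: one row per segment with columns
#'   `segment` (`"constant"`, `"junction_gap"`, `"tag_window"`), `cycle`,
#'   `sequence` (constants only), `min_len`, `max_len`, and 0-based
#'   half-open coordinates `start0`/`end0` under minimum gap lengths.
#' @export
read_layout <- function(schema) {
  stopifnot(inherits(schema, "del_schema"))
  k <- n_cycles(schema)
  gap <- schema$junction_gap
  tail_const <- headpiece_read_tail(schema$headpiece)

  rows <- list(tibble::tibble(
    segment = "constant", cycle = NA_integer_,
    sequence = schema$hairpin_constant,
    min_len = nchar(schema$hairpin_constant),
    max_len = nchar(schema$hairpin_constant)
  ))
  for (ci in rev(seq_len(k))) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      segment = "junction_gap", cycle = NA_integer_, sequence = NA_character_,
      min_len = gap[1], max_len = gap[2]
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      segment = "tag_window", cycle = ci, sequence = NA_character_,
      min_len = schema$code_length, max_len = schema$code_length
    )
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    segment = "constant", cycle = NA_integer_, sequence = tail_const,
    min_len = nchar(tail_const), max_len = nchar(tail_const)
  )
  out <- dplyr::bind_rows(rows)
  out$start0 <- cumsum(dplyr::lag(out$min_len, default = 0L))
  out$end0 <- out$start0 + out$min_len
  structure(out, class = c("del_layout", class(out)),
            junction_gap = gap, code_length = schema$code_length)
}

# Constant read suffix implied by faithful copying of the rG^tr-T junction:
# complement of the last tag's leading T ("A"), of the ribo-G ("C"), then
# the reverse complement of the deoxy part of the headpiece.
headpiece_read_tail <- function(headpiece) {
  stopifnot(grepl("rG$", headpiece))
  deoxy <- sub("rG$", "", headpiece)
  stopifnot(!grepl("[^ACGT]", deoxy))
  paste0("A", "C", reverse_complement(deoxy))
}

# Minimum read length at which all tag windows are present.
layout_min_length <- function(layout) sum(layout$min_len)
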