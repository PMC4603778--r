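#' Generate a set of encoding tag codes
#'
#' Draws random 13-base (by default) codes over A/C/G/T and keeps those at
#' least `min_distance` edit operations away from every previously accepted
#' code (greedy rejection sampling). Distance 3 guarantees unambiguous
#' decoding with a 1-mismatch budget. The published tag architecture frames
#' each code as `T<code>U`, which `full_sequence` reports.
#'
#' @param n Number of tags.
#' @param cycle Cycle index recorded on the tags.
#' @param code_length Code length in bases.
#' @param min_distance Minimum pairwise edit distance between codes.
#' @param seed Optional integer seed for reproducibility.
#' @param max_attempts Rejection-sampling budget; exceeded means the
#'   constraint is infeasible at this `n` and an error is thrown.
#' @return Tibble with columns `cycle`, `well_id`, `code`, `full_sequence`.
#' @examples
#' generate_tag_set(8, min_distance = 3, seed = 7)
#' @export
generate_tag_set <- function(n, cycle = 1L, code_length = 13L,
                             min_distance = 3L, seed = NULL,
                             max_attempts = 200L * n) {
  stopifnot(n >= 1)
  if (n > 4^code_length) {
    abort(sprintf("cannot draw %s distinct codes of length %d (alphabet size 4)",
                  format(n, big.mark = ","), code_length))
  }
  set_seed_if(seed)
  codes <- character(0)
  attempts <- 0L
  while (length(codes) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf(
        "gave up after %d attempts: %d codes of length %d at edit distance >= %d appear infeasible",
        attempts - 1L, n, code_length, min_distance))
    }
    cand <- paste(sample(DNA_BASES, code_length, replace = TRUE), collapse = "")
    if (length(codes) == 0L ||
        min(utils::adist(cand, codes)) >= min_distance) {
      codes <- c(codes, cand)
    }
  }
  tibble::tibble(
    cycle = as.integer(cycle),
    well_id = sprintf("C%dW%04d", as.integer(cycle), seq_len(n)),
    code = codes,
    full_sequence = paste0("T", codes, "U")
  )
}

#' Generate a complete synthetic library schema
#'
#' Builds a desk-scale schema with tags and building blocks for each cycle:
#' cycle 1 amines, cycle 2 bromoaryl acids, cycle 3 boronates plus optional
#' encoded-null wells (tags whose well received no reagent).
#'
#' @param n_blocks Integer vector, reagent-bearing wells per cycle
#'   (default `c(50, 20, 20)`, the desk-scale design of 20,000 trisynthons).
#' @param n_null Encoded-null wells appended to the final cycle.
#' @param seed Integer seed for tag generation.
#' @inheritParams generate_tag_set
#' @inheritParams del_schema
#' @return A [del_schema()].
#' @examples
#' sc <- generate_schema(c(5, 4, 3), seed = 1)
#' library_diversity(sc)   # 60
#' @export
generate_schema <- function(n_blocks = c(50L, 20L, 20L), n_null = 0L,
                            code_length = 13L, min_distance = 3L,
                            seed = NULL, junction_gap = c(1L, 2L)) {
  stopifnot(length(n_blocks) >= 1L, all(n_blocks >= 1L))
  set_seed_if(seed)
  k <- length(n_blocks)
  roles <- if (k == 3L) c("amine", "bromoaryl_acid", "boronate") else
    rep("amine", k)  # role constraints only bind for three-cycle designs
  prefix <- c(amine = "amine", bromoaryl_acid = "acid", boronate = "boronate")
  tags <- list(); blocks <- list()
  for (ci in seq_len(k)) {
    n_wells <- n_blocks[ci] + if (ci == k) as.integer(n_null) else 0L
    tags[[ci]] <- generate_tag_set(n_wells, cycle = ci,
                                   code_length = code_length,
                                   min_distance = min_distance)
    ids <- c(sprintf("%s%d_%03d", prefix[[roles[ci]]], ci, seq_len(n_blocks[ci])),
             if (ci == k && n_null > 0) sprintf("null_%d", seq_len(n_null)))
    blocks[[ci]] <- tibble::tibble(
      cycle = ci,
      well_id = tags[[ci]]$well_id,
      block_id = ids,
      role = c(rep(roles[ci], n_blocks[ci]), rep("null", n_wells - n_blocks[ci]))
    )
  }
  del_schema(dplyr::bind_rows(tags), dplyr::bind_rows(blocks),
             junction_gap = junction_gap,
             min_tag_distance = as.integer(min_distance),
             code_length = as.integer(code_length))
}
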