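#' Construct a DNA-encoded library schema
#'
#' A schema ties together the per-cycle encoding tags, the building blocks
#' they encode, and the constant sequences flanking the encoding region:
#' the headpiece (3'-propargyl, terminal ribo-G) at the 5' end of the chain
#' and the self-priming hairpin ligated after the final cycle. Tags follow
#' the architecture `5'-azido-T<code>U-3'-propargyl(TIPS)`: a 13-base code
#' framed by a leading T and a trailing U, so that every chemical ligation
#' leaves either an `rG^tr-T` (headpiece) or a `U^tr-T` junction in the
#' backbone.
#'
#' @param tags Tibble with columns `cycle`, `well_id`, `code`, one row per
#'   tagged well, or `NULL` for a schema whose tag sequences are not
#'   materialised (diversity arithmetic still works; decoding does not).
#' @param blocks Tibble with columns `cycle`, `well_id`, `block_id`, `role`
#'   (`"amine"`, `"bromoaryl_acid"`, `"boronate"` or `"null"`), and
#'   optionally `display_name`.
#' @param headpiece Headpiece oligo in notation form; must end in a ribo-G
#'   (`rG`), the 5'-side partner of the faithful `rG^tr-T` junction.
#' @param hairpin_constant Constant prefix the self-priming hairpin
#'   contributes to every sequencing read, up to (not including) the first
#'   junction adenosine.
#' @param junction_gap Length-2 integer vector, the allowed number of A
#'   residues a `U^tr-T` junction leaves in the read (1 = single-A skip,
#'   2 = faithful copy of both junction bases).
#' @param min_tag_distance Minimum pairwise edit distance required between
#'   codes of the same cycle.
#' @param code_length Tag code length in bases.
#'
#' @return An object of class `del_schema`.
#' @seealso [generate_schema()], [validate_schema()], [library_diversity()],
#'   [read_layout()]
#' @export
del_schema <- function(tags, blocks,
                       headpiece = "TCGAATGACTCCGATATrG",
                       hairpin_constant = "GGAGCTTGTCACGTACGGAC",
                       junction_gap = c(1L, 2L),
                       min_tag_distance = 3L,
                       code_length = 13L) {
  if (!is.null(tags)) {
    tags <- tibble::as_tibble(tags)
    stopifnot(all(c("cycle", "well_id", "code") %in% names(tags)))
    tags <- dplyr::mutate(
      tags,
      cycle = as.integer(.data$cycle),
      full_sequence = paste0("T", .data$code, "U")
    ) |>
      dplyr::arrange(.data$cycle, .data$well_id)
  }
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("cycle", "well_id", "block_id", "role") %in% names(blocks)))
  if (!"display_name" %in% names(blocks)) blocks$display_name <- blocks$block_id
  blocks <- dplyr::mutate(blocks, cycle = as.integer(.data$cycle)) |>
    dplyr::arrange(.data$cycle, .data$well_id)
  junction_gap <- as.integer(junction_gap)
  stopifnot(length(junction_gap) == 2L, junction_gap[1] >= 1L,
            junction_gap[2] >= junction_gap[1])
  if (!grepl("rG$", headpiece)) {
    abort("`headpiece` must end in a ribo-G ('rG'): it forms the rG^tr-T junction.")
  }
  structure(
    list(
      tags = tags,
      blocks = blocks,
      headpiece = headpiece,
      hairpin_constant = hairpin_constant,
      junction_gap = junction_gap,
      min_tag_distance = as.integer(min_tag_distance),
      code_length = as.integer(code_length)
    ),
    class = "del_schema"
  )
}

#' @export
print.del_schema <- function(x, ...) {
  ncyc <- n_cycles(x)
  cat("<del_schema> ", ncyc, " cycle(s)\n", sep = "")
  wells <- dplyr::count(x$blocks, .data$cycle, name = "wells")
  for (i in seq_len(nrow(wells))) {
    cat("  cycle ", wells$cycle[i], ": ", wells$wells[i], " wells\n", sep = "")
  }
  cat("  tags: ", if (is.null(x$tags)) "not materialised" else nrow(x$tags),
      "; code length ", x$code_length,
      "; junction gap ", x$junction_gap[1], "-", x$junction_gap[2], " A\n",
      sep = "")
  invisible(x)
}

n_cycles <- function(schema) max(schema$blocks$cycle)

cycle_sizes <- function(schema) {
  # number of tagged wells per cycle (encoded combinations)
  tab <- dplyr::count(schema$blocks, .data$cycle)
  stats::setNames(tab$n, tab$cycle)
}

#' Validate a library schema
#'
#' Checks every tag and schema invariant: code length and alphabet, the
#' `T<code>U` framing, code uniqueness and minimum pairwise edit distance
#' within each cycle, the one-to-one tag/building-block well mapping, and
#' (for three-cycle designs) the expected chemistry role per cycle.
#'
#' @param schema A [del_schema()].
#' @return A tibble of violations with columns `cycle`, `well_id`, `rule`,
#'   `message`; zero rows if and only if the schema is valid.
#' @export
validate_schema <- function(schema) {
  stopifnot(inherits(schema, "del_schema"))
  v <- list()
  add <- function(cycle, well, rule, message) {
    tibble::tibble(cycle = as.integer(cycle), well_id = as.character(well),
                   rule = rule, message = message)
  }

  blocks <- schema$blocks
  cyc <- sort(unique(blocks$cycle))
  if (!identical(cyc, seq_along(cyc))) {
    v[[length(v) + 1]] <- add(NA, NA, "cycle_numbering",
                              "cycles must be numbered 1..k without gaps")
  }

  if (!is.null(schema$tags)) {
    tags <- schema$tags
    bad_len <- tags[nchar(tags$code) != schema$code_length, ]
    if (nrow(bad_len)) {
      v[[length(v) + 1]] <- add(bad_len$cycle, bad_len$well_id, "code_length",
                                sprintf("code length != %d", schema$code_length))
    }
    bad_chr <- tags[grepl("[^ACGT]", tags$code), ]
    if (nrow(bad_chr)) {
      pos <- vapply(bad_chr$code, function(s) regexpr("[^ACGT]", s)[1], 1L)
      v[[length(v) + 1]] <- add(bad_chr$cycle, bad_chr$well_id, "code_alphabet",
                                sprintf("non-ACGT character at position %d", pos))
    }
    bad_full <- tags[tags$full_sequence != paste0("T", tags$code, "U"), ]
    if (nrow(bad_full)) {
      v[[length(v) + 1]] <- add(bad_full$cycle, bad_full$well_id, "tag_framing",
                                "full_sequence != 'T' + code + 'U'")
    }
    dup <- tags |>
      dplyr::add_count(.data$cycle, .data$code) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(dup)) {
      v[[length(v) + 1]] <- add(dup$cycle, dup$well_id, "code_unique",
                                "duplicate code within cycle")
    }
    # pairwise edit distance within cycle (only among well-formed codes)
    ok_tags <- tags[nchar(tags$code) == schema$code_length &
                      !grepl("[^ACGT]", tags$code), ]
    for (ci in unique(ok_tags$cycle)) {
      codes <- ok_tags$code[ok_tags$cycle == ci]
      wells <- ok_tags$well_id[ok_tags$cycle == ci]
      if (length(codes) > 1L) {
        d <- utils::adist(codes)
        diag(d) <- NA
        close_idx <- which(apply(d, 1, function(r) any(r < schema$min_tag_distance, na.rm = TRUE)))
        if (length(close_idx)) {
          v[[length(v) + 1]] <- add(ci, wells[close_idx], "min_tag_distance",
                                    sprintf("code within edit distance %d of another code",
                                            schema$min_tag_distance - 1L))
        }
      }
    }
    # tag/block well correspondence
    miss <- dplyr::anti_join(tags, blocks, by = c("cycle", "well_id"))
    if (nrow(miss)) {
      v[[length(v) + 1]] <- add(miss$cycle, miss$well_id, "well_mapping",
                                "tag well has no building block")
    }
    orphan <- dplyr::anti_join(blocks, tags, by = c("cycle", "well_id"))
    if (nrow(orphan)) {
      v[[length(v) + 1]] <- add(orphan$cycle, orphan$well_id, "well_mapping",
                                "building-block well has no tag")
    }
  }

  if (n_cycles(schema) == 3L) {
    expected <- list(`1` = "amine", `2` = "bromoaryl_acid", `3` = c("boronate", "null"))
    for (ci in 1:3) {
      bad <- blocks[blocks$cycle == ci & !blocks$role %in% expected[[as.character(ci)]], ]
      if (nrow(bad)) {
        v[[length(v) + 1]] <- add(bad$cycle, bad$well_id, "cycle_role",
                                  sprintf("role '%s' not allowed in cycle %d",
                                          bad$role, ci))
      }
    }
  }

  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(cycle = integer(), well_id = character(),
                   rule = character(), message = character())
}

#' Library diversity under two counting rules
#'
#' `unique_products` counts distinct chemical products: the product over
#' cycles of the number of distinct non-null building blocks (an acid used
#' in several tagged wells counts once; encoded-null wells count zero).
#' `encoded_combinations` counts distinct DNA encodings: the product of
#' tagged-well counts per cycle.
#'
#' @param schema A [del_schema()].
#' @param count_rule `"unique_products"` or `"encoded_combinations"`.
#' @return A double (counts exceed 32-bit integers at production scale).
#' @examples
#' library_diversity(paper_schema())          # 334,499,166
#' @export
library_diversity <- function(schema,
                              count_rule = c("unique_products", "encoded_combinations")) {
  stopifnot(inherits(schema, "del_schema"))
  count_rule <- match.arg(count_rule)
  per_cycle <- schema$blocks |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(
      wells = dplyr::n(),
      products = dplyr::n_distinct(.data$block_id[.data$role != "null"])
    )
  if (any(per_cycle$wells == 0L) ||
      !setequal(per_cycle$cycle, seq_len(n_cycles(schema)))) {
    abort("every cycle must contain at least one well")
  }
  if (count_rule == "unique_products") {
    if (any(per_cycle$products == 0L)) {
      abort("a cycle contains only encoded nulls; no products can form")
    }
    prod(as.double(per_cycle$products))
  } else {
    prod(as.double(per_cycle$wells))
  }
}

#' Production-scale three-cycle library schema
#'
#' The block layout of the 334-million-member chemically ligated library:
#' 2,259 cycle-1 amine wells, 666 cycle-2 wells carrying 3 x 222 unique
#' bromoaryl acids (each acid tagged in three wells), and 669 cycle-3 wells
#' of which 667 carry boronic acids/esters and 2 are encoded nulls that
#' received no reagent. Tag codes are not materialised (use
#' [generate_tag_set()] to attach codes if decoding is needed at this
#' scale); diversity arithmetic and layout derivation work without them.
#'
#' @return A [del_schema()] with `tags = NULL`.
#' @examples
#' library_diversity(paper_schema())                            # 334,499,166
#' library_diversity(paper_schema(), "encoded_combinations")    # 2259*666*669
#' @export
paper_schema <- function() {
  blocks <- dplyr::bind_rows(
    tibble::tibble(
      cycle = 1L, well_id = sprintf("A%04d", 1:2259),
      block_id = sprintf("amine_%04d", 1:2259), role = "amine"
    ),
    tibble::tibble(
      cycle = 2L, well_id = sprintf("B%04d", 1:666),
      block_id = sprintf("acid_%03d", rep(1:222, each = 3)), role = "bromoaryl_acid"
    ),
    tibble::tibble(
      cycle = 3L, well_id = sprintf("C%04d", 1:669),
      block_id = c(sprintf("boronate_%03d", 1:667), "null_1", "null_2"),
      role = c(rep("boronate", 667), "null", "null")
    )
  )
  del_schema(tags = NULL, blocks = blocks)
}

#' Enumerate all encoded combinations (trisynthons) of a schema
#'
#' @param schema A [del_schema()] with materialised tags.
#' @return A tibble with one row per tag combination and columns
#'   `code1..codeK`, `block1..blockK`, `role1..roleK`.
#' @export
trisynthons <- function(schema) {
  stopifnot(inherits(schema, "del_schema"))
  if (is.null(schema$tags)) abort("schema has no materialised tags")
  k <- n_cycles(schema)
  per_cycle <- lapply(seq_len(k), function(ci) {
    dplyr::inner_join(
      schema$tags[schema$tags$cycle == ci, c("well_id", "code")],
      schema$blocks[schema$blocks$cycle == ci, c("well_id", "block_id", "role")],
      by = "well_id"
    ) |>
      stats::setNames(c("well_id", paste0(c("code", "block", "role"), ci)))
  })
  out <- per_cycle[[1]][-1]
  for (ci in seq_len(k)[-1]) {
    out <- tidyr::expand_grid(out, per_cycle[[ci]][-1])
  }
  out
}

#' Write / read a schema as plain-text tables
#'
#' `write_schema()` writes `tags.tsv` (cycle, well_id, code), `blocks.tsv`
#' (cycle, well_id, block_id, role, display_name) and `config.json`
#' (constant sequences, junction gap bounds, code length, minimum tag
#' distance) into a directory; `read_schema()` reconstructs the identical
#' schema from them.
#'
#' @param schema A [del_schema()].
#' @param dir Directory path (created if missing).
#' @return `write_schema()` returns `dir` invisibly; `read_schema()` a
#'   [del_schema()].
#' @export
write_schema <- function(schema, dir) {
  stopifnot(inherits(schema, "del_schema"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(schema$tags)) {
    readr::write_tsv(schema$tags[c("cycle", "well_id", "code")],
                     file.path(dir, "tags.tsv"))
  }
  readr::write_tsv(schema$blocks, file.path(dir, "blocks.tsv"))
  cfg <- list(
    headpiece = schema$headpiece,
    hairpin_constant = schema$hairpin_constant,
    junction_gap = schema$junction_gap,
    min_tag_distance = schema$min_tag_distance,
    code_length = schema$code_length
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_schema
#' @export
read_schema <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  tags_path <- file.path(dir, "tags.tsv")
  tags <- if (file.exists(tags_path)) {
    readr::read_tsv(tags_path, col_types = readr::cols(
      cycle = readr::col_integer(), well_id = readr::col_character(),
      code = readr::col_character()
    ))
  }
  blocks <- readr::read_tsv(file.path(dir, "blocks.tsv"), col_types = readr::cols(
    cycle = readr::col_integer(), well_id = readr::col_character(),
    block_id = readr::col_character(), role = readr::col_character(),
    display_name = readr::col_character()
  ))
  del_schema(tags, blocks,
             headpiece = cfg$headpiece,
             hairpin_constant = cfg$hairpin_constant,
             junction_gap = cfg$junction_gap,
             min_tag_distance = cfg$min_tag_distance,
             code_length = cfg$code_length)
}
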