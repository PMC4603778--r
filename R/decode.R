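#' Decode sequencing reads into trisynthons
#'
#' Anchors the constant hairpin prefix (mismatch budget
#' `constant_mismatch`), then walks the tag windows in read order (cycle K
#' down to 1). At each junction every allowed gap length (1-2 adenosines by
#' default: 1 is the single-A skip a read-through polymerase leaves, 2 the
#' no-skip fallback) is tried and the 13-base window is matched against the
#' cycle's reverse-complemented codes with at most `max_mismatch`
#' substitutions. A unique best match is required; two codes at equal
#' distance make the read `ambiguous`. No indels are tolerated inside
#' codes - length variation lives only at the junction gaps. Reads shorter
#' than the minimal layout are `truncated` (stalled extensions). Failures
#' are statuses, never errors.
#'
#' @param x FASTQ path (optionally gzipped), character vector of read
#'   sequences, or the tibble returned by `read_fastq`-style readers with
#'   columns `read_id` and `sequence`.
#' @param schema A [del_schema()] with materialised tags.
#' @param max_mismatch Substitution budget per tag code.
#' @param constant_mismatch Substitution budget for the constant prefix.
#' @param rc If `TRUE`, reverse-complement reads before decoding (for
#'   reads delivered in the opposite orientation).
#' @return Tibble with one row per read: `read_id`, `status` (`ok`,
#'   `constant_mismatch`, `tag_unmatched`, `ambiguous`, `truncated`),
#'   decoded `code*`/`block*` columns (`NA` unless `ok`), per-cycle
#'   mismatch counts `mm*` and observed junction gap lengths `gap*`
#'   (indexed from the hairpin side).
#' @export
decode_reads <- function(x, schema, max_mismatch = 1L, constant_mismatch = 1L,
                         rc = FALSE) {
  stopifnot(inherits(schema, "del_schema"))
  if (is.null(schema$tags)) abort("schema has no materialised tags to decode against")
  if (is.character(x) && length(x) == 1L && file.exists(x)) x <- read_fastq(x)
  if (is.character(x)) x <- tibble::tibble(read_id = sprintf("read_%07d", seq_along(x)),
                                           sequence = x)
  seqs <- x$sequence
  if (rc) seqs <- reverse_complement(seqs)
  n <- length(seqs)
  k <- n_cycles(schema)
  layout <- read_layout(schema)
  gaps <- seq(schema$junction_gap[1], schema$junction_gap[2])
  cl <- nchar(schema$hairpin_constant)
  wl <- schema$code_length

  # per-cycle lookup: reverse-complemented code -> block
  index <- lapply(seq_len(k), function(ci) {
    tags <- schema$tags[schema$tags$cycle == ci, ]
    blocks <- schema$blocks[schema$blocks$cycle == ci, c("well_id", "block_id")]
    tb <- dplyr::inner_join(tags, blocks, by = "well_id")
    list(rc = reverse_complement(tb$code), code = tb$code, block = tb$block_id)
  })

  status <- rep("ok", n)
  min_full <- layout_min_length(layout)
  status[nchar(seqs) < min_full] <- "truncated"

  live <- status == "ok"
  if (any(live)) {
    pref <- substr(seqs[live], 1L, cl)
    cmm <- integer(length(pref))
    inexact <- pref != schema$hairpin_constant
    if (any(inexact)) cmm[inexact] <- hamming(pref[inexact], schema$hairpin_constant)
    bad <- cmm > constant_mismatch
    status[which(live)[bad]] <- "constant_mismatch"
  }

  out_code <- matrix(NA_character_, n, k)
  out_mm <- matrix(NA_integer_, n, k)
  out_gap <- matrix(NA_integer_, n, k)
  pos <- rep(cl, n)  # 0-based offset where the next junction gap starts

  for (step in seq_len(k)) {
    ci <- k - step + 1L  # cycle decoded at this window
    live <- which(status == "ok")
    if (length(live) == 0L) break
    idx <- index[[ci]]

    win <- lapply(gaps, function(g)
      substr(seqs[live], pos[live] + g + 1L, pos[live] + g + wl))
    short <- Reduce(`&`, lapply(win, function(w) nchar(w) < wl))
    if (any(short)) status[live[short]] <- "truncated"

    hitmat <- vapply(win, function(w) match(w, idx$rc), integer(length(live)))
    hitmat <- matrix(hitmat, nrow = length(live))

    assigned <- rep(NA_integer_, length(live))
    agap <- rep(NA_integer_, length(live))
    amm <- rep(NA_integer_, length(live))

    exact_any <- rowSums(!is.na(hitmat)) > 0L
    if (any(exact_any)) {
      first_g <- apply(hitmat[exact_any, , drop = FALSE], 1L, function(r) which(!is.na(r))[1])
      code_i <- hitmat[cbind(which(exact_any), first_g)]
      # a second exact hit on a different code at another gap is a tie at 0
      multi <- apply(hitmat[exact_any, , drop = FALSE], 1L,
                     function(r) length(unique(stats::na.omit(r))) > 1L)
      assigned[exact_any] <- code_i
      agap[exact_any] <- gaps[first_g]
      amm[exact_any] <- 0L
      if (any(multi)) {
        rows <- which(exact_any)[multi]
        status[live[rows]] <- "ambiguous"
        assigned[rows] <- NA_integer_
      }
    }

    rem <- which(!exact_any & !short & status[live] == "ok")
    if (length(rem)) {
      dist_g <- lapply(seq_along(gaps), function(gi) {
        w <- win[[gi]][rem]
        d <- matrix(100L, length(rem), length(idx$rc))
        full <- nchar(w) == wl
        if (any(full)) d[full, ] <- hamming(w[full], idx$rc)
        d
      })
      d_best <- Reduce(pmin, dist_g)
      best <- apply(d_best, 1L, min)
      for (ri in seq_along(rem)) {
        b <- best[ri]
        r <- rem[ri]
        if (b > max_mismatch) {
          status[live[r]] <- "tag_unmatched"
          next
        }
        cand <- which(d_best[ri, ] == b)
        if (length(cand) > 1L) {
          status[live[r]] <- "ambiguous"
          next
        }
        gi <- which(vapply(dist_g, function(d) d[ri, cand] == b, logical(1)))[1]
        assigned[r] <- cand
        agap[r] <- gaps[gi]
        amm[r] <- as.integer(b)
      }
    }

    okrow <- which(!is.na(assigned) & status[live] == "ok")
    rows <- live[okrow]
    out_code[rows, ci] <- idx$code[assigned[okrow]]
    out_mm[rows, ci] <- amm[okrow]
    out_gap[rows, step] <- agap[okrow]
    pos[rows] <- pos[rows] + agap[okrow] + wl
  }

  res <- tibble::tibble(read_id = x$read_id, status = status)
  for (ci in seq_len(k)) res[[paste0("code", ci)]] <- out_code[, ci]
  for (ci in seq_len(k)) {
    idx <- index[[ci]]
    res[[paste0("block", ci)]] <- idx$block[match(out_code[, ci], idx$code)]
  }
  for (ci in seq_len(k)) res[[paste0("mm", ci)]] <- out_mm[, ci]
  for (step in seq_len(k)) res[[paste0("gap", step)]] <- out_gap[, step]
  res$status <- ifelse(res$status == "ok" & rowSums(is.na(out_code)) > 0L,
                       "tag_unmatched", res$status)
  res
}

#' Tabulate decoded reads into a per-population count table
#'
#' Decodes one FASTQ per population and tabulates trisynthon counts plus
#' decode-failure tallies. Totals are conserved: per population, the `ok`
#' count plus all failure counts equals the number of input reads, and the
#' count-table column sums equal the `ok` tallies.
#'
#' @param files Named character vector: population label -> FASTQ path.
#'   Alternatively a named list of decode-result tibbles from
#'   [decode_reads()] (e.g. to reuse decodes or supply raw sequences).
#' @inheritParams decode_reads
#' @return A tibble of class `del_counts`: trisynthon `code*`/`block*`
#'   columns and one count column per population. Attributes: `failures`
#'   (population, status, n), `totals` (reads in per population),
#'   `cycle_sizes` (tag wells per cycle, for downstream coverage
#'   arithmetic).
#' @export
count_reads <- function(files, schema, max_mismatch = 1L,
                        constant_mismatch = 1L, rc = FALSE) {
  stopifnot(length(files) >= 1L, !is.null(names(files)),
            all(nzchar(names(files))))
  k <- n_cycles(schema)
  key_cols <- c(paste0("code", seq_len(k)), paste0("block", seq_len(k)))
  decoded <- lapply(names(files), function(pop) {
    f <- if (is.list(files)) files[[pop]] else files[[pop]]
    if (is.data.frame(f) && "status" %in% names(f)) f
    else decode_reads(f, schema, max_mismatch = max_mismatch,
                      constant_mismatch = constant_mismatch, rc = rc)
  })
  names(decoded) <- names(files)

  failures <- purrr::imap_dfr(decoded, function(d, pop) {
    dplyr::count(d, .data$status, name = "n") |>
      dplyr::mutate(population = pop, .before = 1)
  })
  totals <- vapply(decoded, nrow, integer(1))

  tabs <- purrr::imap(decoded, function(d, pop) {
    d |>
      dplyr::filter(.data$status == "ok") |>
      dplyr::count(dplyr::across(dplyr::all_of(key_cols)), name = pop)
  })
  out <- purrr::reduce(tabs, dplyr::full_join, by = key_cols)
  out <- dplyr::mutate(out, dplyr::across(-dplyr::all_of(key_cols),
                                          ~ tidyr::replace_na(.x, 0L)))
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(key_cols[seq_len(k)])))
  structure(out,
            class = c("del_counts", class(out)),
            failures = failures, totals = totals,
            cycle_sizes = cycle_sizes(schema))
}
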