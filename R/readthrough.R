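#' Polymerase profiles for triazole read-through
#'
#' `enzyme_profile()` describes a polymerase by its per-junction probability
#' of traversing a triazole linkage and by the mixture of products it leaves
#' when it stalls (`correct` stall, `minus_A`, `plus_A`). The stall mixture
#' defaults to `{0.6, 0.3, 0.1}`: adenosine deletion is the dominant stall
#' artifact and adenosine addition is seen to a lesser extent, but the
#' underlying proportions are not quantified, so these are configuration
#' values.
#'
#' `enzyme_from_ratio()` converts a measured stall:full product ratio into
#' a profile (`read_through_prob = full / (stall + full)`), and
#' [del_enzymes()] tabulates the measured ratios for the tested enzymes
#' (Klenow fragment, the most permissive, reads through 8 of 10 times).
#'
#' @param name Enzyme name.
#' @param read_through_prob Per-junction traversal probability in `[0, 1]`.
#' @param stall_weights Named numeric, probabilities of `correct`,
#'   `minus_A`, `plus_A` given a stall; must sum to 1.
#' @return An object of class `del_enzyme`.
#' @export
enzyme_profile <- function(name, read_through_prob,
                           stall_weights = c(correct = 0.6, minus_A = 0.3, plus_A = 0.1)) {
  stopifnot(read_through_prob >= 0, read_through_prob <= 1)
  stopifnot(setequal(names(stall_weights), c("correct", "minus_A", "plus_A")),
            all(stall_weights >= 0),
            abs(sum(stall_weights) - 1) < 1e-8)
  structure(
    list(name = name, read_through_prob = read_through_prob,
         stall_weights = stall_weights[c("correct", "minus_A", "plus_A")]),
    class = "del_enzyme"
  )
}

#' @rdname enzyme_profile
#' @param stall,full Non-negative components of the measured stall:full
#'   product ratio (not both zero).
#' @examples
#' enzyme_from_ratio(2, 8, "Klenow")$read_through_prob      # 0.8
#' enzyme_from_ratio(6, 4, "Superscript III")$read_through_prob  # 0.4
#' @export
enzyme_from_ratio <- function(stall, full, name = "enzyme",
                              stall_weights = c(correct = 0.6, minus_A = 0.3, plus_A = 0.1)) {
  stopifnot(stall >= 0, full >= 0)
  if (stall + full == 0) abort("stall and full cannot both be zero")
  enzyme_profile(name, full / (stall + full), stall_weights)
}

#' Measured stall:full ratios of tested polymerases
#' @return Tibble with `name`, `stall`, `full`, `read_through_prob`.
#' @export
del_enzymes <- function() {
  tibble::tribble(
    ~name,                             ~stall, ~full,
    "E. coli DNA Pol I",                    3,     7,
    "E. coli DNA Pol I Klenow fragment",    2,     8,
    "Therminator",                          4,     6,
    "Superscript III",                      6,     4,
    "9N",                                   6,     4
  ) |>
    dplyr::mutate(read_through_prob = .data$full / (.data$stall + .data$full))
}

#' @export
print.del_enzyme <- function(x, ...) {
  cat("<del_enzyme> ", x$name, ": read-through ", x$read_through_prob,
      " per junction; stall mix correct/", "-A/+A = ",
      paste(signif(x$stall_weights, 3), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Primer-extension template over triazole junctions
#'
#' Binds a primer to the 3'-terminal region of a (possibly triazole-linked)
#' template oligo. Extension proceeds template 3' to 5', so junctions are
#' encountered primer-outward; junction types are inferred from the residue
#' on the 5' side of each triazole (`U` -> `U_tr_T`, ribo-G -> `rG_tr_T`).
#'
#' @param template A `del_oligo` (or notation string) with triazole
#'   junctions.
#' @param primer A `del_oligo` (or string) whose sequence is the reverse
#'   complement of the template's 3'-terminal region.
#' @return An object of class `del_template`.
#' @examples
#' ref <- reference_oligos()
#' tmpl <- as_template(ref$notation[ref$id == 3], ref$notation[ref$id == 4])
#' n_junctions(tmpl)   # 1
#' @export
as_template <- function(template, primer) {
  if (is.character(template)) template <- parse_oligo(template)
  if (is.character(primer)) primer <- parse_oligo(primer)
  n <- nrow(template$residues)
  k <- nrow(primer$residues)
  stopifnot(k >= 1, n > k)
  if (length(template$junctions) && max(template$junctions) > n - k) {
    abort("primer annealing site must lie 3' of every triazole junction")
  }
  anneal <- paste(COMPLEMENT[rev(template$residues$base[(n - k + 1):n])], collapse = "")
  if (anneal != oligo_sequence(primer)) {
    warn("primer is not the exact reverse complement of the template 3' terminus")
  }
  jpos <- sort(template$junctions, decreasing = TRUE)  # primer-outward order
  jtype <- vapply(jpos, function(j) {
    res <- template$residues[j, ]
    if (res$base == "U") "U_tr_T"
    else if (res$base == "G" && res$sugar == "ribo") "rG_tr_T"
    else abort(sprintf("unsupported junction context at position %d (%s)", j, res$base))
  }, character(1))
  structure(
    list(template = template, primer = primer,
         junction_pos = jpos, junction_type = jtype),
    class = "del_template"
  )
}

#' @rdname as_template
#' @param x A `del_template`.
#' @export
n_junctions <- function(x) {
  stopifnot(inherits(x, "del_template"))
  length(x$junction_pos)
}

#' Synthetic multi-junction template
#'
#' Builds a template in the style of the multi-triazole read-through
#' constructs: a headpiece segment ending in `rG^tr`, `n_junctions - 1`
#' internal tag-like segments ending in `U^tr`, and a 3' segment carrying
#' the primer binding site.
#'
#' @param n_junctions Number of triazole junctions (>= 1).
#' @return A [as_template()] object with a Cy5 primer.
#' @export
junction_template <- function(n_junctions = 1L) {
  stopifnot(n_junctions >= 1)
  notation <- paste0(
    "TCGAATGACTCCGATATrG^tr",
    strrep("TATGCGTACAGTCCU^tr", n_junctions - 1L),
    "TATAGCGCGATATACACACTGGCGAGCTTGCGTACTG"
  )
  as_template(notation, "5'-Cy5-CAGTACGCAAGCTCG")
}

# Product base string for a given stop: stop = ordinal of the junction the
# polymerase failed to cross (counted from the primer), or Inf for
# full-length. Crossing a U_tr_T junction skips the template U (its partner
# T has already been copied), leaving a single A in the product.
product_bases <- function(tmpl, stop = Inf) {
  bases <- tmpl$template$residues$base
  n <- length(bases)
  k <- nrow(tmpl$primer$residues)
  jset <- tmpl$junction_pos
  out <- character(n)
  len <- 0L
  ord <- 0L
  pos <- n - k
  while (pos >= 1L) {
    hit <- match(pos, jset)
    if (!is.na(hit)) {
      ord <- ord + 1L
      if (ord >= stop) break
      if (tmpl$junction_type[hit] == "U_tr_T") {
        pos <- pos - 1L
        next
      }
    }
    len <- len + 1L
    out[len] <- COMPLEMENT[[bases[pos]]]
    pos <- pos - 1L
  }
  paste0(oligo_sequence(tmpl$primer), paste(out[seq_len(len)], collapse = ""))
}

apply_artifact <- function(seq, artifact) {
  if (artifact == "plus_A") return(paste0(seq, "A"))
  if (artifact == "minus_A") {
    # composition-level deletion of one A; remove the last A in the string
    i <- max(gregexpr("A", seq)[[1]])
    if (i > 0) return(paste0(substr(seq, 1, i - 1), substr(seq, i + 1, nchar(seq))))
  }
  seq
}

product_oligo <- function(tmpl, seq) {
  new_oligo(
    tibble::tibble(base = strsplit(seq, "")[[1]], sugar = "deoxy"),
    five_prime_mods = tmpl$primer$five_prime_mods
  )
}

#' Simulate primer extensions across triazole junctions
#'
#' Walks the junctions primer-outward; each is traversed independently with
#' the enzyme's `read_through_prob`. A traversed `U^tr-T` junction emits a
#' single A in the product (the template U is skipped); the `rG^tr-T`
#' junction is copied faithfully. A stall draws an artifact class from the
#' enzyme's stall mixture.
#'
#' @param template A [as_template()] object.
#' @param enzyme A [enzyme_profile()].
#' @param n Number of independent extensions.
#' @param seed Optional seed.
#' @return Tibble with one row per extension: `full`, `stopped_at`
#'   (junction ordinal from the primer, `NA` when full-length), `artifact`
#'   (`"none"` for full-length), `skipped_A_count`, `product`.
#' @export
simulate_extension <- function(template, enzyme, n = 1L, seed = NULL) {
  stopifnot(inherits(template, "del_template"), inherits(enzyme, "del_enzyme"))
  set_seed_if(seed)
  J <- n_junctions(template)
  p <- enzyme$read_through_prob
  if (J == 0L) {
    stops <- rep(Inf, n)
  } else {
    pass <- matrix(stats::runif(n * J) < p, nrow = n)
    stops <- apply(pass, 1L, function(r) {
      i <- which(!r)
      if (length(i)) i[1] else Inf
    })
  }
  artifact <- rep("none", n)
  stalled <- is.finite(stops)
  if (any(stalled)) {
    artifact[stalled] <- sample(names(enzyme$stall_weights), sum(stalled),
                                replace = TRUE, prob = enzyme$stall_weights)
  }
  # distinct (stop, artifact) pairs map to precomputed products
  key <- paste(stops, artifact)
  uniq <- !duplicated(key)
  prods <- stats::setNames(
    mapply(function(s, a) apply_artifact(product_bases(template, s), a),
           stops[uniq], artifact[uniq]),
    key[uniq]
  )
  skipped <- vapply(stops, function(s) {
    traversed <- if (is.infinite(s)) seq_len(J) else seq_len(s - 1L)
    sum(template$junction_type[traversed] == "U_tr_T")
  }, integer(1))
  tibble::tibble(
    full = !stalled,
    stopped_at = ifelse(stalled, stops, NA_real_),
    artifact = ifelse(stalled, artifact, "none"),
    skipped_A_count = skipped,
    product = unname(prods[key])
  )
}

#' Monte-Carlo full-length fraction of a primer extension
#'
#' @param template A [as_template()] object, or a plain integer junction
#'   count (the template sequence is then irrelevant to the estimate).
#' @param enzyme A [enzyme_profile()].
#' @param n Number of simulated extensions.
#' @param seed Optional seed.
#' @param conf_level Binomial confidence level.
#' @return One-row tibble: `n`, `n_full`, `estimate`, `conf.low`,
#'   `conf.high` (exact binomial), and the analytic value
#'   `read_through_prob ^ n_junctions`.
#' @examples
#' klenow <- enzyme_from_ratio(2, 8, "Klenow")
#' full_length_fraction(1, klenow, n = 1e4, seed = 1)   # ~0.80
#' full_length_fraction(3, klenow, n = 1e4, seed = 1)   # ~0.512
#' @export
full_length_fraction <- function(template, enzyme, n = 10000L, seed = NULL,
                                 conf_level = 0.95) {
  stopifnot(inherits(enzyme, "del_enzyme"), n >= 1)
  J <- if (inherits(template, "del_template")) n_junctions(template)
       else as.integer(template)
  stopifnot(J >= 0)
  set_seed_if(seed)
  p <- enzyme$read_through_prob
  n_full <- if (J == 0L) n else {
    pass <- matrix(stats::runif(n * J) < p, nrow = n)
    sum(rowSums(pass) == J)
  }
  ci <- stats::binom.test(n_full, n, conf.level = conf_level)$conf.int
  tibble::tibble(
    n = as.integer(n), n_full = as.integer(n_full),
    estimate = n_full / n,
    conf.low = ci[1], conf.high = ci[2],
    analytic = p^J
  )
}

#' Analytic product spectrum of a primer extension
#'
#' Enumerates every stop/artifact combination with its exact probability
#' (no sampling): full-length with probability `p^J`, and for each junction
#' ordinal `s`, a stall with probability `p^(s-1) * (1 - p)` split across
#' the enzyme's stall-artifact mixture. Masses are computed with
#' [oligo_mass()] from the product sequence plus the primer's 5' label.
#'
#' @inheritParams simulate_extension
#' @param mods Modification mass table.
#' @return Tibble: `stopped_at`, `artifact`, `probability`, `sequence`,
#'   `length`, `mass`. Probabilities sum to 1.
#' @export
product_spectrum <- function(template, enzyme, mods = default_modifications()) {
  stopifnot(inherits(template, "del_template"), inherits(enzyme, "del_enzyme"))
  J <- n_junctions(template)
  p <- enzyme$read_through_prob
  w <- enzyme$stall_weights
  rows <- list()
  full_seq <- product_bases(template, Inf)
  rows[[1]] <- tibble::tibble(stopped_at = NA_integer_, artifact = "none",
                              probability = p^J, sequence = full_seq)
  for (s in seq_len(J)) {
    base_seq <- product_bases(template, s)
    p_stop <- p^(s - 1) * (1 - p)
    rows[[length(rows) + 1]] <- tibble::tibble(
      stopped_at = s,
      artifact = names(w),
      probability = p_stop * unname(w),
      sequence = vapply(names(w), function(a) apply_artifact(base_seq, a), character(1))
    )
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::filter(.data$probability > 0)
  out$length <- nchar(out$sequence)
  out$mass <- vapply(out$sequence, function(s)
    oligo_mass(product_oligo(template, s), mods), numeric(1), USE.NAMES = FALSE)
  out
}
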