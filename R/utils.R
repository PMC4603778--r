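DNA_BASES <- c("A", "C", "G", "T")

# Watson-Crick complement; U templates like T.
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A")

reverse_complement <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Substitution-only distance between equal-length strings. Indels are priced
# out of the optimal alignment (13-base codes: 13 substitutions < one indel
# pair), so Levenshtein with heavy indel costs counts mismatching positions.
hamming <- function(x, y) {
  d <- utils::adist(x, y, costs = list(ins = 100, del = 100, sub = 1))
  if (length(y) == 1L) as.integer(d[, 1L]) else d
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

`%||%` <- rlang::`%||%`
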