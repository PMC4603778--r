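# Shared fixtures: a small cached schema and a hand-rolled read builder
# that is independent of emit_reads() (used to test the decoder against a
# construction it has never seen).

klenow <- function() enzyme_from_ratio(2, 8, "Klenow")

small_schema <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_schema(c(6, 5, 4), seed = 42)
    cache
  }
})

# Build a read by direct string surgery from a schema row of trisynthons():
# prefix + gap + rc(code3) + gap + rc(code2) + gap + rc(code1) + tail.
build_read <- function(schema, codes, gaps = c(1, 1, 1)) {
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  tail_const <- paste0("AC", rc(sub("rG$", "", schema$headpiece)))
  k <- length(codes)
  parts <- schema$hairpin_constant
  for (i in seq_len(k)) {
    parts <- c(parts, strrep("A", gaps[i]), rc(codes[k - i + 1]))
  }
  paste0(paste(parts, collapse = ""), tail_const)
}

# substitute bases at given 1-based positions
mutate_read <- function(seq, pos, to = NULL) {
  for (i in seq_along(pos)) {
    old <- substr(seq, pos[i], pos[i])
    new <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), old)[1] else to[i]
    substr(seq, pos[i], pos[i]) <- new
  }
  seq
}
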