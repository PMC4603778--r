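test_that("hand-built reads decode through every junction-gap variant", {
  sc <- small_schema()
  tri <- trisynthons(sc)
  row <- tri[17, ]
  codes <- c(row$code1, row$code2, row$code3)

  clean <- build_read(sc, codes)
  d <- decode_reads(clean, sc)
  expect_identical(d$status, "ok")
  expect_identical(c(d$code1, d$code2, d$code3), codes)
  expect_identical(c(d$block1, d$block2, d$block3),
                   c(row$block1, row$block2, row$block3))

  # a 2-A (no-skip) gap at any junction decodes to the same trisynthon
  for (g in 1:3) {
    gaps <- c(1, 1, 1); gaps[g] <- 2
    d2 <- decode_reads(build_read(sc, codes, gaps = gaps), sc)
    expect_identical(d2$status, "ok")
    expect_identical(c(d2$code1, d2$code2, d2$code3), codes)
    expect_identical(d2[[paste0("gap", g)]], 2L)
  }
})

test_that("mismatch budget separates recoverable from unrecoverable errors", {
  sc <- small_schema()
  tri <- trisynthons(sc)
  codes <- c(tri$code1[5], tri$code2[5], tri$code3[5])
  clean <- build_read(sc, codes)
  cl <- nchar(sc$hairpin_constant)
  # cycle-3 window spans positions cl+2 .. cl+14 at single-A gaps
  w3 <- (cl + 2):(cl + 14)

  one_err <- mutate_read(clean, w3[4])
  d1 <- decode_reads(one_err, sc, max_mismatch = 1)
  expect_identical(d1$status, "ok")
  expect_identical(d1$code3, codes[3])
  expect_identical(d1$mm3, 1L)

  # two substitutions in one code exceed the budget; with codes >= distance
  # 3 apart no other code can be within distance 1 either
  two_err <- mutate_read(clean, w3[c(2, 9)])
  d2 <- decode_reads(two_err, sc, max_mismatch = 1)
  expect_identical(d2$status, "tag_unmatched")
  expect_true(is.na(d2$code3))

  d2b <- decode_reads(two_err, sc, max_mismatch = 2)
  expect_identical(d2b$status, "ok")
  expect_identical(d2b$code3, codes[3])

  # an error in the constant prefix consumes the constant budget only
  cerr <- mutate_read(clean, c(3, 7))
  expect_identical(decode_reads(cerr, sc, constant_mismatch = 1)$status,
                   "constant_mismatch")
  expect_identical(decode_reads(cerr, sc, constant_mismatch = 2)$status, "ok")
})

test_that("equidistant codes are dropped as ambiguous, never assigned", {
  # two cycle-1 codes at Hamming distance 2: a read one error off each is
  # a perfect tie at distance 1
  tags <- tibble::tibble(
    cycle = 1L, well_id = c("w1", "w2"),
    code = c("AAAAAAAAAAAAA", "AAAAAAAAAAACC")
  )
  blocks <- tibble::tibble(cycle = 1L, well_id = c("w1", "w2"),
                           block_id = c("b1", "b2"), role = "amine")
  sc <- del_schema(tags, blocks, min_tag_distance = 1L)
  midway <- "AAAAAAAAAAACA"  # Hamming distance 1 from both codes
  read <- build_read(sc, midway)
  d <- decode_reads(read, sc, max_mismatch = 1)
  expect_identical(d$status, "ambiguous")
})

test_that("short reads are truncated and tallies conserve totals", {
  sc <- small_schema()
  tri <- trisynthons(sc)
  codes <- c(tri$code1[2], tri$code2[2], tri$code3[2])
  clean <- build_read(sc, codes)
  stub <- substr(clean, 1, nchar(sc$hairpin_constant) + 15)
  expect_identical(decode_reads(stub, sc)$status, "truncated")

  counts <- simulate_selection(sc, affinity_model(1), copies_per_member = 5,
                               rounds = 1, seed = 4)
  fq <- tempfile(fileext = ".fastq")
  emit_reads(counts, sc, 3000, fq, error_rate = 0.01, enzyme = klenow(),
             seed = 41, population = "x")
  ct <- count_reads(c(x = fq), sc)
  failures <- attr(ct, "failures")
  expect_identical(sum(failures$n), 3000L)
  expect_identical(sum(ct$x), failures$n[failures$status == "ok"])
  expect_identical(unname(attr(ct, "totals")["x"]), 3000L)
})

test_that("decoding is order-independent", {
  sc <- small_schema()
  counts <- simulate_selection(sc, affinity_model(1), copies_per_member = 5,
                               rounds = 1, seed = 4)
  fq <- tempfile(fileext = ".fastq")
  truth <- emit_reads(counts, sc, 500, fq, error_rate = 0.01, seed = 42)
  reads <- clickdel:::read_fastq(fq)
  d1 <- decode_reads(reads$sequence, sc)
  perm <- sample(nrow(reads))
  d2 <- decode_reads(reads$sequence[perm], sc)
  expect_identical(dplyr::count(d1, code1, code2, code3),
                   dplyr::count(d2, code1, code2, code3))
})

test_that("no crosstalk: wrong assignments require two errors in one code window", {
  sc <- small_schema()
  counts <- simulate_selection(sc, affinity_model(1), copies_per_member = 5,
                               rounds = 1, seed = 4)
  fq <- tempfile(fileext = ".fastq")
  truth <- emit_reads(counts, sc, 4000, fq, error_rate = 0.01, seed = 43,
                      population = "p")
  dec <- decode_reads(fq, sc, max_mismatch = 1)
  j <- dplyr::inner_join(dec, truth, by = "read_id", suffix = c("", ".t"))
  ok <- j[j$status == "ok", ]
  wrong <- ok$code1 != ok$code1.t | ok$code2 != ok$code2.t | ok$code3 != ok$code3.t
  # exhaustive truth comparison: any wrong decode must carry >= 2 errors
  expect_true(all(ok$n_errors[wrong] >= 2L))
  # and error-free reads are never wrong
  expect_identical(sum(wrong & ok$n_errors == 0L), 0L)
})

test_that("an empty stream yields an empty table with zero totals", {
  sc <- small_schema()
  fq <- tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  ct <- count_reads(c(none = fq), sc)
  expect_identical(nrow(ct), 0L)
  expect_identical(unname(attr(ct, "totals")["none"]), 0L)
})
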