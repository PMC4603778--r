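test_that("fold enrichment uses the naive-average baseline for dropouts", {
  # the reference arithmetic: 13 of 147,885 selected reads, unseen among
  # 2,037,412 naive reads, against the 334-million-member average
  fe <- fold_enrichment(13, 147885, 0, 2037412, 2259 * 222 * 667)
  expect_equal(round(fe, 1), 29404.5, tolerance = 1e-6)
  expect_identical(round(fe / 10000) * 10000, 30000)

  expect_equal(fold_enrichment(5, 100, 5, 100, 1e6), 1.0)
  expect_equal(fold_enrichment(10, 1000, 20, 2000, 42), 1.0)
  expect_error(fold_enrichment(1, 0, 1, 10, 10), "sel_total")
  expect_error(fold_enrichment(1, 10, 1, 10, 0), "diversity")

  # the two baseline branches agree where naive frequency crosses 1/diversity
  div <- 500
  naive_total <- 5000
  at_boundary <- naive_total / div   # naive_count making freq == 1/diversity
  expect_equal(fold_enrichment(7, 100, at_boundary, naive_total, div),
               fold_enrichment(7, 100, 0, naive_total, div))
})

test_that("label symmetry: swapping populations inverts enrichment", {
  fe_ab <- fold_enrichment(30, 1000, 10, 2000, 1e4)
  fe_ba <- fold_enrichment(10, 2000, 30, 1000, 1e4)
  expect_equal(fe_ab * fe_ba, 1.0)
})

test_that("ranking orders by fold enrichment with lexicographic tie-break", {
  sc <- small_schema()
  tri <- trisynthons(sc)
  counts <- tri |>
    dplyr::mutate(naive = 5L, selected = 5L)
  enr <- rank_enriched(counts, diversity = library_diversity(sc))
  expect_true(all(enr$fold_enrichment == 1))
  expect_false(is.unsorted(paste(enr$code1, enr$code2, enr$code3)))

  # min_count filter removes singletons
  counts$selected[1:4] <- 1L
  enr2 <- rank_enriched(counts, diversity = library_diversity(sc), min_count = 2)
  expect_identical(nrow(enr2), nrow(counts) - 4L)
})

test_that("a planted plane dominates the top of the ranking and is the sole family", {
  sc <- generate_schema(c(8, 6, 6), seed = 9)
  aff <- affinity_model(0.01, planted = tibble::tibble(
    cycle = 3, block_id = "boronate3_004", capture_prob = 0.5))
  counts <- simulate_selection(sc, aff, copies_per_member = 400,
                               rounds = 2, seed = 10)
  fqs <- c(naive = tempfile(fileext = ".fastq"),
           selected = tempfile(fileext = ".fastq"))
  emit_reads(counts, sc, 20000, fqs["naive"], round = 0, error_rate = 0.002,
             seed = 50, population = "naive")
  emit_reads(counts, sc, 20000, fqs["selected"], round = 2, error_rate = 0.002,
             seed = 51, population = "selected")
  ct <- count_reads(fqs, sc)
  enr <- rank_enriched(ct, diversity = library_diversity(sc))
  plane_size_observed <- sum(enr$block3 == "boronate3_004")
  top <- head(enr, plane_size_observed)
  expect_gt(mean(top$block3 == "boronate3_004"), 0.95)

  fam <- detect_planes(enr)
  expect_identical(nrow(fam$planes), 1L)
  expect_identical(fam$planes$cycle, 3L)
  expect_identical(fam$planes$block_id, "boronate3_004")

  # two planted planes sharing the cycle are both reported
  aff2 <- affinity_model(0.01, planted = tibble::tibble(
    cycle = 3, block_id = c("boronate3_002", "boronate3_005"),
    capture_prob = 0.5))
  counts2 <- simulate_selection(sc, aff2, copies_per_member = 400,
                                rounds = 2, seed = 11)
  fq2 <- c(naive = tempfile(fileext = ".fastq"),
           selected = tempfile(fileext = ".fastq"))
  emit_reads(counts2, sc, 20000, fq2["naive"], round = 0, error_rate = 0.002,
             seed = 52, population = "naive")
  emit_reads(counts2, sc, 20000, fq2["selected"], round = 2, error_rate = 0.002,
             seed = 53, population = "selected")
  enr2 <- rank_enriched(count_reads(fq2, sc), diversity = library_diversity(sc))
  fam2 <- detect_planes(enr2)
  expect_identical(sort(fam2$planes$block_id),
                   c("boronate3_002", "boronate3_005"))
})

test_that("plane detection is calibrated on selection-free data", {
  # without any planted signal, uniform sampling should (almost) never
  # produce a family at default thresholds
  sc <- generate_schema(c(6, 5, 5), seed = 12)
  tri <- trisynthons(sc)
  det <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    counts <- tri
    counts$naive <- stats::rmultinom(1, 15000, rep(1, nrow(tri)))[, 1]
    counts$selected <- stats::rmultinom(1, 15000, rep(1, nrow(tri)))[, 1]
    attr(counts, "cycle_sizes") <- c(`1` = 6L, `2` = 5L, `3` = 5L)
    enr <- rank_enriched(counts, diversity = library_diversity(sc))
    nrow(detect_planes(enr, cycle_sizes = c(6L, 5L, 5L))$planes)
  }, numeric(1))
  expect_gte(mean(det == 0), 0.95)
})

test_that("prevalence tables fraction family members per building block", {
  members <- tibble::tibble(
    code1 = c("a", "b", "c", "d"), code2 = letters[5:8], code3 = letters[9:12],
    block1 = c("x", "x", "y", "z"), block2 = "p", block3 = "q"
  )
  pt <- prevalence_table(members, cycle = 1)
  expect_equal(pt$prevalence[pt$block_id == "x"], 0.5)
  expect_equal(pt$prevalence[pt$block_id == "y"], 0.25)
  expect_equal(sum(pt$prevalence), 1)

  single <- members[1, ]
  expect_equal(prevalence_table(single, 1)$prevalence, 1)
  expect_error(prevalence_table(members[0, ], 1), "no members")

  # near-uniform cycle-1 usage inside a wide plane: no block dominates
  sc <- generate_schema(c(40, 5, 5), seed = 13)
  tri <- trisynthons(sc)
  plane <- tri[tri$block3 == tri$block3[1], ]
  pt2 <- prevalence_table(plane, 1)
  expect_equal(max(pt2$prevalence), 1 / 40)
})

test_that("cube coordinates index blocks by schema order", {
  sc <- small_schema()
  tri <- trisynthons(sc)
  counts <- tri[c(1, 25, 60), ] |> dplyr::mutate(selected = c(3L, 1L, 9L))
  cube <- cube_coordinates(counts, sc, "selected")
  expect_identical(nrow(cube), 3L)
  expect_identical(cube$count, c(3L, 1L, 9L))
  order3 <- unique(sc$blocks$block_id[sc$blocks$cycle == 3])
  expect_identical(cube$index3, match(counts$block3, order3))

  # plane members share their fixed coordinate
  plane <- tri[tri$block3 == order3[2], ] |> dplyr::mutate(n = 1L)
  cube_p <- cube_coordinates(plane, sc, "n")
  expect_identical(unique(cube_p$index3), 2L)
  expect_identical(nrow(cube_p), nrow(plane))

  bad <- counts
  bad$block2[1] <- "unknown_block"
  expect_error(cube_coordinates(bad, sc, "selected"), "not in schema")
})

test_that("count tables tidy into long form and glance reports decode rates", {
  sc <- small_schema()
  counts <- simulate_selection(sc, affinity_model(1), copies_per_member = 3,
                               rounds = 1, seed = 14)
  fq <- tempfile(fileext = ".fastq")
  emit_reads(counts, sc, 800, fq, error_rate = 0, seed = 60)
  ct <- count_reads(c(naive = fq), sc)
  long <- tidy(ct)
  expect_true(all(c("population", "count") %in% names(long)))
  expect_identical(sum(long$count), 800L)
  g <- glance(ct)
  expect_equal(g$decode_rate, 1)
  expect_identical(g$total, 800L)
})
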