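ref <- reference_oligos()
ref_oligo <- function(i) ref$notation[ref$id == i]
primer <- function() ref_oligo(4)

test_that("enzyme profiles derive from stall:full ratios", {
  expect_equal(enzyme_from_ratio(2, 8)$read_through_prob, 0.8)
  expect_equal(enzyme_from_ratio(6, 4)$read_through_prob, 0.4)
  expect_equal(enzyme_from_ratio(0, 10)$read_through_prob, 1.0)
  expect_error(enzyme_from_ratio(0, 0), "both")
  tab <- del_enzymes()
  expect_equal(tab$read_through_prob[tab$name == "E. coli DNA Pol I Klenow fragment"], 0.8)
  expect_equal(tab$read_through_prob[tab$name == "E. coli DNA Pol I"], 0.7)
  expect_error(enzyme_profile("x", 0.5, c(correct = 0.5, minus_A = 0.5, plus_A = 0.5)))
})

test_that("templates infer junction count and type from the oligo notation", {
  t3 <- as_template(ref_oligo(3), primer())
  expect_identical(n_junctions(t3), 1L)
  expect_identical(t3$junction_type, "rG_tr_T")
  t9 <- as_template(ref_oligo(9), primer())
  expect_identical(t9$junction_type, c("U_tr_T", "rG_tr_T"))  # primer-outward
  t10 <- as_template(ref_oligo(10), primer())
  expect_identical(n_junctions(t10), 3L)
  expect_warning(as_template(ref_oligo(3), "5'-Cy5-AAAAAAAAAAAAAAA"),
                 "reverse complement")
})

test_that("a fully processive enzyme skips one A per U-triazole junction", {
  always <- enzyme_profile("ideal", 1)
  t9 <- as_template(ref_oligo(9), primer())
  out <- simulate_extension(t9, always, n = 5, seed = 1)
  expect_true(all(out$full))
  expect_true(all(out$skipped_A_count == 1L))
  # full product = all template residues complemented, minus one skipped A
  expect_identical(unique(nchar(out$product)), nrow(t9$template$residues) - 1L)

  t10 <- as_template(ref_oligo(10), primer())
  out10 <- simulate_extension(t10, always, n = 3, seed = 1)
  expect_true(all(out10$skipped_A_count == 2L))
  expect_identical(unique(nchar(out10$product)), nrow(t10$template$residues) - 2L)

  never <- enzyme_profile("blocked", 0)
  stalls <- simulate_extension(t10, never, n = 20, seed = 2)
  expect_true(all(stalls$stopped_at == 1L))
  expect_true(all(stalls$artifact %in% c("correct", "minus_A", "plus_A")))
})

test_that("skipped_A_count always equals traversed U-triazole junctions", {
  t10 <- as_template(ref_oligo(10), primer())
  out <- simulate_extension(t10, klenow(), n = 500, seed = 3)
  # junction order from primer: U, U, rG; traversed junctions for a stall at
  # ordinal s are 1..s-1
  expected <- ifelse(out$full, 2L, pmin(out$stopped_at - 1L, 2L))
  expect_identical(out$skipped_A_count, as.integer(expected))
})

test_that("full-length fraction matches the per-junction model", {
  fl1 <- full_length_fraction(1, klenow(), n = 10000, seed = 11)
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(fl1$estimate - 0.8), 3 * se)
  expect_true(fl1$conf.low <= 0.8 && 0.8 <= fl1$conf.high)

  fl3 <- full_length_fraction(3, klenow(), n = 10000, seed = 12)
  expect_gt(fl3$estimate, 0.5)
  expect_lt(abs(fl3$estimate - 0.8^3), 3 * sqrt(0.512 * 0.488 / 10000))
  expect_equal(fl3$analytic, 0.512)

  expect_equal(full_length_fraction(0, klenow(), n = 10, seed = 1)$estimate, 1)

  # a real template gives the same answer as its junction count
  t10 <- as_template(ref_oligo(10), primer())
  fl_t <- full_length_fraction(t10, klenow(), n = 5000, seed = 13)
  expect_lt(abs(fl_t$estimate - 0.512), 3 * sqrt(0.512 * 0.488 / 5000))
})

test_that("analytic product spectrum enumerates stop/artifact combinations exactly", {
  t3 <- as_template(ref_oligo(3), primer())
  kl <- enzyme_profile("Klenow", 0.8,
                       c(correct = 0.6, minus_A = 0.3, plus_A = 0.1))
  sp <- product_spectrum(t3, kl)
  expect_identical(nrow(sp), 4L)
  expect_equal(sort(sp$probability, decreasing = TRUE), c(0.8, 0.12, 0.06, 0.02))
  expect_equal(sum(sp$probability), 1)

  # degenerate enzyme: one product with probability 1
  sp1 <- product_spectrum(t3, enzyme_profile("ideal", 1))
  expect_identical(nrow(sp1), 1L)
  expect_equal(sp1$probability, 1)

  # law of total probability holds for arbitrary configurations
  for (seed in 1:5) {
    set.seed(seed)
    w <- stats::runif(3); w <- w / sum(w)
    enz <- enzyme_profile("rand", stats::runif(1),
                          c(correct = w[1], minus_A = w[2], plus_A = w[3]))
    t10 <- as_template(ref_oligo(10), primer())
    expect_equal(sum(product_spectrum(t10, enz)$probability), 1)
  }
})

test_that("spectrum masses reproduce the reported extension-product masses", {
  # on the single-junction template: the stall is the 37-mer (11,882), the
  # full-length product the 55-mer (17,443); stall artifacts sit one dA away
  t3 <- as_template(ref_oligo(3), primer())
  sp <- product_spectrum(t3, klenow())
  full <- sp[is.na(sp$stopped_at), ]
  expect_lt(abs(full$mass - 17443), 5)
  stall <- sp[!is.na(sp$stopped_at) & sp$artifact == "correct", ]
  expect_lt(abs(stall$mass - 11882), 5)
  expect_lt(abs(sp$mass[sp$artifact == "minus_A"] - 11567), 5)
  expect_lt(abs(sp$mass[sp$artifact == "plus_A"] - 12192), 5)
})

test_that("spectrum probabilities match Monte-Carlo frequencies", {
  t10 <- as_template(ref_oligo(10), primer())
  sp <- product_spectrum(t10, klenow())
  draws <- simulate_extension(t10, klenow(), n = 20000, seed = 7)
  key <- function(stop, art) paste(ifelse(is.na(stop), "full", stop), art)
  freq <- table(key(draws$stopped_at, draws$artifact)) / nrow(draws)
  for (i in seq_len(nrow(sp))) {
    k <- key(sp$stopped_at[i], sp$artifact[i])
    p <- sp$probability[i]
    obs <- if (k %in% names(freq)) freq[[k]] else 0
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / nrow(draws)) + 1e-9)
  }
})
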