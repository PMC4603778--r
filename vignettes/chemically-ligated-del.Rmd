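---
title: "Modelling chemically ligated DNA-encoded libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemically ligated DNA-encoded libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickdel)
library(dplyr)
```

## The system being modelled

A DNA-encoded library (DEL) records the synthetic history of each small
molecule in an oligonucleotide tag. In the chemical-ligation variant, the
per-cycle tags are joined by copper-catalysed azide–alkyne cycloaddition
(CuAAC) instead of enzymatic ligation: each tag carries a 5'-azido group
and a TIPS-protected 3'-propargyl alkyne, so iterative click/deprotect
cycles grow the encoding strand while the chemistry grows the molecule.
Every ligation leaves a **triazole linkage** in place of a phosphodiester.
Two junction chemistries occur: the headpiece–tag junction (`rG^tr-T`,
ribo-G to T) and all later tag–tag junctions (`U^tr-T`).

Triazole backbones are imperfect polymerase substrates. Two consequences
drive everything downstream:

1. **Stalling.** A polymerase traverses each junction with some
   probability; otherwise it aborts, leaving a truncated product that may
   additionally have gained or lost a deoxyadenosine. Measured stall:full
   ratios for the tested enzymes are tabulated in `del_enzymes()`; the
   Klenow fragment, the most permissive, reads through with probability
   8/(2+8) = 0.8 per junction.
2. **Single-A skipping.** A traversed `U^tr-T` junction is copied into a
   *single* A rather than two; the `rG^tr-T` junction is copied
   faithfully. The decoder must therefore tolerate junction gaps of 1–2
   adenosines, and no information may be encoded in the junction bases.

The package implements the full computational chain: schema and tag-set
design, oligo mass arithmetic, read-through simulation, synthetic
selection with FASTQ emission, junction-tolerant decoding, and
enrichment/family statistics.

## Tag architecture and read layout

Tags follow `5'-azido-T<code>U-3'-propargyl` with a 13-base code. Because
the final hairpin self-primes and extension runs back along the template,
reads carry the hairpin constant first and then the tag codes in
*reverse* cycle order as reverse complements, separated by the junction
adenosines:

```{r}
sc <- generate_schema(c(6, 5, 4), seed = 1)
read_layout(sc)
```

Coordinates are 0-based half-open at minimum gap lengths. Generated tag
sets keep a minimum pairwise edit distance of 3 (default), which makes
1-mismatch decoding provably unambiguous; `generate_tag_set()` uses
greedy rejection sampling and fails loudly when the constraint is
infeasible.

Library diversity has two meanings that the production design keeps
distinct: `unique_products` counts distinct chemical products (an acid
tagged in three wells counts once; encoded-null wells count zero), while
`encoded_combinations` counts DNA barcodes. For the production schema
(2,259 amines; 3 × 222 acids in 666 wells; 667 boronates + 2 nulls in 669
wells) these are 334,499,166 and 1,006,506,486 respectively; the first is
the "334-million-member" figure and is the enrichment denominator.

## Mass model

Average (not monoisotopic) masses, free-acid form, no counterions —
the convention under which the bundled reference oligos reproduce their
reported molecular weights. Internal residue masses are
A/C/G/T/U = 313.21 / 289.18 / 329.21 / 304.20 / 290.17 Da, ribose +16.00;
a 5'-OH/3'-OH oligo is `sum(residues) − 61.96` (removing one bridging
HPO3, adding H2O). Terminal modifications are additive deltas: azido
+24.99 and Cy5 +533.7 are recoverable from the reference set by
subtraction; FAM, biotin linkers and spacers are nominal vendor-style
values used only in consistency entries, and live in an editable table
(`default_modifications()`) rather than in code.

Since cycloaddition conserves atoms, CuAAC ligation is exactly
mass-additive. Internally this fixes the triazole-junction delta at
azido + propargyl − 61.96 = +1.08 Da per junction, so
`oligo_mass(ligate(a, b)) == oligo_mass(a) + oligo_mass(b)` holds
identically. Note this is additivity *relative to the modified
fragments*: the model deliberately does not claim a fixed mass offset
between a triazole junction and a phosphodiester of the same printed
sequence — the reference set itself contains a sequence inconsistency
between the single-junction template and its all-phosphodiester control
(one of its fragments prints one residue short of the corresponding
template segment), so that difference is not a reproducible quantity and
is not asserted anywhere.

Golden mass checks use a ±5 Da tolerance: the reference material itself
reports the stalled product as both 11,880 and 11,882 Da in different
places, so sub-2-Da agreement would be overclaiming.

```{r}
ref <- reference_oligos()
tibble(id = c(2, 4, 5, 6),
       computed = sapply(c(2, 4, 5, 6), function(i) oligo_mass(ref$notation[ref$id == i])),
       reported = ref$reported_mass[match(c(2, 4, 5, 6), ref$id)])
```

## Read-through simulation

Stalling is modelled per-junction i.i.d. — the simplest model consistent
with the measured aggregate stall:full ratios and with the observation
that three-junction templates still give >50% full-length product
(0.8³ = 0.512). The traversal of a `U^tr-T` junction is *deterministic*
single-A emission: the full-length product of the two-junction reference
template is a single species at one-adenosine loss, so the 1-vs-2-A
choice is not stochastic in the data; the no-skip case survives as the
decoder's 2-A fallback because polymerases other than Klenow have been
reported not to skip.

On a stall, the product draws an artifact class from the enzyme's stall
mixture, default `{correct 0.6, minus_A 0.3, plus_A 0.1}`. These weights
are deliberately config, not constants: adenosine deletion dominates and
addition occurs "to a lesser extent", but the proportions were never
quantified.

`product_spectrum()` enumerates all stop/artifact combinations with exact
probabilities (they must sum to 1) and computes each product's mass
through the same mass model; `simulate_extension()` samples the identical
process, and the test suite checks the two routes against each other at
n = 10^5.

```{r}
kl <- enzyme_from_ratio(2, 8, "Klenow")
t3 <- as_template(ref$notation[ref$id == 3], ref$notation[ref$id == 4])
product_spectrum(t3, kl)[c("stopped_at", "artifact", "probability", "mass")]
```

## The synthetic selection generator

The generator is the package's stand-in for unavailable real sequencing
data, and its defaults define the study conditions the tests run under:

* **Library**: 50 × 20 × 20 = 20,000 trisynthons — large enough for
  plane statistics, small enough for exhaustive truth checking.
* **Copies per member**: 1,000. With two rounds this leaves planted
  members (capture 0.5) with ~250 expected copies and background members
  (capture 0.001) with 10^-3, i.e. the planted:background per-copy
  retention ratio is (0.5/0.001)² = 250,000.
* **Selection**: independent Bernoulli capture per molecule copy,
  `Binomial(count, p)` per round. No competition, ligand depletion, or
  PCR amplification bias — read sampling is multinomial from
  post-selection counts. This is adequate for validating decoding and
  enrichment arithmetic, which is what the synthetic data exists to do.
* **Reads**: 10^5 per population, per-base substitution rate 0.005,
  constant Phred 30 qualities, stall truncation from the enzyme profile
  (with Klenow, 1 − 0.8³ ≈ 49% of reads truncate; they are tallied and
  excluded from counts).

What passing tests on this generator do **not** show about real data:
PCR duplicate structure and amplification bias, quality-correlated and
indel errors, chimeric reads, context-dependent stalling, and
condition-dependent capture efficiencies are all absent. The generator's
value is that its truth table makes decoding and enrichment claims
exactly checkable, not that it is a sequencer emulator.

## Decoding rules

* Constant-prefix anchor, 1 mismatch budget (default).
* Junction gaps 1–2 A; both offsets are tried, exact matches first.
* 1 substitution per 13-base code (default), 0 indels inside codes —
  the dominant structural variant is the junction A-loss, which the gap
  handles; with distance-3 codes a 1-mismatch budget cannot cross-assign.
* Ties at equal distance are dropped as `ambiguous`, never assigned.
* Reads shorter than the minimal layout are `truncated`; every failure is
  a status, and per-population tallies always conserve read totals.

## Enrichment and family statistics

Fold enrichment compares the selected frequency with the naive frequency,
or with the naive-library *average* `1/diversity` when the trisynthon was
never sampled naively — no pseudocounts. This is the convention that
makes a 13-read dropout in a 334-million-member library "approximately
30,000-fold" enriched:

```{r}
fold_enrichment(13, 147885, 0, 2037412, 2259 * 222 * 667)
```

Two per-trisynthon tail probabilities are reported. `poisson_tail` is the
textbook quantity P(X ≥ k_sel) at rate `N_sel × baseline`, treating the
baseline as known. For *combining* members into family calls this is the
wrong tool: the baseline is itself an observed naive count, and ignoring
its sampling noise produced false families on almost half of
selection-free simulations. `binom_tail` is the exact conditional test of
the same null — given `k_sel + k_naive` observations, the selected share
is `Binomial(k_sel + k_naive, N_sel/(N_sel + N_naive))` — which stays
calibrated (and for a naive dropout reduces to `f^k_sel`).

`detect_planes()` groups enriched trisynthons by every fixed
(cycle, block), combines member `binom_tail`s with Fisher's method
(−2Σlog p ~ χ²(2k), i.e. the calibrated null probability of a member-tail
product as small as observed), and Bonferroni-adjusts across candidates.
A significance test alone cannot identify *which* cycle carries the
family: a genuine cycle-3 plane makes every cycle-1 and cycle-2 block
look significant too, because each cuts a slice through the plane. The
discriminating geometry is coverage — a true plane is essentially fully
populated among enriched members, while an orthogonal slice covers only
~1/(fixed cycle size) of its candidate plane — so a reported plane must
cover at least `min_coverage = 0.5` of its possible combinations.
Defaults `min_members = 3`, `tail_threshold = 0.01` (Bonferroni-adjusted)
were fixed from the calibration argument above, and a 20-seed
selection-free simulation in the test suite checks the false-family rate.

Prevalence tables divide by family *members* (trisynthons), not reads,
matching how building-block specificity is normally quoted (e.g. "no
single amine above 0.7% of family members" in a family whose cycle-1
position carries no signal).

## Numerical and degenerate-input choices

* Diversity arithmetic is done in doubles (counts exceed 32-bit range).
* Edit distances use `utils::adist`; substitution-only distances price
  indels out of the alignment.
* Tag generation errors out after a configurable attempt budget rather
  than looping forever on infeasible constraints; the pigeonhole bound is
  rejected immediately.
* `enzyme_from_ratio(0, 0)`, empty cycles, empty ligation fragments,
  all-zero read populations, and empty FASTQ streams are all explicit
  errors or well-defined empty results (tested).
* Seeds: every stochastic entry point takes a `seed` argument;
  `emit_reads()` is byte-deterministic per seed and records its seed in
  the optional run-metadata JSON.

## Problem sizes

The shipped tests run the full pipeline at 50 × 20 × 20 with 10^5 reads
per population (the generator's reference conditions), Monte-Carlo
read-through at n = 10^4, and spectrum-vs-sampling cross-checks at 10^5
draws; unit tests use 6-to-8-well cycles where exhaustive comparison
with the truth table is feasible. These sizes were chosen so the whole
suite exercises every claim in minutes on a laptop while keeping every
stochastic tolerance at 3 standard errors of the relevant estimator.

## Known limitations

* Junction chemistry is limited to the two observed types; other
  triazole contexts (e.g. `T^tr-T`) would need new skip rules.
* The mass table's linker entries are nominal; only azido, propargyl and
  Cy5 are pinned by the reference set.
* Stall-artifact weights are unquantified defaults.
* The decoder is exact-window based, not alignment based; indels inside
  codes are out of scope by design.
* Family detection assumes families are axis-aligned planes (fixed
  single-cycle block); substructure-defined families spanning several
  related blocks are only found as multiple planes.
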