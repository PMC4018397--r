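---
title: "Methods: two-library small RNA / mRNA analysis in caprimir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA / mRNA analysis in caprimir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprimir)
```

caprimir reimplements, as a tested R package, the analysis design used
in deep-sequencing studies of developing skeletal muscle that pool
samples into one small RNA library per developmental stage (here: a
fetal library, FC, and a six-month library, SMC) and compare them
without replicates. The package covers library accounting,
sequence-composition profiling, an exact two-library Poisson
differential-expression test, novel-miRNA hairpin screening with a
self-contained folding engine, rule-based miRNA→3′UTR target scoring,
and a miRNA–mRNA integration stage. A seeded synthetic-data module
generates every input with known ground truth, which is what the test
suite and the acceptance script exercise.

## The exact two-library test

Expression is normalized per library as transcripts per million,
`NE = 1e6 · count / total`, where the total is the library's
clean-read count (not the column sum of the miRNA table — libraries
contain non-miRNA reads, which is why `count_table()` carries totals
separately). The fold change is `log2(NE₁ / NE₂)`.

With a single library per condition, each feature's counts are
modelled as Poisson. Following the Audic–Claverie construction, the
count `y` in library 2 given `x` in library 1 (totals `N₁`, `N₂`) has
the conditional law

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}},$$

a negative binomial with size `x + 1` and success probability
`N₁/(N₁+N₂)`. `audic_claverie_p()` therefore evaluates tails with
`pnbinom()`, which is exact and stable at library-scale counts
(`x + y` of order 10⁷) — no explicit factorials, no overflow. The
two-sided p-value is twice the smaller tail, capped at 1.

Three conventions are the package's own choices:

* **Sidedness.** The doubled smaller tail matches symmetric up/down
  calling. Because the law conditions on the library-1 count, the
  swapped test `(y, N₂) vs (x, N₁)` agrees closely but not exactly
  (the two conditional pmfs differ by the constant factor `N₁/N₂`,
  and the two tail conventions meet only at the symmetric center).
  The tests assert factor-bounded agreement and exact up/down class
  mirroring rather than strict invariance, which this law cannot
  provide.
* **No-information features.** `x = y = 0` returns `p = 1` and is
  excluded from DE calling; a pseudocount of 0.01 per million is
  added to zero entries (only) before ratios so printed nonzero
  ratios are untouched.
* **Thresholds.** DE calls use `FDR ≤ 0.001` and `|log2 ratio| ≥ 1`
  (Benjamini–Hochberg via `stats::p.adjust`); the scatter classes are
  ratio > 2, between ½ and 2, and ≤ ½.

```{r}
ct <- count_table("chi-miR-1", 1929430, 9986601,
                  totals = c(15627457, 15593721))
dplyr::select(tidy(de_table(ct)), feature, ne1, ne2, log2fc, de_class)
```

## Profiling

`qc_percentages()` and `category_percentages()` reproduce the
accounting style of published library reports: percentages of
high-quality reads and of genome-mapped totals, rounded **half-up** to
2 decimals — base R's round-half-even does not reproduce printed
report tables, hence `round_half_up()`. Length distributions bin
18–30 nt reads (out-of-range reads fall into `"other"`), and the
nucleotide-bias tables cover first-base composition for lengths 18–25
and per-position composition for positions 1–24, with G+C content per
position; longer reads contribute only their first 24 positions.

## The folding engine and hairpin screen

Novel-miRNA screening needs a folding engine whose optimum can be
verified independently. The engine (`fold_mfe()`, implemented in C++)
minimizes a deliberately small nearest-neighbour model:

* stacking free energies for the 6 pair types (Watson–Crick plus
  G·U), approximate 37 °C values rounded to 0.1 kcal/mol;
* hairpin loops of at least 3 unpaired bases, bulge and internal
  loops penalized by length, tabulated to a cutoff and extrapolated
  logarithmically (1.75·RT·ln(L/L₀));
* no dangling ends and **no multibranch loops** — each closed pair
  encloses at most one helix; the exterior may hold several
  stem-loops.

This is not a Turner-complete folder, and its absolute energies will
differ from Mfold/ViennaRNA values; what it buys is verifiability:
the test suite enumerates *every* admissible structure for sequences
up to 13 nt and checks the DP optimum against an independent scorer,
and all screening thresholds are exposed as parameters so they can be
recalibrated against any other engine. Ties between equal-energy
structures are broken deterministically in the traceback (pairing
preferred over unpaired; inner pairs at the smallest 5′ position,
then the largest 3′ position). A provably lexicographically-smallest
dot-bracket would require comparing optimal substrings per DP state;
determinism is what reproducibility needs, so determinism is what is
guaranteed.

`evaluate_candidates()` mirrors the published screen: windows of
150 nt on each side of a genome hit are extracted strand-aware
(`extract_flanks()`, 0-based half-open coordinates throughout), the
window is folded, and the candidate is trimmed to the top-level helix
harboring the mature read — flanking sequence folds independently and
would otherwise dilute every metric. The trimmed precursor is
refolded and passed through six flags: genome hits ≤ 10; mature
length 16–30 nt; MFE < −18 kcal/mol; stem residence (at most 4 mature
bases inside terminal loops — the published rule says only "residing
in the stem region", so the count is this package's concretization);
MFEI > 0.85 with MFEI = |AMFE|/GC% (positive convention, so the
filter reads as printed; AMFE = 100·MFE/length); and a single
terminal loop. The battery replaces an external machine-learned
pseudo-precursor classifier and is labelled `mipred_surrogate` in
reports.

## Target scoring

`scan_targets()` scores every UTR window against each miRNA under the
plant-rule penalty table: mismatch 1.0, G·U wobble 0.5, 1-nt bulge
2.0, each doubled at miRNA positions 2–13; sites pass at penalty
≤ 4.0 with no mismatch at positions 10–11 and no run of three
mismatches. The source study names this rule family without printing
constants, so the table here follows the cited plant-rule literature
and every constant is an argument. Bulges are limited to one 1-nt
bulge per site, which keeps window enumeration tractable. Overlapping
hits collapse to the best-scoring window. The duplex energy is an
intermolecular stacking sum over the paired run — a ranking field,
not a filter, because the published energy cutoff (if any) is
unknown. Site lists should not be read as reproducing any specific
published target catalogue.

One caveat found during testing: penalty scoring is *not* symmetric
under reverse-complementing both strands — complementation maps A·C
mismatches to G·U wobbles, and the 2–13 doubling window reverses.
Only the perfect-duplex case is transform-invariant, and only that
case is asserted.

## Integration

Strongly differential miRNAs are selected at `|log2 ratio| ≥ 3` — the
published criterion is printed as "−3 ≥ log2 ratio ≥ 3", which is
unsatisfiable as written and is read here as the absolute-value rule.
Their predicted targets are intersected with the DEG set to give DE
targets; enrichment is a plain upper-tail hypergeometric test with BH
FDR (thresholds P < 0.05, FDR ≤ 0.05), replacing an external web
service with something oracle-verifiable. The background is all genes
in the mRNA DE table; the source study does not state its background.
Per-pathway bipartite networks carry direction attributes and degree
tables; pathways are reported strictly by ascending p (published
"ten smallest P-value" tables are not strictly sorted; this package
sorts).

## The synthetic-data module

The generators define the study conditions the tests run under:

* `simulate_libraries()`: 464 features by default (the size of the
  known-miRNA catalogue the design profiles), depths 10⁶ as a
  desk-scale stand-in for ~1.56·10⁷-read libraries, log-normal
  baselines (`sdlog = 1.5`, a realistic miRNA dynamic range of
  several orders of magnitude) normalized so the simulated features
  hold 81.5% of each library's reads (the miRNA share of a muscle
  small RNA library), a planted DE fraction of 0.25 at
  `|log2| = 3` split symmetrically across the two libraries, and
  Poisson counts — matching the Poisson model the test assumes.
  Negative-binomial overdispersion is deliberately absent by default;
  robustness to it is an open question for real data.
* `simulate_hairpins()`: stem 35 bp, loop 10 nt, GC 0.5, 5% stem
  mismatches — precursors of 80 nt, inside the published 65–99 nt
  range — with a 22-nt mature read cut from the 5′ arm.
  `shuffle_seqs()` provides composition-matched negative controls.
* `simulate_utrs()` plants exact reverse-complement sites with a
  requested number of mismatches at recorded positions (mutated to
  bases that can neither pair nor wobble, so the planted state is
  unambiguous); `simulate_pathways()` oversamples DE-target genes in
  designated pathways at configurable odds.

What passing these tests shows — and does not show: the pipeline
recovers planted signal under its own model (Poisson counts, exact
complementary sites, clean hairpins). Real libraries have biological
replicates' dispersion, sequencing error, imperfect annotation and
diffuse target signal, none of which the generator emulates.

## Problem sizes and determinism

The test suite and acceptance script use desk-scale sizes chosen to
make every oracle exhaustive or near-exhaustive: folding oracles at
n ≤ 13 (complete enumeration), the exact-test grid at x, y ≤ 200
across three library-size ratios, 2000-feature null libraries,
20-replicate power and enrichment-ranking runs, 40-hairpin screens.
Every generator call is seeded, seeds are scoped (callers' RNG state
is restored), and `run_pipeline()` writes a manifest echoing every
parameter and seed so any stage output can be recomputed standalone.
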