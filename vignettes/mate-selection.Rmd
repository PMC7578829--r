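---
title: "Predicting progeny diversity and allocating mates in small broodstocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting progeny diversity and allocating mates in small broodstocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broodmate)
```

## The problem

Captive propagation of endangered fish typically starts from a few dozen
wild-caught adults. Every spawning decision — which male with which
female, or which fish to release together into a spawning pond — shapes
how much of the founders' genetic variation reaches the next generation.
With codominant markers (microsatellites scored as fragment lengths, or
SNPs with numeric allele codes) the consequences of each decision can be
computed exactly under Mendelian inheritance, before any eggs are
fertilized. `broodmate` implements that calculation and the two
optimization problems built on it: choosing disjoint breeding pairs for
controlled mating, and choosing male/female subsets for volitional group
spawning.

## The Mendelian pair model

A sire `{a1, a2}` and dam `{b1, b2}` produce, at each locus, one of four
equally likely offspring genotypes `{ai, bj}`. All pair statistics follow
from this enumeration (`pair_offspring()` exposes it directly, and the
closed forms are tested against it):

* `H`, the fraction of the four outcomes that are heterozygous — always a
  multiple of 0.25;
* `ar`, the number of distinct alleles among the four parental copies —
  every parental allele can reach the progeny group, so `ar` (summed over
  loci) measures attainable allelic diversity, not a per-offspring
  expectation;
* `weak`, whether the parental copies form a 3:1 "AAAB" pattern. Such
  pairs produce heterozygotes that sit one mutation-step from
  homozygosity; half their offspring are these *weak heterozygotes*, so
  the pair's expected weak share at the locus is 0.5.

Loci are treated as unlinked and are aggregated by the unweighted mean
(`H`, weak share) or sum (`ar`). A locus where either parent is uncalled
is excluded from all three aggregates for that pair — an
evaluable-data-only policy that avoids biasing pairs with missing
genotypes toward zero.

The weak-heterozygote concept deserves a caveat: pair-level weak status is
unambiguous, but how to report a *group-level* weak-heterozygote share is
a modelling choice. This package defines it as the mean pair-level share
over all male-by-female pairs in the group (`group_weak_het_share()`),
and uses the same definition inside group-spawning predictions. Other
operationalizations (e.g. population-genotype tallies) would give
different numbers; none is canonical.

## The v index and pair selection

Pairs are ranked by a composite score,

```
v = i_H * H/max(H) + i_ar * ar/max(ar) + i_wh * (1 - wh/max(wh))
```

with maxima over the cohort of all enumerated pairs and weights
normalized to sum to one (defaults `i_H = 0.45`, `i_wh = 0.1`,
`i_ar = 0.45` — heterozygosity and allele number weighted equally and
heavily, weak heterozygotes as a light penalty). Design notes:

* *Cohort-maximum normalization* makes each term a "fraction of the best
  attainable in this broodstock", keeps `v` in `[0, 1]`, and makes the
  ranking invariant to rescaling all weights by a constant.
* *Degenerate cohorts*: if a cohort maximum is 0 (say, no pair produces
  any weak heterozygote) the corresponding relative term is defined as 1
  — every pair is already at the best attainable value — which avoids a
  0/0 without distorting the ranking.
* *Ties* are broken by higher `ar`, then lower weak share, then ids, so
  results are reproducible run to run.

`select_best_pairs()` picks `k` pairs with no shared individual — using
each fish in at most one pair spreads genetic representation and limits
future inbreeding. The default greedy rule (take the best-v pair among
unused fish, repeat) has a property that matters operationally: the set
selected at `k = 4` is always contained in the set at `k = 8`, so a
hatchery can scale its program up or down without re-planning. An exact
mode solves the k-cardinality assignment (maximum total v over all
disjoint k-pair sets) by padding the male-female weight matrix with dummy
rows and columns and solving a maximum-weight bipartite matching
(igraph); its total v is never below greedy's, but its sets need not
nest. Tests compare both against brute-force enumeration on small panels.

## Group spawning

For volitional spawning the model assumes *equal contribution*: each
selected sire is equally likely to father any offspring, each dam equally
likely to mother it, and each parent transmits either allele copy with
probability 1/2. (Field data show mass-spawning contributions can be
highly skewed; that is a caveat on the model's realism, not part of the
model.) Per locus, the number of alleles transmissible to the progeny is
the union of the selected parents' alleles, and expected progeny
heterozygosity is `1 - sum_k p_m(k) p_f(k)` with sex-specific pool
frequencies. Allele number is the primary objective — in a rescue
program, losing an allele is irreversible while heterozygosity can
recover — with heterozygosity, then weak share, then id order as
deterministic tie-breakers.

`search_best_set()` enumerates the `choose(M, m) * choose(F, f)` space
exhaustively when it is at most `limit` (default 1e7; subset allele
unions are evaluated as per-locus bitmasks, so enumeration is vectorized
over female subsets). Above the limit it switches to greedy construction
followed by single-individual swaps until no swap improves the
(coverage, heterozygosity) objective. The coverage objective is monotone
and submodular in the selected set, so greedy construction alone already
guarantees at least `1 - 1/e` of the optimal coverage; in the test suite
the greedy-plus-exchange result matches the exhaustive optimum on every
small instance tried. Subset-space sizes are computed by
`count_subsets()` using the multiplicative binomial formula, whose
intermediates are all exactly representable integers (guarded at 2^53),
so counts like C(25, 8) = 1,081,575 and products near 5.3e11 are
bit-exact.

`list_alternative_sets()` supports the practical follow-up question —
"which other sets are nearly as good?" — by exhaustively listing all sets
above an allele threshold and inside a heterozygosity window, ranked
lexicographically.

## The synthetic generator

Real broodstock genotype tables are rarely redistributable, so the
package carries a generator (`simulate_panel()`) used by all tests and
examples. Each individual-locus genotype is drawn independently with
`P(het k,l) = 2 p_k p_l (1 - f_is)` and the complementary homozygote
excess, where `f_is` is an inbreeding-like heterozygote-deficit
parameter; missingness strikes whole genotypes (both alleles together)
independently at a configurable rate. `frequency_recovery_check()`
verifies calibration: at 5,000 individuals, realized frequencies sit
within 0.02 of the specification.

`guzy_like_fixture()` is a preset that emulates the study conditions of a
small endangered lake-minnow broodstock: 23 males, 25 females, 13 loci
whose allele inventories sum to exactly 33 codes, and overall observed
heterozygosity constrained to `[0.30, 0.46]`. The per-locus allele counts
(two 4-allele, four 3-allele, six 2-allele and one monomorphic locus) and
skewed frequencies (e.g. 0.85/0.15 at diallelic loci) were chosen once so
that the expected overall heterozygosity (~0.35) falls mid-band, which is
what low-diversity microsatellite panels in such populations look like.
The generator redraws deterministically from the seed until every
inventory allele is carried by at least one fish, so the panel-wide
allele count is always exactly 33.

What the generator does *not* emulate: linkage between loci, genotyping
error and allelic dropout, family structure among the candidates, or
mutation. Passing tests therefore demonstrate correctness of the
Mendelian arithmetic and the optimizers under idealized sampling — not
robustness to pedigree structure or scoring artefacts in real data.
Because the motivating study's genotypes are not available as data, its
genotype-dependent numbers (e.g. its particular best-set heterozygosity)
are not reproduction targets; only its combinatorial structure and
printed tallies are.

## Numerical and interface choices

* Missing data: allele code 0 or a blank cell on input; genotypes are
  both-or-neither (half-calls are a validation error).
* Genotypes are unordered pairs; every statistic is invariant to allele
  order within a genotype, and parsing preserves file order of
  individuals and loci.
* Sex labels are normalized case-insensitively from a configurable alias
  set (`m/male/1`, `f/female/2`).
* Genepop export uses zero-padded 3-digit allele codes (missing `000`),
  the lingua franca of population-genetics tools; codes above 999 are
  rejected with a suggestion to recode.
* The command line (`exec/broodmate.R`, or `bm_run()` from R) exits 0 on
  success, 1 on usage errors, 2 on data errors; `--no-timestamps` makes
  outputs byte-reproducible.

Problem sizes in the test suite were chosen to keep brute-force oracles
exact and fast: all-shape-class Punnett enumeration for pair statistics;
3×3 panels for brute-force matching; 6×6 panels with `m = f = 3` for
exhaustive spawning-set search; 200 random panels for the greedy nesting
property; 1e5-draw Monte-Carlo offspring simulation (3-standard-error
bands) for group heterozygosity; and 5,000 individuals for frequency
recovery.

## Limitations

The method optimizes single-generation expectations from genotypes alone:
it does not use pedigree or kinship information, does not model skewed
reproductive success in mass spawning, and does not project multi-
generation drift or effective population size. Allele counts are raw
counts, not rarefaction-corrected allelic richness, so comparisons across
groups of very different sizes should be made with care.
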