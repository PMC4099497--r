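---
title: "Mini-barcode methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mini-barcode methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibar)
```

This vignette is the package's account of its science: the models behind
each step, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
choices we made where the design was genuinely open.

## Pairwise identity: the common currency

Every scan, score and distance in the package reduces to the fraction of
compared alignment columns at which two sequences agree. Two conventions
had to be fixed, and neither is universal in the field, so both are
explicit arguments everywhere:

* **Gap policy.** Under the default `pairwise-delete`, a gap opposite a
  base removes the column from the denominator; under `gap-as-mismatch` it
  counts as a difference. Columns gapped in *both* sequences are never
  compared under either policy — they carry no signal about the pair.
  Published identity percentages rarely state their convention, so
  analyses that compare against published values should be run under both
  policies and report which one matches.
* **Ambiguity codes.** By default `R` ≠ `A`: exact symbol equality. This is
  reproducible and conservative — an ambiguous base call never silently
  inflates identity. The optional `compatible` mode counts symbols whose
  IUPAC base sets overlap as matches, which is more forgiving on panels
  with many ambiguity codes but makes "identity" depend on how
  conservatively the reference sequences were base-called.

`region_mean_identity()` averages the per-pair identities over all
unordered record pairs. Pairs with no comparable column in a region are
excluded from the mean rather than erroring, because in gappy rRNA
alignments a short window can be entirely gapped in a few records without
invalidating the window.

## Scanning for mini-barcodes

A mini-barcode design is three contiguous column intervals — left flank,
core, right flank — with the core *more* variable than the flanks. The
scan enumerates every core length in `core_len` at every position,
computes the core identity and the pooled identity of the two flanks, and
keeps windows with `flank_identity ≥ min_flank_identity` and
`core_identity ≤ max_core_identity`.

Defaults: `flank_len = 20` columns (a practical primer length),
`core_len = 50–80` (short enough to amplify from ~50 bp-median extracts
once primers are added, long enough to be diagnostic),
`min_flank_identity = 0.95` and `max_core_identity = 0.80`. These
reproduce the published mini-barcode regime — conserved flanks in the high
90s of percent identity around cores near 70% — without claiming the
(unpublished) thresholds any particular study used.

Candidates are sorted by ascending core identity, then descending flank
identity, and pruned greedily so that no two accepted designs share a core
column. Greedy pruning is deliberate: the goal is a handful of disjoint
loci, not an optimal set cover. Windows whose core contains a gap-majority
column are skipped entirely — such a "core" is not a contiguous stretch of
real molecule, so its amplicon length and haplotypes would be fictions.
The identities reported on a returned design are exactly
`region_mean_identity()` on its regions, so they can always be recomputed
independently.

### Degenerate consensus primers

Per flank column the primer carries the smallest IUPAC code covering all
bases whose panel frequency is at least `1 − include_threshold` (default
0.95, i.e. bases below 5% frequency are ignored). The frequency floor
keeps a single private polymorphism from dragging a position to `N`.
Records with ambiguity codes contribute all their constituent bases. A
column whose gap fraction exceeds `1 − include_threshold` is an error: a
primer cannot sit on a column that is absent from a non-trivial share of
the panel. (We read the threshold symmetrically on both sides — rare
*bases* are droppable and rare *gaps* tolerable — because the alternative
reading, tolerating up to 95% gaps, is not a primer site by any stretch.)

Degeneracy is the product of per-position code cardinalities. The melting
temperature uses the Wallace rule `2(A+T) + 4(G+C)` evaluated on the
modal-base expansion (most frequent panel base per column): Tm here is
annealing-temperature bookkeeping, not thermodynamic design, and the modal
expansion is the single concrete primer molecule most of the pool
resembles.

## Species resolution: haplotype uniqueness

A design's resolving power is the number of species none of whose
gap-stripped core haplotypes is shared with any other species. Strict
string equality is the default ("the barcode is unique" in its plainest
reading); a mismatch tolerance `k` is available but has no claimed
default, since tolerant uniqueness is a different — and rarely published —
statistic. Ambiguity codes are distinct symbols here: treating `R` as
"maybe A" would make uniqueness depend on base-calling confidence.
Unknown-taxon records (no species epithet) are excluded from uniqueness
bookkeeping — uniqueness is a species-level property — but retained for
identity statistics.

## Fragment lengths and amplifiability

Degraded extracts are described by a fragment-length distribution
left-truncated at `min_length = 30` bp (extraction chemistry below ~30 bp
retains essentially nothing). The parametric family is a lognormal fitted
by maximum likelihood *with the truncation term in the likelihood*, so the
fitted parameters describe the underlying molecule population, not the
retained sample. The default profile is calibrated by two facts only — a
truncation bound of 30 bp and a median of 51 bp — via `lognormal_profile()`,
which solves for the location parameter so the *truncated* median hits the
target. The shape default `sdlog = 0.35` gives a moderately concentrated
single-peak trace; nothing in the package depends delicately on it.

Amplifiability of an amplicon of length `a` (including primers — lengths
are quoted the way PCR targets are) has two weightings:

* `count`: `P(L ≥ a | L ≥ min_length)` — the fraction of molecules long
  enough;
* `spanning` (default): `E[max(0, L − a + 1)] / E[L]` — the probability
  that a uniformly chosen template base position lies on a molecule that
  spans the whole amplicon. PCR success is about spanning: both primer
  sites must sit on one molecule, which is why ~140 bp targets fail on
  extracts from which ~60–100 bp mini-barcodes amplify readily. Both
  weightings are non-increasing in `a`; the spanning integrals are done
  with `stats::integrate` at `rel.tol = 1e-9`.

## Replicate-consensus authentication

The ancient-DNA authenticity criterion is replicate agreement: each
barcode is amplified independently several times per sample and sequenced
in both directions, and a sequence is believed only when all reads agree.
`assemble_replicates()` reverse-complements reverse reads, optionally
trims primer bases (they report primer, not template), and compares
columns. Strict mode — the default, because the authenticity argument
rests on *perfect* agreement — authenticates only a unanimous matrix and
records every discordant column as a conflict. Majority mode calls the
modal symbol (ties become the IUPAC code of the tied set), records
conflicts, and never sets the authenticated flag: a majority-called
consensus is a working sequence, not an authenticated one. Reads carry no
quality scores; conflicts are symbol counts, which is what Sanger-style
replicate data supports.

## Distances, trees and the delimitation test

Raw mismatch proportions are corrected with Jukes–Cantor,
`d = −(3/4)·ln(1 − 4p/3)`, which saturates at `p = 3/4`; saturated pairs
are an error by default and capped just below saturation inside bootstrap
resampling, where an unlucky column draw can push a pair over the edge.
JC69 is a deliberate stand-in for heavier ML machinery: on the short,
moderately diverged loci this package targets, the correction choice moves
distances far less than the sampling noise, and JC keeps the simulator and
the analysis in the same model family. Published distances from
GTR-family ML trees are therefore *approximated*, not reproduced, by this
package — a stated limitation, not an accident.

Neighbor joining is implemented with two determinism guarantees that
off-the-shelf implementations do not make: ties in the Q criterion break
by the lexicographically smallest label pair, and a negative pendant edge
is clamped to zero with the deficit transferred to its sibling so the pair
sum is preserved. NJ is exact on additive matrices (tested against
enumeration and against `ape::nj`). Midpoint rooting places the root
halfway along the tree diameter, breaking diameter ties again by smallest
leaf pair; an outgroup, when given, takes precedence. Bootstrap support
resamples alignment columns, rebuilds the NJ tree and counts bipartitions
(via `ape::prop.clades`) as percentages.

The delimitation test asks two one-sided questions about the query's
distance `q` to its nearest relative:

1. Is `q` larger than within-species distances? One-sample t of the
   within-species sample against `μ = q`, alternative "less".
2. Is `q` compatible with congeneric distances? The same test on the
   congeneric sample.

`distinct_species_supported` requires the first to reject and the second
not to; a query inside within-species variation is
`conspecific_not_rejected`; rejecting both (more divergent than congeners)
is `indeterminate` at the species level. The one-sided alternative is the
default throughout because the scientific question is directional, and
published borderline p-values in this setting (p ≈ 0.08 at |t| ≈ 1.5 with
14 df) are only consistent with one-sided tails.

**Sampling units.** `grouped_distances()` aggregates sequence-level pairs
to one value per species (within) and per species pair (congeneric) by
default. Sequence pairs of the same species pair share tree paths and are
strongly dependent; feeding them to a t-test as independent observations
inflates the effective sample size several-fold and makes the congeneric
test reject almost anything. Species-level averages are the exchangeable
units, and they are also what published "average pairwise distance"
samples with df in the low teens must have been. Raw pairs remain
available with `aggregate = "pair"`.

**Patristic versus direct distances.** Both are supported (`nj_tree` +
`patristic_distances`, or `panel_distance_matrix` directly). Tree-path
distances are the natural scale when the published comparison was made on
a phylogeny; direct JC distances avoid committing to a topology. The
package exposes both and the tests exercise both; the delimitation
function itself is agnostic — it consumes whatever distance samples it is
given, and the only requirement is that the query distance and the
reference samples are on the same scale.

**Reconstructing tests from printed summaries.** When only printed summary
statistics are available (mean, sd, n, t, p — each rounded to its printed
precision), `summary_matched_sample()` builds a deterministic sample with
exactly a requested mean and sd by rescaling standard-normal quantiles.
Printed summaries are rounded, and naively plugging rounded values into
`t = (x̄ − μ)/(s/√n)` can shift t by several percent — enough, near a
significance boundary, to flip a verdict that the original unrounded data
did not flip. The package's reconstruction therefore solves for the
unprinted digits from the printed t statistic itself: given printed mean
0.01 (n = 14, t = −35.97 against μ = 0.11), the implied sd is 0.0104
(prints as 0.01); given printed sd 0.04 (n = 15, t = −1.48), the implied
mean is 0.0947 (prints as 0.09). Every reconstructed value is consistent
with every printed value at its printed precision, and the resulting
tests reproduce the printed t, p and verdict. The acceptance script also
reports the naive rounded-summary t (≈ −37.4) alongside, so the size of
the rounding effect is itself on record.

## What the synthetic generator emulates — and what it does not

`simulate_panel()` evolves sequences under Jukes–Cantor (via
`phangorn::simSeq`) along an ultrametric genus/species/individual tree:

* conspecific individuals coalesce at depths averaging half the
  within-species divergence target (default 0.01 substitutions/site),
  spread over species by factors 0.5–1.5 so the within-species
  distribution has spread comparable to its mean rather than collapsing to
  a point;
* congeneric species join along a ladder whose depths are spread widely
  (0.25–0.85 of scale, rescaled so the mean pairwise distance hits the
  0.09 target) — real congeneric distance distributions have standard
  deviations near half their mean, and the wide ladder reproduces that;
* genera are separated at ≥ 0.25 substitutions/site;
* planted barcode loci evolve at 0.1× (flanks) and 5× (cores) the
  background rate, with all rates normalised to mean 1 so tree depths stay
  in substitutions/site; the default alignment is 1000 columns, the scale
  of a mitochondrial 12S alignment, with three planted cores of 60, 64
  and 69 columns (mean 64.3).

`simulate_query_experiment()` grafts a query at a chosen distance
(default 0.11) from a reference record, then emulates the laboratory
scheme — default 3 barcodes × 2 samples × 3 amplifications × 2 directions,
36 reads when nothing drops out — drawing one template fragment per
replicate from the degradation profile (amplicons longer than the fragment
drop out), applying per-replicate template-strand C→T damage and per-read
sequencing errors.

Not emulated, deliberately: indels and alignment error (panels are
consumed aligned; simulated panels are gap-free), rate heterogeneity
beyond the two-rate layout, GTR-family base/rate asymmetries, quality
scores, contamination, and damage beyond C→T. Passing tests on this
generator therefore show that the machinery is correct under a clean
two-rate JC world with known truth; they do not show robustness to
misalignment, saturation or base-composition bias in real panels.

## Numerical and scale choices

* Coordinates are 0-based, half-open, in alignment-column space —
  unambiguous window arithmetic, BED-style.
* All stochastic operations take explicit seeds and are bitwise
  reproducible for a fixed seed.
* Truncated-lognormal fitting uses Nelder–Mead on (meanlog, log sdlog)
  with the truncation term in the likelihood; parameter recovery on
  samples of 10,000 is within 5%.
* Test and acceptance problem sizes are desk-scale by design: panels of
  2–8 genera × 3 species × 2–3 individuals (12–72 records, 1000 columns),
  bootstrap at 20–25 replicates, Monte-Carlo loops of 100–300 draws, and
  12-replicate pipeline-recovery loops. These sizes make every property
  checkable in seconds while leaving the asymptotics to the closed forms
  they are checked against.

## Known limitations

* JC69 and NJ approximate, and do not reproduce, ML/GTR phylogenies and
  their patristic distances; published tree-scale numbers are matched in
  regime, not digit-for-digit.
* Uniqueness is exact-match by default; a panel with one genome per
  species cannot see within-species barcode variation, so real-world
  uniqueness will be somewhat lower than panel uniqueness.
* The spanning model treats template molecules as uniformly positioned
  and ignores PCR efficiency, polymerase processivity and inhibitors: it
  ranks amplicon lengths reliably but its absolute fractions are not
  yields.
* The delimitation t-test assumes approximately normal, exchangeable
  distance samples; with very few species pairs the congeneric test has
  little power and verdicts lean on the within-species test alone.
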