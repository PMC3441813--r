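---
title: "Radiation hybrid mapping with rhmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiation hybrid mapping with rhmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhmap)
```

## The mapping problem

A radiation hybrid (RH) panel is a collection of rodent--donor hybrid cell
lines, each retaining a random sample of fragments of a γ-irradiated donor
genome. Two markers that are physically close are usually broken apart only
rarely, so their presence/absence patterns across the panel co-segregate;
markers far apart behave independently. From a clone-by-marker call matrix
(`0` absent, `1` present, `2` ambiguous) the package estimates pairwise
breakage, groups markers, orders them within groups, expresses distances in
centirays (cR), ties the RH map to a meiotic linkage map through shared
microsatellites, and compares the resulting chromosome maps with model-species
genomes.

## The retention model

All estimators share one generative model. Radiation breaks fall on each
chromosome as a homogeneous Poisson process; the dose enters only through the
calibration constant `kb_per_cr`, so the probability of at least one break
between markers `d` kb apart is

θ = 1 − exp(−d / (100 · kb_per_cr)),

and the map distance is d(cR) = −100·ln(1 − θ). Each fragment is retained
independently with probability `r` (the retention frequency). The donor line
is clonal and homozygous and genotyping is presence/absence, so the diploid
source is treated as haploid-equivalent — the standard RH approximation.

**Two-point model.** For a marker pair, the joint presence probabilities are
P(1,1) = r(1−θ) + r²θ, P(1,0) = P(0,1) = rθ(1−r), and
P(0,0) = (1−θ)(1−r) + θ(1−r)². `estimate_two_point()` maximizes the
multinomial likelihood over (θ, r) by bounded multi-start quasi-Newton
optimization, and reports a base-10 LOD against an unlinked model in which
each marker keeps its own marginal retention. The marker-specific null guards
against spurious LOD produced by retention differences between markers.
`tp_grid_search()` is a deliberately brute-force lattice reference used by the
test suite to certify the optimizer; it shares no code with it.

**Multipoint model.** Within an ordered group, each clone is a realisation of
a two-state (retained/lost) Markov chain whose initial distribution (r, 1−r)
is also the stationary distribution of every transition, which makes the
likelihood exactly invariant under order reversal. Ambiguous calls contribute
no emission factor — they are marginalized, which is how missing genotypes
should enter a likelihood rather than being imputed. An optional per-call
flip-error emission is available but defaults to 0 because vectors entering
mapping are normally pre-cleaned.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `retention_rate` | 0.117 | probability | panel-wide fragment retention of the emulated panel |
| `n_clones` | 190 | count | emulated panel size |
| `kb_per_cr` | 27.5 | kb/cR | physical-to-RH calibration at the 3500-rad dose |
| `kb_per_cm` | 840 | kb/cM | physical-to-genetic calibration of the donor genome |
| LOD threshold | 4.0 → 7.0 | log₁₀ | group formation, raised stepwise during refinement |
| `min_informative` | 25 | clones | floor under which a pair cannot form a linkage edge |
| `theta_ceiling` | 0.8 | — | adjacent breakage above which a group is "aberrant" |
| `max_distance` | 300 | cR | cap keeping −100·ln(1−θ) finite as θ → 1 |
| `ambiguous_halfwidth` | 0.05 | intensity | explicit half-width of the scoring ambiguity band |

The genotyping threshold defaults to 0.30 on the chosen fluorescence axis
with per-marker overrides, mirroring practice where the cutoff is adjusted to
each typing profile; the ambiguity band is made explicit because "close to
the threshold" needs a number to be reproducible. Markers whose intensities
do not split into two clusters (`flag_nonseparating()`) should be excluded
from mapping — with array genotyping of RH panels a substantial fraction of
markers fails this way.

## Ordering

The search objective is the full multipoint log-likelihood with refit
adjacent thetas, not a sum of two-point distances: the multipoint form uses
ambiguous calls correctly and matches the model class of the classical RH
ordering tools. Construction is greedy best-insertion seeded from the
highest-LOD pair; improvement combines 2-opt segment reversal with a
sliding-window ripple (window 4, all permutations); `n_restarts` seeded
restarts (default 10) guard against local optima. Ties are broken by the
canonical orientation (lexicographically smaller end marker first), then
first-found, making results reproducible given the seed. Coordinates are
reported to 0.1 cR. Markers whose calls agree on every mutually informative
clone cannot be resolved by the panel and are merged into one map position by
`colocalize()` (a tolerance on the fitted adjacent θ is available; identical
informative calls is the default reading of "co-localized").

## Group refinement

A group formed at LOD 4 is declared aberrant when its greedy candidate order
contains an adjacent breakage fraction above `theta_ceiling` (or an adjacency
with no usable estimate). Aberrant groups are re-split into connected
components at the next threshold of the schedule (4.5, 5.0, …, 7.0) until
clean or exhausted, in which case the group carries a persistent-aberration
flag. There is no standard quantitative definition of an "obvious
aberration", so this explicit test is a documented, configurable choice.

## Integration and FISH

Groups are anchored to the linkage group holding the majority of their shared
microsatellites; ties go to the LG with the smaller anchor cM span
(deterministic and conservative). Two LGs are merged into one chromosome only
when a single RH group carries at least two anchors from each — one shared
marker could be a genotyping artefact, four-point evidence is the classical
signature. Group orientation uses the sign of the rank correlation between
internal cR order and anchor cM order, falling back to end-marker two-point
LOD toward the neighbouring group, and groups that neither rule can orient
are flagged rather than guessed. FISH constraints, where present, are
authoritative over the statistical ordering — they are physical observations —
and any contradiction is surfaced in the conflict report, never silently
resolved. Chromosomes are named after the linkage groups.

## Comparative synteny

Ortholog hits are filtered at score ≥ 250 and alignment length 80–300 nt (the
length window suppresses retrogene-length hits); per (marker, species) the
best-scoring survivor becomes the anchor, at its interval midpoint. Hits on
"chromosome unknown" sequences count toward cross-species totals but are
excluded from positional analyses. Strand is ignored; orientation is inferred
from coordinate monotonicity. Walking the map order restricted to anchored
markers, maximal same-chromosome runs of length ≥ 2 are conserved segments
(CS), runs of 1 are singletons, and non-anchored markers do not break runs
(anchor sets differ per species, so gaps in one species carry no evidence of
breakage). Within a CS, the greedy left-to-right decomposition into maximal
strictly monotone coordinate runs gives the ordered segments (CSO); greedy is
deterministic and matches the "perfectly conserved order" reading, and a
brute-force check in the test suite guards small cases. No gap limit is
applied to CS runs by default.

## Calibration chain and reporting conventions

With consecutive shared-microsatellite pairs totalling `sum_cR` and `sum_cM`:
cR/cM = sum_cR/sum_cM; kb/cR = kb_per_cM ÷ (cR/cM); physical size =
total map cR × kb/cR; coverage = size ÷ genome size. `kb_per_cm` is an input
constant (default 840) rather than recomputed from genome size over map
length, because published values of the two disagree slightly and the
constant is the one actually used in the chain. Ratios are reported to one
decimal and the physical size is computed from the *rounded* kb/cR — the
convention of published RH reports — while the exact pre-rounding chain is
kept in `$raw`. Marker density divides the full genotyped set by genome size;
kb-per-marker truncates to an integer; mean spacing divides total cR by the
number of map *positions* (not gaps), the convention that reproduces
published spacing figures. Consecutive-pair selection is an explicit stand-in
for an unpublished pair choice.

## The simulator: what it emulates and what it does not

`simulate_rh_dataset()` draws breaks as the Poisson process above, retains
fragments independently (no clone-level retention heterogeneity — real panels
show some, and the config leaves room for it as an extension), applies false
negatives to true presents, then false positives to true absents, then
ambiguity blanking, each on a seed derived from the master seed. The genetic
map is proportional to physical position (cM = kb / kb_per_cm, optionally
jittered), with an optional chromosome split that creates a ground-truth
LG-merge case. Model species are derived by inversions (applied first, on
spans of `inversion_span = 2` markers, interior and non-overlapping), then
fissions, fusions and reciprocal translocations, every cut leaving at least
two markers per side; this discipline makes every breakpoint directly
recordable from the operation log, and gives clean arithmetic: k separated
two-marker inversions produce exactly k + 1 ordered runs on a chromosome.
Marker placement is uniform at random by default; `spacing = "even"` places
markers at equal gaps with bounded jitter, which is how the test suite
guarantees every true gap lies in a chosen window — uniform placement cannot
bound its largest gap.

Passing tests on simulated panels show the estimators are correct *under the
generating model*: real panels additionally contain retention heterogeneity
between clones, non-random breakage (fragile sites), cross-contamination and
marker-specific scoring drift, none of which the simulator emulates.

## Statistical precision at the emulated panel size

Problem sizes in the test suite are deliberately modest (2–4 chromosomes,
6–18 markers each, 190 clones) and every simulation is seeded. Two
information-theoretic facts, which the test suite measures directly, are
worth stating. At 190 clones and retention 0.117, the Fisher information of
an adjacent breakage fraction gives a relative standard error on the fitted
adjacent distance between roughly 29% (50 cR gaps) and 53% (10 cR gaps); the
fitted distances are unbiased and achieve this bound, so the *median*
absolute relative error of adjacent gaps sits near 23%, and no estimator can
do materially better at this panel size — pooled quantities (group lengths,
the cR/cM ratio) average this noise away, which is why the calibration chain
is reliable while individual gaps are not. Likewise the probability that a
single ~48 cR adjacent gap fails the LOD 4 linkage threshold is about 2%, so
terminal markers separated from their group by gaps approaching 50 cR
occasionally detach; gaps up to ~35 cR group essentially always.

## Known limitations

Single RH panel only (no multi-panel merging); haploid equal-retention
likelihood (no diploid or heterogeneous-retention models); order search is
local (greedy + 2-opt + ripple with restarts), adequate for group sizes here
but not a global optimizer for very large groups; centromere positions are
taken from FISH constraints, never inferred; zebrafish-distance species can
be counted for anchors but synteny conclusions at such distances are not
meaningful.
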