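---
title: "Methods: karyotype morphometrics, rearrangement inference, and NOR parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: karyotype morphometrics, rearrangement inference, and NOR parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyomorph)
library(dplyr)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the design
choices made where the design was genuinely open.

## 1. Morphometrics

### Model

Metaphase chromosomes are measured per chromatid (short arm `p_len`, long
arm `q_len`, pixels). Arm lengths are the physical quantity, so chromatids
are averaged into per-chromosome `(p, q)` *before* any ratio is formed:
ratios of averaged lengths are more stable than averages of ratios. From
`(p, q)` and the metaphase total we compute

- relative length `l_pct = 100 (p + q) / total` — normalising by the
  metaphase total removes slide-to-slide variation in resolution, pixel
  size and chromosome condensation, which is why absolute pixel lengths
  never appear downstream;
- arm ratios `r1 = p/q`, `r2 = q/p` (so `r1 * r2 = 1` identically);
- centromeric index `i = 100 p / (p + q)` on the 0–50 scale. On this scale
  a perfectly metacentric chromosome has `i = 50`, and the classical Levan
  interval bounds are 12.5, 25 and 37.5.

The classifier uses inclusive lower bounds (`i >= 37.5` metacentric,
`25 <= i < 37.5` submetacentric, `12.5 <= i < 25` subtelocentric,
`0 < i < 12.5` acrocentric, `i = 0` telocentric). It is total and
order-isomorphic: a larger `i` can never map to a less metacentric
category.

**Arm orientation.** A measurement table cannot encode arm identity beyond
relative length, so rows with `p > q` are swapped and flagged
(`swapped = TRUE`) rather than rejected. The flag matters when a
pericentromeric inversion makes the biologically short arm the longer one;
at arm-length resolution this is undetectable, which is a stated
limitation, not a bug.

### Aggregation and homeolog statistics

Per-type summaries use the median (Q2) and quartiles (Q1, Q3), computed
independently per metric — the median of `i` is *not* derived from the
median of `r1`, so the identity `i = 100 r1 / (1 + r1)` holds only
approximately across independently aggregated medians (within 0.5 index
points on the bundled template). Quartiles use linear interpolation between
order statistics (`stats::quantile` type 7, the R default). The convention
is documented because Q1/Q3 values at n = 11 depend visibly on it; the
choice is recorded in the output rather than hidden.

Homeolog divergence is reported two ways:

1. **IQR overlap** — for each homeolog pair and metric, whether the two
   Q1–Q3 intervals are disjoint, plus a ranking by inter-interval gap.
2. **ANOVA** — one single one-way ANOVA of the metric across *all* 18 type
   groups, followed by Tukey HSD adjustment over all pairwise contrasts,
   then filtered to the 9 homeolog contrasts. The alternative (per-pair
   t-tests) was rejected: it would discard the pooled within-group variance
   estimate and inflate the error rate the Tukey adjustment exists to
   control. Whether to pool metaphases across individuals is not
   distinguishable from the data model; the package pools. Significance
   codes follow the conventional 0.001 / 0.01 / 0.05 thresholds.

## 2. Identification against a template

Measured chromosomes carry no labels; they are assigned to template types
per metaphase by minimising the total cost of a bipartite matching, with
each type contributing `ploidy_copies` slots. The cost of pairing an object
with a type is the Euclidean distance in `(l_pct / sd_l, i / sd_i)` space,
where the scale factors are the dispersions of the template values on each
axis — this makes a percentage-point of length and an index point
commensurable. The optimum is computed exactly by shortest augmenting paths
(Jonker–Volgenant, O(n³); n = 36 here), written in-package because no
pre-installed library provides a linear-assignment solver; tests verify it
against exhaustive enumeration on instances small enough to enumerate.
A greedy nearest-neighbour was rejected because its ties are
input-order-dependent; the global optimum is permutation-invariant, with
residual cost ties broken by lexicographic type label for determinism.

**Ambiguity flags.** An object whose best and second-best type costs differ
by less than `ambiguity_tol` (default 0.05 in normalised cost units) is
flagged. This is the package's substitute for the manual judgement a
cytogeneticist applies to morphologically similar chromosomes (in the
bundled karyotype, the 5L/5S/6S/7L group); it marks uncertainty rather than
resolving it.

## 3. Rearrangement inference from marker maps

Marker maps record gene placements at arm resolution (`chromosome`, `arm`,
optional 1-based `rank` outward from the centromere, `region`). Arm-level
placement is the contract — it is what FISH reliably gives — and ranks are
an optional refinement. The reference map (an ancestral proxy, here the
diploid *X. tropicalis*) is partitioned into synteny groups, one per
reference chromosome.

**Translocation (majority rule).** Within each subgenome copy, a group's
genes are partitioned by target chromosome. A strict minority (< half of
the genes present) on a different chromosome than the majority is called a
translocation of those genes. Exact half splits are reported as
`ambiguous_split`, never as a directed call: a 1:1 split carries no
direction information.

**Fusion (marker-block argument).** Two groups whose majorities co-occupy
one target chromosome constitute a fusion call. Centromere fate follows
from block geometry: a chromosome whose markers are confined to a single
target arm *while spanning both of its ancestral arms* must have its
centromere embedded in that arm — i.e. lost. The retained chromosome's
centromere anchors the target. The fusing arm of the lost chromosome is the
ancestral arm of its most centromere-proximal marker; the fusing arm of the
retained chromosome is read from its markers on the fusion-side arm,
defaulting to that target arm itself when none are observed there.

When a marker contradicts the best model, both candidates can appear
one-arm-confined and arm-consistency scoring alone ties. The package then
prefers the candidate with the *larger* concordant block (more markers
confined to one arm spanning both ancestral arms) as centromere-lost, and
reports the contradicting markers in `conflicts` with `confidence = "low"`.
A conflict downgrades confidence but does not veto a call supported by at
least two concordant markers — vetoing would discard an inference the
marker geometry otherwise supports, and the conflict stays visible in the
output for the analyst to weigh. On the bundled data this is exactly the
*sox9* situation: its p-arm placement on the fused chromosome is
unexplained by a simple q–q fusion, the package records it as a conflict,
and deliberately does not hypothesise a secondary rearrangement to explain
it.

**Inversion.** Homeologous copies of a gene on different arms of
homeologous chromosomes indicate a pericentromeric inversion; the inverted
homeolog is the copy whose arm disagrees with the outgroup, and without an
outgroup the call is emitted with polarity `undetermined` rather than
suppressed. Same-arm copies whose rank order is exactly reversed give a
paracentric call. Unresolved probe copies (`copy = "none"`, e.g. a probe
hybridising to both homeologs) inherit their subgenome from the chromosome
label suffix.

All calls are invariant to marker row order, and relabeling the subgenome
copies flips only the homeolog named, never the call kind.

## 4. rDNA / NOR summarisation

The rDNA stage is bookkeeping, kept separate from inference: NOR count and
locations from 28S signals (deduplicated by chromosome type), chromosome
types lacking any 5S signal, types with 5S on both arms, 28S/5S
co-localisation, and low-intensity flags (read as low repeat copy number).
A conservation check — types missing 5S plus types carrying 5S equals all
types — guards the bookkeeping. The bundled signal table encodes the
published pattern; the arm carrying each telomeric 5S locus is not
published per chromosome, so the bundled file adopts q as a convention and
says so in its header comment.

## 5. NOR jumps by parsimony

NOR-bearing chromosomes are treated as unordered categorical states:
every chromosome-to-chromosome relocation costs 1, reflecting a direct
jump mechanism (transposition-like relocation without intermediate
states). An ordered or distance-weighted cost would presuppose a spatial
model of relocation that nothing in the data supports.

The count is computed by uniform-cost Sankoff dynamic programming over the
rooted species tree: polytomies are handled natively rather than resolved
arbitrarily (a schematic phylogeny should not be forced binary — that would
invent signal); on binary trees the result equals Fitch counting. Leaves
without a state (the *Hymenochirus* outgroup, which has no chromosome
nomenclature homologous to *Xenopus*) are pruned, never imputed. The
implementation reports:

- `min_changes` — the minimum number of jumps;
- full most-parsimonious state sets per internal node (states achieving the
  optimum in at least one reconstruction, from a down/up cost pass);
- per-edge indicators of whether a change is forced in at least one / in
  all most-parsimonious reconstructions;
- one deterministic reconstruction (lexicographically smallest state at
  every tie) from which jumps are classified intra-subgenome,
  inter-subgenome, or `n/a` when a state (e.g. a diploid's "7") carries no
  subgenome suffix.

On the bundled tree and state table the minimum is 5 jumps. No published
jump count exists to compare against; the number is validated by an
exhaustive enumeration oracle on small trees (all ancestral assignments,
trees of up to 7 leaves and 4 states) and cross-checked against an
independent parsimony implementation (phangorn) on the full tree. The tree
topology itself is transcribed from a schematic figure plus textual clade
descriptions; edges not constrained by either were resolved following the
cited species-group memberships, and the state table lists one NOR-bearing
chromosome per species.

## 6. The simulator: what it emulates and what it does not

`simulate_metaphases()` emulates the measurement stage of a karyotyping
study: per-metaphase global scale (lognormal around `scale_mean_px`,
default 10000 px with `scale_cv = 0.2` — a metaphase of 36 chromosomes a
few hundred pixels each, varying between spreads), per-arm multiplicative
measurement noise (`arm_noise_cv`, default 0.05), and within-chromosome
chromatid noise (`chromatid_noise_cv`, default 0.02). Eleven metaphases is
the default sample size, matching common practice. Noise is multiplicative
lognormal so arm lengths remain positive by construction, with no
truncation artifacts. Truth labels ship in a sidecar table, never in the
measurement table, keeping blind identification honest. The published
study does not state its measurement error; the 5% arm-noise default is a
documented, deliberately conservative guess, and no test depends on the
default.

What the simulator does *not* emulate: chromosome bending and condensation
gradients, touching/overlapping chromosomes, segmentation errors that
merge or split objects, or any correlation of errors within an arm. Passing
parameter-recovery tests therefore shows the pipeline is correct under the
stated noise model, not that it is robust to every failure mode of real
image measurement.

Two structural notes. First, the generator normalises template length
shares internally, so the pipeline-recovered `l_pct` medians converge to
the template values *renormalised to a 100% metaphase*; a published
template whose copy-weighted lengths sum to 100.02% is recovered up to
that factor (0.02% relative), and the zero-noise adjointness property
(`pipeline(generate(template, 0)) = template`) is exact for templates
summing to exactly 100%. Second, `simulate_marker_scenario()` applies
rearrangement specs in order to a duplicated two-copy reference with rank
arithmetic preserving marker adjacency, and emits the ground-truth call
list; scenario sweeps in the tests restrict themselves to *identifiable*
scenarios (e.g. a gene translocated into the future fusion partner is
provably unrecoverable, as is the fusing arm of a chromosome whose markers
all sit on its other arm).

## 7. Numerical choices and degenerate inputs

- Quartiles: type 7; documented above.
- Assignment ties: lexicographic type label; input-order invariant.
- Ambiguity tolerance: 0.05 normalised cost units, configurable.
- Parsimony ties: lexicographically smallest state at each node of the
  reported reconstruction; state *sets* are unaffected by the tie-break.
- Validation is total: every malformed input raises a typed condition
  (`karyomorph_schema_error`, `karyomorph_validation_error`,
  `karyomorph_domain_error`, ...) and never yields a partially
  constructed object. Warnings (not errors) cover recoverable oddities: a
  single-chromatid object, a template whose lengths sum off 100%, a
  degenerate template with duplicate feature points.
- The bundled template derives one centromeric index (type 4L) from its
  published arm ratio via `i = 100 r1 / (1 + r1)` because the published
  index cell is corrupted by spreadsheet date formatting; the file header
  records this provenance.

## 8. Problem sizes in the test-suite

The suite's simulation sizes are chosen to make the properties sharp while
keeping a full run in the low minutes on one CPU: 11 metaphases for
end-to-end runs (the study-scale default), 200 metaphases for
median-recovery at 5% arm noise (recovery within 2% relative error), 30
metaphases per noise level for the accuracy-monotonicity check, 500 seeded
scenarios for the rearrangement sweep, exhaustive enumeration oracles up to
7 leaves / 4 states (parsimony) and 7 types (assignment).

## 9. Known limitations

- Positions are arm + rank; no base-pair coordinates, no breakpoint
  localisation.
- Fusion orientation is only as identifiable as the marker geometry allows;
  one marker per ancestral arm is the practical minimum for full recovery.
- The ANOVA pools metaphases and assumes homoscedastic, independent
  measurements across them.
- Identification quality degrades for morphologically similar types; the
  ambiguity flag reports, but cannot repair, this.
- Parsimony counts assume the tree; uncertainty in the phylogeny is not
  propagated.
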