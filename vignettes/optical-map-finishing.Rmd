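---
title: "Optical-map-guided assembly finishing: models and methods"
author: "omfinish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical-map-guided assembly finishing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omfinish)
```

## The problem

Short-read draft assemblies of eukaryotic genomes -- yeasts in particular --
arrive as hundreds of unordered contigs, and the most connected assemblies
are not necessarily the most correct: aggressive scaffolding can collapse
near-identical repeats into a single copy or relocate large segments.
Optical maps provide orthogonal, extremely long-range information: an
ordered list of restriction-fragment lengths along each chromosome, measured
from stretched single DNA molecules. `omfinish` uses chromosome-scale
optical maps as a spatial ruler to (i) place contigs from a primary
(short-read) assembly, (ii) fill the remaining gaps with contigs from a
secondary (long-read) assembly, (iii) emit one consensus sequence per
chromosome with map-sized N gaps, and (iv) evaluate assemblies with
feature-response curves computed from anomalously mapped read pairs.

## Restriction-map alignment

### Model

A contig is digested in silico into fragments $q_1,\dots,q_m$; an optical
chromosome map provides fragments $r_1,\dots,r_n$ carrying multiplicative
sizing error. A *fitting* (glocal) alignment consumes the query end to end
inside a free window of the reference, as a sequence of *blocks*: a block
matches a run of up to `delta_max` query fragments (summing to $Q$) against
a run of up to `delta_max` reference fragments (summing to $R$). Its cost is

$$ \frac{(Q-R)^2}{2\,(\sigma_{rel} R)^2} \;+\; c\,\big[(n_q-1)+(n_r-1)\big], $$

a chi-square-style sizing term under a relative error model (each observed
fragment of true size $s$ has standard deviation $\sigma_{rel}\,s$) plus a
linear penalty $c$ per missed or spurious cut inside the block. This is the
classical likelihood-flavoured scoring family for Rmap alignment; all
constants live in `align_params()` (`sigma_rel = 0.05`, `cut_penalty = 3`,
`delta_max = 5` by default).

The two *terminal* query fragments are boundary fragments: a contig end is a
break point, not a restriction site, so they are matched one-sidedly -- no
sizing cost when the reference side is at least as large (the contig ends
inside a reference fragment, and the end coordinate is placed by linear
interpolation), and the usual sizing cost only for query overhang. The
optimum over all monotone block decompositions is found by dynamic
programming (implemented in C++); the reverse orientation aligns the
reversed fragment list, and ties are broken toward the smaller reference
start, forward before reverse.

### Significance and gates

There is no usable closed-form null for this score, so placement
significance is empirical: the reference fragment order is permuted
`perm_reps = 99` times, the query realigned, and
$p = (1 + \#\{c_{perm} \le c_{obs}\})/(\text{reps}+1)$. Placements require
$p \le 0.05$. Two structural gates complement the statistics: a tier-1
contig must be at least 40 kbp long *and* carry at least 8 in silico
fragments -- shorter contigs simply do not contain enough cuts to be placed
reliably.

### Multi-location placements and collapsed repeats

A collapsed repeat is a multi-copy genomic repeat assembled as a single
copy. Against the optical map its contig aligns, near-equally well, at
every true copy location. The aligner therefore returns all mutually
non-overlapping placements whose cost is within a tie band of the best:
10% relative (`rel_cost_tie`) *plus* an absolute slack
$3\sqrt{m}$ (`cost_tie_scale` $\times\sqrt{m}$). The absolute term is
essential: the costs at two genuinely equivalent loci are two independent
draws of a sum of $\approx m$ half-chi-square terms, so their difference
scales like $\sqrt{m}$ and is *not* small relative to a near-zero best
cost. Accepted multi-location placements are marked `multi_flag`, and the
consensus builder emits the contig sequence at every accepted location.

## Two-tier placement and consensus

Candidates are accepted greedily by ascending **cost per query fragment**
(absolute cost grows with contig size, which would otherwise let short
spurious hits pre-empt long, well-supported placements), rejecting any
candidate overlapping an accepted placement by more than
`overlap_tol = 0.1` of the shorter interval. After tier 1, every maximal
uncovered map interval of at least `min_gap = 10` kbp is offered to the
secondary assembly; a secondary candidate must lie essentially inside the
gap (outside-gap overlap bounded by the same tolerance). Coverage is
reported both after tier 1 and after tier 2, since the two numbers answer
different questions (what the primary assembly explains vs what the
combination explains).

The consensus builder walks each map left to right: placements emit their
(possibly reverse-complemented) sequence; overlaps between consecutive
placements trim the placement with the higher per-fragment cost; every
inter-placement gap of $g$ map-bp emits exactly $g$ Ns, including uncovered
map ends -- the optical map, not the sequence, is the spatial ruler.
Primary contigs with no accepted placement are appended as `unplaced_`
records.

Runs of ambiguous characters (N or IUPAC codes) inside placed primary
contigs are replaced from the secondary assembly. Because tier-2 placement
forbids secondary placements that overlap primary ones, the placement set
retains all *significant* secondary alignments as auxiliary donors; a run
is patched (piecewise, if several donors each cover part of it) by
transferring the run's map interval into donor-contig coordinates by linear
interpolation between matched cut positions. Exact base-level registration
is unnecessary: replacement targets whole ambiguous runs anchored by
flanking matched cuts, and under zero sizing noise the transfer is exact --
which is what the identity tests assert. The completion report separates
`bp_from_secondary_new` (sequence in intervals only the secondary assembly
could cover) from `ambiguous_bp_replaced` (primary ambiguity repaired in
place), mirroring the two ways a long-read assembly completes a short-read
one.

### Redundant maps

When the mapping experiment delivers more maps than chromosomes (e.g.
recombinant variants), smaller maps that duplicate larger ones are flagged:
either most of their placed length comes from contigs also placed on larger
maps, or their own fragment list aligns significantly to a larger map. For
the second route the "shared" fraction counts only blocks whose sizing
agrees within $3\sigma$, since a fitting alignment spans the query
end-to-end by construction.

## Feature-response evaluation

Insert-size statistics are estimated from properly oriented same-contig
pairs by a two-stage robust procedure: a median/MAD screen discards inserts
beyond 3.5 robust standard deviations, then the mean and a
truncation-corrected standard deviation are computed on the survivors. The
screen provides outlier resistance; the second stage restores the
efficiency that a pure MAD estimator lacks (its standard error,
$\approx 1.17\%$ at $10^4$ pairs, would dominate a 1% recovery budget).

Feature calling scans 1 kbp windows every 200 bp. Windows are flagged
`LOW_COV`/`HIGH_COV` when mean per-base coverage leaves
$[0.5, 2]\times$ the global *median* per-base coverage (the median is robust
to repeat spikes); `WRONG_DIST` / `WRONG_ORIENT` / `SINGLETON` when the
corresponding anomalous-pair proportion reaches $\theta = 0.4$; and a
`HIGH_COV` region additionally becomes `COMPRESSED_REPEAT` when at least
$\theta$ of its reads have mates on a different contig or are otherwise
anomalous -- the read-level signature of a collapsed repeat. Adjacent
flagged windows merge; features need at least 5 supporting reads and one
window's length. Low-coverage calls are masked within `edge_exclude = 5`
kbp of contig ends: on a linear molecule only one mate of a pair can start
within about one insert length of a terminus, so expected coverage halves
there and the uniform-coverage model does not apply.

The feature-response curve takes contigs in order of decreasing length
(ties by id) and plots cumulative features against cumulative length over
the estimated genome size; per-kind sub-curves are computed identically.
The original feature-response formulation orders contigs by feature
density; both orderings are available (`order_by`), with length ordering
the default.

## The simulator

The synthetic-data generator is first-class code and defines the study
conditions used by the tests and the acceptance script:

* **Truth genomes**: i.i.d. background at GC 0.40 (a typical yeast
  composition), with tandem repeat arrays of configurable length, copy
  number and copy identity.
* **Derived assemblies**: contigs tile the truth at random breakpoints
  (mean 250 kbp, minimum 50 kbp for the primary; mean 60 kbp for the
  secondary, mirroring the roughly four-fold contiguity gap between a
  scaffolded short-read assembly and a long-read assembly). Injected
  errors: `collapse_repeat` (a two-copy repeat emitted once, with the
  removed copy ghost-mapped onto the kept copy so reads pile up there),
  `relocate` (a segment moved onto a contig of another chromosome),
  `n_run` (sequence overwritten with N; reads there become unmappable) and
  `drop` (sequence absent from the assembly). Every truth-to-contig
  mapping is recorded in a truth table.
* **Optical maps**: per-fragment truncated-normal relative sizing noise
  (`sigma_rel = 0.03`, truncation at $\pm3\sigma$ keeps fragments positive
  without rejection sampling), missed cuts with probability
  `p_miss = 0.05`, spurious cuts as a Poisson process
  (`false_cut_per_bp = 5e-7`), and a 2 kbp desorption limit below which
  fragments merge into their neighbour -- the typical behaviour of
  automated mapping platforms.
* **Read pairs**: pair positions uniform on the truth, inserts
  $\mathcal N(3000, 300^2)$, 100 bp reads at 20--30$\times$; mates are
  emitted as alignment records mapped through the truth table, so every
  anomaly class arises mechanistically (a pair straddling a collapse
  boundary lands on different contigs; one landing in an N-run loses a
  mate) without requiring an external read mapper.

What the simulator does **not** model: base-call errors, chimeric reads,
GC-dependent coverage bias, PacBio read-length distributions, and diploid
heterozygosity. Passing tests therefore demonstrate the pipeline's
correctness under a clean error taxonomy, not robustness to every artefact
of real sequencing data.

## Packaged study conditions and problem sizes

`run_finishing_study()` fixes the chromosome-scale conditions: a 5 Mbp,
3-chromosome genome (2.2/1.7/1.1 Mbp), one collapsed 40 kbp tandem repeat,
three dropped 200 kbp segments (600 kbp recoverable only from the secondary
assembly) and five 10 kbp N-runs (50 kbp of injected ambiguity).
`frc_collapse_replicate()` fixes the detection conditions: a 300 kbp
chromosome with a collapsed two-copy 30 kbp repeat at 20$\times$ pair
coverage, evaluated against an error-free assembly of the same truth.
These sizes keep a full run of either study in the minutes range on a
single core while leaving every length scale (fragment, contig, gap,
chromosome) separated by an order of magnitude.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, half-open everywhere; map files carry kbp with
  exactly three decimals, converted to bp by round-half-up.
* Recognition-site windows containing N (or any ambiguity code) never
  match: a false cut inside an assembly gap would corrupt placement.
* A query with fewer than two fragments returns "no placement" rather than
  an error -- there is no internal cut to anchor an alignment.
* Equal-cost placements tie-break deterministically (smaller reference
  start, forward before reverse); the DP itself resolves ties toward the
  smallest reference end.
* `completion_stats()` reports the ambiguity replacement ratio as `NA`,
  not 0, when there was no ambiguous sequence.
* Permutation p-values use the add-one estimator, so they can never be 0
  and are bounded below by $1/(\text{reps}+1)$.

## Known limitations

* Chimeric contigs cannot be split across two maps: placement is
  all-or-nothing per contig, matching the two-tier strategy's design.
* The empirical permutation null is weakly discriminating for long queries
  against fragment-permuted references; the per-fragment cost screen and
  greedy overlap rules carry part of the rejection burden.
* Ambiguity patching under sizing noise can misregister donor sequence by
  up to a few hundred bp relative to the true locus; lengths and N
  accounting remain exact, and registration is exact in the zero-noise
  limit.
* Only linear chromosomes and single-enzyme maps are supported.
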