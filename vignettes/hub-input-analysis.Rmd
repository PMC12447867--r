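---
title: "Methods: clustering and validating the input network of a hub neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering and validating the input network of a hub neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connhub)
```

This vignette is the package's own account of its methods: the data model,
the hub statistics, the clustering objective and its maximizer, the
validation statistics, the synthetic benchmark, and the numerical and design
choices made where the problem left them open.

## Data model and conventions

A connectome is a pair of tables in the layout of the Hemibrain
"traced-adjacencies" export: a neuron table (`bodyId`, `type`, `instance`,
traced/cropped status) and a directed edge table (`bodyId_pre`,
`bodyId_post`, optional primary-neuropil `roi`, integer `weight` counting
postsynaptic densities). Conventions applied at construction:

* **Self-loops (autapses) are removed.** All downstream statistics — partner
  counts, community weights `m_C`, degree sums `K_C` — are defined on neuron
  *pairs*, so autaptic weight has no place to land; removing it once at load
  time keeps every stage consistent.
* **Pair totals before thresholds.** A connection between two neurons may be
  split over several ROI rows. The conventional reliability threshold
  (weight ≥ 3; weaker connections are potentially erroneous reconstruction
  artifacts) is applied to the per-direction *pair total*, never to
  individual ROI rows, and the ROI split of surviving pairs is preserved.
* **Lenient loading by default.** Edge rows referencing unknown bodyIds are
  dropped with a reported count; a strict mode turns them into errors.
* **Laterality merging.** ROI names carry right/left markers in several
  dialects (`SMP(R)`, `SMP_L`); a trailing marker is stripped before the
  supercategory lookup, so right and left variants of one neuropil always
  merge. Unknown or absent ROIs fall in the `"NotPrimary"` bucket rather
  than erroring, since real exports localize some synapses outside the
  primary neuropils. The packaged ROI map is a reconstruction of the
  standard 12-supercategory nomenclature (SLP/SIP/SMP → SNP, FB/EB/PB/NO/AB
  → CX, and so on), not a copy of any distributed file.

## Hub statistics

Rankings order neurons by input weight plus output weight, descending, with
ties broken by ascending bodyId so results are reproducible (the ordering of
tied neurons is otherwise arbitrary). Partner counts classify each
thresholded partner as pre-only, post-only, or both; cell-type counts
deduplicate at the type level and exclude untyped (`"None"`) neurons by
default, with a flag to pool them as a single pseudo-type.

**Primacy** of a target among a source cell type's outputs aggregates the
outputs of *all* neurons of the source type by postsynaptic type and ranks
the target by `1 + #(types with strictly greater weight)`. Two choices were
open here:

* *Ties do not demote.* "First position" is read as "no type strictly
  greater". At realistic synapse counts exact ties are rare, and any strict
  tie-break would be arbitrary.
* *Untyped postsynaptic neurons are pooled* into one `"untyped"` sink by
  default, so their aggregate weight can legitimately outrank the target; a
  flag ignores them instead. Ignoring them silently inflates primacy, which
  is why pooling is the default.

A connection is classified *reciprocal* when both directions carry weight
and the stronger is at most twice the weaker; *strong* inputs are cell types
with aggregated weight ≥ 100 onto the target.

## The clustering objective

The subconnectome of a hub's inputs — all presynaptic partners and every
connection among them, with **no weight threshold** so that weak but
informative nodes are not isolated — is symmetrized: the undirected weight
of a pair is the sum of both directed totals. Communities are found by
maximizing generalized modularity density

$$Q_g = \sum_{C} \left( \frac{m_C}{m} - \left(\frac{K_C}{2m}\right)^2
\right) \rho_C^{\chi}, \qquad
\rho_C = \frac{2 m_C}{n_C (n_C - 1)},$$

with `m` the total edge weight, `m_C` the weight inside community `C`, `K_C`
its weighted-degree sum, `n_C` its node count, and `χ ≥ 0` the resolution
exponent. Numerical conventions:

* `m` is interpreted as total edge *weight*, not edge count: the same symbol
  divides `m_C`, which is explicitly a weight, and only this reading makes
  the `χ = 0` limit equal standard weighted modularity (verified against an
  independent implementation in the test suite). For unit weights the two
  readings coincide.
* Singletons have `ρ_C := 0` (the `0/0` case), with `ρ_C^0 := 1`, so at the
  coarse resolution singletons contribute their usual modularity term. For
  weighted graphs `ρ_C` may exceed 1; the formula places no cap and none is
  imposed.
* `χ = 0` is the default and the resolution used by the pipeline; higher
  values up-weight dense communities and resolve finer structure. The
  naming caveat: with `ρ^0 = 1` the `χ = 0` limit is classic *weighted
  modularity*, not the distinct "modularity density" quantity of the older
  literature; the displayed equation is implemented verbatim.

## The RenEEL maximizer

`reneel_maximize()` implements Reduced Network Extremal Ensemble Learning:

1. Build an ensemble of `ensemble_size` partitions with the seeded base
   heuristic (default 20 — the working range of extremal ensemble schemes;
   larger ensembles buy diversity at linear cost).
2. Collapse the **core groups** — maximal node sets co-assigned in *every*
   ensemble member (the intersection of the co-membership equivalence
   relations) — into single nodes. Each reduced node carries its internal
   weight and member count, so any partition of the reduced graph scores
   *exactly* as its expansion on the original graph (an invariant checked
   in the tests).
3. Run the heuristic on the reduced graph and expand. If the candidate
   duplicates an ensemble member (canonical-form comparison) or scores
   strictly below the worst member, the ensemble shrinks by one, dropping
   the worst; otherwise the candidate replaces the worst.
4. Repeat until one partition remains. Capacity never grows and
   replacements strictly improve the worst score, so the loop terminates; a
   generous iteration bound guards the degenerate case.

The **base heuristic** is a seeded greedy local-move scheme with
agglomeration: repeated passes offer each node, in seeded random order, a
move to a neighboring community or to a fresh singleton; when no move
helps, communities are collapsed and the process recurses on the aggregate.
Three numerical choices matter:

* *Exact gains.* Moving one node changes only the donor and recipient
  communities, whose objective terms are recomputed in closed form from
  running `(m_C, K_C, n_C)` statistics. The gain is therefore exact for
  every `χ` — there is no approximate incremental score to audit — and
  every accepted move strictly increases `Q_g` (tolerance `1e-12`).
* *Randomized extremal choice.* Among the strictly improving moves the
  heuristic picks one at random, gain-weighted, rather than the best. A
  deterministic best-move rule sends most seeds into the same local
  optimum, which starves the ensemble of diversity; the randomized rule is
  what makes the consensus scheme effective.
* *Multi-start climbs.* At `χ > 0` singleton communities contribute 0, so a
  climb from singletons stalls whenever a dense group is only profitable
  once fully formed (pairwise merges can be negative while the triple is
  positive). Each heuristic call therefore climbs from singletons, from a
  seeded random coarse start, and — at `χ > 0` — from the `χ = 0` solution,
  keeping the best result at the target resolution.

On every random ≤ 8-node test graph (three resolutions, fifty graphs) the
ensemble reaches the exhaustive-enumeration optimum; enumeration is by
restricted growth strings and is capped at 10 nodes (Bell(10) ≈ 1.2e5
partitions).

## Validation statistics

**Co-membership Jaccard.** Two clusterings are compared on the intersection
of their node sets (dropped nodes are counted and reported) as
`pairs co-clustered in both / pairs co-clustered in either`, computed from
the contingency table in closed form. If both partitions are all-singletons
the clusterings are identical and the value is defined as 1; if exactly one
is, the value is 0. The shuffled baseline permutes one partition's labels
over its nodes, preserving module sizes.

**Joint proportions.** For modules `i` of A and `j` of B, the count
`N[i,j]` of shared nodes is normalized by column (`width = N[i,j]/N_B[j]`)
and by row (`height = N[i,j]/N_A[i]`), the two normalizations used in joint
clustering plots; widths sum to 1 over each non-empty column, heights over
each row.

**Input similarity.** Each subconnectome neuron is described by its vector
of synapse weights from every neuron *outside* the subconnectome —
intra-subconnectome edges are excluded so that similarity measures shared
external drive, not the very connectivity that was clustered. Similarity is
the cosine `⟨u,v⟩/(‖u‖‖v‖)`, which for non-negative weights lies in [0, 1];
zero-norm vectors (neurons without external input) get similarity 0 with a
diagnostic count. Pooled means average over all pairs of distinct neurons
within a module and over all cross pairs between modules; singleton modules
have no within pair and report `NA`. The null shuffles module labels
(size-preserving, the same null as the Jaccard baseline) 100 times;
`z = (observed − null mean)/null sd` with the *population* standard
deviation over the shuffled means, and a degenerate null (sd = 0) reports
`NA` rather than an infinite z.

## The synthetic benchmark

`synthetic_spec()` defaults define the benchmark used by the tests and the
acceptance script: four modules of 50 neurons, directed edge probabilities
0.3 within and 0.01 between modules, geometric integer weights on
{1, 2, ...} with mean 8 within and 2 between, a hub receiving inputs from
70% of each module with mean weight 20, cell types of 3–6 contiguous
neurons (the block at each module boundary is fused so some types span two
modules, as real cell types do), half of the hub-input types engineered as
primary-strong, module-specific neuropil profiles (a dominant supercategory
per module plus an SNP component and a `NotPrimary` remainder), and 0.5
weak noise edges (weight 1–2) per neuron.

Rationale for the values the benchmark had to fix itself: the geometric law
is the simplest heavy-tailed positive integer family, parameterized by its
mean, and places realistic mass on weak (< 3) connections that the
no-threshold subconnectome stage must tolerate; a fan-in of 0.7 leaves a
substantial external population so input-similarity columns are non-trivial;
weight means 8/2 make within-module structure dominant without being
degenerate; primacy is planted *after* all stochastic edges, by raising the
chosen types' hub weights to `max(strongest other output + 1, 100)` and
capping the remaining hub-input types below the strong threshold, so the
planted primary-strong set is recoverable exactly on noiseless draws. All
draws flow from one master seed; generation is deterministic.

What the generator does *not* emulate: realistic degree distributions,
distance-dependent connectivity, the empirical abundance of untyped
neurons, or cropped/untraced bodies. Passing the planted-recovery tests
therefore shows the pipeline recovers block-modular structure under
heavy-tailed weights and weak noise — not that real connectome modules are
as cleanly separable.

## Problem sizes used by the tests

The suite validates at sizes chosen for completeness of coverage rather
than scale: the 6-node worked example (closed-form objective value 5/14),
fifty random ≤ 8-node graphs against exhaustive enumeration at three
resolutions, and the 200-neuron planted benchmark (140-node hub-input
subconnectome) for recovery, 10-run consistency, shuffled baselines, and
similarity z-scores, with ensemble sizes 10–12. The same algorithms run
unchanged on real exports; the full-scale convention is the default
ensemble of 20 and 30 consistency runs.

## Known limitations

* Directed and multilayer modularity variants are out of scope; the
  clustering stage always symmetrizes.
* The exhaustive oracle is limited to 10 nodes; above that, optimality is
  only evidenced by the ensemble's consensus.
* `run_pipeline()` consumes a full-connectome reference partition as a file
  when comparing clusterings; it does not recompute multi-resolution
  partitions of a full connectome.
* Very large bodyIds are carried as doubles (exact up to 2^53), matching
  the CSV exports; no 64-bit integer type is introduced.
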