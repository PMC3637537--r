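---
title: "Non-sequential structure alignment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-sequential structure alignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsalign)
```

## The problem

Two protein folds can share a secondary-structure packing arrangement while
connecting the elements in different sequence order: circular permutations,
segment swaps, or wholesale shuffles of the element order. A sequential
aligner, which only considers monotone residue correspondences, cannot
recover such relationships. `nsalign` treats the correspondence as a set of
rigid-body-compatible residue pairs with no order constraint at all, and
searches for the superposition and one-to-one mapping that maximize a
TM-score-like objective. Everything operates on C-alpha coordinates, so
backbone-only models and multi-chain complexes (concatenated with recorded
continuity breaks) are first-class inputs.

## The model, step by step

**Secondary structure.** Residue $i$ is labeled from the distances among
C-alphas $i-2,\dots,i+2$ within one continuous stretch: helix if the three
separation-2 distances are within 2.1 Å of 5.45 Å, the two separation-3
distances within 2.1 Å of 5.18 Å and the separation-4 distance within 2.1 Å
of 6.37 Å; strand analogously with ideals 6.1 / 10.4 / 13.0 Å and tolerance
1.42 Å; else coil. A single smoothing pass (on by default, flag-controlled)
relabels a residue whose two neighbours agree with each other. Residues
within two positions of a terminus or break stay coil — an intrinsic edge
effect of any distance-pattern assignment. Helix runs shorter than 6 and
strand runs shorter than 3 residues are discarded at the element level but
keep their label for the residue-level similarity.

**Comparing elements.** An element of length $n$ yields one comparing
element per short-segment window ($n-5$ windows of 6 residues for helices,
$n-2$ windows of 3 for strands). For a helix window starting at residue $k$
the two end points are axial averages weighted $0.74/1/1/0.74$ over $3.48$
(residues $k..k+3$ and $k+2..k+5$); for strands they are midpoints of
consecutive C-alphas. The element point is the midpoint of the two ends,
$\mathbf v^{\mathrm{para}}$ the unit vector between them, and
$\mathbf v^{\mathrm{perp}}$ the unit perpendicular component of the vector
from the element point toward the window centre (the mid-residue pair for
helices, the middle residue for strands). Representing one element by many
windows is what lets long, bent or twisted elements match a short partner.

**Hashing and voting.** Each comparing element anchors a right-handed frame
($x=\mathbf v^{\mathrm{para}}$, $y=\mathbf v^{\mathrm{perp}}$ re-orthogonalized,
$z = x \times y$). For the model structure, every ordered pair (frame $i$,
element $j\neq i$) deposits the in-frame description of $j$ into the voxel
$\lfloor \mathbf r_j(i)/h \rfloor$, keyed by element type. Recognition
replays the same construction for the query and, for each stored entry of
matching type found in the looked-up voxel, adds
$S = \Theta + \Phi$ to the frame-pair accumulator, with
$\Theta = (\cos\theta - \cos 60^\circ)/(1-\cos 60^\circ)$ for
$|\theta| \le 60^\circ$ (else 0) and $\Phi$ the same function of the angle
between perpendicular vectors. The top-$K$ frame pairs give seed
superpositions $R = B_q B_m^{\mathsf T}$,
$t = o_q - R\,o_m$.

**Residue-level alignment.** Under a seed superposition the similarity
matrix is

$$M_{ij}(d_R) = \frac{1}{1 + d_{ij}^2/d_0^2}\cdot
\frac{\delta_{\sigma_i \sigma_j} + w}{1 + w}
\quad (d_{ij} \le d_R;\ \text{else } 0),$$

with $d_0 = 1.24\,(L-15)^{1/3} - 1.8$ for query length $L$. Alignments are
unions of continuous segments — runs along diagonals (and anti-diagonals in
mixed mode) whose cells are all positive. Segments are selected greedily:
take the highest-scoring run, accept while its score is at least
$S_{\min}$, zero its rows and columns, repeat; then enlarge the cutoff
through $d_1 = R_0$, $d_2 = 1.5R_0$, $d_3 = 2.5R_0$, carrying accepted
segments forward. Because every cell is at most 1 and $S_{\min} = 2.2$,
accepted segments always span at least 3 residues: over-fragmentation into
1–2 residue matches is excluded by construction, which is also why the
reported $N_{\mathrm{ali}}$ and $N'_{\mathrm{ali}}$ (the version ignoring
fragments shorter than 3) always coincide for this aligner.

**Refinement and selection.** Alternate Kabsch superposition on the aligned
pairs with regeneration of the stepwise alignment, scoring each iterate by
$\mathrm{mTM} = \frac1N \sum_{\langle i,j\rangle} M_{ij}(d_3)$, until the
score stops improving. Each of the $K$ seeds is refined (identical initial
segment sets are refined once); results are deduplicated by segment set and
ranked by mTM. Sub-optimal alignments are retained and can be emitted.

**Reverse (inverse-direction) matches.** In mixed mode $\Theta$ uses
$|\cos\theta|$, so antiparallel element pairs can vote, and the segment
search also scans anti-diagonals, pairing $(\alpha+m, \beta-m)$. Forward
mode (the default) never emits reverse fragments.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `R0` | 3.2 | Å | base distance cutoff; steps are (1, 1.5, 2.5)·R0 |
| `h` | 3.2 | Å | hash voxel edge |
| `w` | 1.0 | — | weight of the secondary-structure type factor |
| `s_min` | 2.2 | — | minimum accepted segment score (forces length ≥ 3) |
| `top_k_seeds` | 50 | — | seed superpositions refined per pair |
| `max_refine_iters` | 30 | — | hard cap; convergence is typically 5–6 |
| `mode` | forward | — | `forward` or `mixed` (adds reverse segments) |
| `normalization` | first_structure | — | length used in d0 and mTM |

The defaults are the published parameter set of the method this package
implements; they were tuned there against a curated non-sequential
reference set and are kept as-is. `d0` is clamped below at 0.5 Å: the raw
formula turns negative for chains of ≤ 19 residues, and the clamp (standard
practice for TM-score-family scores) keeps the similarity well-defined on
the short synthetic chains used in testing. Score normalization uses the
designated query (first input); `normalization = "shorter"` is available
because the aligned-residue statistic is conventionally normalized by the
smaller protein.

## Numerical and design choices

* **Kabsch superposition** uses the SVD solution with the reflection branch
  sign-corrected, so returned rotations always have determinant +1
  (proteins are chiral). A single point, or coincident points, fall back to
  a centroid translation with identity rotation.
* **Voxel binning** is plain componentwise floor with single-cell lookup.
  Quantization can drop a vote when a match straddles a voxel boundary; the
  50-seed redundancy plus residue-level refinement absorbs this. A 27-cell
  probe could be added for sensitivity experiments but is not needed on any
  tested fixture.
* **Within-run optimality.** Since segment cells must all be positive and
  the segment score is their sum, the best sub-segment of a maximal
  positive run is the whole run. The segment search therefore enumerates
  maximal runs only — an exact simplification, verified against exhaustive
  enumeration in the tests.
* **Tie-breaking** is deterministic everywhere: segment candidates compare
  (score rounded at 1e-9, forward before reverse, smallest query start,
  smallest model start); recognition ties order by frame indices; equal-mTM
  alignments prefer more aligned pairs, then earlier seed rank. Rounding
  before comparison keeps results bit-stable under rigid transforms of the
  inputs, where floating-point jitter would otherwise reorder exact ties.
* **Chain breaks** (chain changes, numbering gaps, consecutive C-alphas
  more than 4.5 Å apart) terminate secondary-structure runs, comparing-
  element windows and alignment segments; nothing ever spans a break.
* **Reverse segment indexing** follows $(\alpha+m,\ \beta-m)$ for
  $m = 0..l-1$; a lone pair is directionless and is only ever emitted as
  part of a forward run.
* **Degenerate perpendiculars.** A perfectly straight strand (possible only
  for synthetic coordinates) has no defined perpendicular; the
  implementation falls back to the perpendicular component of the global
  +z axis (or +y when the element runs along z), keeping results
  deterministic at the cost of rigid equivariance for exactly degenerate
  inputs. The toy generator adds a sub-0.2 Å seeded perturbation precisely
  to avoid this degeneracy.
* **Convergence** is declared when mTM improves by less than 1e-6; the
  best iterate ever seen is returned, so refinement can never degrade a
  seed's alignment.

## What the synthetic benchmark emulates — and what it does not

`make_toy_structure()` builds compact folds from ideal-geometry elements
(helix: 2.3 Å radius, 1.5 Å rise, 100°/residue; strand: 3.3 Å rise with
±0.9 Å zigzag) joined by smooth arc loops, with a seeded sub-0.2 Å jitter.
`random_toy_spec()` draws 3–6 elements and 40–120 residues — the scale of
single domains. `permute_segments()` reproduces the construction of
non-sequential benchmark pairs: cut at the midpoint of every coil run
between elements, shuffle the segment order (resampling until non-identity),
renumber, and keep all coordinates — so the true residue bijection is known
exactly and the permuted chain carries a break at every junction. Loop
regions are identified with the package's own C-alpha assignment rather
than an external hydrogen-bond-based program; for ideal-geometry toys the
two agree, and the choice removes the only external-binary dependency.

Passing these tests demonstrates the algorithmic contract — exact
self-recovery, recovery of known permutations, rigid invariance,
determinism — on clean, well-separated secondary structure. It does not
demonstrate performance on real structures, where elements are irregular,
labels are ambiguous, domains flex, and reference alignments embody expert
judgment; the published benchmarks for this algorithm family rely on
curated external datasets (MALIDUP, MALISAM and permuted variants) that are
deliberately not bundled here. A known failure mode on hard real pairs is a
1–4 residue register shift relative to a manual reference: the mTM optimum
does not always coincide with expert judgment.

## Problem sizes used in the bundled checks

The test suite and `scripts/acceptance.R` run, at their defaults: 20
self-alignments and 50 permutation-recovery pairs of generated toy folds
(40–120 residues), 100 rigid-invariance re-alignments, 200 random
similarity matrices (≤ 12×12) checked cell-for-cell against exhaustive
segment enumeration, 1000 random rigid placements against the Kabsch
optimum, and 20 TM-score comparisons against an independent
rotation-search oracle. These sizes exercise every code path while keeping
a full run in the low minutes on one core.

## Known limitations

* Alignment quality on real proteins is bounded by the C-alpha
  secondary-structure assignment (≈ 85% three-state agreement with
  hydrogen-bond-based assignments is typical for this family of methods);
  mislabeled elements shrink the seed pool.
* Structures contributing fewer than two comparing elements (no element,
  or a single 3-residue strand) cannot be aligned — the method is
  SSE-driven by design and reports a distinct no-SSE error.
* The greedy segment selection approximates the combinatorial optimum of
  the total segment score; the tests verify it agrees step-for-step with
  exhaustive search on small matrices, not global optimality.
* `N_gap` is defined as (number of maximal consecutively aligned
  fragments − 1), the only connectivity-free reading for non-sequential
  alignments; sequential aligners sometimes count per-sequence gap
  openings instead, so cross-tool comparisons of this statistic need care.
* Weighted superposition, sequence-order-constrained alignment and
  multiple-structure alignment are out of scope; mmCIF input is a possible
  extension (PDB format only in this version).
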