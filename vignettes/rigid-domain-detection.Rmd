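---
title: "Graph-based detection of rigid domains in conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based detection of rigid domains in conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidom)
```

## The model

`rigidom` treats rigid-domain detection as an edge-labeling problem on a
graph built from conformational variability. The input is an ensemble of
M ≥ 2 conformations of the same chain, reduced to one representative atom
per residue (Cα by default, configurable for nucleic acids). Two modelling
assumptions drive everything downstream:

* **Rigidity is low ensemble RMSD.** A residue set S is rigid iff
  RMSD(S) < θ, where RMSD(S) is the mean over all M(M−1)/2 conformation
  pairs of the Kabsch-superposed RMSD restricted to S. This is a strict
  comparison; θ defaults to 3.5 Å, appropriate for transitions whose
  overall motion is several Å. Raising θ merges domains, lowering it
  splits them — the one knob users most often touch.
* **Relative motion concentrates distance variance.** If two residues
  belong to the same rigid body, their distance is nearly constant across
  conformations; if they belong to different bodies, it fluctuates. The
  per-pair sample variance (denominator M−1) is therefore the method's
  signal, and no number of domains is ever supplied by the user.

## Pipeline and parameters

**Protein graph.** Residues k, l are linked iff their distance stays
within δ in *every* conformation; the weight is exp(−Var). The
exponentiated-variance form maps zero variance to weight 1 and large
variance to near 0; it is exposed as a pluggable choice since only this
qualitative behaviour matters. δ defaults to 7.5 Å (10.5 and 13.5 Å are
sensible alternatives; larger cutoffs densify the graph and slow the
inference step without changing results much). A second construction rule
— edge if close in *at least one* conformation, weighted by the fraction
of such conformations — is available as `rule = "any"`; it consistently
coarse-grains worse (higher inconsistency error against known domains,
checked in the test suite), which is why `"all"` is the default. Weights
influence only the coarse-graining step; all later stages consume the
variance signal ξ directly.

**Coarse-graining.** Louvain modularity optimisation groups residues into
communities. The resolution parameter is tuned by bisection until the
community count lies within ±5 of `target_communities` (default 20, cap 30
iterations, best-effort fallback, warning when a community exceeds N/4).
Twenty medium-sized communities balance two failure modes: communities so
large they straddle hinges (raising the inconsistency error), and
communities so small that ξ, an average over |c₁||c₂| pairs, loses
significance. Communities never span connected components. For every pair
of communities, ξ averages the distance variance over **all**
cross-community residue pairs, not only contact-graph edges — the
normalisation 1/(|c₁||c₂|(M−1)) makes ξ a mean of per-pair sample
variances, so merging communities averages ξ with size weights (an
algebraic identity the tests verify).

**Modified line graph.** Coarse edges become vertices; vertices are linked
iff their edges share exactly one community *and* the two non-shared end
communities are not adjacent in the coarse graph. The modification removes
redundancy: if the end communities are adjacent, their relation is already
represented by a line vertex, so an edge feature would duplicate it. Each
line vertex inherits the ξ of its community pair; each line edge carries
the ξ of its end communities.

**Outlier indicators.** Inter-domain community pairs are a minority with
unusually large ξ. Rather than fitting the two overlapping ξ
distributions (mixture fits are unstable with so few inter-domain
entries), the package flags outliers one-sidedly: entry i of the ascending
ξ array is an outlier (γ = −1) iff it exceeds the median and
(value − median)/(1.4826·MAD) > 3. The constant 1.4826 is the standard
normal-consistency factor; the threshold 3 is the conventional cut; both
are configurable. A zero MAD falls back to the mean absolute deviation,
and a zero fallback means no outliers. The outlier set may be *expanded*
by the largest non-outliers (a fraction of the array), which the recursion
uses when a non-rigid component refuses to split.

**CRF scoring and exact MAP.** A labeling y ∈ {−1, +1}^LV of the line
vertices is scored by Σ_v γ_v y_v plus a pairwise feature per line edge.
The pairwise feature distinguishes three regimes, with the following
precedence (ties in ξ are called equal below 10⁻⁹):

| γ_v1 | γ_v2 | γ_e | value |
|------|------|-----|-------|
| +1 | +1 | +1 | +1 if y₁ = y₂ = +1, else −1 |
| +1 | +1 | −1 | hinge case: +1 if the outlier-side vertex (larger ξ) takes −1 and the other +1; 0 if y₁y₂ = −1 and ξ₁ = ξ₂; else −1 |
| at least two of the three equal −1 | | | +1 if y₁γ₁ + y₂γ₂ = 2, else −1 |
| exactly one of γ_v1, γ_v2 equals −1, γ_e = +1 | | | 0 |

The "two values among the indicators are −1" trigger is read as *at least*
two, and the both-vertices-regular case takes precedence — the two
conditions overlap only when all three indicators are −1, which the ≥2
reading assigns to the agreement-reward case. The hinge case is the
method's tie-breaker for ambiguous shared communities: an outlier edge
between two regular vertices suggests the shared community sits in a hinge
and must side with the lower-variance vertex.

MAP inference maximises the unnormalised log-score (the partition function
is label-independent and never computed). The exact backend runs max-sum
bucket elimination over a min-fill ordering; the optimal labeling is then
recovered by sequential conditioning, which deterministically returns the
lexicographically smallest argmax under vertex order with +1 before −1.
Exactness holds whenever the induced width stays within 25 variables;
beyond that the package raises a capacity error advising fewer, coarser
communities instead of silently approximating. A brute-force backend
(≤ 22 vertices) exists purely as an oracle; the test suite checks exact ==
brute force on hundreds of random instances, including the tie rule.

**Recursion.** Coarse edges whose line vertex is labeled −1 are removed;
each resulting component is kept if rigid, consists of one community, or
the depth cap (default 10) is reached, and is otherwise split again — with
γ recomputed from the component's own ξ arrays, because local medians
reflect the subproblem better than indicators inherited from the parent
graph. A non-rigid component that refuses to split is retried with the
outlier set expanded by 0.1 and 0.2 before being accepted as a flagged
"non-rigid leaf"; forcing a split would loop on intrinsically flexible
regions, which this method does not model.

**Merging.** The final components, mapped back to residues, pass through a
deterministic two-phase merge: segments below `min_domain_size` (default
10 residues, matching the common practice of discarding sub-10-residue
domains) are absorbed into the contact-adjacent segment minimising the
merged RMSD; then adjacent segment pairs with merged RMSD < θ are merged
greedily, smallest RMSD first, ties toward the smallest segment index.
Merging is idempotent and compensates for over-splits of a single rigid
body.

**Prior knowledge.** An existing segmentation can steer the result:
contact-graph edges crossing prior boundaries are down-weighted by
α = 0.75 (configurable in (0, 1)), which discourages Louvain communities
that straddle those boundaries. Even an imperfect prior improves hinge
placement.

## The synthetic generator

`make_ensemble()` produces ensembles with exact ground truth: contiguous
domains along a self-avoiding persistent random walk (step 3.8 Å, the Cα
virtual bond; clash cutoff 3.2 Å with a 100-retry budget), hinge rotations
applied to everything downstream of each domain boundary, and isotropic
Gaussian noise. Conformation m rotates each hinge by the fraction
(m−1)/(M−1) of its specified angle, mimicking a morph between end states.
The walk's direction perturbation (0.5) was chosen once so that domains
are elongated and the stated hinge angles displace them well beyond θ —
the large-motion regime (overall RMSD > 5 Å) that rigid-domain benchmarks
target; the two-domain default fixture has within-domain RMSD ≈ 0.7 Å and
whole-chain RMSD ≈ 9 Å.

What the generator does **not** emulate: secondary-structure topology,
side chains, shear (translation-dominated) motions, correlated
experimental noise, missing residues, and sequence heterogeneity between
conformations. Passing the synthetic-recovery tests therefore shows that
the inference machinery recovers clean hinge motions; it does not certify
performance on subtle shear transitions or disordered regions, where the
ξ signal is known to weaken.

## Numerical choices and degenerate inputs

* Sample variances use denominator M−1 throughout, matching the
  ξ normalisation.
* ξ equality in the hinge sub-case is tested at 10⁻⁹; MAP tie-breaking is
  lexicographic with +1 < −1; Louvain runs under a fixed seed — together
  these make the whole pipeline bit-reproducible (identical TSV output on
  repeated runs).
* Identical conformations: every variance is zero, the MAD rule flags
  nothing, MAP labels everything +1, and the pipeline returns exactly one
  domain with RMSD 0.
* Ensembles are validated (M ≥ 2, N ≥ 3, finite coordinates, unique
  residue ids); RMSD requires ≥ 3 residues (superposition is
  underdetermined below that), and the merge phase treats 1–2-residue
  scraps as trivially rigid.
* A coarse graph with no edges (single community) yields an empty line
  graph and a single domain, with a warning.

## Problem sizes in the test suite

The suite exercises 120–150-residue fixtures with M = 2 (ten seeds for the
two-domain recovery check), 200 random line graphs of up to 12 vertices
for the MAP-vs-enumeration oracle, 50 instances × all 2ⁿ labelings
(n ≤ 10) for the scorer oracle, and 1000 random label pairs (N ≤ 30) for
the metric oracles — sizes chosen to exercise every code path while
keeping a full run around a minute.

## Known limitations

* Exactly inference cost grows exponentially with the line graph's induced
  width; very dense coarse graphs (large δ together with many communities)
  can hit the capacity cap. The remedy is a lower `target_communities` or
  smaller δ.
* Domains whose relative motion stays below θ are reported as one domain —
  by design, since the rigidity criterion is the method's definition of
  "domain".
* Hinge residues have intrinsically ambiguous membership; communities that
  straddle a hinge propagate that ambiguity to domain boundaries (a few
  boundary residues may land on either side).
* Sequence alignment across heterogeneous ensembles is out of scope; an
  explicit residue-mapping table is the supported route.
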