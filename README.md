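# rigidom

Detects **rigid domains** in proteins from two or more conformational
states, with the number of domains determined automatically.

Large-scale protein function — enzyme catalysis, transport, signalling — is
often driven by the relative motion of internally conserved structural
units. Given M ≥ 2 conformations of the same chain (crystal structures, NMR
models, trajectory snapshots), `rigidom` segments the residues into domains
whose internal geometry is preserved across all conformations, without
asking the user how many domains to expect. It is aimed at structural
biologists and method developers who need an automated, reproducible
segmentation of conformational transitions.

## Method

Each conformation m is reduced to one representative atom per residue
(Cα by default), giving coordinates X⁽ᵐ⁾ ∈ ℝ^{N×3} and distance matrices
D⁽ᵐ⁾ₖₗ = ‖Xₖ⁽ᵐ⁾ − Xₗ⁽ᵐ⁾‖. The pipeline is:

1. **Protein graph.** Residues k, l are linked iff maxₘ D⁽ᵐ⁾ₖₗ ≤ δ
   (default δ = 7.5 Å); the edge weight is exp(−Var), with Var the sample
   variance of the pair distance across conformations, so conformationally
   stable contacts weigh close to one.
2. **Coarse-graining.** Louvain community detection (resolution tuned
   toward ~20 communities) collapses the graph. For every community pair
   the *mean variance* ξ — the average distance variance over all
   cross-community residue pairs — is the motion signal.
3. **Line-graph CRF.** The coarse edges become vertices of a modified line
   graph (two vertices are linked only if their edges share a community
   *and* the non-shared end communities are not adjacent). One-sided MAD
   outlier detection on the ascending ξ arrays yields ±1 indicators γ; a
   pairwise conditional random field scores every ±1 labeling, and the
   maximum a posteriori labeling is computed exactly by max-sum bucket
   elimination (a boundary-set generalisation of the Viterbi algorithm).
4. **Recursive splitting and merging.** Coarse edges labeled −1 are cut;
   components that are not yet rigid (ensemble RMSD ≥ θ, default
   θ = 3.5 Å, where RMSD(S) = 2/(M(M−1)) Σ_{m<m′} RMSD_S(X⁽ᵐ⁾, X⁽ᵐ′⁾) with
   Kabsch superposition) are split again. A merging routine finally absorbs
   fragments smaller than 10 residues and re-joins adjacent segments whose
   merged RMSD stays below θ.

A prior segmentation (e.g. from another method) can be injected by
down-weighting cross-boundary contacts by a factor α (default 0.75).

## Worked example

A synthetic two-domain ensemble (60 + 60 residues, 60° hinge rotation,
0.3 Å coordinate noise, two conformations) with known ground truth:

```r
library(rigidom)

spec <- fixture_spec(domain_sizes = c(60, 60), hinge_angles = 60,
                     noise_sd = 0.3, n_conformations = 2, seed = 7)
fx  <- make_ensemble(spec)
fit <- rigid_domains(fx$ensemble)
fit
#> Rigid-domain segmentation
#>   120 residues, 2 conformations
#>   2 domains (delta = 7.5 A, theta = 3.5 A)
#>   domain 1:   59 residues, ensemble RMSD 0.71 A
#>   domain 2:   61 residues, ensemble RMSD 0.67 A

segmentation_overlap(fit, fx$truth)
#> [1] 0.9916667
```

The fit reports two domains whose internal ensemble RMSDs (0.71 and
0.67 Å) are far below the rigidity threshold θ = 3.5 Å, while the whole
chain moves by ~9 Å; the recovered labels match the ground truth for 99%
of residues after optimal label assignment (one boundary residue sits in
the ambiguous hinge region). `summary(fit)` adds residue ranges and
diagnostics; `plot(fit)` draws the segmentation along the chain;
`write_segmentation_tsv()` / `run_report()` export results.

Real structures enter through `load_conformation("file.pdb", chain = "A")`
and `build_ensemble()`, which intersects the author residue numbering (an
explicit mapping TSV is supported for aligned ensembles). A command-line
interface wrapping the same functions ships in `inst/scripts/rigidom`
(subcommands `segment`, `compare`, `fixture`).

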