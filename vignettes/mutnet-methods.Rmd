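---
title: "Methods: residue networks, MM-GB/SA bookkeeping and staged Jarzynski PMFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue networks, MM-GB/SA bookkeeping and staged Jarzynski PMFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutnet)
```

mutnet implements the quantitative core of a comparative structure–network
and energetics study of an enzyme and its activity-enhanced mutant (the
motivating system is a D-psicose 3-epimerase with a bound D-fructose
substrate): residue interaction networks and their graph statistics,
end-state MM-GB/SA free-energy bookkeeping, staged steered-dynamics
potential-of-mean-force (PMF) estimation by Jarzynski averaging, and
trajectory observables. Everything runs on synthetic inputs generated by
the package itself, so each stage is testable end to end without external
data. This vignette records the models, the tunable parameters, and the
design decisions behind the defaults.

## Residue interaction networks

A structure is a tibble of pseudo-atoms grouped into residues; the ligand
is an ordinary residue flagged `is_ligand`. `build_rin()` places one node
per residue and typed, weighted edges for noncovalent interactions:

* **cnt** — at least one heavy-atom pair within 4.5 Å (configurable);
  the weight is the number of qualifying atom pairs. Sequence-adjacent
  residues on the same chain are excluded: covalent neighbours are not
  noncovalent interactions.
* **hbond** — donor–acceptor N/O heavy atoms within 3.5 Å; when explicit
  hydrogens are present the donor–H–acceptor angle must also reach 120°.
  The synthetic structures carry no hydrogens, so the distance-only
  criterion with an N/O whitelist applies — a deliberate simplification
  over dot-surface contact algorithms, adequate because every downstream
  statistic consumes only the typed weighted graph.
* **ovl** — any heavy-atom pair closer than the sum of van der Waals radii
  minus 0.4 Å. The radii are fixed in code (C 1.70, N 1.55, O 1.52,
  S 1.80 Å, others 1.70) so results are platform-independent.
* **combi** — added for a pair carrying at least two distinct types, with
  weight equal to the sum of the member weights.

Edges also carry `mc`/`sc`/`ligand` subtype labels (mainchain =
N, CA, C, O, OXT). The labels ride along for reporting and never alter
weights or statistics.

For shortest-path analytics the multi-edges between a residue pair are
first collapsed to their average weight (negative weights dropped), and
weights become distance scores by the max-value rule
`d = (w_max + 1) − w̄`, so the strongest interaction has distance exactly 1
and every distance is ≥ 1. We read the conventional "weighted-degree cutoff
of 1 Å" as this minimum distance score; a reciprocal scheme
(`d = w_max/w̄`) is available behind a flag for sensitivity checks. All
edge types present (including `combi`) join the collapse, mirroring how
average-weight handling treats parallel edges in multi-edge network files.

## Centrality, cliques, communities, clusters

Betweenness follows the shortest-path counting definition
`C_B(i) = Σ_{j<k} P_jk(i)/P_jk` on the distance-weighted collapsed graph,
unnormalized (raw pair counts). The implementation is a Brandes-style
single-source accumulation with a 10⁻¹⁰ relative tolerance for
shortest-path ties (distance scores are averages, hence fractional); the
test suite validates it against an independent Floyd–Warshall
path-counting oracle on 200 seeded random graphs and against
`igraph::betweenness()`. Histograms of betweenness first normalize by
`(n−1)(n−2)/2` — the maximum attainable value — so bin widths like 0.01
are meaningful across networks of different size; both scales are exposed
because frequency distributions are conventionally plotted on the
normalized one. Closeness is `(n−1)/Σ d(i,j)` over reachable nodes (0 for
isolated nodes); hubs are nodes with collapsed degree ≥ 4 by default.

`enumerate_k_cliques()` returns **all** complete k-node subgraphs, not
only maximal ones (delegated to `igraph::cliques()`, validated against
exhaustive subset search). Clique-percolation communities at size k join
k-cliques that share k−1 nodes and take connected components of that
overlap graph. The "total clique count" of a differential report sums all
k-cliques over k ≥ 3; since the counting convention behind published
clique totals is generally ambiguous, a maximal-clique variant is
selectable and neither is asserted against any published total.

`mcode_clusters()` implements the three MCODE stages with the classical
parameterization (node score cutoff 0.2, haircut on, no fluff): node
scores are core number × density of the highest k-core of the closed
neighbourhood; seeds are visited in decreasing score order with ties
broken by node id; expansion admits neighbours scoring at least
`(1 − cutoff) ×` seed score; the haircut removes members attached by a
single edge in one pass. Two consequences worth knowing: only
positive-score nodes seed and clusters need ≥ 3 nodes, so an edgeless
graph yields no clusters; and two dense modules joined by a single bridge
edge merge into one cluster whenever all their nodes share the same score,
because the bridge endpoints pass the expansion threshold — this is the
faithful behaviour of the stated stages, not an artifact.

## MM-GB/SA bookkeeping

`mmgbsa_combine()` applies the component identities of end-state
binding-energy analysis:

* polar: `ΔG_polar = ΔE_ele + ΔG_GB`
* nonpolar: `ΔG_nonpolar = ΔE_vdW + ΔG_SA`
* gas + solvation: `ΔG_MM-GB/SA` = sum of the four terms
* binding: `ΔG_bind = ΔG_MM-GB/SA + (−TΔS)`

The entropic term is consumed as a number in its −TΔS sign convention
(normal-mode analysis is out of scope), so the binding energy is a plain
sum, and the nonpolar solvation map `G_SA = 0.0072 × ΔSASA` is provided as
the linear rule only. All arithmetic is full precision;
`format_energies()` rounds to 2 decimals at presentation. On the
wild-type worked example the full-precision component sum is −22.45,
while the conventional table prints −22.44 — a 0.01 rounding
inconsistency we document rather than reproduce. Per-frame tables are
averaged with `aggregate_frames()`, which reports the sample SD per term
(the ± column of such tables could equally be an SEM; we label ours
explicitly as SD). `decomposition_check()` verifies that per-residue
contributions sum to the total within a stated tolerance.

## Steered dynamics and the staged Jarzynski PMF

The synthetic pulling engine is **overdamped** (Brownian) Langevin
dynamics rather than full inertial Langevin: it is the simplest dynamics
that exhibits realistic work fluctuations, which is all the estimator
needs. A particle on a toy potential `U` is dragged by a harmonic guide of
stiffness `k_spring` (default 40 kcal mol⁻¹ Å⁻²) moving at `v` (default
10 Å/ns):

```
x ← x + (dt/γ)[−U′(x) + k(λ−x)] + sqrt(2 k_B T dt/γ) ξ,   λ(t) = λ₀ + v t
```

with `γ` the effective (mass-scaled) friction in kcal ps mol⁻¹ Å⁻²
(default 1) and `k_B = 0.0019872041` kcal mol⁻¹ K⁻¹, so energies are
kcal/mol throughout and coordinates Å. The accumulated external work is
the guide convention `dW = k(λ−x)·v dt` (it can be negative), `W(0) = 0`.
The explicit update is stable for `dt·(k_spring + U″)/γ ≲ 1`; the default
`dt = 0.01` ps with `k = 40`, `γ = 1` sits at 0.4 and the engine warns
beyond 1.5. The default temperature is 333 K, matching the simulation
conditions the traces emulate; the pulling temperature is configurable
since it is not otherwise pinned down.

`jarzynski_free_energy()` evaluates
`ΔF = −(1/β) ln ⟨exp(−βW)⟩` in shifted log-sum-exp form (subtract the
minimum work before exponentiating), which is exact and overflow-safe. By
Jensen's inequality `ΔF ≤ mean(W)`, with equality for identical works —
both are asserted across every simulated swarm in the tests.

`run_asmd()` reproduces the staged protocol: the reaction coordinate
(default 4 → 30 Å) is divided into equal stages (default 14), each stage
runs a swarm (default 24) of steered trajectories, and the trajectory
whose **final** work is closest to the stage's Jarzynski average is
selected; its end state seeds every trajectory of the next stage, the
1-D analogue of contracting a swarm onto the single JA structure. Full
work profiles could be compared instead of final works; final work is the
simpler reading and is what we use. The per-stage JA curves are chained
with offsets (`assemble_pmf()`), so the PMF is continuous across stage
boundaries and anchored at 0 at the start; selection indices are 1-based
(R convention) with ties to the lowest index. Per-trajectory sub-seeds
are drawn once from the master seed via `sample.int()` — a single
documented derivation that gives decorrelated streams and bit-identical
reruns; a counter-based hash would work equally well and was simply not
needed in R. A bootstrap over trajectories within each stage
(`pmf_endpoint_se()`) provides the endpoint's standard error.

Two calibration points define what the machinery is expected to recover,
and both are recomputed by `scripts/acceptance.R`:

* a harmonic potential `U = ½·0.2·(x−4)²` pulled cold (1 K) with the stiff
  default spring must recover `U(30) − U(4) = 67.6` kcal/mol within 2% —
  the residual error is the friction dissipation `γ v L ≈ 0.26` kcal/mol
  (≈ 0.4%) plus discretization; the minimum sits at the pull start so the
  target is large against that dissipation;
* a flat potential at 333 K must give an endpoint within 3 bootstrap SEs
  of 0 — here the equality removes, to leading order, exactly the mean
  dissipated work via the fluctuation term.

The PMF magnitudes reported for the real solvated enzyme
(roughly 13 and 22 kcal/mol for wild type and mutant) are **not**
reproducible with a 1-D toy particle and are nowhere asserted; only
protocol properties are.

## Trajectory observables

* `hbond_occupancy()` — per donor–acceptor pair, the percentage of frames
  satisfying the hydrogen-bond criterion; rows below a 5% reporting floor
  (the conventional visible floor of such tables; configurable) are
  dropped. Occupancies are frame-order invariant.
* `hbond_count_vs_rc()` — mean ligand–protein hydrogen-bond count in bins
  of the per-frame reaction coordinate.
* `dihedral_series()` — IUPAC-signed torsions in (−180°, 180°]. The
  torsion is invariant under complete atom-order reversal (a property we
  verified against an independent implementation) and negates under
  mirror reflection; colinear triples raise an error naming the frame.
  Which four atoms define a ring-flip dihedral is the caller's choice —
  the package does not auto-detect aromatic rings.
* `centroid_distance()` — unweighted centroid separation of two atom sets
  (e.g. two aromatic rings flanking a dissociation tunnel).
* `pca_fel()` — frames are Kabsch-superposed onto the first frame,
  flattened and decomposed by PCA **without mass weighting** (the toy
  pseudo-atoms carry no masses; note this differs from mass-weighted
  trajectory-analysis conventions). The PC1/PC2 occupancy histogram maps
  to a free-energy landscape `−k_B T ln(P/P_max)`: the most occupied bin
  is 0 and empty bins are `Inf`, never 0.

## The synthetic generator: what it emulates, what it does not

`make_toy_protein()` lays residues on a jittered boustrophedon grid
(4 Å spacing) — a compact space-filling fold whose contact graph has
cliques, communities and hubs like a folded domain — with five
pseudo-atoms per residue (N, CA, C, O, CB) and a three-atom ligand placed
in a pocket near the fold's centre. The construction is purely geometric:
only contact topology matters downstream. The pocket contract (ligand
centroid within 4 Å of the nearest atoms of `pocket_size` residues) is
verified after placement and the generator errors rather than silently
violate it; geometrically the contract cannot hold for large
`pocket_size`. `perturb_trajectory()` adds i.i.d. Gaussian coordinate
noise per frame — persistent contacts stay inside their cutoffs,
marginal ones flicker, which is all the occupancy machinery needs.

What the toys do **not** model: real backbone connectivity and sterics,
solvent, explicit hydrogens, correlated collective motions, or any
energetics of the contact network. Passing tests therefore demonstrate
the correctness of the graph, estimator and bookkeeping machinery on
inputs with known ground truth — not the biological conclusions one
would draw from real trajectories, which require the real system.

## Problem sizes and determinism

The test suite and acceptance script use toy proteins of 8–24 residues,
random graphs of ≤ 15 nodes for oracle equivalence (200 betweenness
graphs, 100 clique-percolation graphs × k = 3, 4, 5), trajectories of
10–2000 frames, and the full 14 × 24 staged protocol on 1-D toys — sizes
chosen so every oracle is exhaustively checkable and the whole pipeline
reruns in minutes on one CPU. Every stochastic step takes an explicit
integer seed; generators are pure functions of (parameters, seed), the
pipeline report is byte-identical under a fixed config, and its
provenance block carries an FNV-1a hash of the resolved configuration.
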