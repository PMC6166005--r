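# mutnet

Comparative residue-network and free-energy analytics for enzyme variants.

When a couple of point mutations make an enzyme measurably better — as
site-directed mutagenesis does for D-psicose 3-epimerase acting on
D-fructose — the structural story behind the improvement is spread across
several layers: how the residue interaction network around the substrate
rewires, how the end-state binding free energy shifts, how much work it
takes to pull the substrate out of its tunnel, and how individual contacts
and ring geometries behave along the way. `mutnet` packages that whole
analysis chain for R, exercised entirely on synthetic structures,
trajectories and work traces so every stage is testable with known ground
truth.

## What it computes

**Residue interaction networks (RINs).** `build_rin()` turns a structure
into a graph: nodes are residues plus the bound ligand; edges are typed
noncovalent interactions — interatomic contacts (`cnt`), hydrogen bonds
(`hbond`), van der Waals overlaps (`ovl`) and combined edges (`combi`) —
weighted by interaction counts. Weights convert to distance scores by the
max-value rule d = (w_max + 1) − w̄ so that stronger interactions are
shorter.

**Graph statistics.** Weighted betweenness by shortest-path counting,

&nbsp;&nbsp;&nbsp;&nbsp;C_B(i) = Σ_{j<k} P_jk(i) / P_jk,

with P_jk the number of shortest paths between j and k; closeness; hubs
(degree ≥ 4); enumeration of all k-cliques; clique-percolation communities
(k-cliques chained by shared (k−1)-node overlaps); MCODE-style clusters;
and a differential wild-type-vs-mutant report (`compare_networks()`).

**MM-GB/SA bookkeeping.** `mmgbsa_combine()` applies the end-state
identities ΔG_polar = ΔE_ele + ΔG_GB, ΔG_nonpolar = ΔE_vdW + ΔG_SA,
ΔG_MM-GB/SA = sum of the four, ΔG_bind = ΔG_MM-GB/SA + (−TΔS), with
G_SA = 0.0072 × ΔSASA as the nonpolar rule and per-residue decomposition
checks.

**Staged Jarzynski PMFs.** `run_asmd()` reproduces the adaptive
steered-dynamics protocol on toy potentials: the pulling coordinate
(default 4 → 30 Å) splits into stages (default 14); each stage runs a
swarm of steered overdamped-Langevin trajectories (default 24; spring
k = 40 kcal mol⁻¹ Å⁻², v = 10 Å/ns); the Jarzynski average
ΔF = −(1/β) ln⟨e^(−βW)⟩ summarizes each swarm and the trajectory closest
to it seeds the next stage; per-stage averages chain into a continuous
PMF anchored at zero.

**Trajectory observables.** Hydrogen-bond occupancy tables with a
reporting threshold, hydrogen-bond counts along the reaction coordinate,
IUPAC-signed dihedral series, ring-centroid distances, Kabsch
superposition, and PCA free-energy landscapes
(−k_B T ln(P/P_max) over PC1/PC2 bins).

**Synthetic data.** `make_toy_protein()`, `perturb_trajectory()`,
`steered_langevin()` and `make_energy_table()` generate every input class
above, deterministically under explicit seeds.

## Worked example

```r
library(mutnet)

# end-state energetics for a wild-type / mutant pair of component means
wt  <- energy_components(E_vdW = -16.67, E_ele = -59.39, G_GB = 57.42,
                         G_SA = -3.81, minus_T_dS = 19.95)
mut <- energy_components(E_vdW = -15.61, E_ele = -72.82, G_GB = 59.62,
                         G_SA = -3.88, minus_T_dS = 19.46)
format_energies(mmgbsa_combine(dplyr::bind_rows(wt, mut)))
#> # A tibble: 2 × 9
#>   E_vdW E_ele  G_GB  G_SA minus_T_dS G_polar G_nonpolar G_mmgbsa G_bind
#>   <dbl> <dbl> <dbl> <dbl>      <dbl>   <dbl>      <dbl>    <dbl>  <dbl>
#> 1 -16.7 -59.4  57.4 -3.81       20.0   -1.97      -20.5    -22.4   -2.5
#> 2 -15.6 -72.8  59.6 -3.88       19.5  -13.2       -19.5    -32.7  -13.2
```

The mutant's binding free energy (−13.23 kcal/mol at 2 decimals) is about
11 kcal/mol more favourable than the wild type's, driven by the polar
term (−13.20 vs −1.97).

```r
# differential network analysis of two toy variants
s_wt  <- make_toy_protein(n_res = 24, pocket_size = 4, seed = 1)
s_mut <- make_toy_protein(n_res = 24, pocket_size = 4, seed = 2)
diff <- compare_networks(build_rin(s_wt), build_rin(s_mut))
diff
#> <mutnet_diff>
#>   clique totals: a=316  b=329
#>   communities: 6 rows; delta betweenness over 25 shared nodes
head(dplyr::arrange(tidy(diff), dplyr::desc(abs(delta))), 3)
#> # A tibble: 3 × 4
#>   node  betweenness_a betweenness_b delta
#>   <chr>         <dbl>         <dbl> <dbl>
#> 1 A:14             92          53.5 -38.5
#> 2 L:1              44          20   -24
#> 3 A:13             42          23.5 -18.5

# staged steered-dynamics PMF on a harmonic toy potential, pulled cold
pot <- toy_potential("harmonic", c = 0.2, x0 = 4)
res <- run_asmd(pot, params = langevin_params(temperature = 1, friction = 1,
                                              dt = 0.01, seed = 11))
glance(res)
#> # A tibble: 1 × 6
#>   endpoint_pmf n_stages n_traj span_start span_end temperature
#>          <dbl>    <dbl>  <dbl>      <dbl>    <dbl>       <dbl>
#> 1         67.4       14     24          4       30           1
autoplot(res)
```

The recovered endpoint (67.4 kcal/mol) sits within 0.4% of the exact
U(30) − U(4) = 67.6 kcal/mol; the small deficit is the friction
dissipation of the finite-speed pull.

`run_pipeline()` chains all stages (networks → energetics → PMF →
trajectory observables) from a single YAML config; `make_demo_inputs()`
writes a complete synthetic input set plus config to get started.

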