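# paircoex

System-level effects of third-party species on pairwise coexistence in
generalized Lotka–Volterra (gLV) communities.

## The problem

Whether two species can coexist is usually studied in isolation, yet in
nature a pair is almost always embedded in a larger community whose
remaining ("third-party") species reshape the conditions the pair
experiences. Because most abiotic and biotic forcing is unknown, the useful
quantity is not a single outcome but a probability: over all environments —
modelled as effective growth-rate vectors `theta` distributed uniformly on
the unit sphere — what fraction allows the pair to persist, and how do
third-party species change that fraction?

`paircoex` answers this for gLV dynamics
`dN_i/dt = N_i (theta_i − Σ_j a_ij N_j)` with a known per-capita interaction
matrix `A`. It is aimed at community ecologists and microbiome researchers
who have (or can infer) pairwise interaction estimates and want to know what
a surrounding community does to each constituent pair.

## The indicators

For a pair `Z = {i, j}` in a pool `S`:

| indicator | definition | meaning |
|---|---|---|
| `F(Z)` | planar angle of the 2×2 sub-matrix / 2π | coexistence probability of the pair in isolation |
| `PC(Z,S)` | `Proj(Z,S) / F(Z)` | expansion of the pair environments where coexistence is *possible* (`Proj` is the shadow of the pool's feasibility cone on the pair plane); always ≥ 1 |
| `LE(Z,S)` | `P(Z,S) / F(Z)` with `P(Z,S) = Σ_{Z ⊆ C ⊆ S} F(C,S)` | long-term (equilibrium) change in coexistence *probability*; `F(C,S)` are the spherical masses of the non-invadable composition regions that partition the `theta`-sphere |
| `SE(Z,S)` | `Sim(Z,S) / Sim(Z)` | the same ratio from finite-time simulations (RK4, T = 200, step 0.01, extinction below 1e−6) |
| `BE(Z,S)` | `SE / LE` | transient buffering: > 1 when the short run favours the pair more than the long run |
| `EE`, `EBE` | replicate-frequency analogues | computed from monoculture / co-culture / poly-culture final-density tables |

Composition masses come from closed-form planar/solid angles for pools of
up to three species and from an orthant-probability Monte Carlo otherwise.
A replicated-experiment generator and a steady-state interaction-matrix
inference (`a_ij = (1 − n̄_i(j)) / n̄_j(i)` on monoculture-normalized
densities) close the loop from raw density tables to the same indicators.

## Worked example

```r
library(paircoex)

A <- canonical_fixtures()$three_species   # diagonally dominant 3-species pool
A
#> Interaction matrix (3 species: sp1, sp2, sp3)
#>      sp1  sp2  sp3
#> sp1 1.00 0.22 0.56
#> sp2 0.22 1.00 0.37
#> sp3 0.56 0.37 1.00

eff <- system_effects(A, n_draws = 2000, seed = 1)
dplyr::select(eff, pair, F_iso, PC, LE, SE, BE)
#> # A tibble: 3 × 6
#>   pair     F_iso    PC    LE    SE    BE
#> 1 sp1+sp2 0.181   1     0.838 0.823 0.982
#> 2 sp1+sp3 0.0875  1.000 0.859 0.813 0.946
#> 3 sp2+sp3 0.137   1.00  0.828 0.778 0.940

cartography_counts(classify_cartography(eff))
#> # A tibble: 1 × 2
#>   quadrant                                          n
#> 1 long-term detrimental / short-term unbuffered     3
```

Reading: every pair's *possible* coexistence range is maximal (`PC = 1`
with `Proj = 1`: some environment of the third species makes any pair
environment workable), yet the coexistence *probability* of each pair drops
by ~15% inside this competitive pool (`LE ≈ 0.84`), the simulated
short-term effects track that closely (`SE ≈ 0.78–0.82`), and buffering is
near-neutral (`BE ≈ 0.94–0.98`). The cartographic classification places all
three pairs in the long-term-detrimental quadrant.

The same pipeline runs from a config file (matrix CSV or seeded recipe,
optional experiment table) via `run_effects_pipeline()`, or from a shell
through `inst/cli/paircoex-effects.R`.

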