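# confdyn

Post-simulation analysis of protein molecular-dynamics trajectories, built
around the question of how a chemical perturbation — the motivating case is
phosphorylation of serine 44 in DNA polymerase β — shifts an enzyme between
conformational states. Long MD trajectories of a wild-type and a modified
system are reduced to a small set of comparable quantities: metric
distributions and their modes, hydrogen-bond and salt-bridge occupancies,
collective motions, free-energy basins, and residue-network centralities.

The package is aimed at structural bioinformaticians who already have
trajectories (from GROMACS or similar) and want a scriptable, testable R
analysis layer rather than one-off tool invocations.

## What it computes

Given frames $r(t) \in \mathbb{R}^{N\times3}$ of Cα coordinates:

* **Structural metrics** — fitted RMSD to a reference, radius of gyration
  $R_g^2 = \sum_k w_k\,|r_k-\bar r|^2 / \sum_k w_k$, per-residue RMSF, and
  normalised distributions with prominence-based mode detection.
* **Interactions** — geometric hydrogen bonds (donor–acceptor distance
  $d \le 3.5$ Å and H–donor–acceptor angle $\le 30^\circ$) with per-pair
  occupancies; salt bridges as minimum side-chain N–O distances (formed at
  $\le 4$ Å), with moving averages and distance-trace Pearson correlations.
* **Essential dynamics** — the Cartesian covariance
  $\mathrm{Cov}_{ij} = \langle (r_i - \langle r_i\rangle)(r_j - \langle
  r_j\rangle)\rangle$ over the $3N$ coordinates of superposed frames, its
  eigenmodes, projections, cumulative variance fractions, half-cosine
  cosine-content screening of principal components, and porcupine vectors.
* **Free-energy landscapes** — $G = -\ln(P/P_{\max})$ in kT over any CV
  pair ((RMSD, $R_g$) or (PC1, PC2)), basin extraction by steepest-descent
  flood fill, and representative-frame selection.
* **Correlation networks** — the dynamic cross-correlation matrix
  $C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
  (\langle\Delta r_i^2\rangle^{1/2}\langle\Delta r_j^2\rangle^{1/2})$,
  an edge-weighted residue graph with $\omega_{ij} = -\ln|C_{ij}|$
  (edges kept where $|C_{ij}| \ge 0.3$), and degree / closeness /
  betweenness centralities
  $C_B(i) = \tfrac{2}{N(N-1)}\sum_{a<b} \tau_i^{ab}/N_{ab}$
  with exact shortest-path tie counting, plus between-condition
  $|\Delta C_B|$ difference maps.

Seeded synthetic-trajectory generators (planted block covariance, two-state
hopping with bimodal RMSD, exact-geometry interaction fixtures) provide
controlled inputs for every layer, and `run_condition()` /
`compare_conditions()` orchestrate the standard two-condition comparison.

## Worked example

A two-state trajectory with planted RMSD centers at 3.7 Å and 7.14 Å,
analysed end to end:

```r
library(confdyn)

ts   <- generate_two_state(n_residues = 60, n_frames = 2000,
                           transition_prob = 0.02, seed = 7)
rmsd <- rmsd_series(ts$traj, reference = ts$reference,
                    selection = "name CA", fit = FALSE)
rmsd
#> RMSD series: 2000 frames, mean 5.624 A, sd 1.705 A (selection 'name CA')

metric_distribution(rmsd, n_bins = 60)
#> Distribution over 60 bins; 2 peak(s) at 3.71, 7.16

rg  <- rg_series(ts$traj, "name CA", mass_weighted = FALSE)
fel <- build_fel(rmsd, rg, n_bins = 24, xlab = "RMSD (A)", ylab = "Rg (A)")
for (b in find_basins(fel, max_G = 2))
  cat(sprintf("basin %d: RMSD %.2f A, Rg %.2f A, G = %.2f kT, %d frames\n",
              b$label, b$center[1], b$center[2], b$min_G, b$n_frames))
#> basin 1: RMSD 7.18 A, Rg 26.55 A, G = 0.00 kT, 994 frames
#> basin 2: RMSD 3.69 A, Rg 26.21 A, G = 0.28 kT, 772 frames
```

The two distribution peaks and the two basin centers recover the planted
3.7 / 7.14 Å states to within a bin width; the basin G values reflect the
sampled occupancies (994 vs 772 frames here, so the basins are nearly
degenerate at 0.28 kT apart). Collective motion and network layers:

```r
ed <- essential_dynamics(ts$traj)
ed
#> Essential dynamics: 60 atoms, 2000 frames, 180 modes
#>   top eigenvalues (A^2): 23.597, 0.102, 0.102, 0.101, 0.101
#>   PC1 variance fraction: 0.685; PC1+PC2: 0.688

net  <- build_network(compute_dccm(ts$traj), cmin = 0.3)
prof <- centrality_profile(net)
head(prof[order(-prof$betweenness), ], 3)
#>    residue_id degree closeness betweenness
#> 30         30     49  1.886004  0.04632768
#> 32         32     49  1.876765  0.04067797
#> 28         28     46  1.816792  0.01412429
```

PC1 alone carries ~69% of the variance — the planted inter-state hop —
and the most central residues sit mid-chain, where the network bridges the
static and mobile halves. On real wild-type vs phosphorylated trajectories
the same quantities come from `run_condition()` on each system followed by
`compare_conditions()`, which tabulates `|ΔC_B| ≥ 0.12` residues and
high-betweenness (`≥ 0.15`) sets.

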