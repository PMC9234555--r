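---
title: "Detecting conformational transitions in protein trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conformational transitions in protein trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdyn)
```

## The problem

Multi-domain enzymes such as DNA polymerase β interconvert between compact
("closed") and relaxed ("open") conformations, and chemical perturbations —
phosphorylation of a single serine, the presence or absence of catalytic
Mg²⁺ — can tip that balance. Molecular-dynamics trajectories record the
motion but not the answer; the analysis problem is to reduce hundreds of
thousands of frames per condition into a small set of comparable,
statistically meaningful quantities. confdyn implements that reduction as a
layered toolkit: each layer is a plain function returning a classed object,
so the whole pipeline is scriptable and each stage is testable in
isolation.

This vignette explains the models and conventions behind each layer, the
defaults and why they were chosen, what the synthetic generators emulate
(and what they do not), and the numerical corner cases.

## Trajectory model and superposition

A trajectory is an `n_frames × 3N` coordinate matrix in Ångström plus a
per-atom topology table. Residue numbers always follow the source file —
biological residue identities like S44 or E335 are file numbers, and domain
definitions (lyase 10–87, D 90–150, C 151–260, N 261–335 by default in
`domain_map()`) interpret those numbers, so nothing is ever renumbered.
GRO files are converted from nm on read; PDB and DCD parsing is delegated
to bio3d. XTC/TRR have no reader in this stack and must be pre-converted —
the error message says how.

Superposition is the Kabsch algorithm with an SVD core and an explicit
determinant correction, so the returned rotation is always proper; weights
default to uniform because the analyses below run on Cα atoms, where mass
weighting is a no-op up to scale (it remains available as an argument).
Degenerate references (fewer than 3 atoms, collinear geometry) are rejected
rather than silently fitted, because the rotation is not identifiable
there.

References for fluctuation-type quantities (RMSF, covariance, DCCM) use an
iteratively refined mean structure: fit to the first frame, average, re-fit
to the average (two rounds). Two rounds are enough for the mean to be
self-consistent to well below coordinate precision on converged sampling,
and the same fit is shared by the covariance and DCCM paths so that
rigid-body residuals cannot masquerade as internal correlation.

## Metrics and mode detection

RMSD, radius of gyration and per-residue RMSF follow their textbook
definitions; Rg is mass-weighted by default (matching the common tooling
convention) with an unweighted option for Cα-only work. Distributions are
normalised histograms (`sum(p) * bin_width = 1`) over 100 bins by default;
bin count is configurable because the appropriate resolution depends on
series length.

Peaks are local maxima filtered by *topographic prominence* — the height
above the higher of the two saddles separating a peak from taller terrain —
with a default floor of 5% of the tallest bin. Prominence, rather than raw
height, is what makes the one-peak/two-peak dichotomy between conditions
robust: sampling noise produces many local maxima but almost no prominent
ones. The floor interacts with sample size — per-bin noise must sit below
it — which is why the defaults suit series of a few thousand frames or
more; a constant series degenerates to a single-bin distribution with one
peak by construction.

## Hydrogen bonds and salt bridges

Hydrogen bonds are geometric: donor–acceptor distance ≤ 3.5 Å **and**
hydrogen–donor–acceptor angle ≤ 30°. The angle is measured at the donor,
the convention used by the GROMACS hbond tool; occupancy of a residue pair
is the fraction of frames with at least one qualifying bond in either
direction, using all annotated donors and acceptors of both residues.
Donors and acceptors come from atom-name tables (backbone N except proline,
side-chain N/O classes, all oxygens as acceptors), not from bond topology,
so topology files without CONECT records work; hydrogens attach to their
donor geometrically (≤ 1.25 Å). Phosphoserine naming dialects
(O1P/O2P/O3P, OP1/OP2/OP3, and the bridging OG on SEP/SP1/SP2 residues) are
all recognised as anionic acceptors, since monoanionic and dianionic
phosphate patches differ in charge but not in which atoms can accept.

Salt bridges track the per-frame *minimum* over all basic side-chain
nitrogen (NZ/NE/NH1/NH2) to anionic oxygen pairs. A formation cutoff of
4.0 Å N–O is the default — a conventional choice, configurable, since mean
distances are reported regardless and occupancy is the only quantity that
depends on it. The basic/acidic roles of the two residue arguments are
resolved from the atom inventory, which makes the distance series symmetric
in argument order; a residue lacking the required atom class fails loudly
with its atom inventory in the message.

Moving averages use a centred window shrunk at the edges (length
preserved), with the 500-frame default window that suits distance traces
sampled every couple of ps. Trace correlation is plain Pearson, refusing
constant inputs rather than returning NaN.

## Essential dynamics

The covariance matrix is the ensemble average with denominator `n` (not
`n − 1`): the object of interest is the second moment of an ensemble, not
an unbiased estimator of a population parameter, and at trajectory sample
sizes the distinction is far below other error sources anyway. It is
unit-weighted on the selected Cα atoms. Eigenmodes are sorted by
descending eigenvalue with ties keeping their original order.

Projections of the fitted, mean-centred frames onto eigenvector *k* have
mean ≈ 0 and mean-square exactly λₖ on the trajectory the model was built
from — an identity the test suite checks to 1e−8 relative, along with
Σλ = trace(Cov) and orthonormal reconstruction of the covariance.

**Cosine content.** Leading PCs of under-sampled trajectories look like
random diffusion, whose leading principal component approaches a
half-period cosine. The screening statistic is

c = 2 (∫₀¹ p(t) cos(πt) dt)² / ∫₀¹ p(t)² dt

with t rescaled to [0, 1], evaluated with trapezoidal quadrature — with
plain Riemann sums a pure half-cosine scores 1 + 1/n rather than 1, which
matters at the 1e−3 level the tests require. One subtlety worth recording:
sin(2πt) is *not* orthogonal to the half-cosine on [0, 1]
(∫ sin 2πt cos πt dt = 4/3π, giving c ≈ 0.72); the mode that genuinely
scores zero is sin(πt). PCs pass the screen when c ≤ 0.1, and
`select_pcs()` returns the lowest-index passing components (the
conventional PC1/PC2 for landscape work), erroring with a
"sampling not converged" message when too few pass.

Porcupine vectors reshape an eigenvector into one 3-vector per residue;
because eigenvectors are unit-norm, the vectors are scaled so their squared
magnitudes sum to `scale²`, and individual magnitudes are capped (default
15 Å) purely for display sanity on dominant modes.

## Free-energy landscapes

Surfaces are −ln(P/P_max) in kT over a 2-D histogram (32 × 32 default,
300 K label): the most populated bin defines G = 0, empty bins are masked
in computation and shown at max-G + 1 kT in plots. Any CV pair works; the
two standard choices are (RMSD, Rg) and (PC1, PC2).

Basins are found by locating local minima below a ceiling (`max_G`,
default 3 kT), assigning every sub-ceiling bin to a minimum by
steepest-descent flood fill (8-connectivity), and merging minima within a
small grid distance (default 2 bins) via union–find — the merge step is
what keeps plateaus and shot-noise double minima from splitting one
physical basin in two. On a flat surface everything merges into a single
basin, which is the honest answer. Representative frames are chosen
nearest the basin-minimum bin center in *z-scored* CV space, because RMSD
and Rg have very different dynamic ranges; ties resolve to the earliest
frame for determinism.

Since G differences are log population ratios, a planted 3:1 two-cluster
occupancy must recover ΔG = ln 3 ≈ 1.10 kT — the calibration the
acceptance checks perform at 50,000 samples, where histogram noise at the
basin minima keeps the error within ±0.1 kT.

## Cross-correlation and residue networks

The DCCM normalises the per-residue displacement covariance by the
marginal fluctuations, so C ∈ [−1, 1] with unit diagonal; it is computed
both directly from fitted frames and from the 3×3 diagonal blocks of the
covariance model, and the two routes agree to 1e−8 (a useful internal
consistency check, since they share no code path after fitting). Residues
with zero fluctuation have undefined correlations; their off-diagonal
entries are set to 0 with a warning.

Network edges carry ω = −ln|C|. The log base only rescales every weight,
leaving shortest-path structure untouched, but the natural log is fixed
here and stated because centrality *values* (and any threshold on them) do
depend on it. A completely dense graph makes degree uninformative, so
edges are kept only where |C| ≥ `cmin` (default 0.3), optionally ANDed
with a Cα-contact filter (10 Å on a reference frame) for users who want
networks restricted to physically proximal pairs; both knobs are
configurable and reported in the network object. Zero-correlation pairs
are always excluded (infinite weight).

Degree uses the binarised adjacency; closeness and betweenness run on
weighted shortest paths (Dijkstra). Betweenness counts *all* tied shortest
paths exactly, Brandes-style, with path-length ties compared at 1e−12
tolerance — on correlation-derived weights exact ties are rare but
symmetric constructions produce them, and splitting path counts across
ties is what the 2/(N(N−1)) normalisation assumes. On disconnected graphs
closeness sums over reachable nodes with the Wasserman–Faust scaling and
isolated nodes score 0; disconnected pairs contribute nothing to
betweenness. Between-condition comparison reports per-residue ΔC_B with a
default selection threshold of 0.12 and an absolute high-centrality
threshold of 0.15 — the conventional cutoffs for flagging residues that
gain or lose communication load after a perturbation.

## Synthetic data: what it emulates, and what it does not

The generators plant known statistical structure so every analysis layer
has a ground truth:

* `generate_gaussian_trajectory()` — multivariate-normal Cα displacements
  about a helical mean with block-structured residue correlation (default
  ρ = 0.8 within two equal "domains", 0 between, σ = 1 Å per site). The
  planted correlation matrix *is* the expected DCCM.
* `generate_two_state()` — a symmetric hidden Markov chain hopping between
  two structures whose unfitted RMSDs to a common reference are 3.7 and
  7.14 Å (the bimodal signature of a closed-to-open transition), with
  0.25 Å isotropic noise and a 0.02/frame switch probability.
* `hbond_fixture()` / `saltbridge_fixture()` — six-atom systems realising
  requested distances and angles exactly (to 1e−6), with standard PDB atom
  names so the donor/acceptor tables engage, including phospho dialects.
* `drifting_mode_series()` — a half-cosine drift plus noise for the
  cosine-content screen.

Every generator is a pure function of its arguments and seed, and restores
the caller's RNG state. What passing tests on these inputs demonstrate is
that the estimators recover *planted* structure at known sample sizes;
what they cannot demonstrate is robustness to the features of real MD data
the generators omit — anharmonicity, fat-tailed and time-correlated noise,
solvent-mediated interactions, periodic-boundary artifacts, and force-field
systematics. Results on real trajectories inherit those caveats.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a desk machine: 10,000
frames × 20 residues for correlation recovery (10 seeds), 20,000 frames
for dominant-mode recovery, 50,000 samples for landscape calibration, 50
seeded runs for basin-count statistics — a few minutes end to end. The key
numerical decisions, collected:

| Choice | Value | Reason |
|---|---|---|
| Covariance denominator | n | ensemble second moment, not an estimator |
| Fit reference | 2-pass iterative mean | self-consistent, shared across layers |
| Histogram peaks | prominence ≥ 5% of max | robust one-vs-two-peak calls |
| H-bond angle | at donor, ≤ 30° | tool convention for the printed criteria |
| Edge weight log | natural | fixed and stated; rescales ω only |
| Tie tolerance | 1e−12 on path length | exact multiplicity on float weights |
| Landscape reference | G = 0 at modal bin | standard for −kT ln P maps |
| Representative frame | z-scored CV distance, earliest tie | scale-free, deterministic |

## Limitations

Trajectory reading covers PDB, GRO and DCD only; frames are assumed whole
(no PBC unwrapping) and the donor/acceptor tables, while covering the
standard residues and phosphoserine dialects, are name-based and will miss
exotic chemistry. Centralities are O(N²–N³) in residues per the dense
Dijkstra/Brandes implementation — comfortably fast to a few hundred
residues, not engineered for whole ribosomes. The landscape basin finder
works on the binned surface; basins narrower than a bin cannot be
resolved, and `max_G` is a physical choice the user owns.
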