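---
title: "Evolutionary-couplings-guided adaptive sampling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary-couplings-guided adaptive sampling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecsampler)
```

## The problem

Rare conformational transitions — receptor activation, folding, protein–protein
association — occur on timescales far beyond what unbiased molecular dynamics
can routinely reach. Adaptive sampling attacks this by running many *short*
unbiased simulations in rounds: after each round the accumulated frames are
clustered into microstates, and a selection rule picks the clusters from which
the next round of simulations is seeded. The seeding rule introduces a
*sampling* bias, not a Hamiltonian one, so estimating a Markov state model
(MSM) over all trajectories recovers unbiased thermodynamics and kinetics.

The selection rule this package is organized around uses evolutionary
couplings: residue pairs inferred, from the statistics of a protein family
alignment, to be in direct physical contact in at least one functional state.
For a conformation with coupled-pair distances $d_1,\dots,d_m$ and a reference
structure with distances $d_1^\mathrm{ref},\dots,d_m^\mathrm{ref}$,

$$\mathrm{SEC} = \sum_{k=1}^m d_k, \qquad
  \Delta \mathrm{SEC} = \sum_{k=1}^m d_k - \sum_{k=1}^m d_k^\mathrm{ref}.$$

Conformations with large positive $\Delta\mathrm{SEC}$ are, by this one
measure, the most different from the reference in the evolutionarily coupled
degrees of freedom; conformations with small SEC (association problems) are
the most native-like. Seeding from the extreme-$\Delta\mathrm{SEC}$ clusters
drives sampling toward alternative functional states without requiring any
knowledge of which contacts form in which state. Microstates are scored by the
mean $\Delta\mathrm{SEC}$ of `n_samples = 50` randomly chosen member frames
(`state_score()`); clusters smaller than 50 use all members, making the score
the exact cluster mean.

## Markov state models

An MSM is a discrete-state, discrete-time kinetic model: a row-stochastic
transition matrix $T(\tau)$ at lag time $\tau$, under which a state
distribution evolves as $p(t_0 + k\tau) = p(t_0)\,T(\tau)^k$
(`propagate()`). The estimation pipeline is conventional:

* **Counting** (`count_and_trim()`): sliding-window transition counts at the
  lag — every frame is a window start. The count graph is trimmed to its
  largest strongly connected component before estimation; without this the
  maximum-likelihood problem is ill-posed. Both choices are the field's
  standard defaults.
* **Reversible maximum likelihood** (`estimate_reversible()`): the transition
  matrix maximizing the likelihood under detailed balance
  $\pi_i T_{ij} = \pi_j T_{ji}$, computed by the standard fixed-point
  iteration on the unnormalized symmetric flux
  $x_{ij} \leftarrow (c_{ij}+c_{ji}) / (c_i/x_i + c_j/x_j)$, iterated until
  the stationary distribution moves by less than $10^{-10}$ between sweeps
  (capped at $10^6$ sweeps; non-convergence is an error, never a silent
  result).
* **Timescales**: implied timescales $t_i = -\tau / \ln \lambda_i$ from the
  eigenvalues of the reversible estimate (computed through the symmetric
  conjugate $\mathrm{diag}(\sqrt\pi)\,T\,\mathrm{diag}(1/\sqrt\pi)$, so they
  are real by construction). Eigenvalues $\le 0$ yield `NA` — the relaxation
  is undefined at that lag, not zero.
* **tICA** (`tica_project()`): slow collective coordinates from the
  generalized eigenproblem $C_\tau v = \lambda C_0 v$ with the time-lagged
  covariance symmetrized and the instantaneous covariance regularized by
  adding $10^{-10}\,\mathrm{tr}(C_0)/d$ to its diagonal — enough to make
  whitening stable without perturbing any non-degenerate direction.
* **k-means** (`cluster_kmeans()`): k-means++ seeding under an explicit seed,
  Lloyd refinement, and a final deterministic nearest-center assignment with
  ties broken toward the lowest center index, so microstate definitions are
  exactly reproducible.

## Kinetic Monte Carlo

`kmc_step()` implements the textbook inversion rule: draw $u \in [0,1)$, form
the running sums $S_n = \sum_{j \le n} p_{ij}$ over the current row, and jump
to the state whose interval $[S_{n}, S_{n+1})$ contains $u$. The half-open
convention means $u = 0$ selects the first state with positive probability.
`kmc_ensemble()` derives one RNG substream per trajectory from
(seed, trajectory index), so ensembles are reproducible and independent of
launch order. First-passage times are counted in frames of $\tau$: a
trajectory absorbed one step after the start has hit time $1\tau$. The
continuous-time (waiting-time) variant of KMC is deliberately out of scope —
the sampled chain is discrete-time by construction.

## Transition path theory

`committors()` solves the forward boundary-value problem
$\sum_j T_{ij} q^+_j = q^+_i$ on intermediates with $q^+|_A = 0$,
$q^+|_B = 1$, and the backward committor on the time-reversed chain
$\tilde T_{ij} = \pi_j T_{ji} / \pi_i$. Gross reactive flux is
$f_{ij} = \pi_i q^-_i T_{ij} q^+_j$ and net flux
$F_{ij} = \max(0, f_{ij} - f_{ji})$. Pathways are extracted from the *net*
flux matrix by an iterative widest-path decomposition: a Dijkstra-style
search maximizing the minimum edge capacity finds the strongest A→B channel,
its bottleneck flux is subtracted along the path, and the search repeats
until `k` paths are found or the residual flux drops below $10^{-12}$.
Equal-bottleneck ties are broken by fewer hops, then by lexicographic state
order — the algorithm itself does not prescribe a tie rule, and an explicit
one keeps output deterministic.

## The Brownian benchmark

`simulate_brownian()` integrates an overdamped 2-D particle by
Euler–Maruyama,

$$x_{t+1} = x_t - \frac{D\,\Delta t}{k_\mathrm{B}T}\,\nabla U(x_t)
  + \sqrt{2 D \Delta t}\,\xi_t,$$

on a sum of Gaussian wells plus an optional harmonic confinement, with an
analytic gradient. Defaults are $D = 1$, $\Delta t = 0.01$,
$k_\mathrm{B}T = 1$ (dimensionless units); a guard aborts with an
instability error if the particle leaves a box 1000 times the domain scale,
the symptom of a timestep too large for the steepest well.

The shipped benchmark surface (`default_potential()`) is a *corridor* of six
metastable Gaussian wells along the diagonal from (10, 10) to the origin
(width 0.6; 12 kT at the endpoints, 11 kT at the intermediates), decorated
with a jittered lattice of ~1–1.5 kT shallow wells and confined by
$\kappa = 0.1$ toward (5, 5). The design is deliberate. Escape from one well
is a Kramers problem with rate roughly $(D\,\Delta U / w^2)e^{-\Delta U/kT}$:
with ~9–11 kT effective barriers one inter-well hop takes on the order of
500–2500 time units. A full serial traversal therefore needs roughly
$10^4$ time units even if every hop goes the right way — far more than one
3,000-time-unit trajectory (300,000 steps) — while a single hop fits
comfortably inside one adaptive round (10 trajectories × 100 time units).
The intermediates are the essential ingredient: a smooth landscape with one
deep well cannot be ratcheted, because a walker reseeded on the well wall
relaxes back to the bottom before escaping. Metastable stepping stones make
progress *persistent*, which is precisely the regime in which adaptive
sampling pays off. The benchmark protocols mirror the classic comparison:
10 serial trajectories × 300,000 steps versus 10 × 10,000 steps × 30 rounds
with 100 clusters and reseeding from the 10 clusters of lowest mean distance
to the target.

## Synthetic known-answer systems

`generate_msm()` builds a nearest-neighbour Metropolis chain over the quartic
double-well profile $E(x) = 16 B x^2 (1-x)^2$ (barrier $B$ in kT at the
midpoint). Metropolis acceptance gives detailed balance by construction, so
the stationary law is *exactly* the Boltzmann weight of the profile — every
stationary-distribution and committor test has a closed-form answer. The
default study conditions are a 50-state chain with $B = 6$ and a sampling
budget of 10 trajectories × 50 steps × 30 rounds with 25 clusters: the
barrier makes a direct crossing within one budget rare (the mean
first-passage time grows like $n^2 e^{B}$), while per-round excursions of a
few states let guided reseeding climb it reliably. The cluster count must
exceed the number of parallel trajectories — if every cluster receives a
seed, the seeding strategies cannot differ — mirroring the large
microstate-to-seed ratios of realistic protocols.

`generate_guided_landscape()` adds a per-state guidance score: the scaled
distance to the target plus Gaussian noise (sd 0.1 of the score range),
re-drawn deterministically until its Spearman correlation with the forward
committor is ≤ −0.8 — informative but imperfect guidance, which is the
regime the method claims to exploit.

`generate_toy_complex()` emits a two-chain toy complex (CA/CB pseudo-atoms),
an inter-chain coupling table whose pairs are in contact in the native pose,
and rigid-displacement decoys, asserted on output to have strictly larger
SEC than the native pose. Fixtures are written in the same CSV/PDB formats
the real pipeline consumes, so integration tests exercise the readers.

What the fixtures do *not* emulate: real force-field energetics, membrane or
solvent environments, metastable-state geometry of any particular protein,
or the statistics of real coupling tables. Passing tests demonstrate the
correctness of the algorithms under known-answer conditions, not the
biological performance of the guidance score on any specific system.

## Structure handling conventions

* Coupled-pair distances default to Cα–Cα, the standard convention in
  contact-prediction work; `closest_heavy` is available since the choice of
  atoms is ultimately a modelling decision.
* Coupling-table residue index $k$ maps to the $k$-th resolved residue of
  the chain (file order), plus an optional explicit offset — coupling tables
  index the alignment/model sequence, not author numbering.
* PDB reading keeps the first MODEL and, where alternate locations exist,
  the highest-occupancy altloc (ties: first in file).
* `superpose_rmsd()` uses Kabsch superposition via SVD with the determinant
  correction; rank-deficient selections (collinear atoms) are handled by the
  SVD directly. `backbone_rmsd()` matches residues across two crystal forms
  by identical (chain, residue number, insertion code), keeps residues with
  complete N/CA/C/O backbones in both, and superposes those atoms — chains
  or engineered insertions present in only one form drop out automatically.
* Dihedral featurization encodes φ, ψ and χ1 as (sin, cos) pairs; residues
  without a χ1 (Gly, Ala) simply contribute no χ1 feature. The
  center-of-mass basis scheme expresses the partner chain's COM displacement
  in an orthonormal frame built by Gram–Schmidt from three anchor
  α-carbons, so the feature co-rotates with the complex; the three anchors
  are a required user parameter.

## Accounting and protocol conventions

* First-passage semantics: the target test runs at every generated frame,
  and a run stops at the first hit. Total simulation time is
  (fully completed trajectories × S) + the frames of the hitting trajectory
  up to the hit. The alternative convention — charging the full final round
  — would only shift all protocols by at most one round of budget.
* Grid cells in `fpt_grid()` report medians over replicates, with runs that
  exhaust their budget entering as the sentinel `Inf`; medians remain
  meaningful while any majority of replicates succeeds.
* Clustering for seed selection operates on the cumulative frame pool by
  default (per-round-only pooling is an option), and an optional frame
  filter can exclude frames from clustering — e.g. association frames with
  inter-monomer center-of-mass distance above 50 Å — without affecting the
  time accounting.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run entirely on synthetic
systems at desk scale, sizes chosen so each experiment has unambiguous
statistics: first-passage validation on ≤ 10-state chains with $10^4$
trajectories; MSM recovery from $10^6$ KMC steps of a 5-state chain;
strategy comparisons on the 50-state funnel with 20 paired replicates; the
Brownian benchmark with 20 seeds per protocol at the full protocol constants
(3 × 10⁶ integration steps per seed). These reproduce the *qualitative*
claims — guided ≤ random ≤ serial, and guided crossing where serial stalls —
not the absolute times of any particular molecular system, which depend on
simulation datasets that are not distributable.

## Known limitations

* The reversible estimator provides point estimates only; no Bayesian error
  bars, hidden Markov models, or PCCA-style lumping.
* Committors and fluxes assume the estimated $T$ is irreducible on its
  active set; disconnected questions are errors, not zeros.
* The Euler–Maruyama integrator is first-order; very stiff surfaces need a
  smaller $\Delta t$ (the divergence guard turns instability into an
  explicit error).
* The sampler-adapter contract covers in-memory model systems; coupling the
  engine to a real MD code is an integration exercise left to the caller.
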