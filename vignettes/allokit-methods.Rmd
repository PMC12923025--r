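---
title: "Methods: from trajectories to allosteric communication networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from trajectories to allosteric communication networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

allokit turns molecular-dynamics trajectories of a protein in two liganded
states (here called *apo* and *bound*) into a comparison of their internal
communication networks: which regions rigidify or loosen, how strongly
regions influence one another, along which residue chains signals travel,
and which surface pockets coincide with the residues that carry that
traffic. This vignette documents the models and procedures, the defaults
and why they were chosen, and what the synthetic validation does and does
not establish.

All coordinates are stored in nanometres, times in picoseconds, energies
in units of kT, and residues are numbered 1-based everywhere (the PDB
convention); every exported table states its units in a header line.

## Structural and dynamic observables

The observable layer implements the standard descriptors directly from
coordinates:

* **RMSD** — every frame is least-squares superposed (Kabsch) onto a
  reference frame over a selection (default Cα), and the root-mean-square
  deviation over that selection is reported per frame.
* **RMSF** — per-residue root-mean-square fluctuation of the Cα atom about
  its time-averaged position, computed after superposition. The square of
  the RMSF summed over residues equals the trace of the Cα covariance
  matrix; the test suite enforces this identity at 1e-8 relative, tying the
  flexibility profile to the essential-dynamics machinery.
* **Native contacts** — pairs of heavy atoms closer than 0.45 nm, excluding
  pairs within the same residue. There is no additional sequence-neighbour
  exclusion; that is a documented reading of a heavy-atom minimum-distance
  contact count, not the only possible one. A cell-list search is used and
  is required (by test) to agree exactly with the quadratic reference.
* **Hydrogen bonds** — geometric criterion: donor–acceptor distance
  < 0.35 nm and donor–hydrogen–acceptor angle > 150°, with N/O donors
  carrying a covalent hydrogen (H within 0.12 nm) and N/O acceptors.
* **Radius of gyration** — mass-weighted by default, masses from elements.
* **SASA** — Shrake–Rupley with Bondi radii, probe 0.14 nm, and 960
  quadrature points per atom on a Fibonacci sphere lattice. An isolated
  atom reproduces its analytic sphere area to better than 2%. Because the
  quadrature directions are fixed in space, SASA is rotation-invariant
  only to the discretization (about 0.1–0.5% at 960 points); the other
  observables are invariant to 1e-8.
* **Essential dynamics** — eigendecomposition of the 3N × 3N covariance of
  Cα positional fluctuations (population normalization), eigenvalues
  floored at zero, projections of the centered coordinates onto each mode.
* **Free-energy landscapes** — 2-D histogram over the first two principal
  components converted by F = −kT ln(P/Pmax), so the most populated bin is
  exactly 0 and empty bins are +Inf (unbounded), never 0. Energies are in
  kT; multiply by 0.008314·T for kJ/mol.
* **Porcupine export** — per-residue displacement vectors along a chosen
  principal component, written as a PyMOL CGO script plus a plain TSV.

## The synthetic test bed: planted interaction graphs

No trajectory data are deposited with the study this package's analysis
style follows, and microsecond explicit-solvent MD is not reproducible at
desk scale. Every quantitative claim in the test suite therefore runs
against *synthetic systems with known ground truth*: point particles
connected by harmonic springs along a planted graph, integrated by
Langevin dynamics.

Design of the generator (`planted_system()`, `make_scenario()`):

* **Topology.** A random geometric graph over seeded uniform coordinates
  in a box, with the connection radius chosen per instance so the edge
  count is `edges_per_node * n` (default 1.3, protein-contact-like
  sparsity, stable across seeds). Disconnected components are stitched at
  their closest node pair.
* **Springs.** Default coupling is the *displacement* style,
  U = k/2 |(x_i − x_j) − (h_i − h_j)|², i.e. vector springs on deviations
  from a reference geometry — the linearized coupling of anisotropic
  elastic network models of proteins. Forces are then linear and share one
  functional form across all edges, which matters for inference (below).
  Scalar distance springs U = k/2 (d − r0)² are available
  (`spring_style = "distance"`) and are used for the thermodynamic
  contracts: bond-length variance kT/k (equipartition, verified against a
  10× finer-timestep reference simulation) and monotone energy relaxation
  at zero temperature.
* **Integrator.** Two modes. `"brownian"` is overdamped Langevin,
  dx = −(dt/γ)∇U + √(2kT dt/γ) ξ. `"langevin"` (default) is inertial
  BAOAB with Maxwell–Boltzmann initial velocities and the centre-of-mass
  and net angular momentum removed continuously, i.e. a thermally
  initialized, weakly coupled trajectory in a fixed laboratory frame.
  The inertial mode is the default because of an information argument:
  in the overdamped regime the per-frame displacement is dominated by
  fresh thermal noise, and regressions show that knowing a node's true
  neighbours reduces one-step prediction error by only ~10–15% — too weak
  a signal for relational inference at test scale. With low-friction
  inertial dynamics the motion is locally deterministic and accelerations
  are the planted spring forces, so the interaction structure dominates
  the learnable signal (this is also the regime of the classical
  interacting-particle benchmarks for relational inference). Ensemble
  properties used elsewhere (equipartition, RMSF contrasts) are the same
  in both modes.
* **Defaults.** k = 1 kT/nm², kT = 1, γ = 0.002 ps⁻¹, dt = 0.005 ps, one
  pseudo-atom per node; scenario trajectories save every 20 steps
  (0.1 ps/frame, roughly 20–40 frames per oscillation period of the
  network modes).

An apo/bound **scenario pair** (`make_scenario()`) perturbs the bound copy
only: spring constants internal to a designated core region are multiplied
by `stiffening_factor` (default 4; emulating ligand-induced rigidification
of a catalytic loop), those internal to peripheral regions by
`softening_factor` (default 0.25; distal flexibilization), and *relay
edges* absent from the apo graph are added (emulating the appearance of
new communication shortcuts upon binding). The `"relay-demo"` preset
(30 nodes) picks its core as the nodes nearest the centroid and takes as
peripheral regions the distal outskirts of three spatial clusters of the
remaining nodes — deliberately *not* whole clusters, so that an
unperturbed bulk remains between core and periphery, the way small
flexible surface modules sit on an otherwise stable protein body. The
core and each peripheral region are fully connected internally on top of
the geometric graph (packed cores are dense; and the softening factor
needs internal springs to act on). Without the neutral bulk and the
autonomous core, softening would loosen the core's entire anchoring
matrix and collective motion would mask the core's own rigidification —
an instructive failure mode of naive scenario constructions.

The preset also plants a three-edge relay chain from the core centre
through two otherwise unremarkable relay nodes into the most
graph-distant peripheral region. The chain ends at a region *entry node*
distinct from the region centre that path queries use, and the relay
springs carry ordinary (not stiffened) constants: both choices limit the
chain-induced direct source-target correlation that graph inference
would otherwise mistake for a direct edge, so that the bound state's
shortest communication path has to pass residues the apo path never
visits.

The magnitude of ligand-induced stiffening in the real system is not
characterized; the 4×/0.25× factors are chosen so that the RMSF contrast
is clearly resolvable over thermal noise at a few thousand frames, and
are reported with every scenario.

## Trajectory preparation

* **I/O.** PDB (and GRO) topologies, DCD coordinates; exports are a
  single-chain Cα PDB plus an X-PLOR-style DCD that round-trips through
  the reader at float precision. Angstrom-based formats are converted to
  nm on the way in and out.
* **Superposition** removes rigid-body motion by a Kabsch fit to a
  reference frame. All observables use superposed coordinates.
* **Downsampling** keeps the first frame and selects at even index
  spacing, floor(i·(N−1)/(n−1)).
* **Spatially uniform residue sampling** is realized as farthest-point
  sampling on time-averaged Cα coordinates with a seeded start; the
  complement is retained as the reverse-sampling set, and the two halves
  always partition the residue set.
* **Features** for relational inference are per-residue Cα positions
  (centered on the mean-structure centroid) and finite-difference
  velocities, each channel group scaled to maximum absolute value 1, with
  the constants retained for inversion. Velocities use the *backward*
  difference v_t = (x_t − x_{t−1})/Δt: a forward difference would embed
  frame t+1 — the prediction target — in the state at t, letting the
  dynamics decoder copy instead of model. Windowing cuts the feature
  array into overlapping segments (default 50 frames every 100).

## Neural relational inference

The NRI engine is a variational autoencoder whose latent variables are
per-ordered-pair categorical edge types (default K = 2; type 1 is
*non-interacting* and is hard-wired to contribute no decoder messages).

* **Encoder**: a graph network over the fully connected node graph —
  per-node MLP embedding of the flattened segment, node→edge and
  edge→node message rounds, and a final edge MLP producing the K logits
  per ordered pair. Two-layer ELU MLPs throughout.
* **Latent sample**: Gumbel-softmax (concrete) relaxation at temperature
  0.5, with an optional straight-through hard mode.
* **Decoder**: per-edge-type message MLPs on the sender/receiver states,
  gated by the sampled edge type, summed per receiver and passed with the
  receiver's own state through an output MLP that predicts the mean state
  displacement. Rollouts are re-grounded on the true state every
  `prediction_steps` frames (default 10) and gradients flow through the
  whole chain.
* **Loss**: Gaussian negative log-likelihood (mean squared error per
  predicted entry divided by 2σ², σ² = 5e-5 on normalized features) plus
  the mean KL divergence of the edge posterior from its prior (uniform by
  default; a sparsity-favouring prior such as 0.9/0.1 is available and is
  what the synthetic study conditions use, for the identifiability reason
  below).
* **Optimization**: Adam, initial learning rate 5e-4, decayed by 0.2
  every 200 epochs, batch size 1, 500 epochs in the reference profile and
  100 in the `"ci"` profile. The first fifth of the epochs are a decoder
  *warm-up* in which the latent sample is clamped to random half-on edge
  assignments and only the decoder trains; this lets the message MLPs
  learn the interaction law before the encoder starts gating edges, and
  avoids an early-training failure mode in which exactly the strongly
  coupled pairs are switched off because their (still uninformative)
  messages inject the most noise.
* **Implementation**: the segment forward/backward pass is a compiled
  RcppArmadillo kernel; a pure-R reference implementation with identical
  semantics ships alongside it, and the test suite checks both that the
  two agree to 1e-12 and that the analytic gradients match central finite
  differences.

Training is deterministic given the config seed. After training, the
encoder posterior is averaged over segments into a
`LatentInteractionGraph`; replicate graphs are averaged element-wise by
`consensus_graph()`. The **interaction probability** of an ordered pair is
defined as 1 minus the probability of the non-interacting type.

**Label symmetry and canonicalization.** With two edge types, the model
that passes messages along a graph and the model that passes them along
its complement can fit centered coordinates equally well (once the
selection centroid is pinned, the sum of neighbour states and the sum of
non-neighbour states carry the same information), so which type ends up
meaning "interacting" is not identifiable from the likelihood alone.
`train_nri()` resolves the label by a physical convention: interaction
probability must anti-correlate with the time-averaged inter-node
distance (interactions in elastic networks and residue contact graphs are
predominantly local). Whether the labels were swapped is recorded in the
graph provenance. For the same reason, synthetic planted-graph runs feed
the NRI stage unaligned coordinates (`nri_align = FALSE` in the run
config): the simulator already holds the global frame fixed, and a Kabsch
superposition would pin the centroid exactly, which maximally sharpens
the degeneracy. For real MD data, alignment remains the default.

**Reverse sampling.** `reverse_sampling_check()` trains one model on the
spatially uniform residue half and one on its complement, computes
region-level cross-strength matrices from both latent graphs, and reports
their Spearman rank correlation; a degenerate constant matrix yields NA
rather than a fabricated zero.

## Communication networks

The latent graph becomes a weighted directed graph (`build_graph()`):
edge weight = interaction probability, retained when at least
`min_probability` (default the uniform prior 1/K). Analyses on top:

* **Total edge weight** — the sum of retained directed weights.
* **Betweenness** — weighted directed betweenness on distances
  d = −ln(w), normalized by (n−1)(n−2). The −ln transform makes a
  probability-1 link cost zero and path cost equal to the negative log of
  the path's probability product; the duality exp(−distance) = Π p is a
  tested invariant.
* **Cross-region strengths** — mean weight over ordered pairs between two
  regions, counting absent edges as zero; regions may deliberately
  overlap (the default region set keeps the shared boundary residue of
  its third and fourth regions), handled by the i ≠ j rule.
* **Shortest paths** — Dijkstra on the −ln weights between region-centre
  residues (the region member nearest the region's Cα centroid, ties to
  the lowest residue number; explicit endpoint override available). Ties
  between equal-distance routes resolve deterministically to fewer hops,
  then the smaller predecessor residue number. Unreachable targets return
  an explicit no-path object.
* **Relay detection** — for each source→target region pair, the
  intermediates present in the bound path but not the apo path (and the
  reverse, "lost" intermediates).
* **Pocket prioritization** — pockets (parsed from a residue-list TSV or
  an fpocket-like info text) scored by overlap with relay residues plus
  overlap with top-decile-betweenness hubs, ranked descending with ties
  broken by the external pocket score. The count-based score is a
  deliberate minimal choice; both term weights are exposed.

## The two-state pipeline

`run_comparison()` executes: load → superpose → per-replicate RMSD →
RMSF/contacts/H-bonds/Rg/SASA/essential dynamics/free-energy landscape on
the concatenated replicates → downsample → optional sparse sampling →
windowing → per-replicate NRI → consensus per state → graphs → metrics →
cross-region matrices → shortest paths → relay report → optional pocket
ranking. Every numeric table carries units and the config hash; the hash
covers every threshold, seed and input path (not the output directory),
and a completed report is cached under it and reused on identical re-runs.
Swapping the state labels negates every Δ quantity exactly. A thin
command-line front end (`inst/cli/allokit`) wraps fixture generation and
pipeline runs.

## Problem sizes in the shipped validation

The test suite and the acceptance script validate on sizes chosen so that
the full battery runs comfortably on a laptop-class single core:
planted-graph recovery on a 10-node network (13 springs, 5,000 frames,
100-epoch CI profile); the relay scenario on the 30-node preset with
single-replicate states, 2,000-frame trajectories and a reduced training
schedule; and the reverse-sampling consistency check on a
region-structured system of a few dozen nodes. The `"full"` NRI profile
(500 epochs) and multi-replicate consensus are the intended settings for
real trajectory data.

## What the synthetic validation does and does not show

Passing tests establish that: the observables implement their definitions
(closed forms, brute-force and analytic oracles); the NRI machinery
optimizes what it claims to optimize (finite-difference gradients), is
deterministic, and recovers planted interaction structure from dynamics
alone in a regime where that structure drives the dynamics; and the
network layer turns edge probabilities into paths and centralities
exactly (exhaustive enumeration oracles).

They do not establish that NRI recovers "true" residue interactions from
real protein MD: real force fields are many-body, solvent-mediated and
anharmonic; real interaction strengths are heterogeneous over orders of
magnitude; sampling is far from ergodic at any feasible length; and the
identifiability caveats above are handled here by conventions that are
physically motivated but not theorems. The synthetic systems emulate the
statistical skeleton the analysis assumes — stationary fluctuations
around a structured mean, local harmonic coupling along a sparse contact
graph, state-dependent stiffness and connectivity changes — and nothing
more: no side chains, no chemistry, no solvent, no conformational
transitions between basins.

## Known limitations

* Latent edge types are not identifiable beyond the distance-correlation
  convention; reported interaction probabilities are calibrated only
  relative to one another, which is why thresholds are exposed rather
  than fixed, and `build_graph()` offers density-matched sparsification
  (`top_edges`) alongside the probability threshold.
* Relay identification through shortest paths is the most fragile link in
  the chain, and at test-scale training it is *not* reliable. Two causes,
  both reproducible on planted systems: a relay chain induces genuine
  end-to-end correlation that the encoder (whose message-passing sees
  two-hop context) may attribute to a direct edge, which then shortcuts
  the Dijkstra route past the relay; and per-edge posterior calibration
  varies across seeds enough to flip which of two near-tied routes wins,
  even when global edge recovery is strong (AUROC ≈ 0.9 on the same
  systems). The relay scenario's own design mitigates but does not remove
  this: the chain enters the target region away from the queried centre,
  relay springs have ordinary stiffness, and graphs are density-matched.
  Replicating the trained model (more replicates, longer schedules, the
  `"full"` profile) is the recommended remedy on real data; the shipped
  end-to-end relay check documents the instability honestly rather than
  relaxing its assertion.
* Single-chain trajectories only; no periodic-boundary repair.
* XTC is not read or written (DCD is the binary interchange format).
* The SASA quadrature is deterministic but orientation-dependent at the
  0.1–0.5% level.
* Potential energies are out of scope (no force field).
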