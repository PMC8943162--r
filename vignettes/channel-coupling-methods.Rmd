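---
title: "Methods: Gaussian coupling analysis, pocket states and pore profiles"
author: "channelmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian coupling analysis, pocket states and pore profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelmi)
```

## Scope and model

`channelmi` implements the trajectory-analysis layer used to study how a
cytosolic ligand-binding pocket communicates with the transmembrane pore of
a homotetrameric ion channel. Three analyses share one data model (a
`topology` of annotated atoms plus a `frameset` of T × N × 3 coordinates in
Å with frame times in ns):

* **Gaussian (quasi-harmonic) mutual information.** The trajectory
  covariance of a coordinate set uses plain trajectory averages,
  C(X_ij, X_kl) = ⟨X_ij X_kl⟩ − ⟨X_ij⟩⟨X_kl⟩, with denominator T
  (population form; a T−1 option exists). The configurational entropy of a
  set with covariance C is H = ½ ln |2πe C|, evaluated through the
  eigenvalue spectrum, never a raw determinant, so near-singular directions
  are controlled explicitly. The mutual information of two disjoint atom
  sets is H(A) + H(B) − H(A,B), all three entropies estimated from the same
  frames. For Gaussian data this equals ½ ln(|C_A||C_B|/|C_AB|) and is
  non-negative for any positive semi-definite joint covariance (Fischer's
  inequality); tiny negative values that the eigenvalue floor can introduce
  are clipped to zero by default, and the unclipped estimate is available
  by option because the literature is not unanimous about clipping.

* **Pocket state statistics.** Pocket "width" is the Cα–Cα distance between
  the lower-lid residue 610 and upper-lid residue 667 (author numbering).
  A frame is *closed* iff width < 11 Å — strictly: a frame at exactly
  11.0 Å is open. Occupancy pools closed time over all replicate units
  (one unit = one monomer of one run) with midpoint-interval time weights,
  so irregular frame spacing is handled; the reported dispersion is the
  standard deviation of per-unit fractions (a per-run alternative is a
  flag, since a "±" on a pooled percentage is ambiguous without a stated
  unit of replication).

* **Pore profiling.** A simplified probe-sphere profiler: at each slice z
  along the channel axis the radius is max over (x, y) of
  min_i(‖p_i − c‖ − r_vdW,i). This is the HOLE/CHAP family of measures with
  a straight axis rather than a curved pathway spline; absolute radii
  therefore compare only qualitatively with curved-pathway tools, and no
  hydration/wetting analysis is attempted.

## Assumptions

The MI layer assumes stationary, approximately Gaussian heavy-atom
fluctuations around a converged mean structure in a common reference frame.
Superposition (Kabsch, proper-rotation branch enforced) provides that
frame; per-monomer analyses fit on the monomer's own TRP-like-domain Cα
atoms, because pooling monomers by entrywise maximum presumes each monomer
is internally aligned. The Gaussian MI is exact for linear couplings only:
purely non-linear dependence is invisible to it, which is a known
limitation of covariance-based estimators, not a defect of the
implementation.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `eigenvalue_floor` | 1e-8 | Å² | H diverges at zero eigenvalues; duplicated atoms or T < d make C_AB singular. The floor is reported (`floor_applied`) whenever it engages, since floored MI values are floor-dependent. |
| covariance denominator | T | — | plain trajectory averages; switchable to T−1. At trajectory sizes of interest the difference is negligible, but the convention is stated so results are reproducible to the digit. |
| pocket cutoff | 11 | Å | separates the 15.5 Å pocket-open and 9.4 Å pocket-closed reference widths; strict `<` documented at the boundary. |
| smoothing window | 2 | ns | centered moving average used for *plotting only*; occupancies always use raw widths, because smoothing before thresholding systematically shortens residence in the rarer state. |
| `z_step` / `max_probe` | 0.5 / 10 | Å | slice spacing and the cap that marks a slice as effectively bulk (outside the channel). |
| vdW radii | Bondi-type table | Å | unknown elements fall back to carbon (1.70 Å); any other table can be supplied. |

## Superposition reference

The reference frame for alignment defaults to the first frame of the
trajectory; an external structure can be supplied. The exact residue span
used as "TRP-like domain" for fitting is configurable rather than
hard-coded, because fitting spans differ between channel structures;
segment definitions are plain (name, chain, first, last) tuples supplied by
the user.

## The synthetic generators and what they do (and do not) show

Every stage's correctness is established against seeded generators with
closed-form truth, not against archived MD output:

* `gen_gaussian_trajectory` — exact multivariate-Gaussian sampling (spectral
  square root, PSD-singular covariances allowed) around a reference; sample
  covariance, entropy and MI converge to prescribed values.
* `gen_coupled_pair` — two pseudo-residues with matched-coordinate
  correlation ρ: population MI = −(d/2) ln(1−ρ²) exactly.
* `gen_markov_pocket` — exact two-state continuous-time Markov chain
  sampled at dt, widths = state mean (defaults 15.5/9.4 Å) + Gaussian
  noise; stationary closed fraction k_oc/(k_oc+k_co).
* `gen_toy_pore` — stacked atom rings; the ring-slice truth
  (ring radius − vdW radius) is only exact when no ring constrains a
  neighbour's slice, so the generator *rejects* ring layouts violating
  r_j² + Δz² ≥ r_i², keeping the returned truth exact rather than
  approximate.
* `gen_rigid_motion` — random proper rotations (quaternion method) plus
  translations; internal geometry is exactly preserved.
* `gen_trpa1_like` — a desk-scale tetramer: 4 chains × 4 segments with the
  analysed residue spans (lid 663–676, S1 706–730, S4 842–865, TRP-like/S6
  961–1005), three backbone heavy atoms per residue, independent isotropic
  fluctuations (sd 0.5 Å) plus one planted latent-coupled residue pair per
  chain (671–988 by default). Within a chain, residues wind through a
  compact ~20 Å ball: this is deliberate, because a fit selection that is
  spatially small relative to the atoms it anchors amplifies per-frame
  superposition jitter into spurious long-range correlations — a real
  artifact of covariance analyses that the fixture would otherwise
  exhibit strongly.

What passing these tests does *not* show: agreement with force-field MD.
The generators have no anharmonicity, no slow conformational exchange
(except the explicit two-state pocket model), no solvent or membrane, and
no non-linear couplings. They validate the estimators and plumbing, not
the physics.

## Numerical choices

* Entropies via `eigen(symmetric = TRUE)`; indefinite matrices (negative
  eigenvalue beyond 1e-8 relative tolerance) are an error, not silently
  floored.
* `pairwise_mi` canonicalizes block order (lowest atom index first) so
  MI(A,B) and MI(B,A) run through bitwise-identical arithmetic — symmetry
  is exact, not approximate.
* The residue-pair matrix estimates one pooled covariance over all segment
  atoms and reads each pair's blocks from it, so every pair shares frames,
  mean-centering and floor.
* Kabsch degeneracy: a collinear (or coincident) fit set has no unique
  rotation and is rejected with an error naming the frame.
* The slice optimizer is Nelder–Mead seeded from the previous slice's
  centre (first slice: selection centroid) with a restart from the
  centroid; on toy systems it matches an exhaustive 0.05 Å grid search
  within 0.05 Å. Blocked slices report 0; clearances above `max_probe` are
  capped and flagged.
* Ties in the edge-list ranking break by residue number of A then B, so
  outputs are byte-stable across reruns.
* Aggregation across monomers matches residue pairs by (segment, residue
  number), not chain, so the four monomers of a homotetramer pool onto one
  index; provenance records which (run, monomer) supplied each maximum.

## Problem sizes

The shipped tests and the acceptance script use 50,000-frame
coupled-pair trajectories for estimator-vs-closed-form checks (sampling
error ≪ 0.02 nats), 250–400-frame tetramer fixtures for end-to-end pathway
runs (finite-sample MI bias ~d_A d_B/2T ≈ 0.1 nats, an order of magnitude
below the planted signal), twelve 1 µs-equivalent Markov units at
dt = 0.1 ns for occupancy recovery, and ≤ 200-atom toy pores. These sizes
were chosen so each check's analytic error budget is comfortably resolved.

## Known limitations

* Gaussian MI misses purely non-linear coupling and can inflate when the
  joint covariance is ill-conditioned; `floor_applied` flags the latter.
* The straight-axis profiler under-reports radii of strongly curved pores.
* PDB round-trips quantize coordinates to 3 decimals and drop frame times;
  the packed binary container (float32 coordinates, float64 times) is the
  lossless-enough alternative for large synthetic runs.
* Occupancy dispersion across 12 units is a spread, not a standard error;
  with strongly autocorrelated state series the effective number of
  independent samples is far below the frame count.
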