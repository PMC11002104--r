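---
title: "The modified hydrophobicity-field model: theory, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The modified hydrophobicity-field model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodm)
```

## The model

Water folds globular proteins toward a micelle-like state: hydrophobic
residues buried centrally, polar residues exposed. `fodm` quantifies how far
an actual structure departs from that state, and summarizes the departure as
the strength of a *modified external field* that would explain it.

Each residue is reduced to one **effective atom** at the centroid of its
heavy atoms, carrying an intrinsic hydrophobicity $H^r_i \in [0,1]$ from a
configurable scale. Four per-residue distributions (each normalized to unit
sum) are compared:

* **T** — the idealized water-field (micelle) distribution: an axis-aligned
  3D Gaussian evaluated at the effective-atom positions,
  $T_i \propto \exp(-x_i^2/2\sigma_x^2)\exp(-y_i^2/2\sigma_y^2)\exp(-z_i^2/2\sigma_z^2)$.
* **O** — the observed distribution, accumulated from pairwise hydrophobic
  contacts: $O_j \propto \sum_{i \ne j,\, r_{ij} \le c}(H^r_i + H^r_j)\,
  w(r_{ij}/c)$ with Levitt's quartic-in-$x^2$ contact polynomial
  $w(x) = 1 - \tfrac12(7x^2 - 9x^4 + 5x^6 - x^8)$, which equals 1 at contact
  and vanishes smoothly at the cutoff $c$.
* **R** — the structureless uniform reference, $R_i = 1/N$.
* **M** — the modified-field distribution
  $M_i = \big(T_i + K\,\widetilde{C}_i\big)_n$ where
  $\widetilde{C} = (T_{\max} - T)_n$ is the normalized complement of the
  Gaussian and the subscript $n$ denotes renormalization to unit sum
  (complement first, then the mixture — the "double normalization"
  convention, stated explicitly because mixture notation of this kind is
  ambiguous).

Two statistics summarize a unit, both built on the Kullback–Leibler
divergence in bits, $D(P\|Q)=\sum_i P_i \log_2 (P_i/Q_i)$ with the
$0\log 0 = 0$ convention:

$$RD = \frac{D(O\|T)}{D(O\|T) + D(O\|R)}, \qquad
  K = \arg\min_{k \ge 0} D\big(O \,\|\, M(T, k)\big).$$

$RD < 0.5$ means O is closer to the micelle field than to the uniform one —
a hydrophobic core is present. $K$ grades the environment: $K \approx 0$
water-like, $K \gtrsim 1$ membrane-like exposure of hydrophobicity, large
$K$ an essentially uniform (water-decoupled) field. $K$ is minimized over
$D(O\|M)$ — the mixture is fitted to the *observed* distribution; fitting
$M$ to $T$ would trivially return 0.

## Parameters and conventions

The published analyses this package reproduces do not state every numeric
convention, so each is an explicit, recorded parameter of `fod_params()`:

| parameter | default | meaning |
|---|---|---|
| scale | Kyte–Doolittle, affine to [0, 1] | intrinsic hydrophobicity $H^r$ |
| cutoff $c$ | 9 Å | pairwise interaction range in O |
| sigma rule | extent/3 (floor 1 Å) | $\sigma_a = \max_i \lvert a_i \rvert / 3$ per principal axis |
| self term | excluded | O is defined by *inter*-residue interactions |
| K grid | 0–10, step 0.01 | exhaustive scan; ties break toward smaller K |
| interface threshold | 9 Å | effective-atom distance defining a P-P contact |

The sigma convention makes the molecular body span three standard
deviations along each principal axis, so T is genuinely "shaped to the
protein"; the 1 Å floor keeps flat or near-planar units well-defined. The
K search is a deterministic grid scan rather than a continuous optimizer
because the objective can be nearly flat for near-uniform T and reported K
values are conventionally read at 0.1 resolution; the grid guarantees
reproducibility and that $D(O\|M(K_{fit})) \le D(O\|T)$ since $K = 0$ is on
the grid. Because every convention shifts RD and K numerically (the
dominant uncertainty when comparing to published tables), the package ships
`sensitivity_sweep()`, which recomputes a unit across scales, sigma rules
and self-term choices and ranks conventions against reference values.

Degenerate inputs are handled explicitly: coincident points are a geometry
error; a unit in which no residue pair falls inside the cutoff has no
observed distribution (error, not silent zeros); a uniform T has no
complement, so M = T for every K and the fit is flagged degenerate with
K = 0; zeros in O are legal and the KL convention absorbs them, while T and
M are strictly positive by construction.

## Analysis granularities

A residue set can be analyzed in two modes. As an **individual unit**, the
Gaussian is generated for the set itself. As a **component** of a parent
unit, orientation, sigmas, T and O come from the parent; the profiles are
then restricted to the subset and renormalized over it, with R uniform on
the subset. Component mode answers "how does this fragment sit inside the
whole?", individual mode "could this fragment have folded on its own in
water?"; restriction to the full parent reproduces individual mode exactly,
which is regression-tested. The same restriction machinery classifies
residues by inter-chain contact status (P-P vs no P-P, contact = effective
atoms within the interface threshold, boundary inclusive) and produces the
bracketed interface RD values; an empty class is reported as absent, never
as zero. `analyze_complex()` emits the standard report for an oligomer: the
whole complex, each chain in both modes, and any named partitions (e.g. a
beta-sheet "stem" and helical "tentacles" of a jellyfish-shaped hexamer)
as components of the complex. Partition and domain residue ranges are
config data, not computed: domain boundaries come from structural
classification and stem/tentacle membership from secondary structure, both
outside this package's scope.

## What the synthetic generators emulate

`make_micelle()` emulates the water-field outcome: points uniform in a ball
(default n = 100, radius 20 Å — spacing compatible with the 9 Å cutoff so O
is never degenerate), with each residue assigned the value of the water
field at its radius, $h = \exp(-r^2 / 2(\text{radius}/3)^2)$. This is full
micellization by construction — h monotone decreasing in radius, so
rank(h) and rank(radius) are perfectly anticorrelated. A rank-uniform
(linear 1→0) assignment was considered and rejected: it spreads too much
hydrophobicity into the shell and does not produce a detectable core under
the three-sigma Gaussian, which would defeat the generator's purpose of
providing a known-positive control. `make_inverted()` flips h (hydrophilic
core, the membrane-like control) and `make_shuffled()` permutes it (no
radial organization). `make_field_profile()` generates (T, O) pairs with
O = M(T, k) exactly, optionally with multiplicative log-normal noise on O
before renormalization (profiles are positive and normalized, so additive
Gaussian noise would be ill-posed) — the basis for parameter-recovery
checks: noiseless on-grid recovery is exact, and with 5 % noise the fitted
K stays within ±0.1 in at least 95 % of trials.

What the generators do **not** emulate: chain connectivity (points are a
cloud, not a self-avoiding walk — the model itself is conformation-agnostic
given coordinates), side-chain geometry, the discrete 20-letter
hydrophobicity alphabet of real sequences (except through
`write_synthetic_pdb()`, which quantizes h to the nearest residue under a
scale), crystallographic artifacts, or missing residues. Passing generator
contracts therefore validates the estimator's mathematics and conventions,
not agreement with any particular crystal structure.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic units:
50 seeds per generator contract at n = 100, 50 noiseless plus 200 noisy
recovery trials at n up to 500, and 10-unit batches for rigid-motion
invariance (tolerance 1e-6, limited by the eigendecomposition) and for the
O(N²) brute-force oracle of O (tolerance 1e-12, pure arithmetic
reordering). Principal-axis signs are arbitrary; every reported quantity is
sign-invariant. Profile normalization is validated at 1e-9.

## Limitations

Reproducing published RD/K tables for real structures requires the same
hydrophobicity scale, sigma rule, cutoff and self-term convention as the
original computation; since those are not all public, agreement should be
checked with `sensitivity_sweep()` rather than assumed, and the bundled
actin/tubulin configs state the conventions they use. Only the first model
of a structure file is read; occupancy-weighted alternate conformers are
reduced to the highest-occupancy one; solvent-accessibility and
secondary-structure computations are out of scope.
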