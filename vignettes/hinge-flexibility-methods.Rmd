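---
title: "Hybrid EPR / cross-linking analysis of hinge flexibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid EPR / cross-linking analysis of hinge flexibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingeflex)
```

## The scientific problem

DnaJ/Hsp40 cochaperones are V-shaped homodimers: two C-terminal domains
(CTDs) dimerize into a rigid core, and each arm carries a J/GF head at
the end of a roughly 100 Å stalk. Crystal structures capture single
orientations of the heads, but two solution observations demand
interdomain flexibility: (i) a short (~11 Å) bifunctional Cys–Cys
cross-linker covalently joins the two heads of one dimer, which is
geometrically impossible in the static V; and (ii) pulsed EPR (four-pulse
DEER/ELDOR) on spin-labelled cysteines shows narrow intramonomer
distance distributions (the head is internally rigid, distance modes in
the 20–30 Å range) next to broad intermonomer components (40–60 Å with
low-probability tails down to 20 Å). The reconciling hypothesis is that
essentially all of the flexibility is concentrated in the short linker
between the head and the CTD stalk.

`hingeflex` implements the complete computational side of testing that
hypothesis: geometric spin-label distance prediction, DEER simulation
and inversion, a coarse-grained Monte Carlo sampler with a
clash + inverse-Boltzmann pseudo-energy, a progressive-flexibility
cross-link feasibility scan, and the crystal-structure geometry
analyses (superposition, NCS RMSD, interdomain rotation angles,
side-chain hydrogen bonds, construct mass) that anchor the model.

## Coarse-grained representation

A protein chain is reduced to one sphere per residue at the C$\alpha$
position, plus a unit C$\alpha\to$C$\beta$ direction per non-glycine
residue (`bead_chain`). This is the resolution at which the relevant
questions live: Å-level distance distributions and ~10 Å cross-link
geometry, not side-chain packing. Consecutive beads must sit 2.8–4.3 Å
apart (the trans-peptide C$\alpha$ spacing is 3.8 Å).

## Spin-label model

The MTSL-like nitroxide is modelled as a tether–cone: a pseudo-C$\beta$
1.53 Å from the C$\alpha$ along the C$\beta$ direction, then the
unpaired-electron position at tether length $L = 6$ Å, on a cone of
half-angle $\theta_c = 55°$ about the C$\alpha$–C$\beta$ axis,
parameterized by one dihedral $\psi$. These defaults give a mean
C$\alpha$-to-label distance of ≈7 Å, typical of MTSL rotamer clouds. A
full rotamer library would add nothing here: the bead model has no
side-chain atoms, and predictions are only compared with EPR
distributions at the Å scale. Rotamer clouds are sampled on a uniform
$\psi$ grid with positions within 3.5 Å of any bead (own residue ±1
exempt) given zero weight; the label frame is built from the C$\beta$
axis and the direction to a neighbouring C$\alpha$, so it transforms
rigidly with its segment.

Distance distributions live on a uniform grid, by default 10–100 Å in
0.5 Å steps, covering the intramonomer (20–30 Å), intermonomer
(40–60 Å) and crystal-dimer (≥80 Å) regimes.

## DEER simulation and inversion

The orientation-averaged dipolar kernel is
$K(t, r) = \int_0^1 \cos[(1-3u^2)\,\omega_{dd}t]\,du$ with
$\omega_{dd} = 2\pi \cdot 52.04\,\mathrm{MHz\,nm^3} / r^3$ (the standard
nitroxide value), evaluated in closed form via Fresnel integrals and
cross-checked against direct quadrature. A trace is
$V(t) = [1-\lambda+\lambda (Kp)(t)]\exp(-kt^{d/3})$ plus i.i.d. Gaussian
noise: modulation depth $\lambda$, stretched-exponential background
from surrounding molecules (dimensionality $d=3$ by default), mandatory
seed.

Background separation fits $(1-\lambda)e^{-kt^{d/3}}$ log-linearly to
the trace tail (default: the last half). This assumes the dipolar
oscillation has decayed there, which holds only when the measurement
window spans several dipolar periods of the longest distance present —
exactly why long time windows are used experimentally for large
distances. `deer_time_grid()` encodes that rule (4 periods by default);
with it, the simulate → correct → invert round trip recovers
single-Gaussian truth means within 1 Å across 20–60 Å at noise
$\sigma = 0.005$.

Inversion solves $\min_{p\ge 0}\|Kp - D\|^2 + \alpha\|Lp\|^2$ with $L$
the second-difference operator, by non-negative least squares on the
stacked system (`pracma::lsqnonneg`), normalizing the result to unit
area. $\alpha = 10$ suits short-window data dominated by 20–30 Å
distances; $\alpha = 100$ suits long-window, large-distance data.

## Pseudo-energy and sampler

A conformation is scored by
$E = w\,E_{clash} + E_{EPR}$:

* **Clash term.** $\sum_{d_{ij}<c}(c-d_{ij})$ over bead pairs within
  $c = 5$ Å, where intra-chain pairs must be more than $s_{min}=4$
  residues apart (consecutive and helical $i,i{+}3/i{+}4$ pairs sit
  naturally below 5 Å and must not be penalized); inter-chain pairs
  always qualify. The source description admits two readings ("number
  of clashes" vs "sum of distances smaller than 5 Å"); the implemented
  $\sum(c-d)$ form is continuous, zero at the cutoff and grows with
  overlap depth — a literal sum of sub-cutoff distances would *reward*
  deeper clashes. A count-based variant sits behind
  `energy_params(clash_mode = "count")` for sensitivity checks.
* **EPR term.** For each restraint with target density $p(r)$,
  $-k_BT\,\log(\max(\hat p(d), p_{floor})/p_{max})$: zero at the target
  mode, logarithmic penalty elsewhere, floored at $p_{floor}=10^{-6}$
  so unobserved distances stay finite rather than forbidden. Metropolis
  acceptance is invariant to the $p_{max}$ normalization; it only fixes
  the reported zero.

Moves are torsion-style rigid-segment rotations: a backbone element at
virtual bond $(i, i{+}1)$ rotates every bead beyond $i$ (and attached
labels) about the C$\alpha_i$–C$\alpha_{i+1}$ axis; a label element
advances one tether dihedral. Acceptance is Metropolis at $k_BT = 1$
(the acceptance scheme, step sizes and temperature are design choices
of this package — the underlying description leaves them open). Within
the moved and fixed segments all internal distances are preserved, so
the clash-energy change is computed only over moved-vs-fixed pairs (in
compiled code); this is what makes 20 000-trial runs take seconds.

Two calibration checks pin the sampler to Boltzmann statistics: on a
single-dihedral toy the sampled distance variance matches a quadrature
reference within 10% at $10^5$ trials, and on a discretized two-state
landscape the occupancy ratio matches $e^{-\Delta E/k_BT}$ within 5% at
$10^6$ trials.

## Synthetic study system

`make_two_domain_dimer()` generates the study conditions: two
mirror-image arms, each a 160-bead CTD solenoid (radius 6 Å, ~100 Å
long, echoing the rod-like CTD fold), an 8-residue zig-zag hinge, and a
100-bead compact serpentine helix bundle as the J/GF head. Chains are
indexed from the CTD so the dimer core is the fixed frame and hinge
rotations swing the heads — the kinematic tree a dimerized molecule
actually has. The hinge zig-zags perpendicular to the V plane, so its
bond axes span both in-plane bending (heads approaching each other) and
torsion.

Geometry defaults were set once so the model emulates the experimental
windows: opening angle 8° and the default site positions put the three
intramonomer label pairs at 20–30 Å means, the two intermonomer pairs
at 40–60 Å, and the static cross-link sites ~41 Å apart. Site names
(`J18`, `GF86`, ...) tag the classic experimental sites being emulated;
the positions are coordinates in the synthetic head, not sequence
numbers of any real protein.

`simulate_truth_ensemble()` draws conformers with independent Gaussian
hinge-dihedral perturbations (std dev = the "true" flexibility),
rejects clashing conformers, and histograms label-pair distances. By
default labels stay at their reference dihedral, so intramonomer pairs
give zero-width distributions (the head is rigid) and all spread is
hinge-borne; `label_mobility = TRUE` adds uniform tether dihedrals,
as used when a distribution should include label-cloud width.

What the generator does **not** emulate: side-chain atoms and real
rotamer energetics, sequence-specific packing, correlated backbone
motions outside the hinge, instrument artefacts (orientation selection,
phase noise, nuclear modulation). Passing tests therefore demonstrate
the correctness and internal consistency of the algorithms under
idealized geometry, not agreement with any particular protein's data.

## End-to-end validation and the cross-link scan

The full-pipeline check runs, for true hinge flexibilities of 5° and
20°: truth ensemble → one simulated DEER measurement per intermonomer
pair (σ = 0.005) → background correction → Tikhonov inversion → EPR
restraints → 20 000-trial restrained hinge-only MC; the sampled
intermonomer mean must land within 3 Å of the truth mean. Both inverted
intermonomer distributions are used as restraints, as one would use
every available measurement: the sampler's stationary density is the
restraint Boltzmann factor *times* the move-measure prior, whose
entropy mildly favours wide head separations, and each additional
restraint strengthens the data term against that tilt. Exact
distribution equality is not expected — mean agreement is the
meaningful statement.

The progressive-flexibility scan reproduces the qualitative
cross-linking finding: with label dihedrals only, the attachment points
never move and the sites stay ~41 Å apart (infeasible); enabling the 8
hinge backbone bonds makes conformations with the sites within the
12 Å linker span occur within 20 000 trial structures, by 5-seed
majority consensus. Feasibility is evaluated on every *generated* trial
structure (accepted or not), matching the idea of checking occurrence
during the run. The scan's EPR restraint is the broad intermonomer
distribution measured at the cross-link site itself (a single-label
dimer measurement, label mobility included) — the restraint most
directly informative about that pair — while the cross-link readout
uses the pseudo-C$\beta$ attachment points, keeping restraint and
readout distinct.

## Numerical choices

* Scan and ensemble-stage move amplitude: 30° maximum step. The
  10° default of `move_set()` is a safe general-purpose value, but at
  20 000 trials it under-explores the ~30 Å head approach; 30° gives
  adequate angular diffusion while keeping acceptance near 0.8. Chosen
  once as the analysis configuration for stages 4–5 and the
  corresponding checks.
* Problem sizes: truth ensembles use 300 conformers (1000 for the scan
  restraint, where tail shape matters); DEER grids 10–100 Å at 0.5 Å;
  time grids from `deer_time_grid()`. These sizes keep every stage's
  statistics stable at the tolerances quoted above.
* Degenerate inputs: glycine sites refuse labels; buried sites (all
  rotamers clashing) are an error; distances outside a restraint's grid
  fall to the probability floor rather than erroring inside a sampler
  run; superposition rejects collinear point sets and always returns a
  proper rotation (mirrored inputs give the best proper fit, never a
  reflection).
* Determinism: every stochastic entry point takes a mandatory seed;
  identical seeds reproduce ensembles bitwise.

## Crystal-structure analyses

The structure module reads PDB coordinate records (first MODEL,
highest-occupancy altloc, SEQRES retained), pairs NCS copies by author
residue number, and reports pairwise C$\alpha$ RMSDs from Kabsch
superposition (proper rotations only). Interdomain rotation angles use
a fixed user-supplied domain partition: superpose on the reference
domain, extract the residual rotation of the moving domain from the
rotation-matrix trace. This deliberately avoids a hinge-search
(DynDom-style) algorithm — the hinge location is an input here.
Hydrogen bonds between domains are counted by a side-chain
polar-heavy-atom distance criterion (≤3.5 Å, donor/acceptor chemistry
respected, no angle term, closest atom pair per residue pair). Sequence
masses use standard average residue masses plus one water, matching
MALDI-level construct checks to ~0.1 Da.

## Known limitations

* The tether–cone label model reproduces cloud-scale means, not
  MMM/rotamer-library fine structure; no attempt is made to match any
  specific rotamer software numerically.
* The background model is a single stretched exponential; excluded-
  volume or multi-component backgrounds are out of scope.
* The sampler has no kinetic meaning: trial counts measure search
  effort, not time.
* Cross-link feasibility is a geometric criterion (attachment points
  within 12 Å); maleimide reaction kinetics and SDS–PAGE readout are
  not modelled.
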