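# hingeflex

Hybrid solution-structure analysis of a flexible multidomain protein
dimer, in R.

DnaJ/Hsp40-type cochaperones are V-shaped homodimers: two C-terminal
domains (CTDs) form a rigid dimeric core and each arm carries a compact
J/GF head on a ~100 Å stalk. Crystal structures freeze single head
orientations, yet in solution a short (~11 Å) bifunctional Cys–Cys
cross-linker joins the two heads of one dimer, and pulsed EPR
(four-pulse DEER/ELDOR) on spin-labelled cysteines shows rigid
intramonomer distances (20–30 Å) next to broad intermonomer components
(40–60 Å with tails down to 20 Å). `hingeflex` implements the complete
computational chain for testing whether flexibility concentrated in the
short head–stalk linker reconciles these observations:

* **structure geometry** — PDB reading (via bio3d), coarse-graining to
  Cα beads, Kabsch superposition, NCS pairwise-RMSD matrices,
  fixed-partition interdomain rotation angles, side-chain H-bond
  enumeration, average sequence mass;
* **spin labels** — a tether–cone MTSL-like model (`L = 6` Å,
  `θc = 55°`), sterically filtered rotamer clouds, label–label distance
  distributions;
* **DEER** — dipolar kernel (Fresnel closed form, quadrature
  cross-check), trace simulation with modulation depth λ,
  stretched-exponential background and noise, tail-fit background
  separation, non-negative Tikhonov inversion
  (`min ‖Kp − D‖² + α‖Lp‖²`, `p ≥ 0`);
* **ensemble sampling** — Metropolis Monte Carlo over torsion-style
  rigid-segment moves with pseudo-energy
  `E = w·Σ(5 Å − d) [clash] − kT Σ log(p̂(d)/p_max) [inverse-Boltzmann EPR]`;
* **cross-linking** — feasibility of sites approaching within the 12 Å
  linker span, and a progressive-flexibility scan over nested move
  sets;
* **synthetic data** — a V-shaped two-domain bead dimer generator with
  known ground truth, used by every validation stage.

## Worked example

Predict what DEER would measure on the rigid synthetic dimer:

```r
library(hingeflex)

model  <- make_two_domain_dimer(synthetic_spec(seed = 1))
clouds <- lapply(model$sites, function(s)
  sample_rotamers(model$chains, s, n = 36))

dd <- pair_distance_distribution(clouds$A.J18, clouds$A.GF86)
dist_mean(dd)   # 23.1  -- intramonomer pair, 20-30 A window
dist_mode(dd)   # 22

dd2 <- pair_distance_distribution(clouds$A.GF86, clouds$B.GF86)
dist_mean(dd2)  # 57.5  -- intermonomer pair, 40-60 A window
```

Simulate a DEER trace for a 30 Å Gaussian pair distribution and invert
it back:

```r
g  <- default_r_grid()
p  <- distance_distribution(g, exp(-(g - 30)^2 / 8))
tr <- simulate_trace(p, lambda = 0.3, k = 0.05, sigma = 0.005,
                     seed = 11, t_grid = deer_time_grid(30))
ff <- background_correct(tr)    # fitted k = 0.0531, lambda = 0.296
tk <- tikhonov_invert(ff, alpha = 10)
dist_mean(tk$p)                 # 29.94 -- truth mean recovered to 0.1 A
```

The distribution mean comes back within 0.1 Å of the 30 Å truth; across
20–60 Å the round trip stays within 1 Å (see
`analysis/03_deer.R`).

## Analysis workflow

The study itself is a sequence of numbered drivers over the package
(each takes an optional seed argument, writes tables under `results/`):

```sh
Rscript analysis/01_build_model.R      # build + validate the V dimer
Rscript analysis/02_label_distances.R  # rotamer clouds, predicted distributions
Rscript analysis/03_deer.R             # DEER simulate -> invert round trip
Rscript analysis/04_mc_ensemble.R      # restrained hinge MC, truth recovery
Rscript analysis/05_crosslink_scan.R   # progressive-flexibility scan
```

Stage 5 reproduces the central qualitative finding: with only label
dihedrals mobile the cross-link sites stay ~47 Å apart and cross-linking
is infeasible; enabling the 8 hinge backbone bonds produces
conformations with the sites within 12 Å during a 20 000-trial Monte
Carlo run (5-seed majority consensus).

The methods vignette (`vignettes/hinge-flexibility-methods.Rmd`)
documents the models, parameter choices and limitations.

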