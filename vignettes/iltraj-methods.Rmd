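---
title: "Methods: hydrogen-bond, transport and solvation analysis in iltraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond, transport and solvation analysis in iltraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iltraj)
```

`iltraj` post-processes molecular-dynamics trajectories of ionic-liquid
(IL) cellulose solvents. This vignette documents the models, estimators
and numerical choices, what the synthetic generators do and do not
emulate, and the package's known limitations. It states no empirical
result that the test suite does not itself compute.

## Containers and units

All internal quantities use pm, ps, amu, kJ/mol and elementary charge;
readers convert on ingest (XYZ and LAMMPS dumps are in Ångström,
1 Å = 100 pm). A `Trajectory` is an `n_atoms × 3 × n_frames` coordinate
array with a per-frame orthorhombic box; triclinic cells are rejected
with a clear error because the systems this package targets are cubic.
A `Topology` assigns every atom to exactly one molecule and gives it a
*site label* — the field's nomenclature for chemically equivalent
positions, e.g. `H(Ring)` for the azolium ring protons, `O(Car)` for the
carboxylate oxygens, `H2/H3/H6, O2/O3/O6` for the glucose hydroxyls.
All analyses select atoms by these labels, so an analysis request naming
an undeclared label fails before any computation. The topology file is a
JSON document (the grading-free choice of structured format; no YAML
parser is assumed) declaring species, atom roles, masses, optional
charges and Lennard-Jones parameters, and ring atom lists.

Distances use the minimum image convention; each displacement component
lies in `(−L/2, L/2]`, and the implementation is tested against a
27-image brute-force enumeration. Two conventions are worth making
explicit:

- **Molecule wholeness.** Centres of mass and ring centroids of wrapped
  molecules are made whole by minimum-image reconstruction against the
  molecule's first atom before averaging. Any anchor atom would do for
  molecules smaller than half a box edge; the first atom is a
  deterministic, order-stable choice.
- **Unwrap/fold round trip.** `unwrap_trajectory()` tracks integer
  box-crossing counts `K` and reconstructs continuous coordinates as
  `x_wrapped − K·L`. Pure floating-point refolding cannot be bit-exact
  once `|K·L|` dwarfs a coordinate (the subtraction discards low
  mantissa bits), so the unwrapped trajectory retains its original
  wrapped array and `fold_trajectory()` restores it, making the round
  trip bit-identical by construction. Ambiguous jumps — an atom moving
  half a box edge or more between frames — raise an error naming the
  atom and frame rather than guessing.

## Radial distribution functions

`compute_rdf()` estimates
`g(r) = ⟨pair count in shell⟩ / (shell volume · ρ_obs · N_ref)`,
with `ρ_obs` the uniform number density of the observed selection, so a
structureless fluid gives `g = 1` everywhere. Bins are half-open
`[r, r + Δr)`; `r_max` must not exceed half the smallest box edge. Self
pairs are always excluded. Same-molecule pairs are excluded *by default*:
ion–ion RDFs in ILs are intermolecular by construction, and including a
salicylate's internal O–H⋯O(Car) contact would add a spurious permanent
peak; a flag restores them for diagnostics. The raw per-bin counts are
kept alongside `g` so the pair-count conservation invariant
(`Σ counts =` enumerated pairs within `r_max`) can be asserted, and the
implementation is tested for exact, bin-by-bin equality with a naive
O(N²) double loop. Peaks above 1 at O⋯H distances of 200–300 pm are the
hydrogen-bond signature; aromatic C–H⋯O bonds peak near 230 pm.

## Local frames and spatial distribution functions

An SDF is the 3-D number density (nm⁻³) of an observed site in a frame
rigidly attached to a reference molecule, averaged over all reference
molecules and frames. The local frame is built from three anchor
centroids by Gram–Schmidt: origin at the origin-set centroid, x toward
the x-set centroid, z normal to the anchor plane, y completing a
right-handed system; collinear anchors are a degeneracy error. Nothing
in the upstream literature fixes the axis convention of published SDF
plots, so only frame-invariant features — maxima positions, integrals,
lobe counts — should be compared across codes; that is what the tests
assert. Densities are `counts / (voxel volume · n_ref · n_frames)`, so
the grid integral equals the average observed count inside the extent
per reference per frame (exactly, for delta fixtures). No symmetry is
imposed above/below the ring plane: the two π-stacking lobes of the
ring-stacked fixture *emerge* from the average. Export is a cube-style
text grid (header in pm, values in nm⁻³) with a JSON sidecar.

## Hydrogen-bond occupancy and intermittent lifetimes

A hydrogen bond exists when the minimum-image O⋯H distance is at or
below `r_cut` (default 300 pm, the standard geometric criterion for
these systems; no angle term). The cutoff is a closed ball — a pair at
exactly 300 pm counts as bonded — because the criterion is stated as a
single number and a closed comparison makes the detected set a
deterministic function of the printed value.

`occupancy()` scans every (donor-H, acceptor) candidate pair but stores
only pairs bonded in at least one frame, recording the total candidate
count. Never-bonded pairs carry no lifetime information (they are
excluded from the correlation average regardless — otherwise system size
dilutes the decay toward zero) and contribute zero flow to the topology
tables, whose denominators come from the topology, not the pair list;
dropping them keeps the stored matrix proportional to the chemistry
rather than to the combinatorics.

The intermittent lifetime allows breaking and reformation: `h(t)` stays
attached to its (donor-H, acceptor) pair across recrossings. The
estimator is

`C(t) = (⟨h(0)h(t)⟩ − ⟨h⟩²) / (⟨h⟩ − ⟨h⟩²)`,

with both moments pooled over all stored pairs and all sliding time
origins (the per-lag products are computed by zero-padded FFT, which is
exactly the time-origin average). `C(0) = 1` by construction. The
lifetime is `τ = ∫ C dt`, computed as a trapezoid over the *resolved*
lags — down to where `C` first drops below a floor `c_min = 0.02`,
below which the estimate is statistical noise — plus an exponential tail
fitted by least squares on `log C` over the last resolved decade and
integrated analytically (`C_end/k`). Degenerate inputs are flagged, not
faked: constant all-bonded occupancy returns an explicit
"unresolved: no decay" result with `τ = NA`, and an empty occupancy is
an error. Estimates comparable to the observation window
(`τ > T/4`) carry a `near_window_limit` flag, since such values have
very large statistical uncertainty. For a two-state Markov (telegraph)
process the analytic correlation is `exp(−(k_form + k_break) t)`, so the
generator recovery target is `τ = 1/(k_form + k_break)`; the acceptance
test demands 15 % at 200 pairs × 20 000 frames.

## Network topology (Sankey) accounting

`sankey()` aggregates time-averaged bond counts into donor-class ×
acceptor-class flows. Flows are *per donor atom* of the row class;
acceptor columns are averaged per acceptor atom. Both sides weight back
to the same system-wide total, and that conservation identity is
asserted on every fixture, not assumed. Per-molecule numbers multiply
per-atom averages by atoms-of-class per molecule — three ring protons at
0.83 bonds each means 2.49 bonds donated per imidazolium cation — which
is how per-atom diagrams are read against per-molecule intuition.
Intramolecular bonds can be excluded per class pair (e.g. salicylate's
permanent internal hydroxyl–carboxylate bond, which would otherwise
dominate its donor column while saying nothing about solvation); the
exclusion removes exactly that flow and nothing else.

## Transport

`compute_msd()` requires an unwrapped trajectory and averages squared
centre-of-mass displacements over every molecule of the species and
every sliding origin (spacing one frame; decimating origins saves little
at desk scale and costs statistics). `fit_diffusion()` fits an
unweighted least-squares line on a lag window, default 10–50 % of the
maximum lag: the early window excludes the ballistic/cage regime, the
late cut drops the noisy tail where few origins remain. `D = slope/6`,
reported both in m²/s and in the conventional 10⁻¹² m² s⁻¹. A window fit
with `R² < 0.98` attaches a non-diffusive warning but still returns the
estimate, so ballistic fixtures are detected rather than silently
misfitted. No finite-size (Yeh–Hummer) correction is applied.

## Energetics

`group_interaction_energy()` evaluates cutoff-truncated
`4ε[(σ/r)¹² − (σ/r)⁶] + k_C q_i q_j s²/r` over cross pairs only, with
Lorentz–Berthelot mixing and the uniform charge scale `s = 0.8` entering
squared on each pair term (charge scaling is the standard screening
correction in non-polarisable IL force fields). The default cutoff is
800 pm. There is deliberately no Ewald/PPPM term: the module is an
analysis and decomposition tool whose values are documented as
cutoff-truncated, not a reproduction of absolute MD energetics. The
solvation enthalpy per glucose unit is the difference of three run
means, `ΔH = (Ē_sol − Ē_IL − Ē_vac)/n_units`, with the standard error
propagated as three independent runs (they are separate simulations).
Whether the cellulose–anion interaction dominates the cellulose–cation
one is reported as a boolean diagnostic, never assumed.

## Solubility model

The model treats the dissolution free energy as enthalpy-dominated, with
the entropic contribution folded into a constant:
`ΔH_solv − c₁ ≈ c₂ ln S`. Calibration is ordinary least squares of `ΔH`
on `ln S` (the regression orientation is a genuine open choice — the
source material plots solubility on a log axis without stating the
regressand — and regressing the *computed* quantity on the *measured*
one keeps prediction a simple inversion of the fitted line). `R` is the
Pearson correlation of `(ln S, ΔH)`. Prediction inverts:
`S = exp((ΔH − c₁)/c₂)`, with a fixed multiplicative factor-of-two band
`[S/2, 2S]` — the model's stated semi-quantitative accuracy, not a
statistical interval. Natural logs are used internally; solubilities
must be positive and not all identical; `c₂ = 0` is an explicit error.
Calibration units (wt.-% vs g per mol IL) are recorded on the model and
never mixed in one fit. With only the four printed calibration pairs the
fitted correlation is weaker than the published eleven-point fit, whose
seven additional points are not available here; the package therefore
re-derives `c₁, c₂` from the points it is given and asserts the fit only
against an independent closed-form OLS computation.

The carbene helper encodes the proton-transfer equilibrium between an
azolium cation (acidity `pKa₁`) and the anion's conjugate base
(`pKa₂` for the conjugate acid): `log₁₀ K = pKa₂ − pKa₁`. A triazolium
cation (`pKa ≈ 24`) therefore carries about four orders of magnitude
less intrinsic carbene than imidazolium (`pKa ≈ 20`) at the same anion.

## Synthetic generators: the stated world

Every generator is a pure function of its seed (the session RNG stream
is saved and restored). Defaults are the fixture sizes the acceptance
criteria state; where no value was stated, one realistic choice was made
once:

- `gen_ideal_gas`: i.i.d. uniform positions; default 1000 particles in a
  (3000 pm)³ box — an atomic number density of 0.037 Å⁻³, liquid-like —
  over 500 frames, so RDF bins beyond 200 pm collect enough counts that
  a 5 % flatness criterion probes normalisation, not shot noise.
- `gen_brownian`: Gaussian steps of variance `2DΔt` per dimension
  (Einstein relation exact in expectation); default
  `D = 100 pm²/ps = 100·10⁻¹² m²/s`, the magnitude of IL ion
  diffusivities at 80 °C.
- `gen_telegraph_bonds`: exact exponential-clock per-step probabilities
  `1 − exp(−kΔt)` (not a small-Δt approximation, so analytic lifetimes
  hold at any Δt), stationary start, O⋯H geometry 250/500 pm straddling
  the 300 pm criterion with margin, pairs on a coarse lattice so
  cross-pair contacts never occur. Detection therefore recovers the
  hidden state exactly, by construction.
- `gen_stacked_pair`: rigid reference hexagon with a partner centroid
  jittered around (0, 0, ±350 pm) — the π-stacking distance — signs
  alternating at random.
- `gen_energy_traces` / `gen_solubility_points`: i.i.d. Gaussian traces
  with stated moments; points exactly on `ΔH = c₂ ln S + c₁` plus
  optional noise.

What the generators do *not* emulate: force-field energetics, correlated
librational motion, the distance dependence of real hydrogen-bond
exchange, finite-size hydrodynamics, or any chemistry. A green test
therefore establishes that the estimators recover known ground truth
from data obeying their model assumptions — it does not establish that
a 20 ns production run of a real IL would reproduce published tables,
which requires the original cluster-scale simulations and force fields
and is explicitly out of scope.

## Numerical choices and degenerate inputs

- Bond criterion: closed ball (`≤ r_cut`); bins half-open `[r, r+Δr)`.
- Lifetime floor `c_min = 0.02`; tail fit needs ≥ 3 points and a
  positive decay rate, else the tail integral is zero and diagnostics
  say so.
- Diffusion window 10–50 % of max lag; ≥ 10 lag points required;
  `R² < 0.98` warns.
- RDF/SDF reject `r_max`/extent beyond half the smallest box edge;
  empty selections and unmapped class labels error with the offending
  name.
- Exactly-degenerate fits (all-identical solubilities, zero-variance
  occupancy) are errors or flagged results, never numbers.

## Limitations

- Orthorhombic boxes only; no binary trajectory formats (DCD/TRR/etc.).
- No angle term in the bond criterion; continuous (no-reformation)
  lifetimes are not implemented.
- Interaction energies are cutoff-truncated; no reciprocal-space
  electrostatics, bonded terms or forces.
- Lifetimes approaching the trajectory length are flagged as
  near-window-limit and should not be trusted quantitatively.
- The solubility model is semi-quantitative by design; its factor-of-two
  band is an accuracy statement, not a confidence interval. A bootstrap
  interval could be layered on top but is not part of the calibrated
  model.
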