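---
title: "Methods: trajectory analysis of protein-DNA complexes with mdtidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of protein-DNA complexes with mdtidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdtidy)
```

mdtidy is a toolkit for the standard post-processing sequence applied to
molecular-dynamics trajectories of protein-DNA assemblies such as the
Cas1-Cas2 heterohexamer bound to protospacer DNA: superposition statistics,
essential-dynamics PCA with a sampling diagnostic, free-energy landscapes,
hydrogen-bond occupancy, bespoke intramolecular angles, interface energy
decomposition, and base-pair-level DNA geometry. This vignette documents
the models behind each stage, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data generators do and do
not emulate.

## Structures, trajectories and selections

A structure is a tibble of atoms (PDB-style fields; coordinates in
Angstrom, residue numbers 1-based as in PDB records, atom indices plain R
row indices). A trajectory couples a topology with an `n_frames x 3N`
coordinate matrix and a frame spacing `dt` in picoseconds. Atom selections
are declarative conjunctions of field constraints (`atom_selection()`), so
the same selection object can be stored in a config file and always
resolves to the same ordered index list. "Backbone atoms" default to
protein N, CA, C, O plus nucleic P, O5', C5', C4', C3', O3'.

Alternate locations are resolved at parse time by keeping the
highest-occupancy conformer (ties broken by altloc letter), a deterministic
rule matching common practice. Waters are recognised by residue name
(HOH/WAT/TIP3/SOL, configurable). Subunit labels (Cas1a, Cas1b and their
primed copies, Cas2, Cas2', the two DNA strands) are positional
conventions that cannot be inferred from a coordinate file, so the mapping
onto chains is always user-supplied configuration (`subunit_map()`); the
package ships a template for the deposited entries that must be verified
against the file actually downloaded. Primed names are written with a
trailing `p` (`Cas1ap`) because `'` is not a portable key character.

Besides multi-model PDB, trajectories can be stored in a small binary
frame stream (magic `MDTS`, little-endian int32 atom count, float64 `dt`,
then float32 coordinates, atom-major x,y,z). Because coordinates are
stored as float32 both ways, write-read-write round trips are bit-exact.

## Superposition, RMSD and RMSF

Rigid-body fits use the Kabsch algorithm (SVD of the weighted cross
covariance with a determinant correction enforcing a proper rotation).
RMSD time series fit every frame independently to the reference on the
chosen selection. RMSF fits all frames to an *iteratively refined mean
structure* (fit, re-average, refit to convergence `1e-6` A, at most 20
iterations) and reports `rmsf_i = sqrt(<|x_i - <x_i>|^2>)`. Iterating
removes the dependence on an arbitrary reference frame.

Two consequences of least-squares fitting are worth knowing. First, a
fluctuation planted on a single atom is partially absorbed by the fit when
the rigid remainder is small, so the closed-form identity `rmsf = a` for
an oscillating atom holds only when the rigid body dominates. Second, for
domain motion (one rigid body moving relative to another) the conventional
protocol is to superpose on the *static* domain
(`superpose_trajectory()` with a chain selection) before analysing the
mobile one; fitting on everything redistributes part of the motion as
compensating rigid transforms.

## Essential dynamics PCA and the cosine content

The positional covariance `C_ij = <(x_i - <x_i>)(x_j - <x_j>)>` is
computed over the selected atoms, non-mass-weighted (the defining formula
carries no mass factor), after superposing each frame onto the iterative
mean (default; disable with `fit = FALSE` for diagnostics such as
random-walk analysis). Eigendecomposition uses a dense symmetric solver;
selections up to roughly 3N = 1e4 are practical, larger ones should be
subsampled explicitly. Because RMSF and PCA share one fitting code path,
the identity `sum(eigenvalues) = sum(rmsf^2)` holds to machine precision
and is enforced in the tests as a cross-module consistency check.

Projections are `p_i(t) = v_i . (x(t) - mean)` with the same fitting
protocol. The cosine content of mode `i`,

`cc_i = (2/T) (int_0^T cos(i pi t / T) p_i(t) dt)^2 / int_0^T p_i^2(t) dt`,

is evaluated by the trapezoid rule on uniformly spaced frames with time
rescaled to `[0, T]`, making the discretisation consistent with the
continuum formula to `O(dt^2)`. The statistic is scale-invariant and lies
in `[0, 1]`; values near 1 are the signature of random-diffusion-like
sampling (the leading PCs of a pure random walk converge to cosines with
`cc -> 1`), so high values flag insufficient sampling. Thresholds from the
literature (about 0.2 for peptides, 0.5 for proteins) are judgement calls;
the package reports the number and leaves the verdict to the user. One
numerical subtlety: `cos(m pi t/T)` and `cos(i pi t/T)` are orthogonal on
`[0, T]` for `m != i`, but `sin(2 pi t/T)` is *not* orthogonal to
`cos(pi t/T)` there (the integral is `4/(3 pi)`), so orthogonality checks
must use a genuinely orthogonal pair.

## Free-energy landscapes

Two projection series (typically PC1/PC2) are histogrammed on an
`n_bins x n_bins` grid spanning the data range padded by 5% per side
(default 80 bins) and converted by Boltzmann inversion,
`G = -ln(count / count_max)` in units of `k_B T`; the most populated bin
defines `G = 0` and empty bins carry `+Inf`. The default temperature for
unit conversion is 310 K (a typical simulation temperature;
`k_B = 0.0019872041` kcal/(mol K)).

Basins are contiguous (8-neighbourhood) regions of occupied bins with `G`
below a depth cut, reported at their minimum bin. Counting *regions*
rather than raw local minima is deliberate: with realistic sample counts,
Poisson noise in bin populations creates many spurious strict minima, while
sub-cut connected components are stable under both noise and +/-20% changes
in bin count. The default cut of 2 `k_B T` keeps sparsely populated
high-`G` bins out of the basin search; equal-`G` plateaus merge into one
basin, so a perfectly flat landscape yields exactly one.

## Hydrogen bonds

Detection uses a donor-heavy-atom to acceptor-heavy-atom distance cutoff
(default 3.5 A) and an angle cutoff (default 45 degrees). Published
cutoff pairs of this magnitude do not always state their angle convention,
and the two in circulation differ, so both are supported: the default
takes the deviation of the donor-H-acceptor angle from 180 degrees; the
alternative takes the H-donor-acceptor angle directly. Which N/O atoms
donate or accept per residue and nucleotide ships as an editable data
table, so no bond topology is required; hydrogens are associated with
their donor heavy atom by distance (same residue, within 1.25 A).
Structures without hydrogens (crystal structures) are analysed in
heavy-atom-only mode, distance criterion only, flagged in the output.

A water bridge between interface sides A and B exists in a frame when one
water is simultaneously hydrogen-bonded (either polarity) to an atom of A
and an atom of B in that same frame; no time-window relaxation is applied.
Occupancy is the fraction of analysed frames in which a (donor, acceptor,
bridge) triple is satisfied; rows under 20% are dropped by default,
mirroring the usual reporting threshold. Candidate pairs are restricted to
cross-interface combinations by `interface_pairs()`.

The neighbour search is a vectorised all-pairs distance evaluation rather
than a cell list: at the problem sizes this package targets (at most a few
thousand candidate polar atoms per side) the vectorised path is faster in
R and trivially satisfies the all-pairs-equivalence contract, which the
test suite enforces against an independent triple-loop oracle on every
run.

## Intramolecular angles

Three named three-point angles cover the conformational coordinates of the
Cas1-Cas2 system: `alpha` (open-close of one Cas1a-Cas2'-Cas1b' surface:
Cα of Glu121 in Cas1a, geometric centre of Cas2', Cα of Arg245 in
Cas1b'), `beta` (Cas1-dimer rotation: Cα of Glu155 in Cas1a', centre of
the Cas2 dimer, Cα of Glu155 in Cas1a) and `gamma` (duplex bend: centres
of the first, middle and last bp levels, each over both paired
nucleotides). Geometric centres are unweighted means over all atoms of the
subunit by default, switchable to Cα-only; on compact domains the two
conventions differ by under ~2 degrees, which is why a +/-2 degree
tolerance is attached wherever a single literature value is compared.
Because `alpha` exists on two symmetric surfaces, `measure_alpha()`
reports both and their mean. Centres are recomputed every frame in
`angle_series()`.

A geometric note on `gamma` for validation purposes: when a duplex is bent
onto a circular arc of total turning `theta`, the chords from the mid-arc
point to the two ends each subtend `theta/2`, so the three-point angle is
`180 - theta/2` degrees, not `180 - theta`. The synthetic bent-duplex
tests assert this correct closed form.

## DNA groove widths and axis bend

`build_bdna()` generates a straight fiber-geometry duplex: base-pair
frames stacked at 3.38 A rise and 36 degrees twist, second strand the
dyad image of the first, phosphate at radius 9.4 A (giving the canonical
~6.7 A successive intra-strand P-P spacing and canonical groove widths),
C1'-C1' about 10.5 A across the pair, Watson-Crick partner atoms at
hydrogen-bonding distance. Sugar atoms are placed schematically between
C1' and P: the builder is intended for groove/axis/bend analysis and
ground-truth generation, not stereochemistry. The 5'-terminal residue of
each strand carries no phosphate.

The full helicoidal-frame optimisation of Curves-class programs is not
reimplemented. Instead the axis is estimated from C1' base-pair midpoints,
which wobble helically (radius ~1.8 A) about the true axis: a local least
squares fit of a quadratic-in-level plus one-harmonic model (window of 7
levels, twist estimated from the data with 36 degrees as fallback) removes
the wobble exactly for an ideal helix and follows smoothly curved axes,
including at the duplex ends where the clamped window extrapolates along
the local curvature. Tangents are smoothed finite differences (window 3),
with one-sided differences at the termini because symmetric smoothing
biases end tangents inward on a curved axis. Bend at level `k` is the
angle between tangents at `k - w` and `k + w` (default window `w = 1`);
absolute bend values from any axis definition are convention-dependent,
which is why the window is exposed as a parameter. High-frequency atomic
noise is amplified by the windowed fits, so per-frame bends on noisy data
should be averaged over frames (`profile_over_trajectory()`).

Groove widths at level `k` are minimal cross-strand P-P distances within
register windows (minor: partner levels `k+2 ... k+6`; major:
`k-7 ... k-1` under the builder's strand convention) minus the
conventional 5.8 A backbone correction. Levels whose register window is
incomplete (fewer than three candidate phosphates: the terminal two levels
at each end) are flagged `NA` rather than reported from a truncated scan,
which would overestimate. On the ideal 23-bp duplex this yields a mean
major groove of ~11.5 A (canonical value 12 A) and minor groove ~6.1 A.

## Interface energetics

The decomposition follows the MM/GBSA pattern with the single-trajectory
approximation (complex geometry reused for the unbound states, as
g_mmpbsa does): cross-interface Coulomb (`k_e = 332.0636` kcal A /
(mol e^2)) and Lennard-Jones (Lorentz-Berthelot combination) terms, a
polar solvation term, and a surface term `gamma * dSASA + beta`
(`gamma = 0.0072` kcal/(mol A^2), `beta = 0` by default). The polar term
is a pairwise Still generalized-Born functional over effective radii from
Hawkins-Cramer-Truhlar-style analytic pairwise descreening (scale factor
0.8 by default, no radius offset); a finite-difference Poisson-Boltzmann
solver is deliberately out of scope, so absolute polar energies are not
comparable with PB numbers, though per-residue rankings are qualitatively
similar. Dielectrics default to 2 inside, 80 outside. For a single ion
the Still functional reduces exactly to the Born formula, which the tests
assert. SASA uses the rolling-probe numerical sphere method on a
deterministic Fibonacci point set (960 points/atom by default; the grid
is deterministic but not rotation-invariant, so rotated replicas agree to
quadrature resolution only).

Per-residue assignment gives each cross-interface pair term half to each
partner's residue; GB and SASA binding terms are differences of per-atom
state contributions and are summed per residue. By construction the
per-residue totals sum to the complex total exactly every frame, enforced
at `1e-6` kcal/mol in the tests. Force-field parameters (charge, sigma,
epsilon, Born radius per atom) are never derived by the package; they
arrive via a whitespace-delimited parameter file keyed by
`chain:resno:name` labels, with `uniform_ff_params()` generating aligned
tables for toy systems.

## Synthetic data: what it does and does not emulate

The generators replace the undeposited production trajectories with
inputs whose ground truth is known exactly:

* `gen_mode_trajectory()` plants orthonormal collective modes with chosen
  amplitudes over white noise — the covariance structure essential
  dynamics assumes. `orthonormal_modes()` draws modes orthogonal to the
  six rigid-body degrees of freedom, since superposition removes those.
  Note that white noise adds its variance along the planted modes too:
  the expected leading eigenvalue is `sigma_k^2 + noise_sd^2`.
* `gen_diffusion_trajectory()` is a cumulative Gaussian random walk, the
  null model for the cosine-content diagnostic.
* `gen_hbond_scene()` builds scheduled donor/acceptor (optionally
  water-bridged) geometries satisfied at exactly 2.9 A collinear on "on"
  frames and broken at 5.0 A on "off" frames, giving exact occupancy
  ground truth.
* `gen_bent_duplex()` maps the ideal duplex onto a circular arc of stated
  total turning with optional Gaussian jitter.
* `gen_hinge_trajectory()` rotates one rigid pseudo-atom body about a
  fixed hinge following an exact angle schedule.

All randomness flows through one seeded generator per call
(`withr::with_seed`), so identical inputs give bit-identical output and
the caller's RNG state is untouched. What the generators do *not* emulate:
solvent, anharmonicity, coupling between modes, realistic secondary
structure, sequence-dependent DNA fine structure, or force-field detail.
Passing tests on synthetic data therefore demonstrate that the estimators
recover known ground truth under their stated assumptions — not that any
particular biological conclusion transfers to real trajectories.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by design:
planted-mode recovery at 5000 frames of a 20-atom toy, Boltzmann-inversion
checks at 1e5 samples on a 40-bin grid, hydrogen-bond oracle equivalence
on 50 frames of up to ~200 atoms, DNA geometry on 23-bp duplexes, the
diffusion diagnostic over 50 seeded walkers of 5000 steps. These sizes
were chosen so every property is measured well inside its sampling
tolerance while the whole suite completes in about a minute; all analyses
are deterministic given inputs and seed, and pipeline reports carry a
config fingerprint, package version and seed in their headers.

## Known limitations

* The simplified axis is not Curves+: absolute bend magnitudes differ by
  convention, and only trends and planted deformations are comparable.
* GB polar energies are not PB energies; only the decomposition pattern is
  comparable across methods.
* Heavy-atom-only hydrogen-bond mode (crystal structures) cannot apply the
  angle criterion and over-reports relative to hydrogen-aware detection.
* The default subunit chain maps for the deposited entries are templates;
  positional labels must be verified against the coordinate file in hand.
* Equilibrium-window choice (e.g. the back half of a run) is always an
  explicit user decision, never auto-detected.
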