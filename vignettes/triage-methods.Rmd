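---
title: "Methods: pre-FEP triage of charge-changing interface mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-FEP triage of charge-changing interface mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepscout)
```

# Scope and model

fepscout screens proposed charge-changing point mutations at
protein–protein interfaces before alchemical free energy perturbation
(FEP) simulations are spent on them, and evaluates the returned
predictions against experiment. The triage chain runs in a fixed
order — validation, side-chain placeability, burial classification,
salt-bridge flagging, protonation planning — because each stage only
makes sense for survivors of the previous one. FEP energies enter only
as numbers in input tables; nothing here integrates equations of
motion.

# Structure model

PDB files are parsed with bio3d behind `read_pdb()`. Author numbering
is kept verbatim (insertion codes honoured, no renumbering); alternate
locations collapse to the highest-occupancy conformer with ties broken
by altloc letter; hydrogens and non-water heteroatoms are dropped, and
waters are dropped by default (`drop_waters = FALSE` keeps them — they
then act as occluders in SASA and Lennard-Jones environment terms).
All geometry downstream is heavy-atom only, because typical crystal
inputs lack hydrogens.

Van der Waals radii are a swappable data asset
(`inst/extdata/vdw_radii.tsv`, Bondi values by default): published
burial percentages depend on the radius set used to compute them, which
is rarely stated, so the table must be replaceable rather than
hard-coded. Unknown elements warn and fall back to 1.7 Å.

The two binding sides of a complex are user-supplied chain sets. For
structures where the partition is not published (e.g. undeposited
homology models) there is nothing to infer it from, so it is required
input, not a guess.

# Solvent accessibility and burial

`atom_sasa()` is Shrake–Rupley: each atom's sphere, inflated by the
probe radius (default 1.4 Å), is sampled at `n_points` lattice points
(default 960) and the accessible fraction times the inflated sphere
area is the atom's SASA. The lattice is a golden-spiral construction
with no RNG, so results are bit-reproducible for a given
configuration; the optional `orientation` matrix re-expresses the
lattice in a rotated frame, which makes SASA exactly invariant under
rigid rotations of the whole system (used as a test invariant). A
point lying exactly on an occluder surface counts as occluded, so
coincident atoms occlude each other symmetrically rather than
half-randomly through floating-point noise.

Fractional SASA of a residue is its summed atom SASA divided by the
reference maximum for its type in a Gly-X-Gly tripeptide. The shipped
reference table (`inst/extdata/max_sasa_gxg.tsv`) is computed by this
package itself: the maximum middle-residue SASA over the rotamer
library in an ideal extended tripeptide, under the default radii,
probe and lattice (`compute_reference_sasa()` regenerates it). A
self-consistent table keeps the normalisation's defining property —
an isolated extended residue has fSASA ≈ 1, never much above — exact
by construction. A published theoretical table is shipped alongside
(`max_sasa_gxg_theoretical.tsv`); its values are 10–20% larger because
they derive from a different radius set and an exhaustive conformer
scan, and using it simply rescales all fSASA values downward by a
roughly constant factor. Either table (or any user file) can be passed
to `sasa_config()`.

Two conventions were genuinely open and are resolved as follows, both
overridable. First, fSASA is computed on the *whole bound complex* by
default (`context = "complex"`), because burial "experienced at the
interface" is a property of the bound form; `context = "side"`
computes it on the isolated binding side instead. Second, the whole
residue is used rather than the side chain only, matching the
residue-level phrasing of burial classification. The buried class is
`fSASA < threshold` strictly (default 10%); a residue exactly at the
threshold is exposed.

# Side-chain placeability and strain

The question this filter answers is narrow: *can the mutant side chain
be placed on the wild-type backbone at all without gross steric
infeasibility?* Accordingly the energy model is deliberately small — a
vacuum Lennard-Jones 12-6 term over heavy atoms (element-level
parameters, geometric combining, 1-2/1-3 exclusions and 0.5-scaled 1-4
within a residue) plus periodic chi torsion terms (threefold, 0.6
kcal/mol barrier, for sp3 bonds; twofold, 2.0 kcal/mol, for planar
carboxylate/amide and aromatic chis). It is not an implicit-solvent
force field and is not meant to score binding; the threshold is
configurable precisely so the filter can be recalibrated against any
richer energy model.

Rotamers come from a compact backbone-independent library: canonical
staggered wells (−60/60/180°) for sp3 chis, planar wells for sp2 and
aromatic chis, fully enumerated (e.g. 27 rotamers for Glu, 81 for
Lys/Arg). Side chains are built from ideal-geometry internal-coordinate
templates; ring closures are handled as fixed template geometry, which
leaves ring-internal energies constant across rotamers and therefore
cancelled in all strain differences.

`place_mutant()` repacks the mutated residue together with every
neighbouring side chain having any atom within 5.0 Å of the wild-type
side chain ("potentially clashing neighbours" needs a number; 5 Å is
the conventional side-chain contact radius). The backbone is fixed at
all times. The search is exhaustive over rotamer combinations up to
10^5 combinations, then deterministic greedy one-at-a-time cycling;
candidates with any heavy-atom pair closer than 1.0 Å to the fixed
environment are invalid outright. Strain of a placement is its
*internal* energy minus the library minimum for that residue type
(`optimize_free_rotamer()`), hence non-negative by construction; the
filter compares mutant strain against the wild-type residue repacked
identically, and rejects when the increase exceeds 5 kcal/mol, or when
no overlap-free combination exists (`delta_strain = Inf`). Proline
mutants (nonstandard backbone) and histidine mutants (protonation not
assignable without crystallographic evidence) are refused at
validation.

# Salt bridges

`detect_bridges()` links every Asp/Glu carboxylate oxygen to every
Arg NE/NH1/NH2 and Lys NZ nitrogen within 4.0 Å (heavy-atom N–O; the
common literature convention, configurable). An edge is bidentate when
two distinct atom pairs within cutoff involve two distinct atoms on at
least one side. Histidine as a base and charged termini are off by
default, both switchable. A mutation is flagged for extended (100 ns)
sampling when its residue carries two or more edges or any bidentate
edge. Bridges that only form *during* a simulation cannot be seen from
the input structure; reports carry that caveat rather than pretending
to cover it.

# Protonation states

For mutations with an Asp/Glu end state, `enumerate_states()` produces
the charged-throughout assignment and a protonated-in-complex
assignment; the unbound state of the latter is protonated only if the
site is buried in the unbound protein too, otherwise charged.
Wild-type-side neutral assignments that rest on system-specific
evidence (e.g. a neutral Glu stabilised by an adjacent carboxylate in
the bound complex) are accepted as explicit `state_assignment()` input
— the package cannot run the simulations that would justify them, so
it does not guess. A packaged example table
(`protonation_examples()`) provides seventeen such curated cases with
per-state values for tests and demonstrations.

The state penalty uses the standard Henderson–Hasselbalch population
cost, `2.303·RT·(pH − pKa)`, applied when the acid is charged unbound
but protonated in the complex, under the limiting approximation that
the bound form is entirely protonated (no bound-state term). The
qualitative rule fixes only this much; the explicit formula, the
default pH of 7.0 and the textbook model pKas (Asp 3.8, Glu 4.4) are
this package's choices and are all configurable.
`select_final()` takes the minimum implied value across states, with a
per-value flag saying whether the penalty is already folded into the
supplied number (spreadsheet FEP results normally are).

# Triage verdicts and FEP settings

Verdicts partition exhaustively: `rejected_unplaceable` iff the
placement failed; `deprioritized_buried` iff placeable and buried;
`send_to_fep` otherwise. Buried cases are deprioritized rather than
dropped because they remain scientifically interesting even when
unpromising for affinity optimisation. Recommended settings:
24 λ-windows and an 8.5 Å buffer for charge-changing cases (12 / 5.0 Å
otherwise), 100 ns sampling when salt-bridge-flagged or when the input
is declared a homology model. Reports are written as TSV (fSASA
rounded half-up to integer percent, as burial tables are printed) and
versioned JSON (full precision, round-trips exactly).

# Benchmark statistics

`rmse()` and `r2()` are the plain definitions; the coefficient of
determination is the squared Pearson correlation by default — the only
convention under which slope rescaling leaves it unchanged — with
`method = "ss"` available for the regression variant. The p-value is a
two-sided permutation test on the correlation (default 10^5
permutations), chosen over a t-test because the experimental panels are
small, non-Gaussian and heavy-tailed. Confidence intervals are
case-resampling percentile bootstrap (default 10,000 replicates, seed
20190329); residual resampling was rejected because the
prediction-error distribution is exactly what is in question.
`truncate_by_experiment()` keeps ΔΔG_exp strictly below the limit
(default +1 kcal/mol). `fit_rescale()` regresses experiment on
prediction per subset and applies only the slope — the direction and
slope-only application match how system-dependent implicit-solvent
scales are corrected in practice. `select_systems()` implements the
two panel-assembly rules (≥1 case at ΔΔG ≤ −0.5 kcal/mol; ≥25%
non-alanine mutations) plus most-favourable-wins among declared
near-duplicates.

# Synthetic data

The fixture module generates every input the other modules need, with
no downloads, and is first-class tested code:

* `make_tripeptide()`: ideal extended Gly-X-Gly with the middle side
  chain in its maximum-exposure rotamer — the defining case of the
  fSASA normalisation.
* `make_complex_fixture()`: a helix pair with known exposed residues; a
  cavity whose concentric cage shells provably exclude every rotamer of
  a large mutant while admitting small ones (cage density is tied to
  the 1.0 Å overlap criterion); and an Asp–Arg pair whose bidentate
  N–O distances are placed exactly by rigid superposition.
* `make_stats_table()`: experiment values from a mixture spanning the
  dynamic range of interface mutation panels (75% near-neutral
  Gaussian, 25% strongly destabilising uniform tail, clamped to −2.55
  to +7.66 kcal/mol) and predictions constructed so the experiment-on-
  prediction regression slope equals the planted `slope`
  (`ddg_pred = (ddg_exp + noise)/slope`); with `slope = 1` this is an
  unbiased FEP-like predictor. A seed is mandatory and the session RNG
  stream is left untouched.

What these fixtures do *not* emulate: real packing heterogeneity,
backbone relaxation, crystallographic disorder, and correlated
prediction errors. Green tests on them demonstrate algorithmic
correctness (oracle agreement, invariances, planted-parameter
recovery), not accuracy on deposited structures — recomputing published
burial percentages for real complexes requires the deposited
coordinates, which are not redistributable inside the package.

# Numerical choices

* SASA lattice 960 points: agrees with a 10,000-point Monte Carlo
  oracle within 2% per residue; cost is linear in points.
* Occlusion uses a 1e-9 Å² tolerance so surface-coincident points are
  deterministically occluded.
* Rotamer search ties break by candidate order (deterministic); greedy
  cycling caps at 20 sweeps.
* Strain of an invalid placement is reported as `Inf`, serialised as
  `"inf"` in TSV and `null`-safe JSON.
* Bootstrap quantiles are type-7; degenerate replicate sets (non-finite
  metric values) are dropped before the quantile.
* The RT constant uses k_B = 0.001987204259 kcal/mol/K; the penalty at
  pH 7 for Asp (pKa 3.8) is 2.303 × 0.5925 × 3.2 ≈ 4.37 kcal/mol.

Problem sizes in the shipped tests and acceptance script — tripeptides,
toy complexes of a few hundred atoms, panels of 106 + 44 synthetic
records, 500-replication coverage runs at 400 bootstrap resamples —
were chosen as the smallest sizes at which the statistical properties
under test are stable.

# Known limitations

* The strain energy model detects steric infeasibility only; a case
  can pass the filter yet still need backbone relaxation FEP cannot
  sample.
* Rigid ring templates mean small ring-closure inconsistencies for
  Trp/His; these cancel in strain differences but the absolute
  internal energies are not force-field quality.
* Filter-stage case counts on any given panel depend on the energy
  model and threshold; different published stages of the same panel can
  disagree by a case or two, and this package simply reports its own
  counts.
* Burial is evaluated on the static input structure; conformational
  averaging is out of scope.
* pKa values are model values; no structure-based pKa prediction is
  attempted, and histidine tautomers are not handled.
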