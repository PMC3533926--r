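---
title: "Models and conventions behind tecdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind tecdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecdyn)
```

`tecdyn` quantifies the differences between the two working conformations
of a multi-subunit RNA polymerase ternary elongation complex (TEC): the
catalytic form, in which the trigger loop closes over the NTP substrate
and excludes water from the active site, and the translocating form, in
which the trigger loop opens and the bridge helix bends against the
RNA/DNA hybrid while the nucleic acids step forward. This vignette
documents the models, the tunable parameters and their defaults, the
numerical conventions, what the synthetic generator does and does not
emulate, and the open design choices we settled.

## Translocation as a projected displacement

Translocation of the nucleic-acid scaffold is measured against a
*translocation vector*: a line through two anchor atoms chosen in the
reference frame (for the downstream DNA/DNA duplex, typically the
3' carbons of a template DNA base and an RNA base bracketing the hybrid;
for the upstream RNA/DNA hybrid, an analogous pair). With
`u = (b − a)/|b − a|` from the reference coordinates, each frame
contributes

```
d(t) = (r_probe(t) − r_probe(0)) · u
```

after the frame is superposed onto the reference over a protein-core fit
selection. The sign convention makes forward translocation positive, and
the reference frame maps to exactly 0.

Three choices deserve comment:

* **The axis is frozen in the reference frame.** Recomputing `u` per
  frame would conflate rotation of the anchor pair with translocation of
  the probe; a flag (`per_frame_axis`) exposes the alternative.
* **The fit selection defaults to all Cα atoms.** The mobile elements
  (trigger loop, bridge helix, nucleic acids) should be excluded from the
  fit when they are the object of study; every entry point accepts an
  explicit selection, and our own analyses fit on the static half of the
  toy helix.
* **Averages versus endpoints.** Whether a "~3 Å forward" statement is a
  run average or a final-frame position is ambiguous in general, so
  `translocation_summary()` reports both the component means and the
  final point. For a noisy linear drift, the least-squares slope times
  the run length is the low-variance endpoint estimator, and that is what
  the acceptance script reports.

## Hinge metrics

**Δψ.** The backbone ψ dihedral of a hinge residue, relative to the first
frame, wrapped into (−180°, 180°]. Torsions follow the standard IUPAC
sign convention (validated against an independent torsion implementation
to 10⁻⁶ degrees). A practical warning: with 0.2 Å Gaussian coordinate
jitter, a single frame's ψ carries roughly 25° of noise, so Δψ against a
*single* noisy reference frame inherits that offset wholesale. Plateau
heights should therefore be estimated as (post-transition mean) −
(pre-transition mean), which cancels the reference noise; recovery tests
and the acceptance script do exactly this. Against a noiseless reference
(a crystal structure), the plain series is fine.

**Bend angle.** A hinge is flanked by two helical segments
(`hinge_definition()`; flanks of at least 4 residues, disjoint). Each
flank contributes an axis — the principal component of its Cα positions,
oriented N→C — and the bend is the angle between the axes. Raw PCA of a
helical segment that does not span an integer number of turns tilts by
several degrees (the spiral is asymmetric about the axis), so the Cα
positions are first smoothed with a one-turn (4-residue) running mean;
this brings the straight-helix baseline from ≈4.6° to ≈1° and keeps a
planted 30° bend inside a ±4° recovery band under thermal noise.

**Secondary structure.** Assignment uses the Kabsch–Sander electrostatic
hydrogen-bond criterion on backbone geometry,

```
E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)  [kcal/mol],
bond if E < −0.5,
```

with the amide hydrogen reconstructed 1.0 Å from N, anti to the preceding
C=O, whenever (as in most MD-derived PDB exports) hydrogens are absent.
Patterns map to the five classes used on hinge timeline plots: two
consecutive i→i+4 turns give H (π-helix folds into H), i→i+3 turns give
G, bridge/ladder patterns give E, isolated turns give T, else C, with
priority H > E > G > T. Full eight-class DSSP (isolated bridges, bends,
π as its own class) is out of scope. On ideal geometry the assignment
agrees with an independent DSSP implementation (mdtraj's) on 100% of
non-terminal residues, and interior helix labels survive 0.2 Å coordinate
noise in ≥95% of replicates; disagreement at chain termini between
implementations is expected and excluded from comparisons.

## Contacts and switch residues

Hydrogen bonds are donor–acceptor heavy-atom pairs within 3.5 Å passing a
120° D–H···A angle where the hydrogen can be reconstructed (backbone N);
side-chain and water donors, which carry no hydrogens in our inputs, are
judged on distance alone. Ion pairs are opposite-sign charged groups
(Arg guanidinium, Lys amine, Asp/Glu carboxylate, Mg, phosphates;
His only when listed as protonated) whose closest heavy atoms lie within
4.0 Å. The thresholds are geometric conventions, not fitted values, and
all live in `contact_criteria()` and the editable TSV typing tables under
`inst/extdata/`. Same-residue pairs and backbone–backbone pairs of
sequence-adjacent residues (covalent 1–3 neighbours) are excluded.

A *switch residue* changes its side-chain partners between the catalytic
and translocating ensembles. For each candidate, per-partner occupancy
(fraction of frames with any qualifying contact) is computed in both
ensembles; the switch score is the largest |occ_A − occ_B| over partners,
and a residue is called a switch at score ≥ 0.5 — i.e. a contact mostly
present in one ensemble and mostly absent in the other. Two filters make
this robust: the candidate side of a contact must be a side-chain atom
(helical backbone i→i+4 bonds are present in both ensembles and would
dilute every score), and water partners are ignored by default (solvent
turnover between independently simulated ensembles is uninformative;
`include_waters = TRUE` restores them). Occupancy thresholds are explicit
knobs, not claims about any particular system.

## Hydration

Water positions are their O atoms (robust to missing hydrogens). A shell
count is the number of distinct water residues with O within the cutoff
(3.5 Å default, a first-solvation-shell convention) of a named center.
A water is *tightly bound* when it stays within the coordination cutoff
(2.5 Å default, Mg inner sphere) in at least 80% of sampled frames. The
residence definition is this package's operational criterion for
"ordered" active-site waters; residence-time autocorrelation analysis is
deliberately out of scope.

## Assay quantification

Runoff accumulation is fit as a single-phase rising exponential
`f(t) = A(1 − e^{−kt})` by Levenberg–Marquardt least squares, with free
amplitude (a flag pins A = 1); `k` and its asymptotic standard error
summarize elongation. On the experimental 5/10/20/40 s grid with 2%
Gaussian noise, 200-replicate calibration recovers the true rate within
5% in the mean and the reported standard errors cover at close to their
nominal 68% rate. Relative elongation rates are `k_mut/k_wt` with
first-order error propagation. Competition fidelity reads
`error/(error + correct)` from the two product bands; footprinting lanes
normalise pre/post band intensities to fractions summing to 1, and NTP
stimulation reports both the fold change and the percent increase of the
post-translocated fraction (0.25 → 0.51 gives 2.04-fold, +104%). All
ratios are invariant to rescaling every band by a positive constant;
backgrounds are assumed pre-subtracted.

## The synthetic toy TEC

The generator builds a caricature of a TEC with standard PDB naming so
the real-structure code paths are exercised: an ideal α-helix (ALA
backbone, φ = −57.8°, ψ = −47°, 1.5 Å rise and ≈100° twist per residue)
standing in for the bridge helix, with a designated hinge residue;
LYS/ASP pseudo side chains planting a switchable NZ–OD1 contact; a rigid
two-strand ladder of DT/DA residues carrying C3' atoms as the RNA/DNA
scaffold; two Mg ions and an ATP-like ligand with an N3 atom; planted
shell waters (optionally resident) and a transient water bath on a
jittered grid inside a 20 Å sphere.

Trajectories apply, per frame: the scheduled hinge bend (rigid rotation
of the post-hinge half about a perpendicular axis through the hinge Cα —
exactly the bend the flank-axis metric measures), scheduled ψ rotations
(about the residue's CA–C bond, advancing ψ by exactly the scheduled
angle), linear ladder drift along the duplex axis, the contact swap (the
switch side chain tracks its current partner's carboxylate), resident
waters tracking their center, transient waters random-walking with
reflection at the 20 Å sphere, and finally isotropic Gaussian jitter.
Everything derives from one integer seed and is bit-reproducible; the
generator restores the caller's RNG state.

Defaults mirror the scale of the real analyses: 38 helix residues (the
bridge-helix length), a 10-bp ladder, 500 frames × 20 ps (a 10 ns run),
0.3 Å/ns drift (≈3 Å forward over the run, the open-TEC magnitude), three
resident waters at Mg-I (the open-TEC count), 0.2 Å thermal jitter, and a
bath of 1600 transient waters bringing the system to ≈1,800 atoms. The
recovery tests run ten seeds at this size; smaller systems (12-residue
helix, tens of waters) back the brute-force oracle comparisons, where an
O(n²) scan must stay affordable.

What the toy does *not* emulate — and hence what passing tests do and do
not show: there is no force field, no excluded volume during dynamics, no
periodic box, no correlated motions, and the "thermal" noise is white
rather than vibrationally structured. Recovery of planted truths
validates the *estimators* (their conventions, signs, wrap-arounds,
occupancy arithmetic), not any claim that a real polymerase behaves like
the toy. Real-trajectory headline numbers (≈3 Å downstream / ≈2 Å
upstream forward translocation of an open TEC, one versus three bound
waters) require the original all-atom trajectories and are deliberately
not reproduced here; the toy plants values of the same magnitude so the
pipeline is exercised in the regime that matters.

## Numerical choices and degenerate inputs

* Coordinates in Å, PDB residue numbering (1-based), inclusive residue
  ranges; `C3*`/`C3'` spellings are unified; water residues are
  HOH/WAT/TIP3/SOL; alternate locations resolve to the highest occupancy,
  ties alphabetically.
* Superposition is unweighted Kabsch via SVD with a proper-rotation
  correction; fewer than 3 fit atoms or a (near-)collinear fit set is an
  error, not a silent fallback. Minimum-image distances are available
  behind a flag for boxed synthetic systems only.
* Frame 1 of a supplied trajectory is the reference for all
  relative-to-initial metrics (which production frame corresponds to the
  "initial structure" is otherwise unknowable from coordinates alone).
* The default frame interval is 20 ps, the stride at which translocation
  scatter points are conventionally plotted; file-carried time stamps
  override it.
* Chain termini yield `NA` dihedrals; residues missing backbone atoms
  warn and yield `NA` (dihedrals) or coil labels (secondary structure)
  rather than aborting a whole trajectory.
* Degenerate assay inputs are flagged, not guessed at: all-zero runoff
  courses, zero-total band pairs, non-positive fitted rates.
* The sheet builder places the second strand by deterministic
  least-squares refinement of the canonical antiparallel narrow-pair
  hydrogen-bond pattern (N···O 2.9 Å with collinear N–H···O approach) from
  a fixed set of flip-axis starts; a residual below 10⁻³ Å² ends the
  search.
* `run_compare()` writes to a staging directory and moves it into place
  on success, so failed runs leave no partial outputs; manifests record
  package version, config hash and input hashes but no timestamps, making
  reruns byte-identical.

## Problem sizes used in validation

Oracle-equivalence checks run 100 random frames of an ~85-atom toy
against pure per-pair scans; parameter-recovery runs ten seeds of the
full ~1,800-atom, 500-frame toy (three scenarios per seed: drift at 0.3 Å
noise, scheduled bend+ψ, and a swapped-contact ensemble); kinetics
calibration uses 200 noisy replicates. The acceptance script repeats the
trajectory scenarios at three seeds. These sizes were chosen to give the
estimators enough data for their stated tolerances (e.g. the ψ-step
standard error at 250+250 frames is ≈2.2°, inside the ±3° band) while
keeping a full validation run in the minutes range on one core.

## Known limitations

Selections have no distance-based clauses (`within X of ...`); contact
typing covers the common charged/polar groups, not modified residues;
hydrogen-bond angles are only enforced where an amide H can be
reconstructed; DSSP classes I, S and B are folded away; the exponential
runoff model is single-phase by construction and will average over
multiphasic courses; and the fidelity normalisation is the raw error
fraction, with more elaborate gel-normalisation protocols out of scope.
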