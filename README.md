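# tecdyn

Trajectory metrics and assay quantification for RNA polymerase ternary
elongation complexes (TECs).

Multi-subunit RNA polymerases cycle between two jobs each time they add a
nucleotide: catalysis, with the mobile trigger loop closed over the NTP
substrate, and translocation, with the trigger loop open and the bridge
helix bending against the RNA/DNA hybrid. `tecdyn` implements the
quantitative readouts used to compare closed (catalytic) and open
(translocating) TEC ensembles from molecular-dynamics trajectories, and
the companion in vitro assay quantifications, as a tested, reusable R
package:

* **Translocation-vector projection.** A translocation vector is drawn
  through two reference atoms (e.g. the 3' carbons of a template DNA base
  and an RNA base bracketing the hybrid); translocation is the
  displacement of the orthogonal projection of a probe atom (e.g. a
  non-template DNA 3' carbon) onto that vector, relative to the initial
  structure: `d(t) = (r_probe(t) − r_probe(0)) · u`, with `u` the unit
  axis in the reference frame. Positive values mean forward
  translocation.
* **Hinge dynamics.** Backbone φ/ψ dihedrals, Δψ(t) relative to the
  initial structure (wrapped into (−180°, 180°]) as a hinge-motion
  metric, helix bend angles between flank axes on either side of a hinge
  (H1–H4 style definitions), and per-residue secondary-structure
  timelines over the five classes {H, G, E, T, C} using the
  Kabsch–Sander hydrogen-bond energy criterion
  `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5 kcal/mol`.
* **Switch residues.** Hydrogen bonds (3.5 Å / 120° defaults) and ion
  pairs (4.0 Å between charged-group heavy atoms) per frame, per-pair
  occupancies over a run, and detection of residues whose side-chain
  partners differ between two ensembles (occupancy difference ≥ 0.5 by
  default).
* **Active-site hydration.** Water counts in shells around named centers
  (ATP N3, RNA 3'-O, Mg-I) and residence-based detection of tightly bound
  waters (within 2.5 Å of the center in ≥ 80% of frames by default).
* **Assay quantification.** Single-phase exponential fits
  `f(t) = A·(1 − e^{−kt})` of runoff accumulation courses (5, 10, 20,
  40 s grid), relative elongation rates with propagated errors,
  competition-fidelity misincorporation fractions, and exonuclease III
  footprint pre/post translocation-state fractions with NTP-stimulation
  folds.
* **Synthetic toy TEC.** A seeded generator plants every ground truth the
  analyses measure — helix bends, ψ steps, translocation drift, contact
  swaps, resident waters — so the whole stack is testable without any
  external trajectory data.

## Worked example

A toy open-like TEC with a planted forward drift of 0.3 Å/ns over a
10 ns run, analysed with the translocation-vector metric:

```r
library(tecdyn)

p  <- toy_tec_params(seed = 1, noise_sigma = 0.3)   # 500 frames x 20 ps
s  <- build_toy_tec(p)
tr <- simulate_trajectory(s, p)

info <- attr(s, "toy_info")
spec <- translocation_spec(info$anchor_a, info$anchor_b, info$probe,
                           label = "downstream")
pts  <- translocation_series(tr, downstream = spec,
                             fit_selection = "chain A and name CA and resid 2-17")
translocation_summary(pts)$endpoint
#> downstream
#>   3.086662
coef(lm(downstream ~ time_ps, data = pts))[2] * max(pts$time_ps)
#>  time_ps
#> 2.951112

ntp_stimulation(0.25, 0.51)
#> $fold
#> [1] 2.04
#>
#> $percent_increase
#> [1] 104
```

The raw endpoint (3.09 Å here) is a single noisy frame; the least-squares
slope estimate (2.95 Å) recovers the planted 3 Å forward step to within
the thermal noise. The second call is the footprinting arithmetic: a
post-translocated fraction moving from 25% to 51% on NTP addition is a
2.04-fold (+104%) stimulation — the "approximately 2-fold" regime typical
of an active wild-type enzyme.

## Command line

A thin wrapper over the package lives at `inst/scripts/tec-dyn.R`:

```sh
Rscript inst/scripts/tec-dyn.R simulate --seed 1 --frames 100 --out-prefix toy
Rscript inst/scripts/tec-dyn.R compare  --config run.yaml
Rscript inst/scripts/tec-dyn.R assay    --runoff courses.tsv --out fits.tsv
```

`compare` runs the full closed-vs-open workflow (translocation, hinge
metrics, secondary-structure timelines, switch residues, hydration) on
two trajectories and writes one TSV per metric plus a summary table and a
JSON manifest; re-running an identical config is byte-reproducible.
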