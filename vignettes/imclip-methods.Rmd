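---
title: "Methods: melting curves, NOE restraints and i-motif topology in imclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: melting curves, NOE restraints and i-motif topology in imclip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imclip)
```

## The system

Short DNA oligonucleotides combining a cytosine tract with GA-repeat
purines (C~3~GAGA, GAGAC~2~mC, AGAGC~3~, AGAGC~2~mC and relatives)
assemble at mildly acidic pH into a tetramolecular architecture: two
parallel-stranded purine·purine homoduplexes clamped together by a
tetramolecular i-motif formed by intercalated hemiprotonated CH^+^·C
pairs. `imclip` implements the computational chain used to study such
assemblies: CD/UV melting-curve processing, NOE-derived distance
restraints, base-pair-geometry and intercalation-topology classification
from coordinates, and trajectory-level stacking and hydrogen-bond
analyses. A synthetic-data module generates every input class so the
whole chain runs and is testable without external data.

Nomenclature used throughout: duplexes *I* and *II*, strands *a* and *b*
within each duplex; residues are numbered 1..n from the 5′ terminus, so
G^4^ of C~3~GAGA is the first purine after the tract. Units are Å,
degrees, °C and mol/L.

## Melting curves

**Model.** Folding is treated as an effective two-state monomolecular
transition with van't Hoff enthalpy ΔH (negative for folding) and
ΔS = ΔH/T~m~, so the equilibrium fraction folded is

$$f_{eq}(T) = \frac{1}{1 + e^{\Delta H (1 - T/T_m)/(RT)}}.$$

The observed signal blends linear folded/unfolded baselines:
s(T) = f·n(T) + (1−f)·u(T), plus Gaussian noise. Concentration
dependence of multimolecular association is deliberately out of scope.

**Kinetics and hysteresis.** During a temperature ramp the fraction
folded relaxes toward equilibrium at a first-order rate k(T),
Arrhenius-scaled from its value at T~m~ with activation enthalpy
|ΔH|/2 (a symmetric-barrier convention; the mechanism only needs to
produce direction-dependent lag). The governing equation
df/dT = ±k(T)/v · (f~eq~ − f) (v = scan rate) is integrated with an
integrating-factor scheme — exact for frozen coefficients on each
substep and unconditionally stable. This matters because k/v spans many
orders of magnitude across a scan: generic stiff solvers fail outright
in the fast-relaxation limit, while the exponential step reduces
smoothly to f = f~eq~. With `relax_rate_at_tm = Inf` heating and
cooling curves coincide pointwise; at 0.05/min and the standard
0.33 °C/min scan rate the generator shows several degrees of
hysteresis, as observed for purine-5′ sequences.

**Defaults.** `thermo_params()` uses ΔH = −60 kcal/mol, giving a
10–90% transition width of ~14 °C, typical of the steep tetramolecular
melts this chemistry produces; scan rate 0.33 °C/min (2 °C steps, ~6 min
per point); curves are sampled on a 2 °C grid.

**Normalization and T~m~.** `normalize_melting()` fits linear baselines
in a cool and a hot window and rescales to fraction folded,
f = (s−u)/(n−u), clamped to [0,1]. Window defaults are the coolest and
hottest 15% of the span, widened so each window holds at least eight
points: baseline-fit noise propagates directly into T~m~, and with a
2 °C step a 15%-of-70 °C window holds only six points, which measurably
dominates the T~m~ error at 2% signal noise (recovery within 1 °C rises
from ~80% to ~96% of curves with the eight-point floor). Coinciding
baselines anywhere in range are a hard error. T~m~ is the temperature
where f crosses 0.5, linearly interpolated between the bracketing
points; when noise creates several crossings the one with steepest
|df/dT| wins. A fitted sigmoid would be an alternative; linear
interpolation is the documented choice. Curves that never cross 0.5
raise an "unmelted/fully melted in range" error.

**Hysteresis.** H = T~m~ − T~ren~, classified on half-open intervals
[0,1) none, [1,5) small, [5,10) medium, [10,∞) large (the printed
thresholds leave membership at the boundaries ambiguous; half-open is
the package convention). H < −0.5 °C is treated as swapped scan
directions.

**Molar CD.** Δε = θ/(32.98·c·l) with θ in mdeg, c molar strand
concentration, l path length in cm.

## NOE buildups and restraints

Cross-peak volumes follow the isolated-spin-pair buildup
V(τ) = k·r^−6^·τ(1 − λτ); `initial_rate()` fits R = k·r^−6^ through the
origin by least squares, including the quadratic spin-diffusion term by
default whenever three or more mixing times are available (the
standard 70/100/150 ms series). One point falls back to V/τ with a
warning. Distances follow from the r^−6^ law against the cytosine
H5–H6 reference: r = r~ref~(R~ref~/R)^1/6^ with r~ref~ = 2.48 Å. When
several cytosines are present, the reference rate is the mean over all
unflagged intra-cytosine H5–H6 peaks (which cytosine served as the
reference is otherwise arbitrary; averaging is the documented choice).
Note that the package's own idealized cytosine template has an H5–H6
separation of `r round(cytosine_reference_distance(), 3)` Å
(`cytosine_reference_distance()`); calibrating synthetic data against
the printed 2.48 Å therefore rescales all distances by the constant
ratio of the two, exactly as an experimental calibration constant
would. Exact round-trip identities in the test-suite use the template
value.

Calibrated distances are categorized as strong (bounds 1.8–3.6 Å),
medium (2.6–5.0 Å) or weak (3.5–6.0 Å). The printed bounds overlap, so
a deterministic partition assigns the category: r ≤ 3.0 strong,
3.0 < r ≤ 4.25 medium, r > 4.25 weak (cuts near the overlap
midpoints); the emitted bounds remain the printed ranges. Overlapped
peaks, peaks with exchangeable protons and peaks visible only at long
mixing times are flagged and emitted with the widened 2.5–6.5 Å range
regardless of distance. Force constants: 20 kcal·mol^−1^·Å^−2^ for
distance restraints, 200 for χ-torsion restraints (syn 25–95° for any
base, anti 170–310° for pyrimidines, 200–280° for purines) and 100 for
base-pair planarity records. Planarity is emitted as four-atom
improper-style records over the hydrogen-bonded edge (donor antecedent,
donor, acceptor, acceptor antecedent) — the exact quadruple is a
package convention, since no standard one exists. Inter-base H-bond
restraints target the idealized template separation, 2.8–3.0 Å.
Restraints are written as a round-tripping TSV and optionally as an
Amber DISANG-style text dialect with flat-bottom wells.

## The idealized model builder

**Base templates.** Planar bases are constructed from mean
crystallographic bond lengths and angles; polar and aromatic hydrogens
sit on in-plane exterior bisectors (N–H 1.01 Å, C–H 1.09 Å), amino
hydrogens symmetric about the C–N bond. C1′ attaches on the exterior
bisector of the glycosidic nitrogen and O4′ is placed so the glycosidic
torsion χ (O4′–C1′–N9–C4 for purines, O4′–C1′–N1–C2 for pyrimidines)
takes any requested value — χ round-trips exactly through
`chi_torsion()`. Supported residues: DA, DG, DC, 5mC, DI (no N2, so
sugar-edge pairing is rejected), 2AP.

**Pairs.** Every pair is C2-symmetric: strand *b* is the in-plane
180°-rotation of strand *a* about the point
p = (D + A + d·w)/2, where D and A are the donor and acceptor
positions, w the donor N–H direction and d the target heavy-atom
separation. This places the partner's acceptor exactly d Å from the
donor along the N–H bond, making both symmetric hydrogen bonds linear
by construction. Geometries: G·G sugar edge (N2H→N3, tight), G·G
Watson–Crick edge (N1H→O6, loose), A·A Hoogsteen edge (N6H→N7, tight),
A·A Watson–Crick edge (N6H→N1, loose), hemiprotonated C·C (N3···N3 at
2.8 Å with symmetric N4H→O2 support); d = 2.9 Å elsewhere.

**Assembly.** The cytosine tracts of duplexes I and II interleave into
a stack of alternating CH^+^·C pairs with a 3.1 Å inter-plane rise and
15° helical twist per stack step; duplex II is rotated 90° about the
stack axis (i-motif duplexes are near-orthogonal in projection). These
helix parameters are typical i-motif values chosen once as tunable
defaults — the determined structures' parameters are not printed
anywhere, so they are placeholders, not reproductions. The purine stems
continue outward from each duplex's junction cytosine. The interleaving
order realizes the end class: 3′E places the tract cytosines nearest
the 3′ terminus outermost, 5′E the 5′-nearest ones. A consequence is
that, for a given sequence, the end class *forces* the junction
compactness: the topology is extended exactly when the junction
cytosine pair (the tract cytosine adjacent to the purine block) is
outermost, and compact when the orthogonal duplex's outer CH^+^·C pair
is intercalated between the junction purine pair and its same-duplex
cytosine pair. `topology_spec()` validates a requested combination and
rejects unconstructible ones by name. Defaults for purine pairing:
the 5′-GA-3′ dinucleotide closest to the tract takes the tight SE/HE
combination (the conserved GA step); all other purines pair via their
Watson–Crick edges; χ defaults to anti (240°) and can be overridden
per residue (e.g. syn G^4^ = 60° in compact AGAGC~3~).

A schematic phosphate backbone (P midway between consecutive C1′
positions, pushed radially outward, with OP1/OP2/O5′/O3′ at standard
bond lengths) provides backbone acceptors for the H-bond analyses. It
is connective only and carries no torsional realism.

## Classifiers

`detect_hbonds()` enumerates donor/acceptor pairs with heavy-atom
distance ≤ 3.5 Å and D–H···A angle ≥ 120° — standard practice values,
exposed as arguments since no criteria are printed. Missing donor
hydrogens are inferred in the base plane from standard geometry, so
deposited coordinates without protons classify identically.
Hemiprotonated C·C pairs are detected from the N3···N3 distance
(≤ 3.0 Å) plus mutual N4H→O2 bonds, because the shared imino proton's
position is not resolvable from heavy atoms. A pair is C2-symmetric
when forward and backward hydrogen-bond length sets agree within
0.3 Å. Hetero purine pairs (G·A mismatches) are recognized and
deliberately returned as unpaired with a note.

`classify_topology()` orders the CH^+^·C pairs by projecting their
centroids onto the sign-aligned mean base-pair normal, requires duplex
membership to alternate along the stack (the defining property of
intercalation; violations raise an invalid-intercalation error), calls
the end class from the outermost pairs' residue indices relative to the
tract, and calls compactness from the junction step: the nearest
stacked neighbour of the junction purine pair *on its core side* is
either a same-duplex cytosine pair (extended) or an orthogonal-duplex
one (compact). Both junctions must agree. All classifications are
invariant under rigid motion. Multi-model files are classified per
model and summarized as call counts — a single static model cannot
represent a topological equilibrium (as reported for GAGAC~3~), so no
populations are claimed.

## Trajectory observables

`subsample()` keeps frames at t = k·stride, k ≥ 1, excluding t = 0 —
the only convention under which 1 μs at a 100 ps stride yields exactly
10 000 snapshots. `average_structure()` superposes every frame onto the
first by least squares (bio3d's fitting routine) and averages
coordinates.

`stacking_overlap()` projects both base pairs of a step onto the
sign-aligned mean of their two base-pair plane normals (the union point
cloud of two elongated pairs is poorly conditioned for a single
least-squares plane), takes each pair's convex hull in that plane, and
intersects the hulls by Sutherland–Hodgman clipping (hand-rolled; both
hulls are convex so the clip is exact, and it is verified against a
Monte-Carlo point-sampling oracle). Areas are reported ring-only and
ring+exocyclic; comparisons with 3DNA-style figures should use the
ring+exocyclic variant. Steps whose pair planes tilt more than 65°
apart are computed but flagged unreliable. Note that in the compact
junction the "orthogonal" duplex II pair is rotated about the stack
axis — its plane stays parallel, so the flag correctly stays off there.

`helical_twist()` is the signed angle between the two C1′(a)→C1′(b)
vectors projected onto the step's mean plane, measured about the step
normal oriented from the first pair toward the second (making the sign
well defined and symmetric in the arguments), in (−180°, 180°].

`hbond_distance_series()` histograms the per-frame heavy-atom
donor–acceptor distance with fixed-width bins (default 0.1 Å; densities
integrate to one) and reports the modal distance and the fraction of
frames below 3.5 Å. Bin width and atom selections are documented
defaults, not reproductions of any figure's settings.

## What the synthetic data do and do not emulate

The generators reproduce the *statistical structure* the analyses
assume: two-state melting with linear baselines and scan-rate-dependent
hysteresis, r^−6^ NOE buildup with spin diffusion and multiplicative
noise, geometrically exact pairing/topology ground truth, and isotropic
Gaussian coordinate jitter with frame-independent noise. They do not
emulate force-field energetics, correlated thermal motion, solvent,
real backbone conformations or multimolecular association kinetics.
Passing tests therefore demonstrate algorithmic correctness and
self-consistency, not agreement with experiment. In particular the
idealized stack is nearly eclipsed (15° twist, no slide), so its
stacking-overlap areas (~25 Å² ring+exocyclic per junction step) are
substantially larger than those of MD-averaged structures (~12 Å²);
deposited coordinates should be used for any quantitative overlap
comparison.

## Problem sizes and numerical choices

The test-suite and acceptance script use: 10 000-frame trajectories for
the subsampling convention; 200-frame ensembles (σ = 0.3 Å) for
averaged-structure overlaps; 100 seeded melting curves for parameter
recovery, each scanned over T~m~ ± 35 °C so the baseline windows sit on
true baseline; 50 random polygon pairs at 2×10^5^ Monte-Carlo points
each for the overlap oracle (≤1% of the smaller hull). The melting
integrator uses 20 substeps per 2 °C interval. Tie-breaks: equal-rate
crossings resolve to the steepest; greedy base-pair assignment ranks
candidates by hydrogen-bond count, then mean bond length.

## Known limitations

- The builder produces a single idealized conformer; ensembles,
  fraying and the topological equilibrium of GAGAC~3~ are out of scope.
- The schematic backbone supports distance queries only; backbone
  torsions, sugar puckers and realistic phosphate geometry are absent.
- Restraint output targets refinement input formats but the package
  does not run refinement or MD.
- Hemiprotonation is inferred geometrically; protonation states are
  not predicted.
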