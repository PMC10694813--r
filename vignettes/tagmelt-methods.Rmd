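---
title: "Melting-point determination and eutectic analysis of binary TAG crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-point determination and eutectic analysis of binary TAG crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagmelt)
```

## The problem

Cocoa-butter fats are mixtures of triacylglycerides (TAGs), and binary TAG
mixtures melt nonlinearly: the melting point of a mixture is not a weighted
mean of the pure components and can dip below both of them (a eutectic).
Predicting where that dip falls normally requires the melting temperature and
enthalpy of fusion of each component, which are often unknown. An
alternative is to simulate it: build a coarse-grained binary TAG crystal,
heat it through a linear temperature ramp, detect where it starts to melt,
and repeat across compositions to trace the phase diagram.

`tagmelt` implements that analysis chain end to end: crystal construction
and random binary substitution, crack-void carving under a composition
constraint, the near-neighbor occupancy (NNO) crystallinity order parameter,
prediction-interval melting-onset detection, replicate aggregation with the
plateau and mechanical-collapse rules on melting-vs-void-size curves, and
phase-diagram/eutectic assembly with a Hildebrand ideal-solubility liquidus
for comparison. In place of a molecular dynamics engine it ships a synthetic
trajectory generator with known ground truth, so every stage of the pipeline
is testable at desk scale.

## Crystal construction

Supercells are stacked from a unit-cell template; the canonical system is
800 molecules from 10 x 2 x 10 copies of a 4-molecule cell
(`build_crystal(default_unit_cell(), c(10, 2, 10))`). The shipped cell is an
idealized stand-in, not a crystallographic structure: a rectangular
1.6 x 1.6 x 4.0 nm cell with molecules on a square 0.8 nm grid in the a-b
plane and chains along c. Two properties of real beta-2 TAG packing are
preserved because the analysis depends on them: central beads have nearest
neighbors well inside the 1.2 nm NNO cutoff (spacings 0.8 and 1.13 nm, eight
in-plane neighbors each), and the molecule is strongly elongated along the
chain axis. We use orthogonal lattice vectors rather than a monoclinic tilt;
a tilt would force triclinic box handling in the GRO files and the
minimum-image arithmetic while changing nothing the method measures.

The three species (`default_species_set()`) are sn-POP, sn-POSt and
sn-StOSt with a 9-bead oleic sn-2 chain (central bead 5 — the reference
site for every distance in the package) and palmitic chains one bead
shorter than stearic ones. Binary mixtures are made by
`substitute_random()`: a seeded uniform draw without replacement relabels
`round(fraction * N)` molecules in place. A shorter TAG occupies fewer bead
sites along the same chain axis, leaving the terminal sites empty — the
"mini-voids" that mixed-chain-length crystals exhibit and one proposed
reason simulated mixture melting points sit below empirical ones.

## Crack voids and the composition constraint

Perfect periodic crystals superheat badly in direct-heating runs because
melting has nowhere to nucleate. `carve_crack_void()` removes `void_size`
molecules nearest a randomly positioned, randomly oriented plane — a planar
"crack" — and then repairs the surviving TAG ratio by swapping molecules at
the slab boundary between the removed and kept sets until the minor-species
percentage is within an absolute tolerance (default 1.5 percentage points)
of its pre-void value. A 10/90 crystal therefore always stays inside
8.5-11.5% after carving, whatever the void size. Infeasible requests (for
example a tolerance of zero when no integer survivor count hits the exact
ratio) raise an error rather than silently clipping: a silently wrong ratio
would poison every downstream composition label.

## The NNO order parameter

A molecule in a crystal keeps the same neighbors; a molecule in a melt
exchanges them. The near-neighbor occupancy of molecule i at frame t is the
number of its cutoff neighbors (central beads within 1.2 nm, minimum-image)
that were also neighbors in the previous frame:
`NNO(i, t) = |N_t(i) ∩ N_{t-1}(i)|`, with the first frame scored as the
full neighbor count. Consecutive-frame persistence is the default;
`mode = "reference"` intersects with frame 0 instead, which decays rather
than recovers when a molecule finds new long-lived neighbors after local
rearrangement. Neighbor search uses a cell list (bins at least one cutoff
wide, 27-cell neighborhoods, duplicate wrapped cells removed); a brute-force
all-pairs path is kept and both are tested for exact agreement against an
independent double-loop oracle.

Summing the NNO over all molecules per frame and mapping frame time to
temperature through the linear ramp (248 to 348 K over 200 ns, 0.5 K/ns, by
default) gives the 2-D total-NNO-vs-temperature curve on which melting is
detected. Trajectories default to 200 evenly spaced frames; output
frequency is a free choice of the pipeline, and 200 frames put one point
every 0.5 degrees, comfortably denser than the onset features being
resolved.

## Onset detection

`detect_onset()` walks candidate split indices k along the curve. For each
k it fits an ordinary least-squares line to points 1..k (the crystalline
baseline) and computes each remaining point's one-sided lower prediction
bound at confidence 0.95. The criterion is met at the smallest k for which
*more than* 95% of the remaining points fall strictly below their bounds.
The head must contain at least 20% of the curve (`min_fit_fraction`), which
prevents degenerate two-point fits; both fractions are exposed in
`onset_config()`.

Where to report the onset once the criterion fires is a genuine design
choice. The split temperature itself is biased early: the criterion
tolerates up to 5% of the tail being still-crystalline, so it fires roughly
`0.05 * (remaining temperature span)` before the data actually departs the
baseline — about 2-5 degrees on the canonical ramp, which would swamp the
method's accuracy. `detect_onset()` therefore reports the *departure
point*: the first remaining point below its bound that is immediately
followed by another below-bound point. Requiring a confirmed successor
suppresses the ~5% of lone false positives a one-sided 95% bound produces
by construction. The split index is kept in the result (`split_index`) for
inspection. On synthetic step curves (flat baseline, 50 units/K decline,
noise sigma 30) this estimator lands 0.4-2.0 degrees after the true break —
the lag is the temperature at which a 50 units/K decline first clears the
prediction bound, about `1.65 * 30 / 50` degrees — and on full synthetic
trajectories it recovers the scenario onset to better than 1 degree.

## Replicates, the plateau rule and mechanical collapse

Per TAG-ratio/void-size combination the melting point is the arithmetic
mean of replicate onsets (the study design uses 50 replicates;
`enumerate_design()` reproduces the full 3 pairs x 9 ratios x 9 void sizes
x 50 replicates = 12,150-run manifest with distinct per-run seeds).
Uncertainty is a seeded percentile bootstrap of the mean (2000 resamples by
default — the bootstrap flavor is a package choice, made explicit because
only "bootstrap error" is specified upstream), and `convergence_trace()`
recomputes mean and error over every replicate prefix to show convergence
in the replicate count.

Melting points fall with void size until the nucleation barrier stops
mattering. On the melting-vs-void-size curve, `detect_plateau()` applies
the rule: with successive drops `d_j = T(v_j) - T(v_{j+1})`, the plateau is
at the first `j` with `d_j > d_{j-1}` ("decreases or remains the same"
never triggers — ties are non-increases). If no difference ever increases,
the plateau falls to the last point before a detected collapse, else the
last point. `detect_collapse()` flags a drop exceeding twice the median of
all prior drops (the factor is exposed; the collapse is only described
qualitatively upstream, so a robust median-based default is used).
Ambiguous curves are resolved by inspection in practice, so
`detect_plateau()` accepts a manual override void size that supersedes the
rule and is recorded in the result, never applied silently.

## Phase diagrams and the Hildebrand liquidus

`find_minimum()` locates the eutectic candidate: the interior composition
with the lowest melting point (endpoints excluded by default, ties broken
toward 50/50 and reported). On the packaged simulated melting-point table
all three binary systems have interior minima strictly below both pure
TAGs — the eutectic signature. For comparison, the ideal-solubility
(Hildebrand) model predicts each component's liquidus branch from
`ln x = (ΔH_f / R)(1/T_m − 1/T)`, solved in closed form; the predicted
liquidus is the upper envelope of the two branches and the branch crossing
is the model eutectic. The packaged enthalpies of fusion are synthetic
placeholders of plausible magnitude (the file says so); substitute measured
values for real predictions. Pure melting temperatures in that file are the
simulated pure-TAG values from the melting-point table.

## The synthetic trajectory generator

`gen_crystal_trajectory()` emulates exactly the statistical structure the
analysis consumes, nothing more. Each molecule draws a personal onset
uniformly from `onset_temperature ± stagger_width/2` (default width 2
degrees — melting is gradual, molecule by molecule, as heating runs show).
Below it the central bead is its lattice site plus fresh Gaussian jitter
(sigma 0.05 nm, small against the 0.8 nm lattice spacing); above it the
bead abandons the site and random-walks (0.3 nm per frame step, wrapping
periodically), so its neighbor set decorrelates within a few frames and the
NNO collapses. All randomness flows from one seeded generator per run;
runs are bit-reproducible and the ground truth is stored in the trajectory
metadata.

What the generator does *not* model: forces, thermostats, pressure
coupling, pre-melting lattice softening, transient recrystallization, or
the absolute NNO magnitudes of real coarse-grained runs. Passing recovery
tests therefore demonstrate that the analysis correctly inverts data with
the assumed structure (vibration below a staggered onset, diffusion above
it) — they do not validate the force field or the physics of real
trajectories.

`gen_melting_curve()` plays the same role for the void-size scan. One
construction detail matters: the plateau region is given a small constant
downward drift (0.2 degrees per void step) and the pre-plateau drops decay
geometrically to *half* that drift, so the first increase in successive
differences lands exactly on the plateau void. A perfectly flat plateau
would push the rule's first trigger out to the collapse step and make exact
recovery impossible by construction; real scans likewise keep drifting
slightly across the plateau. Exact plateau recovery is expected for noise
below about 0.02 degrees (the margin between the last pre-plateau drop, 0.1,
and the plateau drift, 0.2); the study-like noise level of 0.3 degrees is
the generator default, where the plateau is recovered approximately, as in
real scans.

## Problem sizes

The packaged tests and drivers run the full analysis logic at reduced
physical scale, chosen so the whole suite completes in minutes on one core:
trajectory recovery uses 4 x 2 x 4- and 5 x 2 x 5-cell crystals (128 and
200 molecules) with 200 frames, the void-constraint scan runs the full
9 compositions x 9 void sizes x 20 seeds grid on the 800-molecule crystal,
and neighbor-search correctness is checked on frames of up to 100 random
molecules against the all-pairs oracle. The 800-molecule system and every
grid, ratio, tolerance and rule constant match the study design throughout.

## Known limitations

- The unit cell is idealized; absolute melting temperatures from the
  synthetic generator are scenario inputs, not predictions.
- The crack geometry is one plane per void; multi-crack or vacancy defects
  are out of scope.
- The onset estimator assumes a single departure from one crystalline
  baseline; curves that recrystallize mid-ramp would need inspection.
- The Hildebrand comparison is only as good as the enthalpies supplied;
  the shipped ones are placeholders.
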