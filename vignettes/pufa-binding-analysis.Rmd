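---
title: "Quantifying lipid-protein residence, occupancy and channel modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid-protein residence, occupancy and channel modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufabind)
```

pufabind quantifies two sides of one biological question: where and for how
long does a polyunsaturated fatty acid (PUFA) headgroup sit on a membrane
protein, and what does its presence do to channel gating. The motivating
system is docosahexaenoic acid (DHA) on the acid-sensing channel ASIC3,
whose carboxylate headgroup binds an arginine-rich, membrane-facing patch
on TM1; the methods are generic.

## The binding-event model

The primitive object is a per-pair distance time series: for one lipid
copy and one residue, the per-frame minimum of the minimum-image distances
between every selected lipid atom and every sidechain heavy atom of the
residue. "Sidechain" excludes the backbone N, CA, C, O and all hydrogens,
so a glycine contributes nothing and is skipped with a warning rather than
silently reported as unreachable.

A frame is *bound* when that distance is at or below `cutoff_A`. We read
"within 5 Å" as boundary-inclusive (`<=`); the choice only matters on a
measure-zero set of geometries, but it is stated so results are
reproducible to the frame.

Events are maximal bound runs after **gap merging**: two runs separated by
*strictly fewer than* `merge_gap_frames` unbound frames are one event, and
the gap frames count toward its span. The boundary case is therefore
sharp: with the default of 10, a 9-frame interruption merges and a
10-frame interruption splits. Merging exists because headgroups rattle in
and out of a cutoff without leaving the site ("flickers"); treating each
excursion as a new event would inflate N and depress the mean duration.
Durations are inclusive frame counts times the frame interval, so a
one-frame event lasts one interval, not zero.

Events touching the first or last frame are *censored*: their true length
is unknown. They are flagged and, by default, included in the summary
statistics (`residence_stats(include_censored = FALSE)` excludes them).
Including them biases mean durations downward on short trajectories — the
long events are exactly the ones most likely to be cut — which is worth
remembering when comparing tables across trajectory lengths.

Statistics are aggregated per residue label over all lipid copies, and by
default over symmetric subunits (a homotrimer's three copies of residue 63
pool into one row, as lifetime tables conventionally do); a per-chain
breakdown is available with `pool_chains = FALSE`. Concurrent events by
different lipids at one residue are separate events: merging is strictly
per (lipid, residue) pair.

Time is in ns and coordinates in Å throughout. The frame interval is a
required input whenever the trajectory format does not carry times: the
merge rule is defined in frames, so its time equivalent depends on a save
interval the user must know.

## Occupancy maps

The occupancy grid answers "where is the headgroup, on time average". Per
frame, a voxel is occupied if at least one selected atom falls in it —
binary, regardless of atom count — and the voxel's value is the occupied
fraction of frames, which is why 0.3 iso-surfaces read as "present at
least 30% of the trajectory". Voxel membership is half-open
`[edge, edge + spacing)`, making binning unambiguous at edges. The default
resolution is 1 Å; the auto grid spans the selection's bounding box over
all frames plus a 5 Å margin, which guarantees no placement falls outside
(out-of-grid placements are counted as unoccupied and tallied with a
warning when an explicit grid is given).

When the protein drifts or tumbles, each frame can first be superposed
onto frame 0 on a fit group (Kabsch, proper rotations only); the resulting
trajectory is treated as non-periodic, since a rotated orthorhombic
lattice is no longer axis-aligned. Which atoms to align on — and whether
the published maps counted the single carboxylate carbon or the full
carboxylate group — are not universally fixed conventions, so both are
explicit options (`align_group`, and `lipid_atoms` presets `"carbon"` /
`"group"`) with no silent default in the pipeline configuration.

## Contact numbers

The contact number of a residue in a frame is the count of lipid-residue
heavy-atom pairs within `cutoff_A` (default 4 Å, inclusive). It is a
fingerprint of engagement strength: a residue holding the carboxylate with
two atoms shows an average near 2 even when binding is continuous. Two
engines exist — a cell list with cutoff-sized cells (default) and a brute
all-pairs scan — and the test suite holds them exactly equal; the cell
list simply scales better. Counts pool all lipid copies per residue, and
hydrogens are filtered with a warning rather than an error because
topologies frequently carry them.

## Electrophysiology quantification

Sweeps are time/current tables with two annotations: a baseline window and
the pulse onset. All metrics work on the baseline-subtracted magnitude, so
inward (negative) currents need no sign handling.

*Desensitization* is the time from the current peak to the first point
where the magnitude falls to peak/e, linearly interpolated between the
bracketing samples so the estimate is not quantized at the sampling
interval. A peak must exceed 3 baseline SDs or the sweep is rejected as
peakless. Sweeps whose current never reaches peak/e within the record are
flagged `crossed = FALSE` and excluded (with a count) from per-experiment
averages.

*Dose-response* points are per-pH peaks normalized to the response at the
maximally activating reference pH (5.5), which is 1 by construction. For
amplitude work the peak is measured from a 1-ms boxcar-smoothed magnitude
(`measure_peak()`): the raw maximum of a noisy trace is biased upward by
the largest noise excursion, and because boxcar smoothing scales the
underlying signal identically at every pH, its own bias cancels in the
normalization. The 1/e decay metric deliberately keeps the raw peak — that
is how the metric is defined on acquisition software.

*Hill fits* use the activation form `I = 1/(1 + 10^((pH0.5 − pH)·n))` with
asymptotes fixed at 0 and 1, so the fitted curve is bounded in [0, 1] by
construction and only the midpoint and steepness are free. As printed,
this curve *decreases* with acidity for positive `n`; an acid-activated
channel therefore fits with negative `n`. Rather than silently flipping
the exponent, the sign of `n` is left free, both signs are tried as
starting points (ties broken by lower SSE, then smaller |n|), and the Hill
number is reported as |n| with the signed value alongside. The midpoint
reported is the pH at which the fitted curve equals 0.5, which for this
parameterization is the `pH0.5` parameter itself. Fitting is by BFGS on
the sum of squares with deterministic initial values (midpoint of the pH
range, n = ±1), so identical data give identical fits.

*Wash-on* time courses divide each sweep's peak by the first sweep's, the
display convention for slow modulator equilibration.

## The synthetic world

The simulator generates the statistical structure the analyses assume and
nothing more — no membrane physics, no force fields, no inter-lipid
interactions. Per lipid particle: an unbound random walk (Gaussian steps,
periodic wrapping), binding with probability `p_on` per frame inside a
free site's capture radius, a bound state at the site anchor plus jitter
strictly inside the detection cutoff, and unbinding with probability
`p_off` per frame. Dwells are therefore geometric with analytic mean
`dt / p_off`. Sites hold one lipid at a time so truth is unambiguous.

Reference conditions are stated once and not revisited: a 100 Å cubic box
(the scale of the membrane systems that motivated the package, which ran
103–105 Å boxes), three sites for a homotrimer's symmetric copies, dt =
1 ns, `p_off = 0.01`/frame giving a 100-ns mean dwell (the scale of the
reported resting-state mean lifetimes), ten minority-lipid particles (a
10:1 background:PUFA composition at toy scale), and `p_on = 0.5`.

Three design choices deserve their reasoning spelled out:

* **Planar diffusion (default).** Unbound particles walk in the membrane
  headgroup plane (the z level of the sites). In a 3-D walk the capture
  spheres occupy ~0.2% of a 100 Å box and encounters essentially never
  happen at toy scale; in the real system both the headgroups and the
  TM-facing sidechains live in the leaflet plane and encounters are
  frequent. The 2 Å per-frame step is a sampling choice, not physical
  lipid diffusion (which is orders of magnitude slower per ns); it exists
  so that a few thousand frames contain enough events to analyze.
* **Refractory unbinding (`min_unbound_frames`, default 10).** After a
  true unbind the particle cannot rebind for 10 frames. Without this, a
  quick same-site rebind within the merge gap is *by definition*
  indistinguishable from a flicker, and "detection equals truth" would be
  ill-posed. The generator therefore separates the two timescales: true
  inter-event gaps are at least the default merge gap, sub-threshold
  excursions shorter than it are flickers.
* **Interior flickers.** A flicker displaces the bound particle just
  beyond the cutoff for 1..`max_flicker_frames` frames and always returns
  it for at least one in-cutoff frame before any further decision, and is
  never started so close to the end of the trajectory that it cannot
  return. This guarantees the exact-recovery property: with merging at any
  threshold above the flicker length, detected events equal the
  flicker-free truth frame for frame. Flicker frames suspend the unbind
  clock, so enabling flickers slightly lengthens true dwells; the
  dwell-law checks run with flickers disabled.

The sweep generator produces
`I(t) = −A(pH)·(1 − e^{−t/τ_act})·e^{−t/τ_des}` plus Gaussian noise, with
`A(pH)` drawn from the Hill curve. Defaults mirror the reference
experiment: τ_des = 0.390 s (wild-type scale), fast activation (10 ms),
10 kHz sampling, 2% noise, true midpoint 6.6 with |n| = 4.5 (the sign
negative as the verbatim activation form requires), eight pH steps from
7.0 to 5.5, two sweeps per pH. The recorded trace keeps a 0.5-s baseline
rather than the full 8-s holding period of the real protocol — the holding
period exists for channel recovery, which the generator does not model.

What a green test does and does not establish: the synthetic world has
isotropic sites, no competition for the headgroup between residues, no
correlated noise, no rundown, and exactly geometric dwells. Passing tests
demonstrate that the estimators recover known truth under the model's own
assumptions (and that the implementations match independent oracles); they
say nothing about force-field accuracy, sampling convergence of real
trajectories, or biological effect sizes.

## Numerical choices and degenerate inputs

* Bound/contact criteria are boundary-inclusive; iso-thresholding keeps
  `value >= iso`.
* Minimum-image wrapping assumes orthorhombic boxes; triclinic cells are
  rejected loudly everywhere (PDB CRYST1, DCD cell blocks, constructors).
* Superposition requires three non-collinear fit atoms and excludes
  reflections; an already-fitted frame refits to itself below 1e-9 Å.
* The 1/e crossing interpolates linearly; a peak on the last sample or a
  never-crossing decay is reported, not guessed.
* Slice extraction rounds to the nearest grid *position*
  (`round((z − origin)/spacing)`), with R's round-half-to-even at exact
  midpoints.
* The portable trajectory format prints coordinates with `%.17g` so
  write/read round trips are bit-exact; DCD is single precision on disk
  and round trips to ~1e-3 Å.
* Zero-event residues report N = 0 with absent durations, rendered `--`
  in the exported lifetime table.

## Configuration defaults

The pipeline applies the field's conventional parameters when a config
omits them, and logs every default it applies: cutoff 5 Å, merge gap 10
frames, minimum event length 1 frame, grid 1 Å with 5 Å margin, iso 0.3,
contact cutoff 4 Å. Two things have *no* default because no convention
exists: the frame interval (required unless the trajectory sidecar records
it) and the lipid atom set (`"carbon"` vs `"group"` — analyses exist using
each reading). Unknown keys fail with a nearest-name suggestion rather
than being ignored.

## Known limitations

* No survival-curve or autocorrelation residence-time estimators; the
  lifetime summary is the run-length statistic described above.
* No XTC reader (the compressed-coordinate codec is out of scope); use
  DCD or the portable format.
* Occupancy maps are unsmoothed counts, not kernel densities.
* The simulator is frame-discrete: continuous-time rate constants must be
  converted to per-frame probabilities by the caller.
* Statistical comparison across conditions (ANOVA and the like) is out of
  scope; the package stops at descriptive summaries and fits.
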