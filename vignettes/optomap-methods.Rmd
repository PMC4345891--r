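---
title: "Methods: stimulus-response mapping with optomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus-response mapping with optomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomap)
```

## The problem

Patterned optogenetic stimulation projects arbitrary binary illumination
patterns onto a sample through a digital micromirror device (DMD) while an
electrophysiology amplifier records the membrane potential of a patched,
opsin-expressing neuron. Mapping which illuminated regions depolarize the
cell — and by how much — requires coordinating three things: the geometry
(regions of interest on the camera image, rasterized to micromirror
patterns), the schedule (which pattern is exposed when, with a TTL trigger
marking each exposure), and the analysis (cutting the recorded trace into
per-stimulus epochs and reducing each to a response statistic, displayed as
a heat map over the field of view).

optomap implements that computational chain hardware-free. In place of the
DMD/DAQ/amplifier it provides a rig simulator, so every downstream stage —
trigger detection, epoch extraction, artifact rejection, heat mapping,
paired-stimulation integration analysis — can be exercised and validated at
desk scale against known ground truth.

## Coordinates and geometry

All geometry is 0-based with half-open pixel intervals `[x0, x1)`, origin
top-left, x along columns, y along rows; a pixel `(r, c)` has its center at
`(c + 0.5, r + 0.5)`. The source system never states a convention, so this
one is fixed here once.

**Rasterization.** A DMD pixel is ON when its center, mapped to camera
coordinates through the inverse of the camera-to-DMD affine calibration,
lies inside the ROI. Rectangles and ellipses use inside-or-on boundaries
(`(dx/rx)^2 + (dy/ry)^2 <= 1` for ellipses); polygons use the even-odd
crossing rule, which handles self-intersecting outlines predictably. Grid
cells rasterize with half-open rectangle membership instead, so adjacent
cells never share a micromirror. An ROI that covers no DMD pixel is a
warning, not an error: it is legitimate (if useless) geometry.

**Grid arithmetic.** Splitting a span of `W` whole pixels into `n` cells
uses an integer partition: every cell gets `floor(W/n)` pixels and the
remainder goes to the lowest-index rows/columns, so sibling cells differ by
at most one pixel and the tiling is exact and order-independent.
Subdivision below one pixel per cell is refused — the micromirror is the
resolution limit. Because of the one-pixel remainder, a grid does not have
one single cell size; when a single number is wanted (as printed on
figures), `grid_cell_size_um()` reports the *modal* leaf dimension, and
`cell_dimensions_um()` reports any one cell exactly, rounded to the nearest
micrometre with ties away from zero. At 1 μm per camera pixel a
2172 × 1653 px field divides 3 × 3 into 724 × 551 μm cells, one further
3 × 3 subdivision gives 241 × 184 μm, and a second gives 80 × 61 μm:

```{r grid}
g <- grid_create(c(0, 0, 724, 551), 3, 3)
grid_cell_size_um(g)
```

Merging requires sibling leaves whose union is exactly a rectangle (checked
by area conservation, which suffices because siblings are disjoint tiles);
merging all children turns the parent back into a leaf, so
subdivide-then-merge restores the original tiling.

## Protocols

A protocol is an explicit event timeline; nothing in the package depends on
a real-time clock. Choices that the source system leaves open, fixed here:

* the inter-stimulus interval is **onset-to-onset**;
* the trigger-to-onset delay (`trig_delay`) defaults to **0 s** — the
  trigger exists so external equipment can prepare, and epoch alignment
  adds it back explicitly;
* randomization is an explicit-seed **Fisher–Yates** shuffle, applied
  **independently per repeat**, with the realized order stored in the
  protocol metadata (this is what lets epoch extraction invert it);
* the first onset defaults to 0.2 s so the first epoch has a baseline
  window;
* a paired protocol with latency shorter than the exposure deliberately
  overlaps the two exposures (the simulator sums the drives); a latency of
  exactly zero is allowed as the degenerate pair — the two events then
  share a trigger time, which segmentation cannot distinguish, so a grouped
  mask is the practical route for truly simultaneous stimulation.

The integration battery schedules, per repeat and in randomized order,
pattern A alone, B alone, and the grouped A∪B mask, which is what the
supralinearity analysis consumes.

## The rig simulator

The simulated cell is a leaky integrator with a spatial photosensitivity
map over DMD pixels:

$$\frac{dV}{dt} = \frac{V_\mathrm{rest} - V}{\tau_m} + g \sum_{\text{active exposures}} \frac{\langle \text{mask}, S\rangle}{\sum S}$$

The drive of a mask is its sensitivity-weighted overlap normalized by total
sensitivity, so full-field illumination drives at exactly `gain` (mV/ms)
and steady-state depolarization under constant drive is
`tau_m * gain * overlap` — every parameter stays interpretable. Integration
is forward Euler at the recording sample rate (default 10 kHz, implemented
as a first-order recursive filter), adequate for `tau_m >= 5 ms`; at
10 kHz and `tau_m = 20 ms` the peak response matches the closed-form
saturating exponential within 1%. The trigger channel carries 5 V
TTL-like pulses of `min(5 ms, exposure)` at each trigger time.

Spiking, when enabled, inserts a stereotyped triangular waveform (default
+100 mV over 2 ms) at the threshold crossing, then clamps to rest for a
5 ms refractory period. Under sustained suprathreshold drive the cell
therefore fires tonically — intended, since the artifact-rejection logic
must see realistic repeated spikes. Gaussian noise (`noise_sd`, mV) is
added to the recorded voltage as *measurement* noise rather than injected
into the integrator: the dynamics stay deterministic, superposition is
exact with spiking disabled (the basis of the linearity tests), and the
recording is bit-identical under a fixed seed.

What the simulator does **not** emulate: channelrhodopsin kinetics
(activation/desensitization time constants), optics (point-spread,
scattering, out-of-focus light), conductance-based or morphological neuron
models, and camera images. Passing tests therefore validate the analysis
chain's bookkeeping and arithmetic on a known linear(-plus-spike) system;
they do not certify quantitative agreement with any biological recording.

## Epoch extraction

Trigger detection finds rising crossings (`x[k-1] < thr <= x[k]`); the
default threshold is the midpoint of the trace's min and max, which is
robust for clean TTL pulses and overridable for anything else. A debounce
window (`min_gap`, defaulting to half the protocol ISI) absorbs glitches
inside a pulse. Association is strictly ordinal — the k-th trigger is the
k-th scheduled event — with a hard error on any count mismatch, because a
silent misalignment would corrupt every downstream statistic. Epochs span
`[onset - pre, onset + post)` with `onset = trigger + trig_delay`; windows
default to 50 ms / 500 ms and must be configurable since the response
window Δt is an analysis choice. An epoch that would leave the recording
is excluded with a warning rather than padded.

## Evaluation

The default heat statistic is the maximum depolarization: peak voltage in
the response window minus the mean of the baseline window (defaults
Δt = 100 ms, baseline 50 ms). All evaluators are baseline-referenced and
hence invariant to constant offsets. Clipping is **off** by default in the
evaluator; 30 mV is the conventional *presentation* clip used when
rendering heat maps so that action potentials do not dwarf subthreshold
responses, and the figure path applies exactly the same
`min(heat, clip)` rule through the shared `heat_alpha()` function.

Artifact rejection discards an epoch when a spike that began before
stimulus onset overlaps the response window, or when any spike lands in the
baseline window; the two sub-rules are individually toggleable because the
source procedure specifies only "spontaneous spikes overlapping
stimulation". The spike detector (amplitude threshold −20 mV, slope
threshold 20 mV/ms) is a deliberate minimal design — threshold-plus-slope —
chosen so a slow 45 mV depolarization is not mistaken for a spike. Evoked
spikes (onset after the stimulus) never cause rejection.

Heat is the **mean of per-trial values**, not the value of the mean
waveform: per-trial evaluation preserves rejection granularity. Both the
per-trial values and the mean waveform of surviving trials are stored, so
either view is reproducible. Trial bookkeeping is conserved:
`n_trials + n_rejected` equals the epochs seen per pattern.

The integration index is `heat_AB − (heat_A + heat_B)`. With spiking
disabled the simulated cell is linear and the index is zero to within
integration tolerance; a spike threshold placed between the single and
combined drives makes it strictly positive — the qualitative signature of
supralinear dendritic summation.

Evaluators are pluggable: a spec declares ordered parameter descriptors
(name, type, default, units) that callers query *before* invocation, so
the CLI and config files can drive custom statistics (latency, rise time,
or user-registered functions) without code changes.

## Reporting and reproducibility

Heat maps color each region with a single hue whose alpha is the affine
map of clipped heat onto the color scale, clamped to [0, 1]; undefined
heats (all trials rejected) render as dashed outlines. Since there is no
interactive figure, every region's underlying waveforms are pre-exported
(overlaid trials + mean, plus a CSV) and indexed from the heat map's JSON
sidecar — the same information as click-to-inspect, in portable files.

An experiment archive holds the recording (CSV trace table at full
`%.17g` precision plus a JSON attribute sidecar), the mask TIFF stack with
its JSON sidecar, the protocol, the evaluation parameters, optional
results, and a manifest of MD5 content hashes written last and atomically —
so a partially written archive is detectably incomplete, and re-analysis
from the archive alone reproduces the stored heats bit for bit. The
experiment log is plain UTF-8 text, one ISO-8601-stamped line per entry,
append-only and flushed per entry; protocol builders, aggregation and
archiving auto-log when `options(optomap.log = )` is set.

## Problem sizes and validation design

The test suite runs entirely at desk scale, chosen to keep the full
validation fast while leaving every mechanism exercised: DMD grids up to
128 × 128 for the exhaustive rasterization oracle (200 random shapes
against per-pixel membership, with `mgcv::in.out` as the independent
polygon oracle); 50 randomized protocols for the simulate → detect →
segment round-trip at 1 kHz; and a 100-run parameter-recovery suite — a
Gaussian sensitivity blob at a uniformly random position in a 72 × 72 px
field, a 9 × 9 grid battery with 3 repeats at 2 kHz and 1 mV recording
noise — requiring the hottest cell to contain the blob center in at least
95 of 100 seeded runs. The blob (σ = 3 px against 8 px cells, peak
depolarization ≈ 20 mV) reflects a soma-sized hotspot with a comfortable
but not overwhelming signal-to-noise ratio; runs whose blob lands within a
fraction of a pixel of a cell edge can legitimately resolve to a
neighboring cell, which is why the criterion is 95% rather than 100%.

## Known limitations

* The drive model has no opsin kinetics, so absolute simulated voltages are
  not comparable to biological recordings; only relative/spatial structure
  and the analysis arithmetic are validated.
* Ordinal trigger-event association assumes no spurious or missing
  triggers; the count check turns such faults into hard errors rather than
  recovering from them.
* Simultaneous (zero-latency) paired exposures are expressible but not
  segmentable from a single trigger channel; use a grouped mask.
* Archive hashes are MD5: an integrity check against corruption, not a
  cryptographic guarantee.
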