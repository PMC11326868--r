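---
title: "Excitatory-inhibitory integration in medial olivocochlear neurons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitatory-inhibitory integration in medial olivocochlear neurons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Medial olivocochlear (MOC) neurons are the brainstem efferents that inhibit
cochlear outer hair cells.  They receive fast excitation from cochlear-nucleus
T-stellate cells and disynaptic inhibition via the MNTB, and how those two
streams align in time decides when and how fast an MOC neuron fires.  `mocsyn`
implements the full computational workflow for studying that question: a
compartmental conductance-based MOC neuron model with excitation-inhibition
(E-I) latency-sweep protocols, a postsynaptic-current (PSC) analysis pipeline
(detection, kinetic feature extraction, gap-statistic/k-means clustering,
random-forest classification), relative-fluorescence quantification for
calcium imaging, and synthetic-data generators that emulate each recording
modality with known ground truth.

This vignette is the package's methods account: the models and their
assumptions, the parameters that matter, the numerical choices, and the
limitations we know about.

```{r setup}
library(mocsyn)
```

## The compartmental MOC neuron model

### Morphology and passive properties

The model cell follows the published description of a reconstructed MOC
neuron: a cylindrical soma (33.6 x 6.1 um), a 180 x 1 um axon, and three
primary dendrites (lateral 12.8, dorsal 10.1, medial 7.3 um; 1 um diameter)
that branch into daughter dendrites.  Discretised with one segment per
section, the cell has exactly 86 segments.  Axial resistivity is 210 Ohm cm,
specific capacitance 1 uF/cm^2, and simulations run at 35 C (channel rates
defined at 22 C are scaled by a Q10 of 3).

```{r}
model <- build_model()
model
```

The exact branching topology of the original reconstruction is not published,
so the fixture is an approximation constrained three ways: the stated section
counts (46/25/10 daughters per primary), the 86-segment total, and — decisive
for the physiology — the cell's effective capacitance.  The published
input-output gains (a 1.5 nS peak excitatory conductance producing a ~1.9 mV
somatic EPSP with a ~15 ms decay) pin the product of capacitance and input
resistance tightly; they are only reproducible near the top of the stated
daughter dimension ranges (31.4 um long, 2 um wide, ~17,300 um^2 total
membrane).  We therefore fix the daughters there and treat the published
dimension ranges as spanned by the tree as a whole (primaries at 1 um,
daughters at 2 um).  This is the single largest structural uncertainty in the
model and the root cause of its residual misfits (below).

### Channels

The membrane carries the standard auditory-brainstem channel set — fast
transient Na+, high- and low-threshold K+ (KHT, KLT), HCN and leak — using
the classic ventral-cochlear-nucleus kinetic schemes.  The published density
table for this cell has typographically corrupted units (cS, kS and nS per
cm^2 appear), so the working densities are treated as free parameters and
fixed by system identification: they were optimised once so that the
*printed synaptic input parameters* reproduce the *printed model output
waveforms*.  The literal table is kept for reference:

```{r}
moc_table_densities()
```

Two deliberate choices depart from the donor kinetic schemes:

* **E_K = -90 mV** (rather than the scheme's -70 mV), the physiological
  potassium reversal for a high-potassium internal solution.
* **`kbl_lt`** exposes the KLT activation rate as a named multiplier, since
  the source lists an explicit activation-rate entry (0.6 ms^-1) for this
  channel.

A per-compartment-group voltage shift for the Na+ activation and inactivation
curves (`na_mshift`, `na_hshift`) is available for axon-initial-segment-type
configurations, but the calibrated model does not need it (defaults 0).

### The near-threshold amplification regime

The identified operating point places the cell in a regime worth stating
explicitly, because it explains several otherwise puzzling published numbers
simultaneously.  With a uniform Na+ density of 0.161 S/cm^2 the resting cell
is stable, but subthreshold depolarisations ride a strong Na+ window
amplification whose gain grows toward a fold (ignition) near -56 mV:

* a single evoked EPSP (peak ~-58 mV) is amplified but safely subthreshold —
  the growth rate of the instability at that voltage is slow compared with
  the PSP duration;
* the E/I amplitude ratio exceeds the passive prediction, as in the
  reference values (1.91 / 0.269 = 7.1 against a passive ~6.6), because only
  depolarisations are amplified;
* the evoked EPSP decay is stretched by critical slowing (the fitted decay
  roughly doubles the passive membrane constant), while the much faster
  miniature EPSP mixes in fast charge-redistribution modes and decays in
  ~8-9 ms;
* 100 Hz trains of the same EPSPs summate to a plateau that crosses the fold
  after two to four pulses, producing first-spike latencies of tens of
  milliseconds and sustained ~28 Hz firing — and a ~0.5 mV standing
  inhibition is enough to delay ignition by many milliseconds, which is
  exactly the E-I timing sensitivity the protocols measure.

### Numerics

The cable equation is integrated implicitly (backward Euler) over the
Hines-ordered tree, with gating states advanced by exact exponential
relaxation against the voltage at the start of each step (the standard
staggered scheme) and double-exponential conductance synapses carried as
pairs of analytically decayed states.  The default step is dt = 0.025 ms.
The integrator was validated against an independent dense linear-ODE solution
on a passive tree (maximum deviation ~6e-4 mV), and on the calibrated model
halving dt changes the evoked-PSP amplitude by under 0.1% and the AP count of
the train protocols not at all.

Holding at -60 mV uses bisection on a constant somatic current until the
settled somatic potential is within 0.1 mV of target; the settled state is
reused as the initial condition of protocol simulations.

PSP amplitudes are extrema relative to the pre-onset baseline.  Decay time
constants come from a single-exponential least-squares fit (amplitude and
offset profiled out, tau optimised on a log grid) starting at the
90%-of-peak crossing of the relaxation, with the fit window capped at five
fitted time constants (two passes); the same convention is used for recorded
and simulated waveforms.  AP detection uses an upward threshold crossing at
-10 mV with a 1 ms refractory.  Because the source does not disclose its
AP-rate formula, both `(N-1)/(t_last - t_first)` (primary) and `N/window`
are reported.

### Calibration

`calibrate_model()` formalises the identification.  Stage 1 (optional)
re-fits subthreshold density scales so the printed evoked inputs reproduce
the evoked amplitude targets; the shipped defaults are already its product.
Stage 2 fits the miniature synapses: each class's weight is root-found so the
simulated mini amplitude matches the recorded mean exactly, and the mini
decay constant is optimised under the constraint that a single-vesicle event
cannot outlast the compound evoked conductance of its class
(`tau_decay <= 6` ms for excitation, `<= 3.64` ms for inhibition).

```{r, eval = FALSE}
cal <- calibrate_model(build_model())
tidy(cal)
```

For the mEPSP the recorded decay (8.65 ms) is reachable and fitted.  For the
mIPSP the bound binds: the recorded 18.1 ms mini decay exceeds anything this
membrane can produce, and the model returns its membrane-limited ~11 ms with
the residual reported.  The reference model shows the same failure mode
(model 14.4 ms against recorded 18.1 ms); ours is more severe because of the
capacitance ceiling discussed above.

### Known residual misfits

With the 86-segment, range-capped morphology the model cannot match every
published output simultaneously.  Three quantities sit outside a 10% band of
their reference values and stay there across the entire accessible parameter
family: the control evoked-PSP amplitude (ours ~1.84 mV vs 1.64 mV), the
EPSP-only amplitude (~2.11 vs 1.91 mV, marginal), and the mIPSP decay
(~11 vs 14.4 ms).  All three trace to the same constraint: amplitude and
decay scale oppositely with total conductance at fixed capacitance, and the
geometry cap fixes the capacitance ~10-15% below what the published
input-output pairs jointly imply.  We report these honestly rather than
distorting the stated morphology further.

## Protocols

`run_evoked_psp()` simulates single combined PSPs (control pairs the EPSP
with an IPSP lagging by the midline-evoked median E-I latency of +2.8 ms);
`run_ei_single_sweep()` and `run_ei_train_sweep()` step the E-I latency
difference from -10 to +10 ms in 1 ms increments (positive: excitation
first), the latter with 20-pulse 100 Hz trains and an optional IPSP weight
scale of 0.51 to mimic depressed inhibition.  First-AP latency is referenced
to the first EPSP onset; simulations run to the train end plus a 100 ms tail.
Named presets for these protocols ship as YAML under
`inst/extdata/protocols/`.

```{r, eval = FALSE}
h <- set_holding(model)
sweep <- run_ei_train_sweep(model, holding = h)
plot_ei_sweep(sweep)
```

In the calibrated model, inhibition at any latency reduces the AP rate and
delays the first spike relative to the EPSP-only train; the most effective
latencies are near -10, -1 and +9 ms and the least effective near -6 and
+4 ms, reflecting the 10 ms period of the train.  The modulation depth with
delta is shallower than in the reference figures (~0.3 Hz against ~3.5 Hz),
another consequence of the capacitance-limited operating point.

## The PSC analysis pipeline

**Detection** (`detect_events()`) thresholds deviations from a local
baseline (median of the preceding 2 ms) at 2x the baseline RMS noise, in the
polarity expected for the holding potential (-60 mV: inward; 0 mV: outward,
chloride-mediated).  Candidates come from a lightly smoothed trace (0.1 ms
boxcar), must be at least one refractory period apart, and pass a minimal
shape filter — the deflection must persist over 0.3-1.3 ms after the peak at
half the detection threshold — standing in for the unspecified accept/reject
heuristics of the commercial software this emulates.  **Features**
(`extract_features()`): onset is the last 10%-of-peak crossing before the
peak (linearly interpolated), rise time spans 10-90% of peak, amplitude is
peak minus local baseline, and the decay constant is fitted as above over at
most five estimated tau or up to the next event.  Events more than 20 ms
after the preceding stimulus are flagged spontaneous and excluded from
evoked analyses.

**Clustering**: each cell's events are sorted by `gap_select_k()` (gap
statistic with a uniform-over-range reference, best-of-25 k-means per k,
1-SE selection rule, smallest qualifying k; the method can select one
cluster) followed by `kmeans_cluster()`, with clusters re-indexed by
ascending mean onset latency.  The default feature set is onset latency,
rise time and decay tau, z-scored; amplitude can be added with a flag — the
source lists amplitude among the imported variables but states that sorting
excluded it, and we follow the sorting statement while keeping the option.
Cluster summaries report onset jitter (SD of onset latency), peak jitter
(SD of onset latency + time to peak) and occurrence probability (events per
stimulus per sweep, capped at 1).  `label_clusters_by_holding()` labels a
-60 mV cluster inhibitory iff a 0 mV cluster matches it in latency within
`max(2 x pooled jitter, 0.5 ms)` — the correspondence rule has no published
tolerance, so ours is a documented default — and `ei_latency_difference()`
returns first-inhibitory minus first-excitatory onset latency (positive:
excitation first).

**Classification** (`train_ei_classifier()`): a 500-tree random forest
(`floor(sqrt(7)) = 2` features per split) over the seven variables — rise
time, decay tau, amplitude, occurrence probability, onset jitter, peak
jitter and categorical animal age — mirroring the workflow of training on
midline-evoked PSCs labeled by holding-potential correspondence and applying
the model to auditory-nerve-evoked PSCs.  `predict_ei()` reports the
fraction of trees voting excitatory; an exact 0.5 tie is classified
inhibitory and flagged (the published ">0.5" rule leaves ties undefined).
Clusters take the majority label of their events, and mixed clusters are
split into one excitatory and one inhibitory cluster.  Accuracy is reported
both out-of-bag and by resubstitution, since the published accuracy does not
say which it is.

## Calcium imaging quantification

Relative fluorescence is quantified as the ratio `F_max / F_baseline`
(`compute_dff()`), with the baseline the mean of the first 15 frames (~5 s)
and the maximum taken within the stimulation window.  The published group
values (~1.0-1.2) behave as ratios on this scale, and their ~68%/75%
suppression figures are reproduced by operating on the evoked component
above 1: `percent_suppression()` computes
`100 * (dff_control - dff_blocked) / (dff_control - 1)`, clipped to
[0, 100], returning `NA` when there is no evoked signal.  This ratio reading
is an inference from the printed numbers and is flagged as such.  ROIs are
active if fluorescence exceeds two baseline SDs above the baseline mean in
at least two of three stimulation bouts (`classify_active()`).  Polygon ROIs
rasterise by the even-odd pixel-centre rule.

## Synthetic data: what it does and does not emulate

The generators provide every input the pipeline needs with known ground
truth.  `generate_sweep_set()` renders stimulus-locked PSCs in latency
clusters (Gaussian onset jitter, per-stimulus independent Bernoulli
occurrence, truncated-normal amplitude magnitudes, unit-peak biexponential
waveforms) with polarity applied at render time from the holding potential
against class reversals of 0 mV (excitatory) and -20 mV (inhibitory, the
chloride reversal of the emulated internal solution), scaled by driving
force and normalised to magnitude 1 at -60 mV.  Default cluster parameters
are the recorded midline-evoked population statistics (excitatory latency
1.92 +/- 0.25 ms, probability 0.80; inhibitory 4.47 +/- 0.50 ms, 0.45).
Noise is Gaussian, low-pass filtered with a 4-pole Butterworth at 10 kHz
(emulating the recording chain's on-line filter; the trace is rescaled to
the requested RMS afterwards, which also fixes the noise calibration
exactly).  Events sum linearly — a clamped-cell assumption — and there is no
dendritic filtering, series-resistance artifact, or spontaneous background
activity; passing tests therefore demonstrate correctness of the analysis
logic, not robustness to every pathology of real recordings.  The amplitude
distribution is a truncated normal because only medians and dispersions of
the recorded amplitudes are published.

`generate_feature_table()` draws labeled classifier features from per-class
truncated normals parameterised by the same recorded statistics.
`generate_calcium_movie()` produces ROI traces with three stimulus-locked
bouts, a per-ROI baseline, exponential transient decay (3 frames) and frame
noise (default 0.3 fluorescence units, ~0.3% of baseline — appropriate for
ROI-averaged fluorescence, and small enough that the max-statistic bias of
the ratio estimator stays inside the pipeline's 2-point recovery
tolerance); a pixel-level path with polygon ROIs is available through
`rasterize_roi()`/`compute_roi_traces()`.

## Problem sizes used by the test suite

The packaged tests exercise the pipeline at reduced but statistically
adequate sizes chosen as the package's own defaults: gap-statistic recovery
uses 50 seeds of 40-120-point mixtures with 30 bootstrap references and 10
k-means starts (the analysis default for real cells remains kmax = 10,
B = 500, nstart = 25); detection operates on 100-sweep sets at SNR 5;
classifier checks use 500 training rows per class; calcium recovery uses 100
ROIs.  The train sweep runs all 21 latencies at full resolution.

## Limitations

* The morphology is an approximation under a hard segment-count constraint;
  its capacitance ceiling produces the documented residual misfits.
* Channel kinetics are adopted schemes, not fits to MOC voltage-clamp data.
* The near-threshold operating regime makes train statistics sensitive to
  parameter changes of a few percent; this matches the reference behaviour
  but means the model should be re-validated after any density change.
* Detection is threshold-based; overlapping events are not decomposed, and
  deconvolution/template approaches are out of scope.
* The 0.51 IPSP scale is a static stand-in for synaptic depression; no
  short-term plasticity is modelled.
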