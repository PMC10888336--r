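---
title: "Methods: mechano-functional characterization of neuronal networks in hydrogels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechano-functional characterization of neuronal networks in hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelfun)
```

## Scope

`gelfun` characterizes 3D neuronal cultures grown in soft hydrogel scaffolds
from two complementary angles: the *mechanics* of the scaffold, measured by
small-amplitude oscillatory shear (SAOS) rheology, and the *function* of the
neuronal network living inside it, measured by calcium imaging and reduced to
directed effective-connectivity graphs. Raw recordings of this kind are rarely
shared, so the package also ships a seeded synthetic-data generator that
emulates the whole experiment with known ground truth. Every processing stage
is validated against that truth; this vignette explains the models, the
tunable parameters, and the design decisions behind them.

## Rheology

### Model

Under SAOS, a viscoelastic gel driven at strain
$\gamma(t) = \gamma_0 \sin(\omega t)$ responds with stress
$\sigma(t) = \gamma_0\,[G'(\omega)\sin(\omega t) + G''(\omega)\cos(\omega t)]$.
The storage modulus $G'$ captures elastic energy storage, the loss modulus
$G''$ viscous dissipation; for the fibrin-based gels emulated here
$G' \approx 10\,G''$ throughout. The complex shear modulus has magnitude
$|G^*| = \sqrt{G'^2 + G''^2}$ and converts to an axial (Young's) modulus via

$$E = 2\,|G^*|\,(1 + \nu),$$

with Poisson ratio $\nu = 0.25$, the standard value for fibrin matrices. With
$G''/G' = 0.1$ this makes $E \approx 2.51\,G'$.

### Reduction pipeline

Three standard tests are reduced (`run_rheology()` chains them per
day-in-vitro, DIV, with 3 replicates each):

* **Time sweep** ($\omega = 2\pi$ rad/s, $\gamma_0 = 5$\%, 15 min): the gel
  relaxes toward mechanical equilibrium. `detect_transient()` reports the
  settle time $t_T$, defined as the earliest time after which $G'$ stays
  within $\pm 5\%$ of the terminal plateau (mean of the last quarter of the
  record). Because a measurement with 5% multiplicative noise leaves a
  $\pm 5\%$ band about a third of the time *at every sample*, the literal
  "stays inside forever" rule never settles on noisy data; the default method
  therefore fits $G'(t) = G_\infty(1 + a e^{-t/\tau})$ (Levenberg–Marquardt)
  and evaluates the band rule on the fitted curve,
  $t_T = \tau \log(|a|/0.05)$. The raw empirical rule, applied to a
  running-median-smoothed series, remains available as `method = "band"`.
* **Strain sweep** ($\gamma_0$ 0.1–100\%, $\omega = 2\pi$ rad/s): verifies
  the linear viscoelastic region. `check_lvr()` reports the log–log slope of
  $G'$ vs $\gamma_0$ and flags $|$slope$| > 0.1$ or any $G''/G'$ crossing.
  Rows whose oscillation torque falls below the 2 nN·m instrument floor are
  discarded first (`filter_torque_floor()`); in practice this removes the
  lowest strain amplitudes.
* **Frequency sweep** ($\omega$ 0.6–600 rad/s, $\gamma_0 = 5$\%): the gels
  show a low-frequency plateau for $\omega \lesssim 10$ rad/s and an abrupt
  thickening above $\sim 50$ rad/s. `plateau_modulus()` averages $G'$ and
  $G''$ over the plateau band with a *geometric* mean (moduli are
  log-distributed across replicates) and reports the first frequency at which
  $G'$ exceeds the plateau by 50% as the thickening onset. $|G^*|$ entering
  the Young's modulus is taken from these plateau averages rather than a
  single frequency point, which is more robust at equal bias in the flat
  band.

Stage statistics group the per-DIV estimates into early (DIV 1–3), young
(DIV 4–8) and mature (DIV 13–20) bins — DIVs 9–12 are flagged unassigned —
and compare them with two-sided equal-variance Student's t-tests
(`compare_stages()`, Welch optional), starring $p<0.05$ and $p<0.01$.

### Synthetic sweeps

`generate_sweeps()` draws tables from a parametric truth (`rheo_truth()`):
plateau $G'_p$, fixed loss ratio 0.1, thickening
$G'(\omega) = G'_p\,[1 + ((\omega - \omega_c)/\omega_c)^2]$ above
$\omega_c = 50$ rad/s (continuous at the onset, exactly flat below it — the
transition is visible in real data but not parameterized there, so a simple
power law is used), exponential time-sweep relaxation whose settle time *is*
the `transient_time_true` parameter, a $-0.03$ log–log strain slope, and
multiplicative lognormal noise with CV 0.05 (a typical replicate scatter for
soft-gel rheometry). Torque is emulated as $\gamma_0 |G^*|$ in nN·m, which
places the lowest strain-sweep rows below the 2 nN·m floor as in real sweeps.

The built-in `rheology_preset()` trajectories emulate three gel conditions:
a soft gel whose stiffness drops early and then stabilizes ("T1",
$E \approx 300 \to 200$ Pa), a stiff gel decaying by about a factor two over
three weeks ("T2", $E \approx 590 \to 340$ Pa), and a flat, lifeless gel
("T3", $E \approx 250$ Pa throughout). These reproduce the qualitative
orderings (stiff > soft at every stage; flat trajectory shows no significant
stage differences) — the quantitative trajectories are generator inputs, not
measurements. When checking the flat preset we do not demand that *every*
p-value exceed 0.05: a 5% test rejects 5% of true nulls, so the suite instead
requires the number of rejections over 30 seeded comparisons to stay inside
the binomial false-positive envelope (at most 4) with a median p well above
threshold.

## Functional analysis

### Trace processing

Recordings emulate a single-plane fluorescence session: 15 min at 33
frames/s over a 7.1×7.1 mm field at 5.9 μm/pixel, 8-bit. A 30×30 grid of
14×14 μm regions of interest (2×2 px) is laid over the field
(`build_roi_grid()`, 900 ROIs), traces are ROI-mean pixel values
(`extract_roi_traces()`), and ROIs without significant transients are dropped
(`filter_active_rois()`: peak ΔF/F ≥ 0.1 *and* at least one detected event —
on a 900-ROI field with ~100 active cells this keeps ≈ 100).

Normalization follows $\Delta F/F_i(t) = (F_i(t) - F_{i,0})/F_{i,0}$ with two
estimators the data do not pin down by themselves:

* $F_{i,0}$ (rest level): the 10th percentile of the raw trace — robust to
  sparse transients.
* Drift: a running *median* baseline (30 s window, computed block-wise and
  interpolated), subtracted before division. A running low-percentile
  baseline would leave the noise floor sitting ~1.3σ above zero; the median
  keeps resting ΔF/F centered at exactly zero, which the event detector's
  MAD-based thresholds assume.

### Event detection

`schmitt_detect()` is a hysteretic two-threshold (Schmitt) trigger: an event
opens at the first crossing of the high threshold and closes when the trace
falls below the low one, so noise between the thresholds cannot retrigger.
Defaults, per trace: high = median + 4 MAD-sd, low = median + 2 MAD-sd of the
ΔF/F distribution, minimum duration 3 frames. Two refinements matter in
practice:

* **Onset backtracking.** A GCaMP6s-like kernel (0.2 s rise, 1.0 s decay,
  peak-normalized) crosses its detection thresholds several frames after the
  true activation, with a lag that depends on the SNR. The reported onset is
  therefore the transient *foot*: the last pre-threshold frame at or below
  median + 0.5 MAD-sd of a 3-frame-smoothed trace. At SNR 5 this recovers
  over 90% of ground-truth events within ±2 frames; without it the raw
  threshold crossing is biased ~3 frames late.
* **Dead time.** The decay tail hovers near the low threshold long enough for
  noise to re-cross the high threshold; runs starting within 0.3 s of the
  previous closure are treated as its continuation. Consequently activations
  closer than the hysteresis closure time merge into one detected cluster —
  the detector reports activation clusters, not deconvolved spike counts.

Population activity is the fraction of neurons with ≥1 event in a sliding
0.5 s window stepped by 0.1 s (no partial windows). Synchronization peaks are
local maxima exceeding mean + 3 sd of the series *and* an absolute floor of
20% of the network; without the floor, a nearly silent recording promotes
two-neuron coincidences to "peaks". Peaks closer than one window merge.
`firing_rate()` is events per neuron per minute.

### Effective connectivity

Directed coupling is inferred with a binned plug-in transfer-entropy
estimator. Rasters are binarized (bin = 2 frame periods ≈ 0.06 s; 0.03 s for
raster-level experiments), and for each ordered pair

$$\mathrm{TE}_{I \to J} = \sum p\!\left(y_{t+1}, y_t^{(k)}, x^{(k)}\right)
  \log_2 \frac{p\!\left(y_{t+1} \mid y_t^{(k)}, x^{(k)}\right)}
              {p\!\left(y_{t+1} \mid y_t^{(k)}\right)},$$

with Markov order $k = 2$ and the source history ending one bin before the
predicted target bin (the same-bin term is always excluded, so instantaneous
co-activation contributes nothing). No bias correction is applied: with
binary alphabets and $10^4$–$10^5$ bins the plug-in bias is small and common
across pairs, and the normalization absorbs it. Significance uses

$$z_{I \to J} = \frac{\mathrm{TE}_{I \to J} - \langle \mathrm{TE}_{joint}\rangle}{\sigma_{joint}},$$

where by default $\langle \mathrm{TE}_{joint}\rangle$ and $\sigma_{joint}$
are the mean and sd of the pooled pair estimates of the same recording (the
self-contained reading of "joint distribution"; a per-pair circular-shift
surrogate null is available via `te_config(null = "surrogate")`). An edge is
declared when $z > 2$, strictly — ties at exactly 2 are not significant. A
practical consequence of pooled standardization: the detection threshold
scales with the spread of the *true-edge* TE distribution, so heterogeneous
firing rates depress recall; the burst-conditioning option
(`conditioning = "exclude_bursts"`, dropping bins in which more than 40% of
the network is co-active) removes the synchronous-event component that
otherwise dominates the pool in bursty cultures, and is enabled in the
functional presets.

Graph traits follow the standard definitions on the binarized directed
matrix $A$: average connectivity $\langle k \rangle = L/N$ (each directed
edge counted once); global efficiency
$GE = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$ with unweighted directed
shortest paths and $1/\infty = 0$; modularity
$Q = \frac{1}{2m} \sum_{ij} (A_{ij} - k_i k_j / 2m)\,\delta(c_i, c_j)$ with
$k_i$ the row sums and $m = \tfrac12 \sum_{ij} A_{ij}$, evaluated exactly in
that form on the directed matrix (a `symmetrize` flag gives the undirected
convention used by some toolboxes — which of the two a given published value
used is usually not stated, so both are provided). Partitions come from the
Louvain algorithm run on the symmetrized graph with seed-controlled
tie-breaking; the reported $Q$ is always re-evaluated with the package's own
formula, and a partition scoring below the single-community baseline
($Q = 0$) is replaced by it. Networks export to GraphML/GEXF with position,
community and degree attributes for standard graph tools.

## Synthetic functional data

* **Ground-truth network** (`generate_network()`): somata uniform in a
  cylinder (radius 3 mm, height 0.6 mm), edge probability
  $\propto e^{-d/\lambda}$ ($\lambda$ = 400–600 μm) boosted ×4 within
  communities (angular sectors, guaranteed non-empty), rescaled so the
  realized density matches the request; 80% of neurons marked excitatory.
  Edge weights default to 1 — the truth is a minimal cascade whose directed
  causality the TE analysis can provably detect; heterogeneous weights widen
  the true-edge TE distribution and are available via `weight_range`.
* **Spiking** (`simulate_spikes()`): discrete-time stochastic cascade — per
  bin, $p_{fire} = p_{base} + c \cdot (\text{active presynaptic inputs at }
  t - \text{delay})$, clipped to [0, 1], with an absolute refractory period.
  Synchronous network events are a global Poisson drive recruiting a random
  60–90% subset in one bin — this reproduces sharp population-activity peaks
  without a biophysical burst model. "Strong coupling" in the recovery
  experiments means $c = 0.15$ per input at 0.5 Hz baseline: each presynaptic
  spike lifts the target's firing odds an order of magnitude above baseline
  while keeping the cascade subcritical (branching ratio
  $\approx c \cdot \langle k_{out} \rangle < 0.5$), so firing rates stay
  homogeneous — near criticality, rate heterogeneity widens the true-edge TE
  spread and the pooled z-rule loses recall.
* **Fluorescence** (`render_fluorescence()`): each event adds a
  difference-of-exponentials kernel (rise 0.2 s, decay 1.0 s, published
  GCaMP6s-like kinetics; peak = amplitude × F0, default amplitude 0.8 ΔF/F),
  plus additive Gaussian noise, plus a slow sinusoidal drift with random
  phase. `render_frames()` optionally rasterizes traces into an 8-bit TIFF
  stack (Gaussian somata, 1203×1203 px at the default field) for testing the
  image-domain entry point.
* **Presets** (`functional_preset()`): the soft condition ("T1") pairs a
  denser truth (density 0.06 at n = 60) with synchronous drive (1.5
  bursts/min); the stiff one ("T2") is sparser (0.04) with no drive and a
  lower total rate (≈ 2.1 vs ≈ 2.9 activations/neuron/min). These express
  the observed phenomenology — the soft gel supports more local connectivity
  and collective events — as generator inputs.

## What the synthetic tests do and do not show

Passing recovery tests demonstrates that each estimator inverts the
package's own forward model at realistic noise levels and problem sizes, and
that the analysis pipeline's qualitative contrasts (soft vs stiff, decaying
vs flat) survive the full chain. They do not certify performance on real
recordings, where calcium kernels vary across cells, noise is non-Gaussian
and correlated, optics blur neighbouring somata, activity is nonstationary,
and true connectivity is neither binary nor static. The generator
deliberately omits photobleaching, realistic point-spread functions,
biophysical neuron models and hydrogel microstructure.

## Numerical choices and problem sizes

Recovery experiments use n = 20–30 neurons (inference) or 60 (presets),
15-minute recordings, and 10 seeds per claim; oracle-equivalence checks use
100 random digraphs up to N = 30, exhaustive partition enumeration up to
N = 8, and exact joint-histogram TE on series up to length 20 — sizes chosen
so the whole suite, including the end-to-end preset contrasts, completes in
a few minutes while keeping each statistical margin wide. Degenerate inputs
are handled explicitly: a constant source gives TE exactly 0; a zero-variance
TE pool yields no edges with a warning; modularity on an edgeless graph and
stage comparisons with zero variance are errors rather than silent zeros;
`1/∞ = 0` in global efficiency; ties at `z = 2` are not significant; Louvain
ties are broken by a seeded node order.
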