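---
title: "Methods: co-localization scoring and IPSC kinetics in synquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-localization scoring and IPSC kinetics in synquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

synquant quantifies two complementary views of inhibitory synaptic
transmission: the anatomical composition of inhibitory boutons in 3-d
fluorescence volumes, and the kinetics of the inhibitory postsynaptic
currents (IPSCs) those boutons produce. This vignette explains the models
and procedures, the parameters that matter, what the synthetic generators
emulate, and the numerical choices behind the implementation.

## Bouton co-localization scoring

### Model

Inhibitory boutons appear as sub-micron puncta in a Vgat channel (the
vesicular GABA/glycine transporter marks all inhibitory terminals).
Whether a bouton also carries a second marker — the glycinergic reporter
Syp-TdT, the fast calcium sensor Syt1/2, or an axon-tracing YFP — is
decided from the voxelwise relationship between the two channels around
that bouton, not from marker intensity alone. The statistic is the
coefficient of determination $R^2$ of an ordinary least-squares regression
of the marker channel on the Vgat channel over a fixed volume of interest
(VOI) of $1.5 \times 1.5 \times 1\,\mu m$ centered on the bouton. Two
channels that rise and fall together across the punctum give $R^2$ near 1;
a marker that is mere background gives $R^2$ near 0. When the fitted slope
is negative the channels are anticorrelated, and the score is set to 0.01
exactly; this floor keeps anticorrelated boutons inside the reportable
score range while marking them unambiguously below every classification
threshold. A slope of exactly zero is not anticorrelated and reports the
computed $R^2$.

Classification uses strict thresholds on these scores: GlyT2$^+$ when
$R^2_{\text{Vgat/Syp-TdT}} > 0.4$, GlyT2$^-$ when $< 0.1$, unclassified in
the dead band between; Syt1/2$^+$ and YFP$^+$ when their scores exceed
0.4. Boutons in the dead band are reported as `unclassified` rather than
silently pooled, so downstream summaries can treat them explicitly.

### Detection, VOI geometry and edge masking

Boutons are detected as 26-neighborhood local maxima of the Gaussian
smoothed Vgat channel (default $\sigma$ = 1 voxel in x/y, 0.5 in z), above
an intensity threshold (default: volume background + 5 robust SDs), with a
minimum separation of 0.5 um (brighter peak wins). Maxima closer than half
a VOI to a volume face are dropped rather than padded, so every analyzed
bouton has a complete VOI of measured voxels.

At the default voxel size (0.1 um in x/y, 0.2 um in z) the VOI footprint
is $15 \times 15 \times 5$ voxels, centered on the peak voxel. Neighboring
boutons can intrude into the outer shell of the VOI and corrupt the
regression, so voxels whose centers lie strictly within 0.25 um of any VOI
face *and* whose Vgat intensity exceeds an edge threshold are excluded
from the fit. The shell width is applied as a physical distance on all
three axes (2 voxels per x/y face, 1 section per z face at defaults).
Below-threshold shell voxels are retained. The edge threshold is
`background mean + edge_intensity_k x background SD`, with the background
estimated volume-wide by median and MAD (robust to the sparse bright
puncta); `edge_intensity_k = 2` by default. The minimum number of included
voxels (default 10) guards against degenerate fits.

Arrays are indexed `[y, x, z]` (1-based, the natural R convention for
stacked image slices), and the physical coordinate of voxel $i$ along an
axis with pitch $\Delta$ is $(i - 0.5)\Delta$, i.e. voxel centers.

### The synthetic volume generator

`generate_volume()` renders boutons as anisotropic 3-d Gaussian puncta
(default $\sigma_{xy} = 0.3\,\mu m$, $\sigma_z = 0.4\,\mu m$ — generator
choices matching the sub-micron scale of boutons at these voxel sizes, not
measured values) on a uniform background, with 8-bit quantization and
additive Gaussian noise. A marker channel carried by a bouton receives
$\alpha$ times that bouton's own Vgat signal (plus optional extra noise
and a correlation-degrading mixture controlled by `rho`); a marker the
bouton lacks receives pure background, or a configurable `bleed` fraction
to stress the classifier's dead band. Contaminating neighbors — Vgat-only
puncta placed within one VOI footprint of a host bouton — exercise the
edge masking. Placement uses rejection sampling with a hard-core minimum
separation and raises a placement error when the attempt budget is
exhausted.

The generator reproduces the acquisition geometry (voxel sizes, bit
depth, stack extent) and the statistical structure the scorer relies on
(correlated vs uncorrelated channels, neighbor contamination, 8-bit
noise). It deliberately does not simulate optics: no PSF convolution, no
spectral bleed-through between detectors, no tile stitching. Passing
recovery tests on generated volumes therefore validates the measurement
chain — detection, masking, regression, thresholds — under known truth,
but does not certify performance on real microscopy with blur or chromatic
offsets.

## Evoked IPSC kinetics

### Measurements

All analyses work on the magnitude of the baseline-subtracted current;
at a holding potential of $-60$ mV with a high-chloride internal solution,
synaptic currents are inward (negative), and the baseline is the mean over
the 10 ms preceding the stimulus, per trial.

* **Jitter** is the sample standard deviation ($n-1$) across trials of the
  per-trial peak time, located on a 0.5 ms boxcar-smoothed copy of each
  trial within the response window. It is invariant under a common time
  shift of all trials.
* **Peak amplitude and time, half-rise, decay and charge** come from the
  trial-averaged trace. Half-rise is the first crossing of 50% of peak,
  linearly interpolated, measured from stimulus onset. The decay time
  constant is a single exponential $A e^{-t/\tau}$ fitted by nonlinear
  least squares (Levenberg–Marquardt, log-linear fallback) from the peak
  to the 10%-of-peak crossing. Charge is the trapezoidal integral over the
  window in pC. Synchronous inputs use a ~100 ms window, asynchronous
  inputs ~500 ms (configurable).
* **No-response criterion.** A component counts as absent when its
  smoothed peak is below 3 smoothed-baseline-noise SDs — or below 1.5
  times the largest opposite-polarity excursion in the window. The second
  condition matters for long analysis windows: the maximum of pure noise
  over hundreds of milliseconds almost always exceeds 3 SDs, but noise is
  symmetric while synaptic responses are unidirectional, so requiring the
  positive peak to dominate the negative excursion separates the two
  reliably.

### Component subtraction

Antagonist experiments isolate transmitter components by subtraction: the
drug-sensitive component is mean(control) $-$ mean(after drug), and the
after-drug average is the spared component. `subtract_components()`
computes kinetics on both and reports glycine/GABA ratios of amplitude and
charge; a component that fails the no-response test contributes zero, so a
purely GABAergic input yields a glycine/GABA ratio of exactly 0. Charge is
additive by linearity of the integral: charge(control) = charge(after
drug) + charge(difference).

### Gap-junction bursts

Spikelet bursts from electrically coupled neighbors contaminate recordings
and, unlike synaptic currents, do not reverse at 0 mV. Two remedies are
implemented. *Rejection*: trials whose maximum normalized cross-correlation
with a burst template (supplied, or derived from the 0 mV average) exceeds
0.6 are discarded. *Subtraction*: the averaged 0 mV trace is scaled by a
least-squares fit over a synaptic-free window and subtracted from the
$-60$ mV average. Rejection is preferred when bursts are rare; subtraction
when they are small and consistent.

### Trains

For stimulus trains (e.g. 10 stimuli at 50 Hz), per-stimulus charge is the
trial-averaged integral over each inter-stimulus window (the last stimulus
gets one interval), normalized to the first stimulus; the decay of the
last IPSC is fitted after the final stimulus. Charges are windowed rather
than deconvolved, so a kernel that has not decayed within one interval
spills a few percent of its charge into the next window; recovery tests
use kernels that decay fully within the interval.

### The synthetic recording generator

`simulate_evoked()` draws, per trial and stimulus, a quantal count
(Poisson around the quantal content, or deterministic for noise-free
recovery tests), latencies from the latency model, a transmitter per
quantum, and lognormal amplitudes, then superposes quantal kernels

$$q(t) = A_{norm}\,(1 - e^{-t/\tau_r})\,e^{-t/\tau_d},$$

normalized so the continuous-time peak (at
$t^* = \tau_r \ln(1+\tau_d/\tau_r)$) equals the quantal amplitude.
Defaults order the two transmitters as observed at mixed inhibitory
synapses — glycine fast and large ($\tau_r$ = 0.3 ms, $\tau_d$ = 5 ms,
60 pA), GABA slow and small ($\tau_r$ = 1 ms, $\tau_d$ = 15 ms, 40 pA);
the numeric values are generator choices. Synchronous latencies are
Gaussian truncated at zero (default 1 ± 0.3 ms); asynchronous latencies
are a delayed exponential (default 2 ms + Exp(50 ms)). During trains the
asynchronous tails of successive stimuli overlap, so asynchronous release
rates sum across the train and per-window charge accumulates instead of
decaying between stimuli; an optional buildup factor can additionally
scale asynchronous content per stimulus.

Synaptic current scales with driving force relative to $-60$ mV and
vanishes at the reversal potential, so paired $-60$/0 mV protocols behave
as in the recording chamber; injected gap-junction bursts do not scale.
Gaussian noise is added and sweeps are low-pass filtered with a 4-pole
digital Butterworth (zero-phase) at the acquisition cutoff (default 4 kHz
at 20 kHz sampling) — a stand-in for an amplifier's analog Bessel filter,
adequate for these analyses but not a model of its phase response. The
generator does not model conductance-based membranes, subthreshold
oscillations, dendritic filtering, or series-resistance artifacts; test
results bound analyzer accuracy under known quantal truth, not under
every recording pathology.

## Miniature events

`detect_minis()` implements a two-stage screen. Candidate onsets are
upward crossings of the first derivative of a 1 kHz low-pass smoothed copy
of the trace at `deriv_k` (default 5) robust noise scales, where the noise
scale is the MAD of the derivative (MAD-based estimates ignore the sparse
events themselves). Candidates must then pass an integration test: the
baseline-subtracted integral over the following 10 ms must exceed
`integ_k` (default 3) times the SD expected for integrated noise over that
window, taken as $\sigma \sqrt{n}\,\Delta t$ for $n$ samples of noise SD
$\sigma$. (A literal threshold of noise SD x window length would be of the
same order as a genuine small event's charge and reject it; the
statistical scale is the intended discriminator.) Onsets closer than 5 ms
merge into the earlier one; amplitudes are measured from a local 2 ms
pre-onset baseline; decay is the interpolated time from peak to $1/e$ of
the amplitude. At 5x-noise amplitudes the detector reaches 95% recall and
precision at 2 Hz event rates; the residual misses are dominated by event
pairs closer than the merge interval and by events whose smoothed
derivative fluctuates just below threshold.

## Reproducibility and problem sizes

Every stochastic generator takes an explicit seed and is bit-reproducible
under it; `run_pipeline()` derives all stage seeds from one global seed
and writes a manifest echoing parameters, seeds and outputs, so a config
re-run reproduces every file byte for byte. Volumes are written as
multi-page TIFF with a YAML sidecar naming the channel axis; sweeps as
delimited text with a YAML metadata sidecar.

The validation suite runs at deliberately desk-friendly scales chosen to
make each statistical assertion well-powered: recovery volumes of
$50 \times 50 \times 3\,\mu m$ with 200 boutons, 1000-VOI scorer/oracle
comparisons, 15–50 trial sweep sets, and a 600 s miniature recording at
2 Hz. Latency-model and train defaults in the packaged scenarios were
fixed once, from the qualitative regimes the scenarios represent
(sub-millisecond synchronous jitter; asynchronous release persisting for
tens to hundreds of milliseconds), before being used in tests.

## Known limitations

* $R^2$ is the only co-localization metric; Manders or Costes-style
  analyses are out of scope, as are deconvolution and atlas registration
  (regions enter as label images or per-bouton labels).
* The decay fit is a single exponential; genuinely biexponential decays
  will report an intermediate $\tau$.
* Whether dead-band boutons ($0.1 \le R^2 \le 0.4$) should be excluded or
  pooled is context-dependent; synquant reports them as `unclassified` and
  leaves the choice to the analyst.
* The burst template is stylized (three biphasic spikelets); rejection and
  subtraction only rely on shape consistency, but real burst waveforms
  vary more than the generator's do.
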