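# synquant

Quantitative analysis of inhibitory synaptic transmission from two kinds
of raw data:

* **3-d fluorescence volumes** of inhibitory boutons. Boutons are detected
  as local maxima of a Vgat channel (Vgat, the vesicular GABA/glycine
  transporter, marks all inhibitory terminals); around each bouton a fixed
  1.5 × 1.5 × 1 µm volume of interest (VOI) is extracted and the
  co-localization of a second marker (the glycinergic reporter Syp-TdT,
  the fast calcium sensor Syt1/2, or an axon-tracing YFP) is scored as the
  R² of an ordinary least-squares regression of marker on Vgat over the
  VOI voxels. Edge-shell voxels (outer 0.25 µm) carrying supra-threshold
  Vgat signal from neighboring boutons are excluded; anticorrelated VOIs
  (negative slope) score 0.01 exactly. Boutons classify as GlyT2⁺
  (R² > 0.4), GlyT2⁻ (R² < 0.1), Syt1/2⁺ and YFP⁺ (R² > 0.4), and
  per-region composition and contingency tables are summarized.

* **Voltage-clamp IPSC recordings.** Evoked-response kinetics: trial
  jitter (SD of per-trial peak times), half-rise time, single-exponential
  decay τ, peak amplitude and charge; pharmacological component
  subtraction (control − after-drug averages) with glycine/GABA amplitude
  and charge ratios; gap-junction burst rejection or 0 mV-scaled
  subtraction; charge dynamics across 50 Hz stimulus trains; and
  miniature-IPSC detection by a combined first-derivative and integration
  threshold.

Both pipelines ship with synthetic-data generators (bouton volumes with
known class labels; quantal release simulations with synchronous/
asynchronous latency models, GABA vs glycine kinetics, Poisson minis and
burst contaminants) so every stage is testable against ground truth.
See `vignettes/synquant-methods.Rmd` for the full methods description.

## Worked example

```r
library(synquant)

# --- imaging: generate a 30 x 30 x 3 um volume with 40 boutons, analyze it
spec <- volume_spec(shape_xy = c(300L, 300L), n_z = 15L)
pop  <- bouton_population(count = 40, p_glyt2 = 0.4, p_syt12 = 0.5, noise_sd = 5)
vol  <- generate_volume(spec, pop, seed = 7)
tab  <- analyze_volume(vol$stack, coloc_config(), spec$voxel_size_um)
head(tab[, c("id", "x_um", "y_um", "z_um", "r2_syp_tdt", "r2_syt12",
             "glyt2_label", "syt12_pos")])
#>   id  x_um  y_um z_um   r2_syp_tdt  r2_syt12 glyt2_label syt12_pos
#> 1  1 11.65 21.05  0.5 0.0100000000 0.9661311         neg      TRUE
#> 2  2  8.75 27.35  0.5 0.9724847743 0.0100000         pos     FALSE
#> 3  3 25.45 20.65  0.7 0.0002320533 0.9814877         neg      TRUE
#> 4  4 14.15 25.35  0.7 0.0015366320 0.0100000         neg     FALSE
#> 5  5 27.75  9.25  1.1 0.9821390761 0.9837985         pos      TRUE
#> 6  6  7.15 20.85  1.1 0.9689225367 0.9701243         pos      TRUE
```

Each row is one detected bouton: its centroid (µm), the regression R²
against each marker channel (0.01 is the anticorrelation floor), and the
resulting class labels. Summarizing by region:

```r
tab$region <- "pio"
summarize_regions(tab)$table
#>   region n_boutons fraction_glyt2_pos n_yfp_pos n_syt12_pos n_yfp_and_syt12
#> 1    pio        40              0.475         0           0               0
```

(47.5% of classified boutons are GlyT2⁺; the generated mix was 40%, and no
YFP channel was simulated, so YFP counts are empty.)

```r
# --- electrophysiology: simulate and measure a synchronous glycinergic input
acq <- acquisition_spec(sweep_duration_s = 0.5, stimulus_times_s = 0.05)
rel <- release_model(latency = latency_model("synchronous"),
                     quantal_content = 10, transmitter_mix = 1)
sw  <- simulate_evoked(rel, acq, n_trials = 20, noise_sd_pa = 2, seed = 7)
compute_kinetics(sw, window_ms = 100)
#> <kinetics_result>
#>   n_trials: 20
#>   jitter: 0.147 ms | half-rise: 1.14 ms | decay tau: 5.07 ms
#>   peak: 661 pA at 2 ms | charge: 4.06 pC
```

The sub-millisecond jitter and fast rise/decay are the signature of
synchronous glycinergic release; an asynchronous scenario
(`latency_model("asynchronous")`) yields jitter in the tens of
milliseconds and slow rise.

Configuration-driven end-to-end runs (generation → analysis → tables +
manifest) go through `run_pipeline()`; a thin command-line wrapper with
subcommands (`simulate-volume`, `score-coloc`, `simulate-traces`,
`analyze-evoked`, `detect-minis`, `report`, `run`) is installed at
`inst/cli/synquant.R`.

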