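# endorecycle

Quantification of photoactivation pulse-chase microscopy of the
endocytic recycling pathway, for cell biologists measuring how a surface
receptor (e.g. the TCRζ chain) is sorted through Rab5/Rab4/Rab11a
endosomes and returned to the plasma membrane.

A restricted pool of photoactivatable cargo (PA-mCherry, PS-CFP2) is
switched on inside a small region and followed through the cell. The
package computes the assays' standard readouts from multi-channel
time-lapse movies:

* **Sorting** — per-frame percentage of endosomal photoactivated
  intensity inside a marker compartment,
  `100 · Σ I_PA(PA-mask ∩ marker-mask) / Σ I_PA(PA-mask)`, with exit
  slopes (OLS from 50 s), half-maximal times (first interpolated
  crossing of half the final plateau), and the summed total recycling
  half-time.
* **Recycling** — plasma-membrane signal after subtracting the
  photoactivated-compartment mask, as percent increase over the
  pre-activation baseline, with plateau means over 900–1200 s.
* **Vesicles** — Laplacian-of-Gaussian detection with subpixel
  centroids, greedy nearest-neighbour tracking, and the cross-channel
  nearest-neighbour fraction (% of A-vesicles within 320 nm of a
  B-vesicle) with a randomised repositioning control.
* **Fusion (TIRF)** — automated fusion-event detection (appearance +
  spread-or-decay confirmation) and the 15% intensity-drop co-fusion
  classifier: an event contains the partner protein if
  `(I_init − mean(last three maxima)) / I_init > 0.15` on the partner
  channel.
* **Spatial organisation** — intensity-weighted dispersion
  `Σ I_i d_i / Σ I_i` (distance to the intensity-weighted centroid, µm)
  and per-object circularity `4π·area/perimeter²` with a Crofton
  perimeter estimator.
* **Statistics** — per-timepoint Wilcoxon rank-sum divergence time
  (earliest T with p ≤ α for all t ≥ T), equal-slopes ANCOVA, one-sample
  t vs a normalised 100%, Student/Welch/Mann–Whitney two-sample tests,
  and a two-sided variance F-test.

Every analysis stage has a seeded simulator with ground truth
(`simulate_sorting_assay()`, `simulate_recycling_assay()`,
`simulate_tirf_fusion()`, `simulate_group_traces()`,
`simulate_aggregation()`), so the whole pipeline is testable without raw
microscopy data. Movies are plain multi-page TIFF with a JSON
calibration sidecar; ROIs are JSON; results are tidy CSV.

## Worked example

Simulate the sorting assay at its acquisition protocol (five 2.5 s
photoactivation pulses, then 150 frames every 2.5 s; 200 vesicles with
entry rate 0.02 s⁻¹ and exit rate 0.005 s⁻¹ at SNR 5), quantify it, and
compare with the known truth:

```r
library(endorecycle)

sim <- simulate_sorting_assay(
  sorting_sim_params(n_vesicles = 200, k_entry_per_s = 0.02,
                     k_exit_per_s = 0.005, snr = 5), seed = 42)
cfg <- analysis_config(threshold_method = "background")
tr  <- endosomal_incorporation_trace(sim$movie, "cargo", "marker", cfg)

max(abs(tr$values - 100 * sim$truth$occupancy_fraction), na.rm = TRUE)
#> [1] 2.451612

half_maximal_time(tr)$time_s      # seconds after the first pulse
#> [1] 30.73414
```

The measured percentage tracks the true two-state occupancy within
~2.5 percentage points at every one of the 155 frames here, and the
half-maximal sorting time of ~30 s matches the closed-form value for
these rates (ln-mixture over the five pulse cohorts, ≈ 33 s, within one
2.5 s frame of the trace-based estimate at this vesicle count). Combining
the two published component half-times reproduces the total:

```r
tot <- total_recycling_halftime(186.6, 375)
attr(tot, "formatted")
#> [1] "9 min 21.6 s"
```

A whole figure-level analysis (simulate → quantify → test, with traces
CSV, summary JSON and provenance) is one call:

```r
run <- run_figure_pipeline("divergence", seed = 1, out_dir = "out")
run$summary$divergence_time
#> [1] 50
```

or from a shell via the thin wrapper
`Rscript inst/cli/endorecycle.R --pipeline divergence --seed 1 --out out`.

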