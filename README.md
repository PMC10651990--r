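# acinet

Seizure dynamics of the anterior cingulate–insula network from
stereo-EEG (SEEG).

In anterior cingulate and anterior insular epilepsies the two regions
often discharge near-simultaneously at seizure onset, so visual review
cannot tell the seizure-onset zone (SOZ) from the early-propagation
zone. `acinet` quantifies the coupling between one ACC and one AIC
bipolar channel across four 10-s periods — interictal (IID), preictal
(PI), seizure onset (SO), propagation (SP) — and answers who drives
whom:

* **h²** — a nonparametric nonlinear correlation in [0, 1]:
  `h²_{X→Y}(τ) = 1 − VAR(Y(t+τ)|X(t)) / VAR(Y(t+τ))`, maximized over
  lags |τ| ≤ 0.1 s in 2-s sliding windows, on signals filtered to the
  patient-specific onset band.
* **Direction index** — `D = (sgn Δh² + sgn Δt) / 2 ∈ {−1, −½, 0, ½, 1}`,
  combining the asymmetry of h² and of the optimal lags; D > 0 means
  channel 1 drives channel 2.
* **E:I proxy** — the power spectrum is decomposed into an aperiodic
  component `L = b − log₁₀(k + F^χ)` plus up to three Gaussian peaks
  over 1–80 Hz; the negative aperiodic exponent `−χ` serves as an
  ordinal excitation/inhibition index (flatter spectrum = higher E:I).

Because the underlying clinical recordings are not publicly available,
the package includes a seeded synthetic SEEG generator (1/f^χ
backgrounds, narrowband ictal oscillations, lagged nonlinear coupling
with per-period schedules) that carries full ground truth, so every
estimator is validated by parameter recovery.

## Worked example

```r
library(acinet)

# a 90-s two-channel scenario: onset at 70 s, channel 1 is the SOZ
report <- run_pipeline(list(sim = sim_config(seed = 0)))
print(report)
#> <acin_report>
#>   band: alpha (8-13 Hz)
#>   period   mean_h2     mean_D n_windows    ei_ch1    ei_ch2
#> 1    IID 0.2148466 0.05555556         9 -2.003945 -2.106621
#> 2     PI 0.1727340 0.16666667         9 -1.818536 -1.872421
#> 3     SO 0.7341763 0.11111111         9 -1.211083 -1.546402
#> 4     SP 0.7008764 0.27777778         9 -1.434985 -1.720918
#>   SOZ call: ch1 (mean D at onset = 0.111)
```

Reading the output: the onset band was auto-selected as α from the
SO-period spectrum; connectivity (`mean_h2`) jumps from 0.21 interictally
to 0.75 at onset; the direction index at onset is positive, so channel 1
is called the driver (the SOZ) — matching the simulated ground truth;
and the E:I proxy (`ei_*`, = −χ) rises at onset in both channels, with
the larger interictal-to-onset increase in the SOZ channel (0.793 vs
0.560). `report$stats` holds the twelve paired period contrasts
(IID–PI, IID–SO, PI–SO, SO–SP for each of h², D, E:I), FDR-corrected
within each measure family.

Individual stages are exported — `gen_seizure_scenario()`,
`read_edf()` / `write_edf()`, `make_bipolar()`, `welch_psd()`,
`parameterize_spectrum()`, `ei_index()`, `bandpass()`, `sliding_h2()`,
`segment_periods()`, `select_onset_band()`, `classify_soz()` — see the
vignette in `vignettes/network-dynamics.Rmd` for the methods.

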