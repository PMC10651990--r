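---
title: "Methods: seizure dynamics of a two-region intracranial network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seizure dynamics of a two-region intracranial network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acinet)
```

## The scientific problem

In some focal epilepsies the anterior cingulate cortex (ACC) and the
anterior insular cortex (AIC) fire so nearly simultaneously at seizure
onset that visual review of stereo-EEG cannot tell which region leads.
`acinet` implements a quantitative analysis of one bipolar channel pair
across four 10-second periods — interictal (IID), preictal (PI), seizure
onset (SO), and propagation (SP) — that addresses three questions:

1. **How strongly are the two regions coupled?** A nonparametric,
   frequency-specific nonlinear correlation (h²).
2. **Which region drives which?** A direction index D built from the
   asymmetries of h² and of the optimal time lags.
3. **How does local excitability evolve?** An ordinal
   excitation/inhibition (E:I) proxy read from the aperiodic (1/f)
   exponent of the power spectrum.

Because clinical recordings of this kind are not publicly deposited, the
package ships a seeded synthetic SEEG generator with full ground truth;
every estimator is validated by parameter recovery against it.

## The h² statistic and the direction index

For two windowed signals $X, Y$ and a lag $\tau$, the nonlinear
correlation is

$$h^2_{X \to Y}(\tau) = 1 -
  \frac{\operatorname{VAR}\!\left(Y(t+\tau) \mid X(t)\right)}
       {\operatorname{VAR}\!\left(Y(t+\tau)\right)},$$

where the conditional expectation is a piecewise-linear curve through
(bin median of $X$, bin mean of $Y$) over equal-count bins of $X$. It is
bounded in $[0, 1]$ and asymmetric: a non-invertible forward map (e.g.
$y = x^2$) yields $h^2_{X\to Y} \gg h^2_{Y \to X}$, which is exactly the
signature linear correlation misses. The lag scan evaluates every
integer-sample shift in $[-0.1, +0.1]$ s (positive $\tau$: $Y$ follows
$X$). From the two directed maxima the window's direction index is

$$D_{XY} = \tfrac{1}{2}\left(\operatorname{sgn}\Delta h^2 +
  \operatorname{sgn}\Delta t\right), \qquad
  \Delta h^2 = h^2_{X\to Y} - h^2_{Y\to X}, \quad
  \Delta t = \tau_{X\to Y} - \tau_{Y\to X},$$

taking values in $\{-1, -\tfrac12, 0, \tfrac12, 1\}$; $D = +1$ means $X$
drives $Y$. Under true $X\to Y$ driving with delay $d$ the conventions
give $\tau_{X\to Y} = +d$, $\tau_{Y\to X} = -d$, hence $\Delta t = +2d$
and $D = +1$. Analyses run in 2-s sliding windows stepped by 1 s (nine
windows per 10-s period), on signals band-passed (zero-phase 4th-order
Butterworth) to the patient-specific onset band.

### Numerical choices in the estimator

The regression variant behind h² is not standardized in the literature,
so the package fixes and documents its own:

* **Bins.** `nbins = max(4, floor(sqrt(n)/2))` equal-count bins
  (16 for a 2-s window at 512 Hz); equal-count keeps every bin mean
  well-estimated, and bin medians give robust abscissae.
* **Edges.** The regression curve is extended linearly beyond the outer
  bins; lag-shifted windows are trimmed to their overlapping support and
  never zero-padded (padding manufactures spurious zero-lag similarity).
* **Lag near-ties.** h² estimates on ~1000-sample windows carry
  finite-sample noise of order `nbins/n` (~0.01–0.02). Lags whose h²
  falls within `lag_tol = 0.02` of the maximum are treated as tied and
  resolved toward the smallest $|\tau|$, then toward negative $\tau$.
  Without this, a near-flat profile hands the lag to whichever scan-
  boundary fluctuation happens to be largest.
* **Asymmetry dead-zone.** For autocorrelated 2-s windows, replicate
  h² estimates fluctuate on the 0.05 scale, so
  $|\Delta h^2| < 0.05$ is treated as no asymmetry
  ($\operatorname{sgn} = 0$) when forming a window's D. The raw
  difference is always reported alongside.
* h² is clipped to $[0,1]$ against rare residual overshoot at the
  extrapolated ends; a constant regressor returns 0, a constant target
  is an error.

A known confound is worth stating: when the two channels have unequal
spectral content, the redder (more autocorrelated) channel is the more
effective regressor and h² acquires a direction bias even for
independent signals. The dead-zone suppresses the small-sample part of
this, but comparisons are cleanest between channels filtered to the same
band, which is how the pipeline uses the statistic.

## Spectral parameterization and the E:I proxy

Power spectra are estimated by Welch's method (Hann taper, per-segment
mean removal, density normalization). The stated legacy combination of a
0.5-s segment with a 1-Hz fit floor and 0.5-Hz minimum peak width is
internally inconsistent (0.5-s segments give 2-Hz resolution), so the
default segment is 2 s (0.5-Hz resolution) with 50% overlap;
`segment_s = 0.5` remains available for coarse estimates.

The log-spectrum over 1–80 Hz is decomposed as an aperiodic component
plus up to three Gaussian peaks,

$$\log_{10} P(F) = \underbrace{b - \log_{10}(k + F^{\chi})}_{L(F)}
  + \sum_n a_n \exp\!\left(-\frac{(F - c_n)^2}{2 w_n^2}\right),$$

with the knee $k = 0$ in the default fixed mode, so $L$ is a straight
line of slope $-\chi$ in log–log space (base-10 logarithms throughout;
the base only rescales $b$). The fit loop is: robust aperiodic fit →
flatten → iterative peak extraction → subtract peaks → aperiodic refit
on the peak-removed spectrum. The robust fit iterates least squares,
discarding at each step the top 2.5% of positive residuals, so broad
oscillatory bumps are eroded progressively rather than only at their
tips.

Peak extraction seeds a Gaussian at the largest flattened-spectrum point
if it exceeds **both** a relative threshold (2.0 SD of the flattened
spectrum) and an absolute floor (`min_height = 0.3` log₁₀ units, i.e.
about a doubling of power). The absolute floor is essential: the maximum
of ~160 stochastic log-power bins sits near 2.4–2.6 SD *by construction*,
so a purely relative rule would "detect" a peak in most peak-free
spectra regardless of how small the noise is. Widths are guessed from
the half-height extent and clamped so the full width stays within
[0.5, 12] Hz (Gaussian width parameter in [0.25, 6]); all seeded peaks
are then jointly refined by bounded Levenberg–Marquardt.

The E:I index is $-\chi$: a flatter spectrum (smaller exponent) reads as
a higher excitation-to-inhibition balance. Only the *ordering* of values
is interpreted — across periods or between channels — never the absolute
scale.

## Period segmentation and band selection

Sample intervals are half-open $[start, end)$ with 0-based indices.
PI ends at the onset sample, SO starts there, SP covers onset + 10 s to
onset + 20 s, and IID ends `iid_offset_s` before onset. Clinically the
interictal reference sits hours from the seizure; the simulator default
compresses the gap to 60 s because the estimators see only the segment's
statistics, not its clock distance (`iid_offset_s = 7200` restores the
clinical layout).

The onset band is patient-specific: the SO-period spectrum of each
analysis channel is parameterized, the largest-amplitude peak's center
frequency is assigned to one of seven bands — δ [0.5, 4), θ [4, 8),
α [8, 13), low-β [13, 20), high-β [20, 30), low-γ [30, 45),
high-γ [45, 80] — and connectivity is computed in that band. The bands
form a half-open partition (top band closed at 80 Hz), so every center
maps to exactly one band. With no detectable peak the band holding the
flattened-spectrum maximum is used, with a warning.

## Statistics and the SOZ call

Period-level h² is a two-step average: per window, the mean of the two
directed values; per period, the mean over windows. Period-level D is
the mean of per-window D (a pooled-window alternative exists but is not
the default). The four period contrasts (IID–PI, IID–SO, PI–SO, SO–SP)
are tested on window-level paired samples with a normality gate:
Shapiro–Wilk at α = 0.05 on both samples and their differences selects a
paired t test or a Wilcoxon matched-pairs signed-rank test, two-sided.
Benjamini–Hochberg correction is applied within each measure family
(h², D, E:I — the family structure is configurable since it is a
genuine modelling choice). E:I contrasts use window-level exponent fits
(2-s windows, 1-s Welch segments) of the hypothesized SOZ channel.

The seizure-onset-zone call uses the sign of mean D at SO as primary
evidence (the driver is called SOZ) and the channel with the larger
IID→SO E:I increase as secondary evidence. D wins disagreements (which
are flagged); an exactly-zero D defers to the E:I evidence with an
`indeterminate-D` flag.

## The synthetic generator: what it emulates, and what not

Each channel pair is built as driver $X$ = unit-variance $1/f^{\chi}$
background (spectrally shaped white noise, per-period exponents) plus,
from onset, a narrowband stochastic oscillation; follower
$Y = \sqrt{1-c^2}\,W + c\,f(X_{t-d})$ with its own background $W$,
coupling strength $c$ and delay $d$ switching abruptly at period
boundaries. Default schedules: $c$ = 0.05 / 0.15 / 0.7 / 0.4 and SOZ
$\chi$ = 2.0 / 1.8 / 1.2 / 1.5 (non-SOZ 2.0 / 1.9 / 1.5 / 1.6) over
IID / PI / SO / SP; $d$ = 20 ms. The $\sqrt{1-c^2}$ weighting keeps the
follower's variance approximately constant, so h² changes are
attributable to coupling rather than amplitude. The default transform
$f$ is the centred quadratic — a non-invertible map that only a
nonlinear estimator detects — with identity and saturating-sigmoid
alternatives.

Two pathway details matter and are deliberate:

* **The ictal rhythm propagates directly.** The oscillation is injected
  into the follower delayed by $d$ and weighted by the period's $c$.
  A purely quadratic pathway would leave the follower with *no*
  onset-band content at all (squaring moves narrowband power to DC and
  twice the center frequency), making band-limited direction analysis
  blind — unlike real propagated ictal activity.
* **The coupled pathway is low-passed** (zero-phase first-order
  Butterworth, default 80 Hz), emulating the dendritic/synaptic
  filtering of propagated activity. Without it the quadratic transform
  injects near-white broadband power into the follower, whose fitted
  1/f exponent then no longer reflects its scheduled value. A sharper
  filter would be worse, not better: a steep roll-off inside the 1–80 Hz
  fit range adds a spectral knee that biases the exponent upward.
  Zero-phase filtering leaves the coupling lag intact.

Other defaults chosen once for realism: ictal oscillation at 10 Hz
(α onset, the most common pattern in this syndrome family), 3 Hz
bandwidth, amplitude 1.5 × the background RMS; onset at 70 s of a 90-s
record; signals scaled to 50 µV RMS for EDF output (±2000 µV physical
range). One root seed drives deterministically derived per-component
streams, so identical configurations are bit-identical.

What the generator does **not** emulate: neural-mass or biophysical
seizure dynamics, volume conduction, artifacts and line noise,
nonstationarity within periods, and multi-electrode spatial structure.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-calibrated under the stated statistical structure — not
that the pipeline's clinical conclusions transfer to any given patient
recording.

## Validation design and problem sizes

The test suite validates by parameter recovery at desk scale: exponent
recovery over $\chi \in \{0.5, \dots, 2.5\}$ on 60-s signals (20 seeds
each, mean absolute error ≤ 0.15 observed ≈ 0.02); Gaussian-peak
recovery and false-positive control on 0.5-Hz grids; lag recovery of a
20-ms delay to one sample; direction recovery over 100 coupled epochs
($c = 0.7$, the onset-state value, with matched $\chi = 1.2$ backgrounds
so that coupling is the only asymmetry between the coupled and null
arms) against 100 zero-coupling controls; and a 20-scenario cohort
(10 per driving direction) for the D-based SOZ call. Matching the
background exponents in the epoch studies is deliberate experimental
design: with unequal exponents the spectral-asymmetry confound described
above contaminates both arms.

## Known limitations

* Narrowband lag estimation is intrinsically ambiguous modulo the
  oscillation period; the near-tie rule resolves this toward small
  lags, which is correct for delays shorter than half a cycle.
* The E:I proxy is ordinal and uncalibrated; knee-mode fits exist but
  no claim is made above 80 Hz or about synaptic time constants.
* One seizure, one channel pair per run; multi-seizure aggregation and
  all-pairs network graphs are out of scope.
* The EDF layer targets continuous 16-bit recordings with whole-second
  durations; annotations (EDF+ TAL streams) are not parsed.
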