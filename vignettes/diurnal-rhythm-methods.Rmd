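---
title: "Detecting diurnal rhythms in hourly search-volume series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diurnal rhythms in hourly search-volume series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diurnalseek)
```

## The problem and the model

Hourly relative search volume (RSV) is the metric Google Trends exports:
integer values 0–100, with 100 the busiest hour of the normalization
window. A month of hourly RSV for a health-related query superimposes

* a **diurnal component** — the 24 h cycle of interest we want to measure,
* **slow trends** — multi-day drifts in baseline interest (news events,
  weekday/weekend effects, seasonal drift),
* **high-frequency noise** — sub-daily sampling jitter, and
* **observation noise** from Google's sampling and integer quantization.

`diurnalseek` isolates the diurnal component by band-pass filtering in the
wavelet domain rather than by fitting a parametric curve: no assumption is
made about the *shape* of the daily cycle (it need not be sinusoidal), only
about its *time scale*. Components with Fourier periods above 32 h are
treated as trend, components below 4 h as noise, and everything between is
kept. The choice of an analyzing band of 4–32 h brackets the 24 h target
with one octave of margin on each side.

### Wavelet transform

The transform is the analytic Morlet CWT in the Torrence–Compo
formulation, computed in the frequency domain with zero-padding to the next
power of two. The series mean is removed before the transform and stored.
Scales follow the dyadic grid $s_j = s_0\,2^{j\,dj}$ and map to Fourier
periods by $\lambda = 4\pi s / (\omega_0 + \sqrt{2 + \omega_0^2})$
($\approx 1.033\,s$ at $\omega_0 = 6$). The band-limited inverse is

$$\hat x(t) = \frac{dj\,\sqrt{dt}}{C_\delta\,\psi_0(0)}
  \sum_{j\,:\,4 \le \lambda_j \le 32} \frac{\Re\,W_j(t)}{\sqrt{s_j}},
  \qquad C_\delta = 0.776,\; \psi_0(0) = \pi^{-1/4}.$$

The analysis this package reproduces named no mother wavelet, scale grid or
reconstruction constants (it used a commercial toolbox). Morlet with
$\omega_0 = 6$, $s_0 = 2\,dt$, $dj = 0.125$ and the published
Torrence–Compo constants are the de facto standard for biological rhythm
detection and the only fully documented convention, so they are the
defaults here; exact numeric parity with a different toolbox's CWT is not a
goal.

### Downstream statistics

The reconstructed, mean-restored series is folded into a days × 24 matrix.
Column means give the mean diurnal profile; its maximum minus minimum is
the **peak–trough difference in percentage points (pp)** of the 0–100 RSV
scale, the effect size reported throughout. Hour $h$ labels the clock
window $[h{:}00, h{+}1{:}00)$, and ties at flat extrema resolve to the
earliest hour for determinism.

Two significance analyses follow:

* **Hour versus hour.** One-way equal-variance ANOVA across the 24 hourly
  distributions (days as replicates), then Tukey–Kramer all-pairs
  comparisons on the pooled within-group variance. The adjusted p-value is
  two-sided; directionality comes from comparing group means, giving the
  asymmetric indicator "hour *i* significantly greater than hour *j*".
  With the equal group sizes a folded month produces, the Kramer unequal-n
  form reduces exactly to classic Tukey HSD (the implementation handles
  both, and is cross-checked against base R's `TukeyHSD`). By default this
  analysis runs on the reconstructed series — the statistical question is
  about the diurnal component, and the method description places the ANOVA
  directly after reconstruction — with a raw-RSV mode available.
* **Time blocks.** Raw hourly RSV (deliberately *not* the reconstruction:
  the trichotomy is defined on the values "between 0 and 100") is split
  into night (0–7), work (8–15) and evening (16–23), compared by one-way
  ANOVA, then by the three pairwise pooled-variance t tests with Bonferroni
  correction $p_{adj} = \min(1, 3p)$. The default observation unit is the
  hourly value (n = 8 × days per block); a `unit = "day"` mode collapses
  each day to one mean per block, trading power for robustness to
  within-day dependence, since the source analysis did not state which it
  used.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `band` | c(4, 32) | hours | trend/noise cut points; both edges inclusive for retention |
| `omega0` | 6 | — | standard Morlet trade-off of time/frequency resolution; reconstruction constants published only for this value |
| `dj` | 0.125 | octaves | fine enough that reconstruction error of a sinusoid is ≈1% |
| `s0` | 2·dt = 2 | hours | smallest resolvable scale at hourly sampling |
| `n_scales` | reach ≥128 h | — | covers four octaves above the diurnal period so trends are resolved before being discarded |
| `alpha` | 0.05 | — | conventional significance level of the source analysis |
| `max_gap` | 2 | hours | longest gap repaired by linear interpolation |

## The synthetic world

`synthetic_config()` states the validation world once:

```r
unclass(synthetic_config())[1:12]
```

* **What it emulates.** A 31-day month (744 hourly values per term; with
  the six study terms, 4464 values) of night-peaking interest: a cosine of
  amplitude 15 RSV units peaking at 2 AM (acrophase 2, matching the
  observed night peaks), a 20-unit trend at 72 h and a 3-unit jitter at
  2 h — one component on each side of the 4–32 h band, so band rejection
  has an exact target — plus white noise with SD 5, renormalization to
  max = 100 and integer quantization. The baseline of 55 keeps clipping at
  0/100 inactive out to about three noise SDs, so ground truth computed
  pre-clipping stays exact. The high-frequency term is a fixed-period
  cosine with random phase rather than broadband noise, again so that the
  rejection tests have a closed-form target.
* **What it does not emulate.** Google's sampling variability between
  repeated downloads, privacy thresholding (the `<1` suppression), weekly
  (168 h) structure, and any non-sinusoidal shape of the real diurnal
  cycle. A green parameter-recovery test therefore establishes that the
  pipeline recovers a known band-limited diurnal signal from trend and
  noise — not that real search data meet the generator's assumptions.
* **Ground truth under renormalization.** Rescaling a term by
  $k = 100/\max$ scales the true peak–trough difference to $2Ak$; the
  generator reports per-term $k$ and $2Ak$ so recovery is judged on the
  same scale the pipeline outputs.

## Numerical choices

* **Mean handling.** The series mean is removed before the transform;
  diurnal profiles are computed on mean-restored reconstructions so pp
  values live on the 0–100 scale. Truncating the zero-padded inverse
  transform back to the series length leaves a small residual mean
  (edge effect); `bandpass_reconstruct()` removes it so the deviations are
  exactly zero-mean.
* **Cone of influence.** The Morlet e-folding rule: at distance $d$
  samples from the nearer end, periods up to $1.033\,d\,dt/\sqrt 2$ are
  trustworthy. Accuracy claims (correlation, amplitude) are evaluated
  interior to the COI at the 24 h level; the folded profiles use all days,
  which costs a few percent of amplitude from the ~1.4 attenuated days at
  each end of a month — well inside the recovery tolerance.
* **Band membership** is inclusive at both edges (4 ≤ λ ≤ 32 retained):
  the stated rule discards periods *longer than* 32 h, so 32 h itself is
  kept.
* **Stitching.** Weekly segments are cross-calibrated by the ratio of
  means over their overlap (robust to integer quantization, unlike
  per-hour ratios), overlapping hours resolve to the earlier segment, and
  the stitched month is renormalized to max = 100 — this makes pp
  differences well-defined on the monthly scale, consistent with scaling
  to the maximum weekly RSV. Abutting segments without overlap cannot be
  cross-calibrated; each is normalized to its own maximum and the report
  carries a warning. How the original weekly downloads were actually
  merged was unstated; this rule is the package's own convention.
* **Timestamps** are an abstract uniform hourly grid in UTC; no time-zone
  or DST arithmetic is done. (Finland switched to summer time on
  2017-03-26, yet the motivating dataset held exactly 744 = 31 × 24
  values, so the export grid was evidently uniform; the package keeps that
  convention.)
* **Degenerate inputs.** All-constant groups with equal means raise a
  degenerate-variance error rather than returning NaN F statistics;
  `<1` cells parse to 0; gaps longer than `max_gap` are refused rather
  than repaired.

## Design choices where the design was open

* **Per-term statistics.** The hour-versus-hour analysis runs per query
  term (the source figures show one panel per query), not pooled.
* **Post-hoc family for blocks**: pairwise pooled-variance t tests with a
  ×3 Bonferroni factor — the simplest family consistent with "Bonferroni
  correction".
* **Configuration files** for the pipeline and CLI are JSON (mirroring the
  function arguments) rather than YAML, since the package otherwise needs
  no YAML dependency.
* **CLI.** The analysis is function-first; a thin `inst/exec/diurnal-seek`
  wrapper exposes `run` and `simulate` for shell use.

## Limitations

* No significance contours against red-noise backgrounds in the power
  spectrum, and no mother wavelets other than Morlet.
* The hourly ANOVA treats days as independent replicates; day-to-day
  autocorrelation of search behavior is not modelled (the source analysis
  shares this limitation). The `unit = "day"` block mode is the only
  concession to within-day dependence.
* Peak/trough location is the argmax/argmin of 24 hourly means — no
  cosinor fitting, no multimodal peak detection.
* The published per-term pp differences (37.3/33.5/30.6/12.8/12.0/11.8)
  derive from a March 2017 dataset that was never deposited and cannot be
  re-downloaded in identical form; they serve as qualitative references
  only, and no test asserts them.
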