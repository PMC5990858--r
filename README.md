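# diurnalseek

Detection and quantification of diurnal (24-hour) rhythms in hourly
relative-search-volume (RSV) time series — the normalized hourly query
metric that Google Trends exports — aimed at infodemiology and public-health
surveillance questions such as *when during the day do people search for
depression-related help?*

Hourly RSV series mix three things: the diurnal cycle of interest, slow
multi-day trends, and sub-daily noise. `diurnalseek` separates them with a
continuous wavelet transform and quantifies what remains:

1. **Band-pass reconstruction.** A Morlet CWT (ω₀ = 6, Torrence–Compo
   convention) decomposes the series over scales; the inverse transform is
   taken over only the scales whose Fourier periods λ = 4πs/(ω₀ + √(2+ω₀²))
   lie in 4 h ≤ λ ≤ 32 h, discarding trends (λ > 32 h) and noise (λ < 4 h):

   x̂(t) = (dj √dt) / (C_δ ψ₀(0)) · Σ_{j: λⱼ ∈ band} Re(Wⱼ(t)) / √sⱼ,
   with C_δ = 0.776, ψ₀(0) = π^(−1/4).

2. **Diurnal profile.** The reconstruction is folded into days × 24 hours;
   the column means give the mean diurnal profile, summarized by its peak
   hour, trough hour and the peak–trough difference in percentage points
   (pp) of the 0–100 RSV scale.

3. **Hourly significance matrix.** One-way ANOVA across the 24 hourly
   distributions (days as replicates) followed by Tukey–Kramer all-pairs
   comparisons yields a directional 24×24 matrix: hour *i* significantly
   greater than hour *j* at α = .05.

4. **Trichotomization.** Raw hourly RSV is split into three 8-hour blocks —
   night (0:00–7:59), work (8:00–15:59), evening (16:00–23:59) — and
   compared by ANOVA with Bonferroni-corrected pairwise t tests.

Weekly Google Trends downloads are each normalized to their own maximum;
`stitch_weekly()` rescales overlapping segments onto one scale via the
ratio of means over the shared hours and renormalizes the stitched series
to max = 100. A synthetic generator (`synthetic_config()`,
`generate_series()`) produces series with known diurnal amplitude, trend,
high-frequency and white noise, giving every stage a ground truth.

## Worked example

```r
library(diurnalseek)

cfg <- synthetic_config(n_days = 31, terms = "masennus", seed = 2017)
gen <- generate_series(cfg)                 # 744 hourly values, known truth
rec <- reconstruct_series(gen$series$masennus, band = c(4, 32))
prof <- mean_profile(fold_days(rec))
prof
#> <diurnal_profile> term='masennus'  max. at 2-3, min. at 14-15, difference 30.3 pp
gen$truth$true_pp_difference["masennus"]    # 30.5 pp ground truth

sig <- tukey_kramer(fold_days(rec), alpha = 0.05)
sig$greater["2", "8"]                       # TRUE: 2-3 AM > 8-9 AM

block_anova_posthoc(gen$series$masennus)
#> <block_analysis> term='masennus'  unit=hour  F=111  p=7.12e-43
#>    block   n     mean       sd
#>    night 248 67.96774 16.27493
#>     work 248 46.17339 16.63292
#>  evening 248 53.91935 16.64349
#>  block_a block_b mean_diff     p_raw p_bonferroni
#>    night    work    21.794 4.667e-41    1.400e-40
#>    night evening    14.048 8.765e-20    2.629e-19
#>     work evening    -7.746 3.169e-07    9.508e-07
```

The synthetic month peaks at 2 AM with a 30.5 pp true peak–trough
difference; the pipeline recovers the peak window (2–3 AM) and estimates
30.3 pp. The night block's mean RSV exceeds the work block's by 21.8 points
(Bonferroni p ≈ 10⁻⁴⁰).

`run_pipeline(config, out_dir)` executes all stages for every term and
writes per-term profile, significance-matrix and block CSVs plus a JSON
manifest; a thin CLI wrapper lives at `inst/exec/diurnal-seek`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline from scratch on the stated synthetic world (31
days × 6 query terms, night-peaking diurnal signal, 72 h trend, 2 h jitter,
white noise), prints each term's peak/trough window and pp difference, and
writes the JSON report to `--out`.
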