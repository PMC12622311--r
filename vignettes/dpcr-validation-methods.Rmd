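---
title: "Methods: duplex dPCR GM quantification and its in-house validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex dPCR GM quantification and its in-house validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcrval)
```

## The measurement model

Digital PCR partitions a reaction into tens of thousands of sub-reactions
(droplets or nanoplate chambers) and scores each one positive or negative at
end point. If target molecules distribute with mean $\lambda$ copies per
partition, partition occupancy is Poisson and the fraction of negative
partitions estimates $e^{-\lambda}$, so

$$\hat\lambda = -\ln\!\frac{n_{\mathrm{tot}} - n_{+}}{n_{\mathrm{tot}}},
\qquad
\widehat{\mathrm{var}}(\hat\lambda) = \frac{e^{\hat\lambda} - 1}{n_{\mathrm{tot}}}$$

where the variance is the delta-method transform of the binomial variance of
the negative fraction. Instrument software ordinarily performs this step; the
package implements it directly (`estimate_lambda()`) so quantification is
auditable. Concentration follows from the partition volume $v_p$:
copies/µl $= \hat\lambda / v_p$, and copies/reaction scale by the reaction
volume. The 95% confidence interval is the normal-approximation interval on
$\lambda$, transformed and floored at zero; at the partition counts involved
(≥ 10,000 accepted partitions, usually ≥ tens of positives) the normal
approximation is adequate, which the coverage tests confirm empirically.
Wells in which *every* partition is positive carry no quantitative
information; `estimate_lambda()` raises a saturation error rather than
returning a clipped value, because a clipped estimate would bias every
downstream validation statistic.

GM content as a mass fraction combines the two channels of a duplex well:

$$\mathrm{GM\%} = \frac{cp_{\mathrm{GM}}}{cp_{\mathrm{lec}}}
\cdot \frac{1}{CF} \cdot 100$$

with $cp$ the copies per reaction of the event-specific target and of the
lectin reference gene, and $CF$ the event-specific conversion factor that
maps a copy ratio onto a certified mass fraction. Conversion factors are
published per event and reference material; they are configuration inputs
here (default 1), as are the certified reference values. Measured GM%
above 100 is reported as computed, never truncated: with an essentially
pure reference material, noise can legitimately push the estimate past the
certified value, and truncation would bias trueness.

## Platform regimes

Two preset `platform_profile()`s describe the regimes the generator
emulates: a droplet system (~20,000 droplets of 0.85 nl in 20 µl, wells
accepted above 10,000 droplets) and a 26,000-partition nanoplate (0.91 nl,
40 µl). The partition volumes are vendor-nominal figures; everything in the
profile is overridable because these constants differ between instruments
and software versions. The 10,000-accepted-partitions rule is applied to
both regimes unless overridden — the nanoplate literature states no separate
minimum, and using one common floor keeps the QC comparable across
platforms.

## Partition classification and rain

Real channels show a third population: "rain", partitions of intermediate
fluorescence that belong clearly to neither cluster. `classify_partitions()`
uses a two-fence rule: the negative fence sits $f$ robust spreads (MAD)
above the negative population's median, the positive fence $f$ spreads below
the positive median (default $f = 3$); everything at or above the positive
fence is positive, everything strictly between the fences is rain. The two
populations are located by 2-means clustering initialised at the amplitude
extremes, which is deterministic and robust to moderate rain because medians
and MADs ignore the band. This is a deliberate simplification of
percentile-fence rain classifiers distributed as analysis scripts for
droplet readers; it reproduces their behaviour on separable populations and
is documented as an approximation, not a reimplementation. Rain partitions
count as **negative** for quantification, matching end-point callers that
threshold at the positive fence; whether the original instrument analyses
excluded rain from the total instead is not documented, and the choice
matters only at rain fractions far above the acceptance limit. That limit is
the standard one: rain must stay below 2.5% of partitions
(`rain_fraction()`), evaluated strictly.

## Well QC and cross-talk

A sample well passes QC when every channel has at least the platform minimum
of accepted partitions and the reference channel amplifies (more positives
than the NTC limit); an NTC passes when no channel exceeds that limit
(default ≤ 2 positive partitions). Verdicts are flags with reason codes —
wells are never silently dropped, and `gm_measurements()` logs every
exclusion so validation statistics stay auditable. The GM channel of a
sample is deliberately not required to amplify: a 0% material is a valid
sample.

`crosstalk_check()` applies the NTC rule to the GM channel of wells that
contain only the reference gene. Its precondition (no GM event present)
cannot be verified from counts alone, so a heuristic guards it: a GM-channel
positive fraction above 0.5% is far beyond what optical bleed-through
produces and is treated as genuine amplification — an invalid layout — rather
than a cross-talk failure. The threshold sits two orders of magnitude above
the NTC limit on a 20,000-partition well, so the two regimes cannot collide.

## The validation battery

All thresholds follow the minimum-performance requirements used for GMO
quantification methods and are configurable in `run_config()`:

| Parameter      | Statistic                                   | Acceptance        |
|----------------|---------------------------------------------|-------------------|
| Trueness       | relative bias of the mean vs reference      | within ±25%       |
| Precision      | RSDr (pooled within-run SD / mean)          | ≤ 25%             |
| Dynamic range  | both criteria per level                     | widest contiguous passing span |
| Linearity      | per-run OLS of measured on nominal GM%      | R² ≥ 0.98, slope 1 ± 0.25 |
| LOQ (asym.)    | RSDr at candidate low levels                | ≤ 25%, ≥ 30 replicates |
| Robustness     | per-condition RSDr and bias                 | both < 30%        |

**Precision.** The repeatability SD pools within-run variation: it is the
square root of the one-way ANOVA residual mean square across runs (computed
with `stats::aov`). Whether "repeatability" pools runs or treats all
replicates as one group is often left implicit in validation reports; the
pooled choice is what "repeatability conditions within runs" means
operationally, and a flat-SD fallback covers single-run data. Intermediate
precision adds the between-run component from the standard one-way
random-effects moment estimator (negative estimates truncated at zero). Runs
are labels; day structure is carried as a label only, not as a nested
variance component.

**Bias** is computed signed and compared as a magnitude, matching the
convention of printing all-positive bias columns.

**Linearity** is fitted by ordinary least squares on the linear GM% scale —
consistent with validation tables whose intercepts are small positive
numbers alongside slopes near one, which a log-scale fit would not produce.
Replicates are averaged within run × level before the per-run fit (the
`aggregate` argument). This matches how per-run validation reports with
R² ≈ 1.00 at replicate RSDr of 10–20% must have been computed: on raw
replicate pairs, R² is bounded near $1 - c^2 \Sigma x^2 / \Sigma(x-\bar
x)^2 \approx 0.987$ at 10% noise and can never print as 1.00. A related
numerical fact documented here because it shapes the tests: with
multiplicative noise of CV $c$, the per-run slope estimate carries a
sampling SE of about $c/\sqrt{r}$ from the top level alone ($r$ replicates
per level) — about 0.04 at $c = 0.1$, $r = 6$. Individual run slopes
therefore scatter well beyond ±0.05 by construction, while the mean slope
across five runs is stable to ±0.02. The parameter-recovery tests assert
the mean slope and hold individual runs to the 1 ± 0.25 acceptance band.

**Asymmetric LOQ.** The package operationalises the LOQ as: the lowest
candidate level, measured with at least `min_replicates` replicates
(default 30), whose GM% replicates satisfy RSDr ≤ 25%; the LOQ is the mean
measured GM copies per reaction at that level. "No candidate passes" is a
verdict, not an exception. This definition is stated prominently because
tabulated LOQ procedures in validation reports are not always
reconstructable from the printed summaries.

**Robustness.** `robustness_design()` builds the full factorial of up to six
two-level factors (the canonical four: mastermix −10%, annealing +1 °C,
ramp +0.5 °C/s, oligonucleotides −10%) in deterministic standard order, and
`robustness_evaluate()` requires every condition to keep RSDr and |bias|
strictly below 30%. Conditions with fewer than two replicates are flagged
incomplete and fail the overall verdict; missing data can never pass
silently. No multiplicity correction is applied across levels or conditions —
the acceptance rules are per-level hard thresholds by design.

**Measurement uncertainty** combines relative components in quadrature:
$u_{\mathrm{rep}} = (\mathrm{RSDr}/100)/\sqrt{n}$ for the mean,
$u_{\mathrm{bias}} = \sqrt{b^2 + u_{\mathrm{ref}}^2}$ with $b$ the relative
bias and $u_{\mathrm{ref}}$ the reference material's relative standard
uncertainty, and $U = 2\,u_c\,\bar{x}$ at coverage factor $k = 2$. This is
the relative-combination pattern of the uncertainty guidance for GMO
analysis. Published U columns typically fold in further sources (pipetting,
partition-volume calibration) whose inputs are not recoverable from summary
tables, so printed U values are not reconstruction targets here.

## The synthetic-data generator

`simulate_experiment()` emulates the statistical structure the analysis
assumes, per (level × replicate × run) duplex well:

* accepted partition counts drawn Gaussian around the platform nominal with
  CV 5% (real instruments lose droplets/partitions), floored at the QC
  minimum so QC failures are injected deliberately, not at random;
* lectin loading at `lec_copies_per_reaction` (default 100,000 — a typical
  extract concentration that leaves the lowest level, 0.05%, with ~50 GM
  copies per reaction, the regime where an asymmetric LOQ is meaningful);
* a common lognormal DNA factor (CV 5%) on both channels — it cancels in the
  ratio, as total-DNA pipetting error does;
* an independent lognormal factor (CV 10% by default) on the GM/lectin ratio,
  representing mixture heterogeneity and channel-specific pipetting — this is
  what sets the RSDr floor of simulated validation runs;
* GM and lectin occupancies as independent Poisson loadings (duplex assays
  are run after optimisation has removed interference; no partition-level
  competition is modelled);
* one NTC per run with Poisson(0.2) contaminating positives per channel, so
  the ≤ 2 rule is occasionally exercised.

`simulate_amplitudes()` adds the fluorescence layer: exactly
`round(rain_fraction × n_total)` partitions uniform in the rain band, carved
out of the negative pool (consistent with rain counting as negative), the
rest Gaussian. `simulate_gm_measurements()` generates at the measurement
level (GM% = level × unit-mean lognormal) for tests whose target is the
validation statistics themselves.

What the generator does **not** emulate: optical cross-talk between
channels, droplet-size variation and its effect on partition volume,
inhibitor chemistry (inhibition appears only as the recovery multiplier in
`simulate_dilution_series()`), day-nested run effects, and between-extract
variation. Tests passing on this generator therefore demonstrate that the
statistical pipeline is correct under its stated model; they do not
demonstrate robustness to instrument-specific artefacts, which only real
exports can show.

## Mixture planning

Gravimetric mixtures are planned on reference-gene copy balance: blending a
GM stock of level $s$ with non-GM material at mass fraction $w$, where each
component contributes lectin copies proportional to its copies-per-mass
yield $a$, gives blend level $s\,w\,a_g / (w\,a_g + (1-w)\,a_w)$, solved in
closed form for $w$. With equal yields this is the intuitive
$w = \mathrm{target}/\mathrm{stock}$; unequal yields (different varieties,
different extraction efficiencies) shift $w$ and are the reason real
mixtures are planned on measured copy numbers rather than on mass alone.

## Problem sizes and numerical choices in the tests

The test-suite simulations use the study-scale design (7 levels × 6
replicates × 5 runs, ~20,000 partitions per well) for the end-to-end run,
and 200-replicate Monte-Carlo loops at 20,000 partitions for estimator
consistency, CI coverage and parameter recovery — sizes at which Monte-Carlo
error is a few times smaller than the tolerances asserted, chosen as the
package's own verification budget. Engineered fixtures (exact sample mean
and CV by standardisation) are used wherever an acceptance rule is asserted
at a sharp threshold, so those tests are deterministic rather than
probabilistic.

## Known limitations

* Vendor export formats are not parsed; a single neutral CSV dialect is
  defined and documented instead (see `read_partition_csv()`).
* The rain classifier is a two-fence approximation, not a reimplementation
  of percentile-fence tools; on heavily overlapping populations it errs
  conservative (more rain).
* Uncertainty budgets cover repeatability and trueness components only.
* Collaborative-trial (inter-laboratory) statistics are out of scope; the
  battery here is the in-house tier that precedes a collaborative trial.
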