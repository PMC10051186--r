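---
title: "Methods: from wearable sensor streams to microenvironment-resolved exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wearable sensor streams to microenvironment-resolved exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wearexpo analyses personal exposure (PE) to air pollutants measured by
low-cost sensors worn by study participants: particulate matter (PM1,
PM2.5, PM10, in µg·m⁻³), nitrogen dioxide (NO2, µg·m⁻³) and black carbon
(BC, ng·m⁻³), sampled once per minute, together with a GPS track. The
package covers the whole chain a campaign of this kind needs: artifact
curation, automatic microenvironment assignment, rule-based post-processing,
environment-stratified exposure statistics, and collocation-based sensor
qualification. A synthetic campaign generator with known ground truth makes
every stage testable without access to field data.

This vignette explains the models and the decisions behind them; the README
shows the code to run the pipeline.

## Curation of per-minute sensor series

Wearable low-cost sensors produce spiky, gappy, occasionally absurd data.
`curate()` applies, in a frozen order:

1. **Warm-up trimming** (NO2 only). Electrochemical cells read high for a few
   minutes after power-on. Every gap of more than `warmup_gap = 10` minutes
   in the recorded series is treated as a power-on boundary and the first
   `warmup_minutes = 3` minutes of data after it are discarded. Discarded
   values are *invalidated in place* (the row stays, the value becomes
   missing) rather than dropped: dropping rows would shift the boundary and
   make re-curation trim again, so invalidation is what makes curation a
   fixed point (`curate(curate(x))` removes nothing).
2. **Range filtering.** Per-channel plausibility limits, configuration-exposed
   with defaults NO2 [0, 1000], PM [0, 2000] µg·m⁻³, temperature
   [−30, 60] °C, humidity [0, 100] %RH.
3. **Peak removal.** A value $s_i$ is an artifact when
   $s_i > f \cdot \mathrm{mean}\{s_j : i-k \le j \le i+k,\ j \ne i\}$
   with $k = f = 2$: a five-minute window, flagging values more than twice
   the mean of their neighbours. The rule is one-sided (negative excursions
   are left to the range limits), missing neighbours are excluded from the
   mean, and a position with fewer than two usable neighbours is never
   flagged. `curate()` applies the rule to convergence: removing a genuine
   spike lowers its neighbours' window mean and can expose an adjacent
   flagged value, so a single pass is not a fixed point while the iterated
   rule is. `detect_peaks()` itself is the single-pass mask, which is what
   the brute-force oracle in the test suite checks exactly.
4. **BC noise floor.** The aethalometer's detection limit is about
   1500 ng·m⁻³ (three SDs of its background signal), so values below
   −1500 ng·m⁻³ are physically meaningless and removed; negative values at
   or above the floor are retained deliberately, because clipping them would
   bias low-concentration averages upward. The boundary is inclusive.
5. **Particle-size consistency.** By definition PM1 ⊆ PM2.5 ⊆ PM10; minutes
   where all three channels are present but the ordering fails are removed
   from all three.
6. **GPS speed filter.** A single forward pass drops every point implying a
   great-circle speed above 130 km/h from the last retained point —
   appropriate for an urban/suburban campaign. Per-minute mean speed is then
   derived from the surviving segments (midpoint rule).
7. **Fusion.** All channels are joined on the minute grid; a row exists only
   where at least one of the seven *sensor* channels has a value (speed or
   position alone does not make a row). Labels come from covering annotation
   intervals; sub-minute GPS collapses to a per-minute centroid.

Every removal is counted per (channel, rule) and returned point-by-point, so
lossy steps are fully auditable. On the default synthetic campaign about 8%
of values are removed, consistent with the roughly-ten-percent regime such
campaigns report.

The stage order (warm-up → range → peak → floor → ordering) is frozen and
pinned by a count-consistency property test; whether peak removal should
precede or follow range filtering is not determined by the problem, so the
package documents its choice rather than exposing it.

## Microenvironment assignment: multi-view stacking

Exposure depends strongly on context, so minutes are classified into five
microenvironments — home, office, indoor (shops, restaurants, stations),
outdoor, transport — from the sensor streams themselves.

Each of the eight channels (seven sensors plus GPS-derived speed) is a
*view*. For every minute and view, the trailing `W = 15`-minute window is
summarised by eight features: mean, SD, min, max, median, IQR, OLS slope,
and the fraction of missing minutes. Windows are time-based (gaps count as
missing, they are not skipped), and a view with an empty window is *absent*,
never zero-filled. Fifteen minutes is long enough to stabilise the
statistics yet shorter than most bouts; no principled value exists, so W is
a config parameter.

A first-level probability random forest is trained per view on its eight
features. The meta-learner sees, per view, exactly two entries — the
predicted class and its probability (so eight views make a 16-entry input
row) — and maps the concatenation to the final label and confidence.
Stacking uses out-of-fold first-level predictions (K = 5) so the
meta-learner never sees in-sample first-level output; at prediction time an
absent view contributes the sentinel class `"absent"` with a uniform
probability. Random forests (via ranger) were chosen because the learner
family is not dictated by the method; forest sizes, K, and W are config
arguments. All fits are seeded and single-threaded, making training and
prediction bit-reproducible.

Class imbalance is severe by construction — home and office dominate any
realistic week — so training windows are balanced first: classes above the
median class count are undersampled uniformly; classes below it are topped
up with SMOTE, each synthetic row being $x + \lambda(x_{nn} - x)$ with
$\lambda \sim U(0,1)$ and $x_{nn}$ among the 5 nearest minority neighbours.
Balancing operates on window-feature rows, not raw minutes, so synthetic
samples live in the learner's input space; original rows are never altered
and every synthetic row carries a provenance flag. GAN-style time-series
augmentation is deliberately out of scope: it adds an unverifiable training
component, and the balancing interface accepts a pluggable augmenter should
one want it.

Train/test splits are grouped by participant. Random minute-level splits
leak: adjacent minutes of one person are nearly identical, and a model
evaluated that way reports accuracy it will not deliver on a new
participant.

## Rule-based post-processing

Model output is corrected per participant in three steps:

1. **Stop segmentation.** Per-minute positions are binned on a 100 m
   equirectangular grid around the track centroid (adequate at city scale;
   projection error is far below the cell size at mid-latitudes). At one-minute
   GPS cadence a participant-week produces only tens of distinct cells — a
   handful of dense site pixels and transit pixels a few counts high — so
   cells at or above the median of the cell-count distribution are treated
   as dense sites (a higher quantile would land among the sites themselves
   and split them); minutes in such cells moving slower than 2 km/h —
   below walking pace but above the apparent speed of GPS jitter, so
   strolling near a site is not swallowed into its stop — in runs of at
   least 5 minutes, become stop segments.
   Within each stop segment the modal predicted label wins, but only over
   label runs that lie entirely inside the segment and are shorter than the
   stop minimum: a person does not oscillate between office and home inside
   one sitting, yet a sustained sub-episode, or the arrival/departure
   minutes of a run crossing the segment boundary, is evidence rather than
   flicker and is left alone.
2. **Home rule.** The home site is the cell with the most located minutes
   between 02:00 and 05:00 *local clock time* (Europe/Paris by default,
   per-participant configurable) over the whole record; stop segments at
   that site are relabelled home. The rule's known failure mode is honest:
   a participant who spends every night of the record in one hotel will
   have the hotel identified as "home".
3. **Label smoothing.** Runs shorter than 3 minutes are absorbed into the
   adjoining longer run (shortest runs first, ties to the earlier
   neighbour); missing labels are never absorbed or absorbing. The operation
   is idempotent.

Cell size, quantile, minimum stop and bout lengths are all config-exposed;
none has a canonical value. The reported change counts per rule make the
correction auditable, and on synthetic campaigns post-processed accuracy is
never below raw accuracy.

## Exposure statistics

`daily_means()` applies the representativeness rule: a participant-day
enters only if strictly more than 20% of its 1440 minutes carry a value.
`resolution_stats()` produces the three-resolution summary (pooled daily
mean; hourly mean/SD/median computed on hourly means, not pooled minutes —
the two-stage reading of the day/hour/minute table; minute-level p95).
`environment_stats()` gives the boxplot statistics per environment (p10/p90
whiskers, p25/p75 box, median, mean) with a low-support flag below 30
minutes, `time_budget()` the share of labelled time per environment, and
`who_compare()` flags participant-days whose mean exceeds the WHO 24-hour
guidelines (NO2 25, PM2.5 15, PM10 45 µg·m⁻³; PM1 and BC have none and are
skipped explicitly). All percentiles are linear-interpolation (type 7)
order-statistic quantiles, pinned and documented.

## Sensor qualification

`evaluate_sensor()` compares a sensor series against a reference instrument
after block-averaging both to a common step (references report at 1, 5 or
15 minutes). Seven metrics are computed: RMSE; Pearson, Kendall and
Spearman correlations; the presence ratio (recorded over expected samples);
a threshold match score (agreement on exceeding the reference's p90); and a
low-frequency energy score (one minus the normalised periodogram energy of
the sensor-minus-reference error below the 60-minute cutoff — 1 means no
drift). The integrated performance index (IPI) maps each defined metric to
[0, 1] — RMSE via $1/(1 + \mathrm{RMSE}/\mathrm{IQR}_{ref})$, correlations
via $(r+1)/2$, the rest natively — and takes their (by default unweighted)
mean, so a perfect sensor scores exactly 1. Match score and LFE follow
operational definitions that are stated, config-exposed and versioned here;
the metric *names* are standard in the sensor-qualification literature but
their exact toolbox formulas live in a secondary source, so this package
states its own and lets an implementer substitute others. For the same
reason, published IPI tables from physical collocation campaigns are not
reproduction targets: they depend on data that was never released.

## The synthetic campaign generator

The generator emulates the statistical structure the analysis assumes, with
every piece of ground truth retained:

* **Schedules.** Days are built as stochastic routines: per-day environment
  budgets are the occupancy fractions of 1440 minutes (defaults home 68%,
  office 24%, indoor 3%, outdoor 1%, transport 4%) with multiplicative
  gamma jitter; the home budget anchors the night (midnight to a jittered
  wake time, and the evening), other budgets split into bouts of typical
  length `mean_bout`, shuffled, with transport bouts bracketing the day as
  commutes. An iid-entry semi-Markov scheduler was rejected at design time:
  its realized weekly occupancy wanders by many points, and it puts nights
  anywhere, contradicting the night-time home rule's premise. The routine
  design converges to the requested occupancy by construction (within
  ~1–2 points over a week) and sleeps at home.
* **Emissions.** Pollutant baselines are log-normal per (environment,
  channel), temperature and humidity Gaussian, with means following the
  campaign-reported ordering (transport NO2 highest at 45 µg·m⁻³, home low
  at 18 µg·m⁻³ NO2 and 9 µg·m⁻³ PM10; indoor PM highest). Minute-scale
  deviations follow an AR(1) process (φ = 0.9): real ambient series are
  strongly autocorrelated, and white-noise baselines would make the
  windowed-mean peak rule fire on noise. Cooking-like activity peaks (linear
  four-minute rise, exponential decay) occur at home and indoors. The three
  PM channels are generated jointly — pm25 = pm1·(1+u₁), pm10 = pm25·(1+u₂)
  with per-bout gamma ratios, u ≥ 0 — so clean data satisfy the size
  ordering *by construction* and only artifacts can violate it, giving the
  ordering filter known ground truth. The `separation` knob divides all
  dispersions; `separation = 3` gives ≥3-SD mean gaps on the discriminative
  channels and is the condition under which the classifier properties are
  asserted.
* **Artifacts.** Isolated multiplicative spike glitches (factor ≈ 8, six
  per hour per channel, at least five minutes apart, every one recorded in
  a ledger), 2% random dropouts, two power-off periods per day (giving
  warm-up transients a +40 µg·m⁻³ NO2 bias after restart), AR(1) zero-mean
  BC instrument noise (SD 300 ng·m⁻³ — white noise at this SNR would
  swamp the peak rule; instrument noise is autocorrelated at the minute
  scale), 5 m GPS jitter and teleport outliers that exercise the speed
  filter.
* **Geometry.** Stationary bouts cluster at fixed home/office/indoor sites;
  outdoor bouts are walking loops; transport interpolates between sites at
  realistic speeds. Positions are built in local metres and converted to
  WGS84 once.

Everything flows from one explicit seed (participant-level sub-seeds are
drawn from it), so campaigns are bit-reproducible.

**What passing tests do and do not show.** The generator reproduces the
*structure* the pipeline relies on — occupancy, level ordering,
autocorrelation, artifact types, site geometry — not calibrated physical
distributions; no public per-environment distributions exist to calibrate
against. Classifier accuracy on well-separated synthetic environments
demonstrates that the stacking machinery works, not that 90% accuracy is
attainable on any real cohort; real environments overlap more, transitions
are fuzzier, and sensors drift between calibrations. The test problem sizes
(one participant-week for curation properties; ten participant-weeks,
grouped 7/3, for the classifier; five for the end-to-end run) were chosen
as the smallest studies at which the stochastic properties are stable.

## Numerical conventions and limitations

* Timestamps are stored and compared in UTC; local clock time (default
  Europe/Paris) is applied only where it matters: day boundaries for daily
  means and the night window of the home rule.
* Duplicate timestamps on read keep the last occurrence (logged);
  sub-minute samples are floored to the minute and averaged.
* Missing values are empty CSV fields, never sentinels; a removed value and
  a never-recorded value are distinguished only by the removal report.
* Percentiles are type-7 everywhere; the IPI's RMSE scale is the reference
  IQR; correlation of a constant series is reported missing, not zero.
* Single-home assumption in the home rule; no map-matching; no humidity
  correction of PM (deliberately, matching field practice for these
  sensors); no inter-unit sensor variability model.
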