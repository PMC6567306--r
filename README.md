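# pheromap

Long-term, annotation-free activity monitoring for a single person living
alone, from nothing but binary ambient sensors (PIR motion detectors, door
contacts, pressure mats). `pheromap` is aimed at ambient-assisted-living
researchers and tinkerers who have an event log — or want to simulate one —
and need a reproducible answer to: *is today's activity pattern still this
person's usual routine, and when did the routine change?*

## The method

1. **Places, not floor plans.** The home is abstracted to a few
   behaviorally significant places (P1 bedroom, P2 kitchen, P3 bathroom,
   P4 living room); every sensor belongs to one place. Raw logs are
   preprocessed (motion-OFF removal, 60 s per-sensor debouncing, 10 min
   pressure-mat muting) and binned into hourly per-place counts.
2. **Virtual-pheromone maps.** Each hour becomes a 128×128 grayscale
   image: place *p* holds a pheromone source of intensity equal to its
   hourly count, sensed at distance *x* as

   p(x) = P·(1 − x/σ) for x ≤ σ, else 0,

   sources superpose additively, and (in evaporation mode) decay linearly
   with time constant τ. Pixel brightness encodes aggregated intensity.
3. **Similarity vs a reference week.** A reference set of 24 hourly images
   is built from counts averaged over a low-variability week. Each day's
   images are compared hour-by-hour with the global single-window
   structural similarity index

   SSIM(x,y) = (2μₓμᵧ + C₁)(2σₓᵧ + C₂) / ((μₓ² + μᵧ² + C₁)(σₓ² + σᵧ² + C₂)),

   C₁ = (0.01·255)², C₂ = (0.03·255)², and the **daily index** is the mean
   of the hourly SSIMs (optionally over an hour subset, e.g. 7–9 for the
   breakfast window).
4. **Detection.** Singular deviating days are flagged one-sidedly at
   median − 3·MAD; sustained routine change is located by an exhaustive
   single change-point scan accepting only descending steps that remove
   more than 30 % of the series' SSE.

A built-in simulator generates realistic event streams (Poisson hourly
rates per place, ON/OFF pairs, double-fires, injectable anomalous days,
mid-series sensor upgrades, sensor faults), so the whole pipeline runs and
is tested without downloading any dataset.

## Worked example

Sixty simulated days containing two 80 % away-days and one 4-hour sleep
shift (days 15, 25, 35), plus a kitchen sensor-set upgrade at day 40:

```r
library(pheromap)
res <- evaluate_scenario(scenario_full(seed = 1))
res$report
#> <anomaly_report>
#>   3 outlier day(s):
#>     2021-03-15  index 0.275  (robust z -10.0)
#>     2021-03-25  index 0.641  (robust z -3.1)
#>     2021-04-04  index 0.205  (robust z -11.3)
#>   descending shift at 2021-04-08: mean 0.807 -> 0.717 (SSE reduction 49%)
```

All three injected anomalies are flagged with no false positives — the two
away-days are unmistakable (robust z ≈ −10: the home goes nearly dark, so
the day's maps barely correlate with the reference), the sleep shift a
milder deviation that still crosses the −3 threshold — and the sensor
upgrade is located at
2021-04-08, one day off the true change (day 40 = 2021-04-09): from that
day the kitchen's event flow quadruples, the morning maps stop matching
the pre-upgrade reference, and the daily index steps down from 0.81 to
0.72.

File-based use mirrors the same pipeline:

```r
cfg <- pipeline_config(input = "events.txt", dialect = "casas",
                       mapping = hh126_mapping(),
                       reference = list(criterion = "min_dispersion", days = 7),
                       out_dir = "out")
run_pipeline(cfg)   # daily_activity.csv, similarity.csv/.png, anomaly_report.json
```

or from a shell via the thin CLI
(`Rscript $(Rscript -e 'cat(system.file("cli","pheromap.R",package="pheromap"))') run --help`),
with subcommands `simulate`, `preprocess`, `maps`, `similarity`, `detect`
and `run`.

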