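# thermopattern

Derives short-term **temperature change patterns** from radiometric thermal
video of cattle eyes and muzzles and quantifies how unique those patterns
are within an individual.

The eye and the hairless muzzle are *thermal windows* — richly
vascularized surfaces whose temperature tracks autonomic state. A mobile
thermal camera (80 × 60 px, 8.7 frames/s, 0.07 °C sensitivity) filming a
calf for 1–2 minutes yields, per region, a mean-temperature series of a
few hundred points. This package is for researchers in animal welfare and
veterinary physiology who want to turn such series into comparable pattern
vectors and test whether the eye and muzzle of the same animal move
together — evidence that the short-term pattern is physiological signal
rather than noise.

## What it computes

Per region, the raw per-frame ROI mean series is conditioned into a
pattern vector:

1. **Outlier rejection** — Tukey fences
   `[Q1 − g(Q3 − Q1), Q3 + g(Q3 − Q1)]` with `g = 1.5`, quartiles as
   Tukey's hinges; out-of-fence frames become missing.
2. **Standardization** — `z = (x − x̄)/s` (sample sd), removing individual
   and ambient offsets.
3. **Regridding** — linear interpolation onto the uniform `1/fps` grid;
   interior gaps bridged, edges trimmed.
4. **Low-pass filtering** — zero-phase order-4 Butterworth, cutoff
   0.08 Hz, removing sensor noise, respiration (~0.5 Hz) and cardiac
   (~1.5 Hz) components.

The eye and muzzle patterns `V1, V2` are then compared by cosine
similarity,

```
cos(V1, V2) = (V1 · V2) / (‖V1‖ ‖V2‖)
```

and its significance assessed by permuting the muzzle vector 10,000 times:
`p = #{null ≥ observed} / 10000`. Results are reported in three similarity
bands (`0.5-1`, `0.3-0.5`, `<0.3`) with per-sample quality flags.

A synthetic-data module generates paired eye/muzzle recordings with a
shared low-frequency latent pattern, sensor noise, respiration/cardiac
oscillations, outlier spikes, detection dropouts and the two
detection-failure modes seen in the field (mislocated eye, sideways
muzzle) — at series level or rendered as full 80 × 60 frame stacks with
ROI polygon tracks — so the entire analysis runs with no external data.
I/O covers calibrated multi-page float TIFF stacks (JSON sidecar),
per-frame CSV rasters, VIA-style polygon annotation JSON and series CSV.

## Worked example

```r
library(thermopattern)

## one synthetic sample under the study conditions: 90 s at 8.7 fps,
## shared-variance coupling 0.9, default noise
p <- generatePairedSeries(syntheticSampleConfig(seed = 1), sampleId = "demo")
p$eye
#> TemperatureSeries 'eye' (demo): 783 frames, 0 missing, range 30.56-42.53 degC

res <- runSample(p$eye, p$muzzle, config = pipelineConfig(seed = 1))
res
#> SimilarityResult 'demo': cosine = 0.745, p = 0, bin 0.5-1
res@null
#> PermutationNull: p = 0 (0 of 10000 >= observed), null mean 0.0012 sd 0.0374
```

The two conditioned patterns agree with cosine 0.745 — in the top
similarity band, comparable to the ~0.7 values genuine paired recordings
show. The permutation null is centred at 0 with sd 0.037, so the observed
similarity is about twenty null standard deviations out and no permutation
reaches it: `p = 0` under the count/N formula, i.e. the pattern's shape
cannot be explained by frame order chance.

Cohort-level use mirrors the field design (33 samples, some with
detection failures):

```r
cohort <- generateCohort(
  33, syntheticSampleConfig(coupling = 0.9), seed = 1,
  failureModes = c(sideways_muzzle = 3, eye_detection_failure = 4))
summ <- runCohort(cohort, pipelineConfig(nPermutations = 10000, seed = 1))
summ
#> CohortSummary: 33 samples, mean cosine 0.756
#>      bin n_samples median_p max_p
#>    0.5-1        28   0.0000     0
#>  0.3-0.5         1   0.0000     0
#>     <0.3         4   0.3461     1
#>   4 flagged sample(s)
```

The four mislocated-eye samples are the four flagged ones; their cosines
sit near zero while the coupled samples land in the `0.5-1` band with
`p < 0.01`. `plotPatterns()` and `plotStages()` write the overlay and
stage-by-stage figures.

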