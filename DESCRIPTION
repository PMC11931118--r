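Package: thermopattern
Title: Temperature Change Patterns from Infrared Thermography of Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives short-term temperature change patterns from radiometric
    thermal video of cattle eyes and muzzles and quantifies their
    within-individual uniqueness. Per-frame region-of-interest mean
    temperatures are conditioned by Tukey-fence outlier rejection,
    z-score standardization and zero-phase low-pass filtering (0.08 Hz),
    and paired eye/muzzle patterns are compared by cosine similarity with
    a permutation test. Includes readers and writers for calibrated
    multi-page float TIFF frame stacks, VIA-style polygon annotations and
    per-frame CSV rasters, plus a synthetic-data generator that emulates
    paired thermal recordings, sensor noise, respiration and cardiac
    interference, outlier spikes and region-detection failures, so the
    full analysis is testable without field footage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    signal,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'conditioning.R'
    'filter.R'
    'io-frames.R'
    'io-via.R'
    'pipeline.R'
    'plots.R'
    'rasterize.R'
    'similarity.R'
    'synthetic.R'
    'utils.R'
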