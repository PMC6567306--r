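Package: pheromap
Title: Virtual-Pheromone Activity Maps for Long-Term Routine Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns binary ambient-sensor event logs (PIR motion detectors,
    door contacts, pressure sensors) from a smart home into hourly grayscale
    activity maps built with a virtual-pheromone model over a small set of
    behaviorally significant places (bedroom, kitchen, bathroom, living
    room). Daily map sets are compared against an hourly-averaged reference
    week with the structural similarity index (SSIM), producing a per-day
    similarity series in which singular low-similarity days and sustained
    descending shifts flag deviations from the resident's long-term routine.
    Includes readers for CASAS-style text logs and a generic CSV dialect,
    the preprocessing rules the method requires (motion-OFF removal,
    per-sensor debouncing, pressure-sensor muting), robust outlier and
    change-point detectors on the similarity series, and a synthetic
    daily-routine simulator so the whole pipeline can be exercised without
    any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
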