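Package: mzmerge
Title: Merging, Replicate Quality Control and Annotation of LC/MS
    Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-extraction utilities for untargeted LC/MS metabolomics.
    Feature tables produced at multiple peak-detection parameter settings are
    merged into a single optimized table by ppm mass-tolerance and retention
    time grouping, keeping the most reproducible representative of each
    redundant group. Sample quality is scored by mean pairwise Pearson
    correlation among analytical replicates and feature quality by percent
    intensity difference (PID, duplicate designs) or coefficient of variation
    (CV, triplicate and higher designs). Further tools match and contrast
    feature lists across datasets (overlap, unique features, Venn counts,
    rare features consistent within individuals), rank parameter settings and
    setting pairs by the score S = N - w * median PID, and batch-annotate m/z
    values against a local compound database via adduct mass arithmetic. A
    synthetic-data generator with known ground truth supports end-to-end
    testing without raw spectra.
License: GPL (>= 2)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
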