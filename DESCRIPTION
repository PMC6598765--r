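Package: carrycal
Title: Carry-Over DNA Calibration and Quality Control for CUT&RUN Fragment Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and quality control for CUT&RUN chromatin profiling
    experiments. Samples in a series are calibrated by counting fragments that
    map to a constant-abundance calibration genome: either a heterologous
    spike-in (e.g. S. cerevisiae nucleosomal DNA) or the E. coli DNA carried
    over from purification of the pA/MNase or pAG/MNase fusion protein, which
    is bound per bead in constant amount and so acts as a built-in calibrant.
    Includes an exact scanner for (TA)n low-complexity regions and a fragment
    exclusion filter, scaled fractional-count genome coverage tracks, peak
    summit-window scoring with IgG percentile-based outlier removal, peak-vector
    correlation (R squared) matrices, FRiP down-sampling series, and a seeded
    synthetic multi-genome fragment simulator so the whole pipeline is testable
    at desk scale. A command-line front end covers every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
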