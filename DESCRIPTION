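Package: catrans
Title: Calcium Transient Analysis for Injection and Place-Conditioning Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Event-level analysis of single-cell calcium imaging recordings
    from drug-injection and conditioned place preference (CPP) sessions.
    Converts delta-F-over-noise fluorescence traces into calcium transient
    trains via sparse non-negative AR(1) deconvolution (online active-set /
    pool-adjacent-violators), classifies neurons as injection-excited or
    injection-inhibited with an intertransient-interval shuffling permutation
    test or a binned z-scored trace comparison (exact Wilcoxon signed-rank),
    identifies context-encoding neurons from chamber-occupancy episodes with
    exact Mann-Whitney U tests, aligns event rates around chamber entries,
    and scores place preference. A synthetic session generator with known
    ground truth lets every stage run and be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
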