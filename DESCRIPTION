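Package: vsbench
Title: Virtual-Screening Benchmark Metrics and Decoy-Set Bias Auditing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate structure-based virtual-screening results and
    to audit the chemical libraries they are benchmarked on. Implements the
    early-recognition metrics used in large docking benchmarks (docking
    enrichment at a percentile, the BEDROC score with its alpha/percentile
    calibration, and the pairwise net balance between programs), per-target
    actives-versus-decoys bias statistics (normalized property differences,
    their absolute sum S, and 2D-fingerprint Tanimoto similarity summaries),
    binding-site hydrophobicity profiling from probe-surface contacts, a
    tiered Pearson correlation screen, and unbiased-subset success-rate
    reporting. A synthetic-data module generates benchmark collections with
    known ground truth (ranked screens with tunable early enrichment,
    property tables with injected actives/decoys drift, fingerprint families,
    and cavity point sets) so the whole pipeline is testable end to end
    without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    ChemmineR,
    ChemmineOB,
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
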