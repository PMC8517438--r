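Package: hlacombine
Title: Consensus HLA Genotyping by Combining Multiple NGS Typing Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Harmonizes class I HLA (HLA-A, -B, -C) genotype calls emitted by
    a panel of eight next-generation-sequencing typing tools (OptiType,
    HLA-HD, PHLAT, seq2HLA, arcasHLA, HLAscan, HLA*LA and Kourami), selects a
    consensus genotype when at least six tools agree at two-field (four-digit)
    resolution, and recommends PCR sequencing-based typing otherwise.
    Includes the full evaluation suite for caller panels: per-tool
    availability and accuracy against a PCR-SBT reference, per-agreement-size
    true/false-call tallies with pooled accuracy, precision/recall/F1,
    pairwise correction and complementary scores, complementary ratios, a
    combination-accuracy model with threshold-based custom calling, a
    synthetic call-table simulator with correlated tool errors, and a
    constructive fixture generator that realizes exact per-group tallies.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
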