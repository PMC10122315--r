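Package: xwastrio
Title: Sex-Stratified X-Chromosome-Wide Methylation Association Analysis
    for ART Trio Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for X-chromosome-wide association studies (XWAS) of DNA
    methylation in mother-father-newborn trios, contrasting newborns
    conceived by assisted reproductive technologies (ART) with naturally
    conceived newborns.  Implements the full analysis chain: quality
    control and normalization of Illumina-style beta-value matrices
    (probe exclusion lists, detection p-value masking, greedy
    probe/sample filtering, per-sex gap-based multimodality detection,
    beta-mixture quantile normalization of type I/II probes),
    sex-stratified per-CpG linear mixed models with a plate random
    intercept and optional parental-methylation adjustment,
    empirical-null correction of test statistics by a three-component
    Gaussian mixture fitted with a Gibbs sampler, false discovery rate
    selection, correlation-adjusted inverse-variance statistics for
    differentially methylated regions, 50-kb co-methylation reports,
    stratified bootstrap consistency analysis, and a synthetic trio-data
    generator that emulates sex-specific X-chromosome methylation
    structure (X-inactivation intermediate modes, escape probes, probe
    type compression, plate batch effects, co-methylation blocks, and
    parent-child correlation) so the whole pipeline is testable without
    access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
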