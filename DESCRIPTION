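Package: cogsvd
Title: Comparative GSVD of Patient-Matched Tumor and Normal Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("cogsvd", "maintainers", email = "maintainers@cogsvd.invalid",
           role = c("aut", "cre"))
Description: Models two patient-matched DNA copy-number datasets (probes x
    patients, log2 relative copy number) with the generalized singular value
    decomposition (GSVD) formulated as a comparative spectral decomposition.
    Components ("probelets" across patients, "arraylets" across the genome)
    are ranked by angular distance, i.e. tumor-vs-normal exclusivity, and a
    tumor-exclusive arraylet is turned into genome-wide gain/loss calls at
    chromosome, arm, segment and probe resolution. Includes cross-platform
    probe matching by genomic overlap, correlation- and coefficient-based
    patient classification with a norm-scaled cutoff, Kaplan-Meier, log-rank,
    Cox and concordance survival machinery, hypergeometric and Mann-Whitney
    enrichment of patient annotations, and a synthetic-cohort generator with
    planted, survival-linked copy-number structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
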