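Package: methdetect
Title: Detection P-Values for Infinium Methylation Arrays from
    Non-Specific Background Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes detection p-values for Illumina Infinium DNA
    methylation microarrays (450K/EPIC-like designs) by estimating the
    normal background fluorescence distribution either from Illumina's
    negative control probes (NEG, the conventional approach) or from the
    non-specific fluorescence observed at the silent-allele beads of
    completely methylated and completely unmethylated Type I CpG sites
    (NSP). Includes the z-test on total intensity with a corrected
    variance (and a compatibility mode reproducing the historical
    standard-deviation-addition misspecification), masking of undetected
    observations, two benchmarks (Y-chromosome detection by sex across
    p-value cut-offs, and technical-replicate outlier concordance), and a
    seeded synthetic-array simulator with ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
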