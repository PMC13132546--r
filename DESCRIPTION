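Package: codepscreen
Title: Co-Dependency Overlap Screening, 1:1 Binding Kinetics, and NSAF
    Spectral-Count Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for guilt-by-association candidate-gene prioritization
    over CRISPR gene-effect matrices: per-seed top-k co-dependency lists
    (Pearson correlation across cell lines), an overlap score counting how
    many seed lists contain each gene, and a percentile-based score cutoff.
    Companion modules fit 1:1 Langmuir binding kinetics to biolayer
    interferometry sensorgrams (double reference subtraction,
    Savitzky-Golay smoothing, observed-rate and steady-state fits yielding
    kon, koff, KD, Rmax) and normalize affinity-purification mass
    spectrometry spectral counts to NSAF/pNSAF with bait-versus-control
    enrichment summaries. Ground-truth-known synthetic generators (planted
    correlated gene modules, forward-simulated sensorgrams, multinomial
    spectral counts) support end-to-end validation, and a command-line
    entry point exposes each workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
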