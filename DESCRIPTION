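Package: msrepair
Title: Repair of Adduct and Precursor Metadata in MS/MS Spectral Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating tandem mass spectrometry (MS/MS) spectral
    libraries whose adduct and precursor m/z metadata are missing or
    inconsistently formatted. Implements a threshold-scored dynamic-programming
    spectral alignment (optimized spectral alignment, OSA) with city-block
    tie-breaking, reference spectral similarity and distance metrics
    (greedy cosine, spectral entropy, and binned vector-space distances), a
    tolerant adduct-notation grammar with theoretical precursor m/z
    arithmetic, a learned character n-gram classifier that normalizes
    malformed adduct strings, identifier- and ion-mode-filtered adduct
    prediction with benchmarking and metadata-reliability assessment, MSP and
    HMDB-style XML/CSV input and output, library subsetting and descriptive
    statistics, and a deterministic synthetic-library generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
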