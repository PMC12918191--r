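# msrepair

Repair of adduct and precursor m/z metadata in MS/MS spectral libraries.

## The problem

Untargeted metabolomics leans on open MS/MS spectral libraries (GNPS, HMDB,
MassBank, MoNA, MS-DIAL), but their metadata are uneven: adduct annotations
are missing from a large share of spectra (about half of HMDB's
experimental spectra) or written in incompatible notations — `[M+H+H2O]+`
and `[M+H2O+H]+` are the same chemical species, yet string-matching
pipelines treat them as different and typically discard what they cannot
resolve. Each lost adduct also loses the precursor m/z it implies, and with
it the spectrum's usefulness for annotation.

`msrepair` is for library curators and metabolomics bioinformaticians who
would rather repair those spectra than drop them. It predicts missing
adducts by comparing a deficient spectrum against library spectra of the
same compound acquired in the same ionization mode, normalizes malformed
adduct strings with a grammar backed by a learned classifier, and provides
the surrounding library services (HMDB-style library construction,
subsetting, statistics, benchmarking, metadata-reliability assessment).

## The method in brief

**Optimized spectral alignment (OSA).** Two sorted peak lists are aligned
by dynamic programming over a zero-initialized (m+1)×(n+1) matrix:

    dp[i,j] = max( dp[i-1,j-1] + final_score,
                   dp[i-1,j]   + gap_penalty,
                   dp[i,j-1]   + gap_penalty )

where `final_score = 1/(1 + (qs_int_i − ss_int_j)²)` if
`|qs_mz_i − ss_mz_j| ≤ 0.005` Da and −1 otherwise, and
`gap_penalty = −0.1` (smaller in magnitude than the mismatch penalty, so
skipping a peak beats force-matching distant ones). Among score-optimal
tracebacks the one minimizing the summed m/z city-block distance over its
aligned pairs is chosen. Without intensities the intensity score is
uniformly 1. Greedy cosine, spectral-entropy similarity and ten binned
vector distances are implemented alongside for benchmarking.

**Adduct grammar + corrector.** Adduct strings parse to a structured form
(multiplier, gained/lost ions, charge) with a deterministic canonical
rendering and theoretical precursor m/z
`(k·M + Σgains − Σlosses − z·mₑ)/|z|`. Strings the grammar cannot parse go
to a character-n-gram TF-IDF + single-hidden-layer network classifier
(200 hidden units) trained on permutation/corruption variants of a
61-label dictionary; the grammar always takes precedence on parsable
input.

**Adduct prediction.** For a query lacking an adduct: retrieve subject
spectra with the same InChIKey (or SMILES/formula) and congruent ion mode,
pick the best match under a chosen metric, transfer its canonical adduct,
and — when the query's exact mass is known — emit the theoretical
precursor m/z for the predicted adduct.

## Worked example

Everything below runs on synthetic libraries with planted ground truth —
no downloads. `make_benchmark_suite()` builds four overlapping subject
libraries plus an HMDB-like library whose adducts are 50% blanked:

```r
library(msrepair)

suite   <- make_benchmark_suite(seed = 1)
subject <- concat_libraries(suite$libraries, name = "integrated")
library_stats(suite$hmdb)
#> <library_stats> 100 spectra | 50 (50.0%) missing adduct
#>   ion modes (spectra):     positive=50  negative=50  unknown=0
#>   ion modes (identifiers): positive only=0  negative only=0  both=25  missing=0
#>   25 identifiers | spectra per identifier mean 4.0 max 4
```

Pick one of the annotation-deficient spectra and repair it:

```r
ids <- vapply(suite$hmdb$spectra, function(s) s$metadata$spectrum_id, character(1))
blanked <- subset(suite$truth, spectrum_id %in% ids & blanked)
q <- suite$hmdb$spectra[[match(blanked$spectrum_id[1], ids)]]
q$metadata$adduct      # "" — this is the deficiency
predict_adduct(q, subject, metric = "osa")[
  , c("subject_id", "score", "predicted_adduct", "theoretical_precursor_mz")]
#>    subject_id     score predicted_adduct theoretical_precursor_mz
#> 1 MSDIAL:0086 0.9985098           [M+H]+                  360.057
```

The OSA similarity against the best same-compound, same-mode subject
spectrum is 0.9985; the transferred adduct `[M+H]+` equals the planted
truth (`blanked$true_adduct[1]`), and the theoretical precursor m/z
(360.057 Da) agrees with the spectrum's recorded precursor (360.0559 +
jitter). The adduct grammar behind the comparison:

```r
canonical_string(parse_adduct("[M + H2O + H] +"))
#> [1] "[M+H+H2O]+"
theoretical_precursor_mz("[M+H]+", 180.063388)
#> [1] 181.070664
```

A trained corrector fixes formatting errors the grammar alone cannot:

```r
model <- train_adduct_corrector(build_corpus(), seed = 7)
correct_adduct(model, c("[M + H] +", "M+Na", "xyz"))[, c("input", "label", "corrected")]
#>       input   label corrected
#> 1 [M + H] +  [M+H]+      TRUE   (grammar)
#> 2      M+Na [M+Na]+      TRUE   (model)
#> 3       xyz    <NA>     FALSE   (below the confidence floor)
```

A thin command-line wrapper over the same functions ships in
`inst/cli/msrepair` (`io-validate`, `adduct-canon`, `adduct-mz`, `osa`,
`correct`, `match`, `build-hmdb`, `subset`, `stats`, `synth`).

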