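---
title: "Repairing adduct metadata in MS/MS spectral libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repairing adduct metadata in MS/MS spectral libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrepair)
```

## The problem

Open MS/MS spectral libraries are rich but unevenly curated. Two metadata
fields matter disproportionately for metabolite annotation: the **adduct**
(the ionized form of the neutral molecule, e.g. `[M+H]+` or `[2M+Na]+`) and
the **precursor m/z** it implies. In practice these fields are often missing
— in HMDB-style experimental exports, roughly half of the spectra lack an
adduct — or written in incompatible notations (`[M+H+H2O]+` and
`[M+H2O+H]+` denote the same species). Most cleaning pipelines simply drop
such spectra. msrepair instead *repairs* them, with three cooperating parts:

1. a **spectral alignment similarity** (OSA: optimized spectral alignment)
   used to find, among library spectra of the same compound and ionization
   mode, the one most similar to an annotation-deficient query, whose adduct
   is then transferred;
2. a **deterministic adduct grammar** that parses, canonicalizes and does
   mass arithmetic on adduct strings, plus a **learned corrector** for
   strings the grammar cannot parse;
3. library-level services: HMDB-style library construction from XML + CSV,
   metadata subsetting, descriptive statistics, benchmarking, and a
   metadata-reliability assessment.

## Optimized spectral alignment

Two peak lists $QS = ((qs\_mz_1, qs\_int_1), \ldots, (qs\_mz_m, qs\_int_m))$
and $SS$ (length $n$), both sorted in m/z, are aligned by dynamic
programming over a $(m+1)\times(n+1)$ matrix initialized to zero:

$$dp[i,j] = \max \begin{cases}
dp[i-1,j-1] + final\_score & \text{(match or mismatch)}\\
dp[i-1,j] + gap\_penalty & \text{(gap in subject)}\\
dp[i,j-1] + gap\_penalty & \text{(gap in query)}
\end{cases}$$

with

$$final\_score = \begin{cases}
intensity\_score & |qs\_mz_i - ss\_mz_j| \le mz\_tolerance\\
-1 & \text{otherwise,}
\end{cases}
\qquad
intensity\_score = \frac{1}{1 + (qs\_int_i - ss\_int_j)^2}.$$

Defaults: `mz_tolerance = 0.005` Da and `gap_penalty = -0.1`, deliberately
smaller in magnitude than the mismatch penalty of $-1$ so that skipping a
peak is always cheaper than force-matching distant peaks. Without
intensities the intensity score is identically one and the score counts
tolerance-compatible matches.

Design choices worth stating explicitly:

* **Boundary semantics.** The matrix is initialized to zero and the result
  is `dp[m, n]`. Zero boundaries make the *leading* unmatched run on one
  side free (the traceback may enter the matrix anywhere on the first
  row/column), while interior and trailing gaps are charged. The
  brute-force test oracle (`osa_brute_force()`) encodes the same convention
  by direct scoring of enumerated matchings, with no DP, so the equivalence
  test is meaningful.
* **Intensity normalization.** Intensities are scaled by each spectrum's
  maximum before scoring, making `intensity_score` scale-free across
  libraries that store intensities on arbitrary scales. A consequence:
  for a single-peak spectrum the normalized intensity is always 1.
* **City-block tie-break.** When several tracebacks achieve the optimal
  score, the one minimizing $\sum |qs\_mz - ss\_mz|$ over its aligned pairs
  is returned. This sum is accumulated along the chosen traceback *without
  tolerance gating* (mismatched diagonal pairs contribute their full
  deviation). A second forward pass propagates the minimal attainable
  city-block among score-optimal predecessors; score equality during the
  pass is tested at an absolute epsilon of 1e-9, comfortably below any
  score difference the scoring scheme can produce and above accumulated
  floating-point error. Residual ties resolve deterministically
  diagonal → up → left.
* **Normalization for reporting.** `normalized_score = raw_score /
  max(m, n)`, clipped to $[0, 1]$. Both raw and normalized scores are
  returned, since either convention may be wanted when comparing score
  distributions.

The DP inner loop is implemented in C++ (Rcpp), as the matching workflows
score hundreds of thousands of pairs.

## Reference similarity and distance metrics

The benchmark compares OSA against the two spectral metrics designed for
intensities and ten generic vector distances:

* **Greedy cosine** pairs peaks within a tolerance (default 0.1 Da, the
  matchms convention) greedily in order of descending intensity product,
  each peak used once, and scores
  $(\sum_{pairs} q_i s_j)^2 / (\sum q_i^2 \sum s_j^2)$ on max-normalized
  intensities — the square of the familiar greedy cosine, which keeps the
  identical-spectra → 1 and no-pairs → 0 contract.
* **Spectral entropy similarity**: after consolidating peaks within the
  tolerance (default 0.05 Da) and normalizing intensities to sum 1,
  $1 - (2 S_{mix} - S_q - S_s)/\ln 4$ where $S$ is Shannon entropy and
  $S_{mix}$ the entropy of the half-weight mixture spectrum; clipped to
  $[0, 1]$.
* **Vector distances** (city-block, Euclidean, squared Euclidean,
  Chebyshev, Minkowski of order 3, Bray–Curtis, Canberra, cosine,
  correlation, Jensen–Shannon) operate on *binned* spectra: intensities
  summed over half-open bins $[kw, (k+1)w)$ of width $w = 0.01$ Da spanning
  the union m/z range of the pair. Binning is our convention — generic
  distances need equal-length vectors and nothing about the inputs
  dictates how to build them; the choice is recorded prominently because
  conclusions about the generic metrics' fitness depend on it.

## The adduct grammar

An adduct is modelled as (multiplier, gains, losses, charge): `[2M+Na]+`
is two copies of M, one sodium gained, charge +1. The parser is tolerant
(missing brackets, whitespace, unicode minus, `2+`/`+2`/`++` charges,
count prefixes); the canonical renderer orders gains before losses, `H`
first then alphabetically within each group, collapses repeats (`2H`), and
renders charge as `+`, `-`, `2+`, … The canonicalization is idempotent and
`parse` / `canonical_string` are mutually inverse on canonical strings —
this pair of properties is what lets the benchmark compare adducts as
strings without formatting noise. The ordering convention itself is ours:
equivalence of orderings is chemistry, the canonical representative is a
repo convention.

Theoretical precursor m/z is
$(k\,M + \sum \text{gains} - \sum \text{losses} - z\,m_e)/|z|$ with
monoisotopic component masses from a user-extensible shipped table and the
electron mass ($m_e = 0.00054858$ Da) included per unit charge; `[M+H]+`
therefore uses the proton mass 1.0072765 Da. Including $m_e$ keeps
theoretical values well inside the 0.25 Da adduct/precursor concordance
margin observed on curated spectra.

Placeholder annotations (`""`, `UNKNOWN`, `?`, `n/a`, …) parse to a
sentinel rather than erroring, because the matching workflow must route
them to prediction, not reject them.

## The learned adduct corrector

The corrector exists for strings the grammar cannot parse (missing
charges, exotic delimiters, truncated brackets). Its training corpus is
built from the shipped dictionary of 61 canonical labels: for each label,
all positional permutations of its ions, and ten systematic formatting
corruptions of each (spaces around delimiters, dropped/doubled brackets,
charge written inside the bracket, unicode minus, lower-case `m`, padding,
numeric charge suffixes) — at least ten variants per label by
construction. Observed strings can be folded in; those mapping to no
dictionary label are routed to an `UNKNOWN` bucket.

Preprocessed strings are vectorized as character-level 1–3-gram counts
with smooth inverse-document-frequency weighting and l2 row normalization,
and classified by a single-hidden-layer network (200 hidden units, ReLU,
softmax output) trained full-batch with Adam for at most 500 iterations,
deterministically under a seed. The trainer is implemented in base-R
matrix algebra: with ~280 n-gram features and 61 labels the network has
~70k weights, a size at which quasi-Newton optimizers with dense
curvature approximations are memory-prohibitive, while full-batch
first-order training converges in seconds on a corpus of ~900 short
strings. Evaluation uses a stratified 80/20 hold-out (labels with fewer
than two examples are excluded from the split with a warning); the
hold-out accuracy on the synthetic corpus exceeds 0.99 under the default
seed, the package's scaled analog of the high correction accuracy
achievable on real library vocabularies.

Deployment is **rule-first, model-second**: if the preprocessed input
parses, the grammar's canonical form is returned with confidence 1 — the
learned component can never contradict the deterministic grammar on
parsable input (tested exhaustively over the corpus). Model predictions
below a confidence floor of 0.5 are reported uncorrected rather than
silently relabelled.

## Matching, benchmarking and reliability

Candidate retrieval filters the subject library on an identifier
(InChIKey by default; SMILES and molecular formula are supported but
documented as weaker — formulas collide on isomers) **and** on congruent
ion mode, where `unknown` never matches: assigning an adduct across
ionization modes is exactly the error the filter exists to prevent, and a
query with unknown mode yields a failure record. Best-match selection is
extremal score (max for similarities, min for distances); exact ties
resolve by smallest absolute precursor difference, then input order (a
convention — nothing in the data dictates it). `min_score` defaults to
none for OSA and can be set per call.

A query/subject pair is classified by two concordance criteria: equal
canonical adducts, and precursor m/z deviation ≤ 0.5 Da; `both`,
`adduct_only`, `precursor_only`, `mismatch` accordingly, with a missing or
unparsable field making its criterion non-concordant (never an error).
The match rate is the percentage of queries matching on at least one
criterion. Benchmarks run at two levels: m/z only (intensities replaced
by a constant) and m/z + intensity, the latter restricted to the three
metrics designed for intensities.

The reliability assessment samples `n` spectra per library without
replacement per repetition (repetition $r$ reseeds with `seed + r - 1`),
scores all query–subject pairs with greedy cosine, keeps each query's
best subject at score ≥ 0.95, and tabulates, for each anchor field F, the
percentage of kept pairs differing in another field G among those equal
in F, averaged over repetitions. Sampling without replacement is a
recorded convention.

## The synthetic generator

Every workflow is testable without downloads because the generator plants
its own ground truth:

* **Compounds**: format-valid 27-character pseudo-InChIKeys, CHNOS
  formulas with monoisotopic masses in 80–900 Da, pseudo-SMILES plus a
  distinct non-canonical variant string, planted isomer pairs.
* **Spectra**: the base fragmentation pattern is a deterministic pure
  function of (compound, adduct) — hash-seeded pseudo-peaks forming an
  adduct-specific ion series (fragments shifted like the precursor, plus
  the precursor ion). Fragment chemistry is *not* modelled: the methods
  under test only ever compare peak lists, so chemically realistic
  fragmentation would add nothing the tests could detect. Spectra of the
  same compound under different adducts are globally shifted, which is
  what makes adduct transfer by spectral similarity work here by
  construction.
* **Corruptions**: m/z jitter (default SD 0.002 Da), multiplicative
  intensity jitter (5%), and exact-count corruption — `round(fraction·n)`
  spectra get blanked, permuted or malformed adducts, or the variant
  SMILES — so tests can assert counts exactly. Defaults (20% blanked
  adducts, 0.002 Da jitter) are the package's study conditions.
* **The benchmark suite** (`make_benchmark_suite()`): four overlapping
  subject libraries (two replicates of 28 compounds × 3 adducts each)
  sharing a planted intersection of 25 InChIKeys, one of which annotates a
  third of its spectra with permuted adduct forms (mirroring the
  notational heterogeneity of real repositories), plus an HMDB-like
  library of 100 spectra with exactly 50% of adducts blanked — the
  annotation-deficiency regime the repair targets.

What passing on these fixtures shows — and what it does not: recovery
rates near 100% demonstrate that the pipeline's filtering, scoring,
canonicalization and bookkeeping are correct under realistic noise, not
that real libraries (replicates across instruments, collision energies,
contaminant peaks, wrong metadata) would yield the same rates. On the
fixtures even a binned city-block distance matches well, because
same-compound candidate sets are small and clean; the separation between
spectral and generic metrics observed on real data is *not* reproduced
quantitatively here, and the package makes no claim that it is.

## Problem sizes and determinism

The shipped validation uses: 200 random peak-list pairs (lengths ≤ 6) per
intensity mode against the exhaustive alignment oracle; the 61-label
corpus (~940 variants) for the corrector; the benchmark suite above
(~770 spectra) for end-to-end recovery; and reliability sampling at
n = 500 with 5 repetitions. These sizes were chosen so the whole
validation runs in about a minute on one core while every rate is
estimated from hundreds of decisions. All randomness flows from explicit
integer seeds; every generator and the trainer are bitwise reproducible
under a fixed seed.

## Known limitations

* Adduct prediction never crosses ionization modes; spectra with unknown
  mode are failures by design.
* The grammar's ion vocabulary is the shipped table; unknown tokens are
  parse errors (extensible via `ion_mass_table(path)`).
* Isotopologue adducts and in-source fragments are out of scope; charge
  states beyond ±3 are parsed but not specifically validated.
* MSP is the only library text format read and written; MGF/mzML are out
  of scope.
* The corrector's label set is closed: it can only map to dictionary
  labels, by design — novel adducts should be added to the dictionary,
  not hallucinated by a classifier.
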