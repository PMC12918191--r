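#' Retrieve candidate subject spectra for a query
#'
#' Subject spectra whose identifier equals the query's and whose normalized
#' ion mode is congruent (equal; `"unknown"` never matches — inconsistent
#' ionization modes are a defined failure mode, not a fuzzy match).
#' InChIKey comparison uses the full 27-character key; formula matching is
#' documented as loose (isomers share a formula). Order is preserved.
#'
#' @param query an `ms_spectrum`.
#' @param subject a [spectral_library()].
#' @param identifier `"inchikey"`, `"smiles"` or `"formula"`.
#' @return integer vector of subject indices (possibly empty). When the
#'   query lacks the identifier or has unknown ion mode the result is empty
#'   with attribute `"failure_reason"` set.
#' @export
find_candidates <- function(query, subject, identifier = "inchikey") {
  identifier <- match.arg(identifier, c("inchikey", "smiles", "formula"))
  id <- meta_field(query, identifier)
  mode <- normalize_ionmode(meta_field(query, "ionmode"))
  if (is.na(id)) {
    return(structure(integer(0), failure_reason = "missing identifier"))
  }
  if (mode == "unknown") {
    return(structure(integer(0), failure_reason = "unknown ion mode"))
  }
  hit <- vapply(subject$spectra, function(s) {
    sid <- meta_field(s, identifier)
    smode <- normalize_ionmode(meta_field(s, "ionmode"))
    !is.na(sid) && sid == id && smode == mode
  }, logical(1))
  idx <- which(hit)
  if (length(idx) == 0) {
    attr(idx, "failure_reason") <- "no congruent subject spectra"
  }
  idx
}

#' Best-scoring candidate under a metric
#'
#' Similarity metrics select the maximum score, distance metrics the
#' minimum. Exact score ties are broken by the smallest absolute precursor
#' m/z difference when both precursors are present, then by subject order.
#'
#' @param query an `ms_spectrum`.
#' @param candidates list of candidate `ms_spectrum` objects (non-empty).
#' @param metric a [metric_spec()] or metric name.
#' @return list with `index` (into `candidates`), `spectrum`, `score`.
#' @export
best_match <- function(query, candidates, metric = metric_spec("osa")) {
  stopifnot(length(candidates) > 0)
  if (is.character(metric)) metric <- metric_spec(metric)
  scores <- vapply(candidates, function(s) metric_score(query, s, metric),
                   numeric(1))
  extremal <- if (metric$kind == "similarity") max(scores) else min(scores)
  ties <- which(abs(scores - extremal) < 1e-12)
  if (length(ties) > 1) {
    qpre <- meta_number(query, "precursor_mz")
    deltas <- vapply(ties, function(i) {
      spre <- meta_number(candidates[[i]], "precursor_mz")
      if (is.na(qpre) || is.na(spre)) Inf else abs(qpre - spre)
    }, numeric(1))
    ties <- ties[order(deltas)]  # stable: subject order breaks residual ties
  }
  i <- ties[1]
  list(index = i, spectrum = candidates[[i]], score = scores[i])
}

#' Classify a query/subject pair by metadata concordance
#'
#' Adduct concordance means equal canonical adduct strings; precursor
#' concordance means an absolute precursor m/z deviation of at most
#' `precursor_tol` (0.5 Da). A field missing (or, for adducts, unparsable)
#' on either side makes that criterion unevaluable and it counts as
#' non-concordant, never as an error.
#'
#' @param query,subject `ms_spectrum` objects.
#' @param precursor_tol concordance tolerance in Da.
#' @return one of `"both"`, `"adduct_only"`, `"precursor_only"`,
#'   `"mismatch"`.
#' @export
classify_match <- function(query, subject, precursor_tol = 0.5) {
  qa <- safe_canonical_adduct(meta_field(query, "adduct"))
  sa <- safe_canonical_adduct(meta_field(subject, "adduct"))
  adduct_ok <- qa != "UNKNOWN" && sa != "UNKNOWN" && qa == sa
  qp <- meta_number(query, "precursor_mz")
  sp <- meta_number(subject, "precursor_mz")
  prec_ok <- !is.na(qp) && !is.na(sp) && abs(qp - sp) <= precursor_tol
  if (adduct_ok && prec_ok) "both"
  else if (adduct_ok) "adduct_only"
  else if (prec_ok) "precursor_only"
  else "mismatch"
}

#' Predict the adduct of an annotation-deficient spectrum
#'
#' The repair step: candidates are retrieved by identifier and ion mode,
#' the best match selected under the metric, and the subject's canonical
#' adduct copied into the prediction. When the query carries an exact mass,
#' the theoretical precursor m/z of the predicted adduct is computed too.
#' Failures (no candidates, candidates all lacking usable adducts, or a
#' best score below `min_score`) are returned as records, never as errors.
#'
#' @param query an `ms_spectrum` whose adduct is missing or to be repaired.
#' @param subject a [spectral_library()].
#' @param metric a [metric_spec()] or name.
#' @param identifier identifier field used for retrieval.
#' @param min_score optional score floor under a similarity metric; below
#'   it the prediction is withheld.
#' @return a one-row data.frame (a match record): `query_id`, `subject_id`,
#'   `metric`, `score`, `match_type` (`"failure"` when no prediction),
#'   `predicted_adduct`, `theoretical_precursor_mz`, `failure_reason`.
#' @export
predict_adduct <- function(query, subject, metric = metric_spec("osa"),
                           identifier = "inchikey", min_score = NULL) {
  if (is.character(metric)) metric <- metric_spec(metric)
  qid <- meta_field(query, "spectrum_id")
  rec <- data.frame(query_id = qid, subject_id = NA_character_,
                    metric = metric$name, score = NA_real_,
                    match_type = "failure",
                    predicted_adduct = NA_character_,
                    theoretical_precursor_mz = NA_real_,
                    failure_reason = NA_character_,
                    stringsAsFactors = FALSE)
  idx <- find_candidates(query, subject, identifier)
  if (length(idx) == 0) {
    rec$failure_reason <- attr(idx, "failure_reason")
    return(rec)
  }
  cands <- subject$spectra[idx]
  adducts <- vapply(cands, function(s) {
    safe_canonical_adduct(meta_field(s, "adduct"))
  }, character(1))
  usable <- adducts != "UNKNOWN"
  if (!any(usable)) {
    rec$failure_reason <- "candidate adducts all UNKNOWN"
    return(rec)
  }
  cands <- cands[usable]
  adducts <- adducts[usable]
  bm <- best_match(query, cands, metric)
  if (!is.null(min_score) && metric$kind == "similarity" &&
      bm$score < min_score) {
    rec$score <- bm$score
    rec$failure_reason <- "best score below min_score"
    return(rec)
  }
  rec$subject_id <- meta_field(bm$spectrum, "spectrum_id")
  rec$score <- bm$score
  rec$match_type <- "predicted"
  rec$predicted_adduct <- adducts[bm$index]
  em <- meta_number(query, "exact_mass")
  if (!is.na(em)) {
    rec$theoretical_precursor_mz <-
      theoretical_precursor_mz(adducts[bm$index], em)
  }
  rec
}

#' Benchmark matching metrics against ground-truth adducts
#'
#' Every query spectrum with a known adduct is matched against the subject
#' library under each metric and the best match classified by adduct and
#' precursor concordance ([classify_match()]). The match rate is the
#' percentage of queries whose best match agrees in adduct form or
#' precursor m/z (types `both`, `adduct_only`, `precursor_only`) relative
#' to all queries; queries with no retrievable candidate count as
#' `failure`. Two comparison levels are supported: `"mz_only"` scores with
#' uniform intensities, `"mz_and_intensity"` uses recorded intensities and
#' is restricted to the metrics designed for them (`osa`, `entropy`,
#' `cosine_greedy`); other metrics are skipped with a warning.
#'
#' @param query_lib,subject_lib spectral libraries.
#' @param metrics character vector of metric names.
#' @param level `"mz_only"` or `"mz_and_intensity"`.
#' @param identifier identifier field used for retrieval.
#' @return object of class `match_benchmark`: list with `summary`
#'   (data.frame metric, level, n, match_rate, counts per match type) and
#'   `records` (per-spectrum data.frame).
#' @export
benchmark_adduct_match <- function(query_lib, subject_lib,
                                   metrics = c("osa", "entropy",
                                               "cosine_greedy"),
                                   level = c("mz_only", "mz_and_intensity"),
                                   identifier = "inchikey") {
  level <- match.arg(level)
  intensity_capable <- c("osa", "entropy", "cosine_greedy")
  records <- list()
  summaries <- list()
  for (mname in metrics) {
    if (level == "mz_and_intensity" && !mname %in% intensity_capable) {
      warning("metric '", mname, "' is not designed for intensities; skipped",
              call. = FALSE)
      next
    }
    spec <- metric_spec(mname, use_intensities = level == "mz_and_intensity")
    recs <- lapply(query_lib$spectra, function(q) {
      if (level == "mz_only") q$peaks[, "intensity"] <- 1
      qid <- meta_field(q, "spectrum_id")
      idx <- find_candidates(q, subject_lib, identifier)
      if (length(idx) == 0) {
        return(data.frame(query_id = qid, subject_id = NA_character_,
                          metric = mname, score = NA_real_,
                          match_type = "failure",
                          failure_reason = attr(idx, "failure_reason"),
                          stringsAsFactors = FALSE))
      }
      qa <- safe_canonical_adduct(meta_field(q, "adduct"))
      if (qa == "UNKNOWN") {
        return(data.frame(query_id = qid, subject_id = NA_character_,
                          metric = mname, score = NA_real_,
                          match_type = "failure",
                          failure_reason = "query adduct unknown",
                          stringsAsFactors = FALSE))
      }
      cands <- subject_lib$spectra[idx]
      if (level == "mz_only") {
        cands <- lapply(cands, function(s) {
          s$peaks[, "intensity"] <- 1
          s
        })
      }
      bm <- best_match(q, cands, spec)
      data.frame(query_id = qid,
                 subject_id = meta_field(bm$spectrum, "spectrum_id"),
                 metric = mname, score = bm$score,
                 match_type = classify_match(q, bm$spectrum),
                 failure_reason = NA_character_,
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    n <- if (is.null(recs)) 0L else nrow(recs)
    if (n > 0) records[[mname]] <- recs
    counts <- table(factor(recs$match_type,
                           levels = c("both", "adduct_only", "precursor_only",
                                      "mismatch", "failure")))
    rate <- if (n > 0) {
      100 * sum(counts[c("both", "adduct_only", "precursor_only")]) / n
    } else {
      NA_real_
    }
    summaries[[mname]] <- data.frame(
      metric = mname, level = level, n = n, match_rate = rate,
      both = counts[["both"]], adduct_only = counts[["adduct_only"]],
      precursor_only = counts[["precursor_only"]],
      mismatch = counts[["mismatch"]], failure = counts[["failure"]],
      stringsAsFactors = FALSE)
  }
  structure(list(summary = if (length(summaries)) {
                   do.call(rbind, c(summaries, make.row.names = FALSE))
                 },
                 records = if (length(records)) {
                   do.call(rbind, c(records, make.row.names = FALSE))
                 }),
            class = "match_benchmark")
}

#' @export
print.match_benchmark <- function(x, ...) {
  cat("<match_benchmark>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Assess per-field metadata reliability between two libraries
#'
#' Random-pair sampling procedure: per repetition, `n` spectra are sampled
#' without replacement from each library, every query is matched against
#' every subject with greedy cosine, the best subject kept per query when
#' its score reaches `threshold`, and for every anchor field F the error
#' rate of field G given F is the percentage of kept pairs differing in G
#' among those equal in F. Rates are averaged over repetitions (repetition
#' r uses seed + r - 1).
#'
#' @param libA,libB query and subject libraries.
#' @param n sample size per library (clamped to the smaller library with a
#'   warning; sampling is always without replacement).
#' @param reps number of repetitions.
#' @param threshold similarity score floor for a highly confident pair.
#' @param seed integer seed.
#' @param fields metadata fields to cross-tabulate.
#' @param tolerance greedy-cosine pairing tolerance (Da).
#' @return object of class `reliability_matrix`: list with `error_rate`
#'   (fields x fields matrix, `NA` diagonal; `error_rate[F, G]` = % of
#'   G-mismatches among F-equal kept pairs), `n_kept` (average kept pairs
#'   per repetition), `reps`, `threshold`.
#' @export
reliability_assessment <- function(libA, libB, n = 5000, reps = 10,
                                   threshold = 0.95, seed = 1L,
                                   fields = c("inchikey", "smiles",
                                              "formula", "name"),
                                   tolerance = 0.1) {
  nmax <- min(length(libA), length(libB))
  if (n > nmax) {
    warning("n clamped from ", n, " to ", nmax,
            " (sampling without replacement)", call. = FALSE)
    n <- nmax
  }
  acc <- matrix(0, length(fields), length(fields),
                dimnames = list(fields, fields))
  cnt <- acc
  kept_total <- 0
  for (r in seq_len(reps)) {
    set.seed(seed + r - 1L)
    ia <- sample(length(libA), n)
    ib <- sample(length(libB), n)
    qs <- libA$spectra[ia]
    ss <- libB$spectra[ib]
    bm <- cpp_cosine_best_match(lapply(qs, `[[`, "peaks"),
                                lapply(ss, `[[`, "peaks"), tolerance)
    keep <- which(!is.na(bm$score) & bm$score >= threshold)
    kept_total <- kept_total + length(keep)
    if (length(keep) == 0) next
    qmeta <- lapply(fields, function(f) {
      vapply(qs[keep], meta_field, character(1), key = f)
    })
    smeta <- lapply(fields, function(f) {
      vapply(ss[bm$index[keep]], meta_field, character(1), key = f)
    })
    names(qmeta) <- names(smeta) <- fields
    for (f in fields) {
      eqF <- !is.na(qmeta[[f]]) & !is.na(smeta[[f]]) &
        qmeta[[f]] == smeta[[f]]
      for (g in setdiff(fields, f)) {
        ok <- eqF & !is.na(qmeta[[g]]) & !is.na(smeta[[g]])
        if (any(ok)) {
          acc[f, g] <- acc[f, g] + 100 * mean(qmeta[[g]][ok] != smeta[[g]][ok])
          cnt[f, g] <- cnt[f, g] + 1
        }
      }
    }
  }
  if (kept_total == 0) {
    warning("no spectrum pair passed the score threshold", call. = FALSE)
  }
  err <- acc / cnt
  err[cnt == 0] <- NA_real_
  diag(err) <- NA_real_
  structure(list(error_rate = err, n_kept = kept_total / reps,
                 reps = reps, threshold = threshold),
            class = "reliability_matrix")
}

#' @export
print.reliability_matrix <- function(x, ...) {
  cat(sprintf(
    "<reliability_matrix> threshold %.2f | ~%.0f kept pairs/rep | %d reps\n",
    x$threshold, x$n_kept, x$reps))
  cat("error_rate[F, G] = % of G mismatches among F-equal pairs\n")
  print(round(x$error_rate, 2))
  invisible(x)
}
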