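make_match_fixture <- function() {
  subject <- spectral_library(list(
    tiny_spectrum("s1", "KEYA", "positive", "[M+H]+",
                  mz = c(100, 150, 200)),
    tiny_spectrum("s2", "KEYA", "positive", "[M+Na]+",
                  mz = c(122, 172, 222)),
    tiny_spectrum("s3", "KEYA", "negative", "[M-H]-",
                  mz = c(98, 148, 198)),
    tiny_spectrum("s4", "KEYB", "positive", "[M+H]+",
                  mz = c(110, 160, 210))
  ), name = "subject")
  query <- tiny_spectrum("q1", "KEYA", "positive", "",
                         mz = c(100.001, 150.001, 199.999))
  list(subject = subject, query = query)
}

test_that("candidate retrieval filters on identifier and congruent ion mode", {
  fx <- make_match_fixture()
  idx <- find_candidates(fx$query, fx$subject, "inchikey")
  expect_identical(idx, c(1L, 2L))  # same key, positive only

  unknown <- fx$query
  unknown$metadata$ionmode <- "unknown"
  r <- find_candidates(unknown, fx$subject)
  expect_length(r, 0)
  expect_identical(attr(r, "failure_reason"), "unknown ion mode")

  noid <- fx$query
  noid$metadata$inchikey <- NULL
  r2 <- find_candidates(noid, fx$subject)
  expect_identical(attr(r2, "failure_reason"), "missing identifier")

  # formula retrieval is documented as loose: isomers both return
  iso <- spectral_library(list(
    tiny_spectrum("i1", "KEY1", formula = "C6H12O6"),
    tiny_spectrum("i2", "KEY2", formula = "C6H12O6"),
    tiny_spectrum("i3", "KEY3", formula = "C5H10O5")
  ), name = "iso")
  q <- tiny_spectrum("q", "KEYX", formula = "C6H12O6")
  expect_identical(find_candidates(q, iso, "formula"), c(1L, 2L))
})

test_that("best match takes the extremal score with precursor tie-break", {
  q <- tiny_spectrum("q", "K", precursor_mz = "200.00")
  cands <- list(
    tiny_spectrum("c1", "K", mz = c(100, 155, 200), precursor_mz = "200.30"),
    tiny_spectrum("c2", "K", mz = c(100, 150, 200), precursor_mz = "200.01")
  )
  bm <- best_match(q, cands, metric_spec("cosine_greedy"))
  expect_identical(bm$spectrum$metadata$spectrum_id, "c2")

  # distance metric: smallest wins
  bm2 <- best_match(q, cands, metric_spec("cityblock"))
  expect_identical(bm2$spectrum$metadata$spectrum_id, "c2")

  # exact score tie (identical peak lists) resolved by precursor delta
  cands_tie <- list(
    tiny_spectrum("t1", "K", mz = c(100, 150, 200), precursor_mz = "200.30"),
    tiny_spectrum("t2", "K", mz = c(100, 150, 200), precursor_mz = "200.01")
  )
  bm3 <- best_match(q, cands_tie, metric_spec("osa"))
  expect_identical(bm3$spectrum$metadata$spectrum_id, "t2")
})

test_that("match classification follows the concordance rules", {
  mk <- function(adduct, precursor) {
    tiny_spectrum("x", "K", adduct = adduct, precursor_mz = precursor)
  }
  expect_identical(classify_match(mk("[M+H]+", "181.07"),
                                  mk("[M+H]+", "181.08")), "both")
  expect_identical(classify_match(mk("[M+H]+", "181.07"),
                                  mk("[M+H]+", NULL)), "adduct_only")
  expect_identical(classify_match(mk("[M+H]+", "181.07"),
                                  mk("[M+Na]+", "181.37")), "precursor_only")
  expect_identical(classify_match(mk("[M+H]+", "181.07"),
                                  mk("[M+Na]+", "181.87")), "mismatch")
  # formatting noise never breaks adduct concordance (canonical comparison)
  expect_identical(classify_match(mk("[M+H2O+H]+", "181.07"),
                                  mk("[M + H + H2O] +", "181.07")), "both")
  # symmetry when both fields are present on both sides
  a <- mk("[M+H]+", "181.07")
  b <- mk("[M+Na]+", "181.17")
  expect_identical(classify_match(a, b), classify_match(b, a))
})

test_that("adduct prediction copies the best subject's canonical adduct", {
  fx <- make_match_fixture()
  rec <- predict_adduct(fx$query, fx$subject, metric = "osa")
  expect_identical(rec$predicted_adduct, "[M+H]+")
  expect_identical(rec$subject_id, "s1")

  # no same-identifier candidates -> failure record, not an error
  lost <- fx$query
  lost$metadata$inchikey <- "KEYZ"
  rec2 <- predict_adduct(lost, fx$subject)
  expect_identical(rec2$match_type, "failure")

  # withheld below min_score: this query's peaks all miss the tolerance
  off <- tiny_spectrum("q2", "KEYA", "positive", "",
                       mz = c(100.02, 150.02, 200.02))
  rec3 <- predict_adduct(off, fx$subject, metric = "osa",
                         min_score = 0.999)
  expect_identical(rec3$match_type, "failure")
  expect_identical(rec3$failure_reason, "best score below min_score")

  # candidates whose adducts are all unknown -> failure
  blank <- fx$subject
  for (i in seq_along(blank$spectra)) blank$spectra[[i]]$metadata$adduct <- ""
  rec4 <- predict_adduct(fx$query, blank)
  expect_identical(rec4$failure_reason, "candidate adducts all UNKNOWN")
})

test_that("benchmarking partitions queries and gates intensity metrics", {
  suite <- make_benchmark_suite(seed = 21)
  queries <- subset_library(suite$hmdb, values = list(ionmode = "positive"))
  subj <- concat_libraries(suite$libraries, name = "integrated")
  bench <- benchmark_adduct_match(queries, subj, metrics = c("osa"),
                                  level = "mz_only")
  s <- bench$summary
  expect_equal(s$n, length(queries))
  expect_equal(s$both + s$adduct_only + s$precursor_only + s$mismatch +
                 s$failure, s$n)
  expect_equal(nrow(bench$records), length(queries))

  expect_warning(
    b2 <- benchmark_adduct_match(queries[1], subj,
                                 metrics = c("cityblock"),
                                 level = "mz_and_intensity"),
    "not designed for intensities")
  expect_null(b2$summary)

  empty <- spectral_library(name = "empty")
  b3 <- benchmark_adduct_match(empty, subj, metrics = "osa")
  expect_true(is.na(b3$summary$match_rate))
})

test_that("reliability assessment recovers a planted mismatch rate", {
  cmp <- make_compounds(40, seed = 31)
  A <- make_library(cmp, adducts = c("[M+H]+", "[M-H]-"), replicates = 3,
                    plan = corruption_plan(fraction_blank_adduct = 0,
                                           fraction_noncanonical_smiles = 0.1,
                                           seed = 32),
                    name = "A")
  B <- make_library(cmp, adducts = c("[M+H]+", "[M-H]-"), replicates = 3,
                    plan = corruption_plan(fraction_blank_adduct = 0,
                                           seed = 33),
                    name = "B")
  expect_warning(
    rel <- reliability_assessment(A$library, B$library, n = 500, reps = 2,
                                  threshold = 0.95, seed = 5),
    "clamped")
  err <- rel$error_rate
  expect_equal(err["inchikey", "formula"], 0)
  expect_equal(err["inchikey", "name"], 0)
  expect_gt(err["inchikey", "smiles"], 5)
  expect_lt(err["inchikey", "smiles"], 15)
  # determinism under the seed
  rel2 <- suppressWarnings(
    reliability_assessment(A$library, B$library, n = 500, reps = 2,
                           threshold = 0.95, seed = 5))
  expect_identical(rel$error_rate, rel2$error_rate)
})
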