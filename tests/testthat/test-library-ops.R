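test_that("HMDB library construction joins, drops and reports exactly", {
  d <- withr::local_tempdir()
  cmp <- make_compounds(3, seed = 8)
  # CSV covers compounds 1-2 only; each compound yields 2 spectra
  fx <- write_hmdb_fixtures(cmp, d, adducts = c("[M+H]+", "[M-H]-"),
                            drop_compound_rows = 3)
  lib <- build_hmdb(fx$xml_dir, fx$csv)
  rep <- attr(lib, "report")
  expect_equal(rep$n_joined, 4)
  expect_equal(rep$n_dropped_no_compound, 2)
  expect_equal(rep$n_parse_failed, 0)
  expect_length(lib, 4)
  md <- lib$spectra[[1]]$metadata
  expect_true(all(c("inchikey", "smiles", "formula", "exact_mass", "name")
                  %in% names(md)))
  # joined spectra still lack the adduct: that is the deficiency under study
  expect_true(all(vapply(lib$spectra,
                         function(s) is.null(s$metadata$adduct),
                         logical(1))))
  # the built library round-trips through MSP
  f <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, f)
  lib2 <- read_msp(f)
  expect_length(lib2, 4)
  expect_identical(lib2$spectra[[1]]$metadata, lib$spectra[[1]]$metadata)

  empty <- withr::local_tempdir()
  expect_warning(e <- build_hmdb(empty, fx$csv), "no XML files")
  expect_length(e, 0)
})

test_that("subsetting is conjunctive, closed-interval and idempotent", {
  cmp <- make_compounds(5, seed = 9)
  gen <- make_library(cmp, adducts = c("[M+H]+", "[M-H]-"), replicates = 1,
                      plan = corruption_plan(fraction_blank_adduct = 0,
                                             seed = 10),
                      name = "sub")
  lib <- gen$library  # 5 positive + 5 negative spectra
  pos <- subset_library(lib, values = list(ionmode = "positive"))
  expect_length(pos, 5)
  expect_true(all(vapply(pos$spectra,
                         function(s) s$metadata$ionmode == "positive",
                         logical(1))))
  # idempotent and contained in the input
  expect_length(subset_library(pos, values = list(ionmode = "positive")), 5)

  pres <- vapply(lib$spectra, function(s) as.numeric(s$metadata$precursor_mz),
                 numeric(1))
  lo <- sort(pres)[3]
  hi <- sort(pres)[7]
  both <- subset_library(lib, values = list(ionmode = "positive"),
                         ranges = list(precursor_mz = c(lo, hi)))
  manual <- sum(pres >= lo & pres <= hi &
                  vapply(lib$spectra,
                         function(s) s$metadata$ionmode == "positive",
                         logical(1)))
  expect_length(both, manual)

  # a missing field fails its predicate
  expect_length(subset_library(lib, ranges = list(retention_time = c(0, 10))),
                0)
})

test_that("subsetting rejects invalid criteria", {
  lib <- spectral_library(list(tiny_spectrum("a", "K")), name = "x")
  expect_error(subset_library(lib), "at least one predicate")
  expect_error(subset_library(lib, values = list(nonesuch_field = "x")),
               "unknown field")
  expect_error(subset_library(lib, ranges = list(precursor_mz = c(5, 1))),
               "lo <= hi")
})

test_that("library statistics count annotation completeness", {
  cmp <- make_compounds(25, seed = 12)
  gen <- make_library(cmp, adducts = c("[M+H]+", "[M-H]-"), replicates = 2,
                      plan = corruption_plan(fraction_blank_adduct = 0.48,
                                             seed = 13),
                      name = "stats")
  st <- library_stats(gen$library)  # 100 spectra, 48 blanked
  expect_equal(st$n_spectra, 100)
  expect_equal(st$missing_adduct, 48)
  expect_equal(st$missing_adduct_pct, 48)
  expect_equal(sum(st$ionmode_spectra), 100)
  # every compound occurs in both modes
  expect_equal(as.integer(st$ionmode_identifiers[["both"]]), 25)
  expect_equal(st$n_identifiers, 25)
  expect_equal(st$spectra_per_identifier[["mean"]] * st$n_identifiers, 100)
  expect_equal(sum(st$adduct_frequency), 52)

  st0 <- library_stats(spectral_library(name = "empty"))
  expect_equal(st0$n_spectra, 0)
  expect_equal(st0$missing_adduct_pct, 0)
})

test_that("pairwise exclusion restricts queries to the shared InChIKeys", {
  suite <- make_benchmark_suite(seed = 41)
  pairs <- pairwise_exclusion_sets(suite$libraries)
  expect_length(pairs, 4)
  shared <- attr(pairs, "intersection")
  # oracle: direct set intersection of the per-library key sets
  keysets <- lapply(suite$libraries, function(lib) {
    unique(vapply(lib$spectra, function(s) s$metadata$inchikey, character(1)))
  })
  expect_setequal(shared, Reduce(intersect, keysets))
  expect_setequal(shared, suite$shared_inchikeys)
  for (p in pairs) {
    qkeys <- unique(vapply(p$query$spectra,
                           function(s) s$metadata$inchikey, character(1)))
    expect_setequal(qkeys, shared)
    expect_equal(length(p$subject),
                 sum(vapply(suite$libraries, length, integer(1))) -
                   length(suite$libraries[[p$query$name]]))
  }

  disjoint <- list(
    spectral_library(list(tiny_spectrum("a", "KEYA")), name = "A"),
    spectral_library(list(tiny_spectrum("b", "KEYB")), name = "B")
  )
  expect_warning(dp <- pairwise_exclusion_sets(disjoint), "no InChIKey")
  expect_length(dp[[1]]$query, 0)
})
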