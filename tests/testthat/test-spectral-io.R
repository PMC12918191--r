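test_that("MSP round trip is the identity on metadata and peaks", {
  cmp <- make_compounds(4, seed = 2)
  gen <- make_library(cmp, adducts = c("[M+H]+", "[M-H]-"), replicates = 1,
                      plan = corruption_plan(seed = 4), name = "rt")
  lib <- gen$library
  lib$spectra[[1]]$metadata$name <- "µ-D-glucopyranose (±)"  # unicode survives
  f <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, f)
  lib2 <- read_msp(f, name = "rt")
  expect_length(lib2, length(lib))
  for (i in seq_along(lib$spectra)) {
    expect_identical(lib2$spectra[[i]]$metadata, lib$spectra[[i]]$metadata)
    expect_equal(lib2$spectra[[i]]$peaks, lib$spectra[[i]]$peaks,
                 tolerance = 1e-6)
  }
  # empty library -> empty file -> empty library
  f2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(spectral_library(name = "empty"), f2)
  expect_length(suppressWarnings(read_msp(f2)), 0)
})

test_that("MSP parser normalizes keys, accepts '=' and sorts peaks", {
  f <- withr::local_tempfile(fileext = ".msp")
  writeLines(c(
    "NAME: alpha",
    "PrecursorMZ: 181.0707",
    "Ion_mode: P",
    "PRECURSORTYPE=[M+H]+",
    "Num Peaks: 3",
    "200.1 5",
    "100.2\t10",
    "150.0 1"
  ), f)
  lib <- read_msp(f)
  expect_length(lib, 1)
  md <- lib$spectra[[1]]$metadata
  expect_identical(md$precursor_mz, "181.0707")
  expect_identical(md$ionmode, "positive")
  expect_identical(md$adduct, "[M+H]+")
  expect_equal(lib$spectra[[1]]$peaks[, "mz"], c(100.2, 150.0, 200.1))
})

test_that("malformed MSP blocks are skipped with a warning, never truncated", {
  f <- withr::local_tempfile(fileext = ".msp")
  writeLines(c(
    "NAME: good",
    "Num Peaks: 2",
    "100 1",
    "200 2",
    "",
    "NAME: short",
    "Num Peaks: 3",
    "100 1",
    "200 2",
    "",
    "NAME: nopeaks"
  ), f)
  expect_warning(expect_warning(lib <- read_msp(f), "declared 3 peaks"),
                 "missing Num Peaks")
  expect_length(lib, 1)
  expect_identical(lib$spectra[[1]]$metadata$name, "good")
  expect_length(attr(lib, "errors"), 2)
})

test_that("duplicate m/z within a spectrum merge by summing intensities", {
  sp <- spectrum_record(c(100, 100, 150), c(1, 2, 5))
  expect_equal(sp$peaks[, "mz"], c(100, 150))
  expect_equal(sp$peaks[, "intensity"], c(3, 5))
})

test_that("HMDB XML parsing maps fields and errors on defects", {
  d <- withr::local_tempdir()
  cmp <- make_compounds(3, seed = 5)
  fx <- write_hmdb_fixtures(cmp[1, ], d, adducts = "[M+H]+")
  sp <- read_hmdb_xml(list.files(fx$xml_dir, full.names = TRUE)[1])
  expect_identical(sp$metadata$hmdb_id, cmp$hmdb_id[1])
  expect_identical(sp$metadata$ionmode, "positive")
  expect_null(sp$metadata$adduct)
  expect_gt(nrow(sp$peaks), 0)

  nomode <- file.path(d, "nomode.xml")
  writeLines(paste0(
    "<ms-ms><database-id>HMDB0000001</database-id><ms-ms-peaks>",
    "<ms-ms-peak><mass-charge>100.5</mass-charge>",
    "<intensity>10</intensity></ms-ms-peak></ms-ms-peaks></ms-ms>"), nomode)
  expect_identical(read_hmdb_xml(nomode)$metadata$ionmode, "unknown")

  nopeaks <- file.path(d, "nopeaks.xml")
  writeLines(paste0("<ms-ms><database-id>HMDB0000002</database-id>",
                    "<ms-ms-peaks></ms-ms-peaks></ms-ms>"), nopeaks)
  expect_error(read_hmdb_xml(nopeaks), "no peaks")

  noid <- file.path(d, "noid.xml")
  writeLines(paste0("<ms-ms><ms-ms-peaks><ms-ms-peak>",
                    "<mass-charge>100</mass-charge>",
                    "<intensity>1</intensity>",
                    "</ms-ms-peak></ms-ms-peaks></ms-ms>"), noid)
  expect_error(read_hmdb_xml(noid), "database-id")
})

test_that("compound CSV honours schema, optional mass and duplicate ids", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "HMDB_ID,Name,Formula,InChIKey,SMILES,Exact Mass",
    "HMDB0000001,glucose,C6H12O6,AAAAAAAAAAAAAA-BBBBBBBBBB-N,OCC1OC(O)C1,180.063388",
    "HMDB0000002,alanine,C3H7NO2,CCCCCCCCCCCCCC-DDDDDDDDDD-N,CC(N)C(=O)O,"
  ), f)
  cmp <- read_compound_csv(f)
  expect_length(cmp, 2)
  expect_equal(cmp[["HMDB0000001"]]$exact_mass, 180.063388)
  expect_null(cmp[["HMDB0000002"]]$exact_mass)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "hmdb_id,name,formula,inchikey,smiles,exact_mass",
    "HMDB0000001,first,C6H12O6,K1,S1,180.0",
    "HMDB0000001,second,C6H12O6,K1,S1,181.0"
  ), f2)
  expect_warning(cmp2 <- read_compound_csv(f2), "duplicate")
  expect_length(cmp2, 1)
  expect_identical(cmp2[["HMDB0000001"]]$name, "second")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("hmdb_id,name,formula", "x,y,z"), f3)
  expect_error(read_compound_csv(f3), "missing required column")
})

test_that("key and ion-mode normalization are idempotent and total", {
  keys <- c("PRECURSORMZ", "PrecursorMZ", "precursor_mz", "Ion mode",
            "IONMODE", "ionization mode", "Adduct", "PRECURSORTYPE",
            "Exact Mass", "unheard-of key")
  once <- vapply(keys, normalize_msp_key, character(1))
  twice <- vapply(once, normalize_msp_key, character(1))
  expect_identical(unname(twice), unname(once))
  expect_identical(unname(once[1:3]), rep("precursor_mz", 3))
  expect_identical(unname(once[4:6]), rep("ionmode", 3))
  expect_identical(unname(once[7:8]), rep("adduct", 2))

  expect_identical(normalize_ionmode(c("P", "pos", "POSITIVE", "+")),
                   rep("positive", 4))
  expect_identical(normalize_ionmode(c("N", "neg", "Negative", "-", "−")),
                   rep("negative", 5))
  expect_identical(normalize_ionmode(c("", "weird", NA)),
                   rep("unknown", 3))
})
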