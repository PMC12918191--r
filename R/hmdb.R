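#' Read an HMDB-style experimental MS/MS spectrum XML file
#'
#' Parses the schema used by HMDB spectrum exports (emulated by the
#' package's synthetic fixtures): a `database-id` element, an optional
#' `ionization-mode`, an optional `collision-energy`, and a peak list of
#' `(mass-charge, intensity)` entries. Adduct and precursor m/z are
#' typically absent from these files — that deficiency is what the repair
#' workflow addresses.
#'
#' @param path path to one spectrum XML file.
#' @return an `ms_spectrum` with metadata `hmdb_id`, `ionmode`
#'   (`"unknown"` when the ionization element is absent) and optionally
#'   `collision_energy`.
#' @export
read_hmdb_xml <- function(path) {
  doc <- xml2::read_xml(path)
  id <- xml2::xml_text(xml2::xml_find_first(doc, ".//database-id"))
  if (is.na(id) || !nzchar(id)) {
    stop("missing database-id in ", path, call. = FALSE)
  }
  mode <- xml2::xml_text(xml2::xml_find_first(doc, ".//ionization-mode"))
  ce <- xml2::xml_text(xml2::xml_find_first(doc, ".//collision-energy"))
  peaks <- xml2::xml_find_all(doc, ".//ms-ms-peak")
  if (length(peaks) == 0) {
    stop("no peaks in ", path, call. = FALSE)
  }
  mz <- as.numeric(xml2::xml_text(
    xml2::xml_find_first(peaks, ".//mass-charge")))
  it <- as.numeric(xml2::xml_text(
    xml2::xml_find_first(peaks, ".//intensity")))
  if (any(is.na(mz)) || any(is.na(it))) {
    stop("unparsable peak values in ", path, call. = FALSE)
  }
  md <- list(hmdb_id = id,
             ionmode = if (is.na(mode)) "unknown" else mode)
  if (!is.na(ce) && nzchar(ce)) md$collision_energy <- ce
  spectrum_record(mz, it, md)
}

#' Read an HMDB-style compound metadata CSV
#'
#' Delimited text whose header names (case-insensitively, with separator
#' variants) the columns `hmdb_id`, `name`, `formula`, `inchikey`,
#' `smiles`, `exact_mass`. Duplicate ids keep the last row with a warning;
#' an empty exact mass leaves that field absent.
#'
#' @param path CSV file path.
#' @return named list: `hmdb_id` -> list of compound fields.
#' @export
read_compound_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, encoding = "UTF-8")
  names(df) <- vapply(names(df), normalize_msp_key, character(1))
  names(df)[names(df) == "hmdbid"] <- "hmdb_id"
  required <- c("hmdb_id", "name", "formula", "inchikey", "smiles",
                "exact_mass")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("compound CSV missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$hmdb_id)) {
    warning("duplicate compound id(s): ",
            paste(unique(df$hmdb_id[duplicated(df$hmdb_id)]),
                  collapse = ", "), "; last row wins", call. = FALSE)
    df <- df[!duplicated(df$hmdb_id, fromLast = TRUE), ]
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    entry <- list(name = df$name[i], formula = df$formula[i],
                  inchikey = df$inchikey[i], smiles = df$smiles[i])
    em <- suppressWarnings(as.numeric(df$exact_mass[i]))
    if (!is.na(em)) entry$exact_mass <- em
    entry
  })
  stats::setNames(out, df$hmdb_id)
}

#' Build an HMDB-style spectral library from XML spectra plus compound CSV
#'
#' Each spectrum XML is joined to the compound table on its database id;
#' joined spectra gain `inchikey`, `smiles`, `formula`, `exact_mass` and
#' `name`. Spectra whose id has no compound entry (and files that fail to
#' parse) are dropped and counted — the join is reported, not guessed.
#'
#' @param xml_dir directory of spectrum XML files (`*.xml`).
#' @param compound_csv compound metadata CSV path.
#' @param name provenance label for the library.
#' @return a [spectral_library()] with a `"report"` attribute: list with
#'   `n_joined`, `n_dropped_no_compound`, `n_parse_failed`.
#' @export
build_hmdb <- function(xml_dir, compound_csv, name = "HMDB") {
  files <- sort(list.files(xml_dir, pattern = "\\.xml$", full.names = TRUE))
  if (length(files) == 0) {
    warning("no XML files found in ", xml_dir, call. = FALSE)
  }
  compounds <- read_compound_csv(compound_csv)
  spectra <- list()
  dropped <- 0L
  failed <- 0L
  for (f in files) {
    sp <- tryCatch(read_hmdb_xml(f), error = function(e) NULL)
    if (is.null(sp)) {
      failed <- failed + 1L
      next
    }
    id <- sp$metadata$hmdb_id
    cmp <- compounds[[id]]
    if (is.null(cmp)) {
      dropped <- dropped + 1L
      next
    }
    sp$metadata$name <- cmp$name
    sp$metadata$formula <- cmp$formula
    sp$metadata$inchikey <- cmp$inchikey
    sp$metadata$smiles <- cmp$smiles
    if (!is.null(cmp$exact_mass)) {
      sp$metadata$exact_mass <- format(cmp$exact_mass, digits = 10)
    }
    sp$metadata$source_library <- name
    spectra[[length(spectra) + 1L]] <- sp
  }
  lib <- spectral_library(spectra, name = name)
  attr(lib, "report") <- list(n_joined = length(spectra),
                              n_dropped_no_compound = dropped,
                              n_parse_failed = failed)
  lib
}
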