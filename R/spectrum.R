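#' msrepair: repair adduct and precursor metadata in MS/MS spectral libraries
#'
#' Curation toolkit for tandem mass spectral libraries: a dynamic-programming
#' spectral alignment (OSA), reference similarity/distance metrics, a tolerant
#' adduct grammar, a learned adduct-string corrector, identifier- and
#' ion-mode-filtered adduct prediction with benchmarking, HMDB-style library
#' construction, metadata subsetting, and a deterministic synthetic-data
#' generator with planted ground truth.
#'
#' @useDynLib msrepair, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd cor quantile
#' @importFrom utils read.csv head
#' @keywords internal
"_PACKAGE"

#' Construct a single MS/MS spectrum
#'
#' The basic unit of all matching: a metadata map (field name to string) plus
#' a peak list. Peaks are sorted by ascending m/z; duplicate m/z values are
#' merged by summing intensities so that peak lists are strictly ascending, as
#' required by the alignment preprocessing.
#'
#' @param mz numeric vector of mass-to-charge ratios (Da), all > 0.
#' @param intensity numeric vector of non-negative relative abundances.
#' @param metadata named list (or named character vector) of metadata fields;
#'   names are normalized to lower-case canonical keys (see
#'   [normalize_msp_key()]) and values coerced to single strings. An
#'   `ionmode` entry is normalized to `"positive"`, `"negative"` or
#'   `"unknown"`.
#' @return an object of class `ms_spectrum`: a list with elements `metadata`
#'   (named list of strings) and `peaks` (two-column numeric matrix `mz`,
#'   `intensity`, strictly ascending in `mz`).
#' @examples
#' sp <- spectrum_record(c(100.1, 181.07), c(50, 999),
#'                       list(name = "demo", ionmode = "P", adduct = "[M+H]+"))
#' sp$metadata$ionmode
#' @export
spectrum_record <- function(mz = numeric(), intensity = numeric(),
                            metadata = list()) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("all m/z values must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("all intensities must be finite and >= 0", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  # merge exact duplicate m/z (sum intensities) to keep strict ascending order
  if (anyDuplicated(mz)) {
    grp <- match(mz, unique(mz))
    intensity <- as.numeric(tapply(intensity, grp, sum))
    mz <- unique(mz)
  }
  md <- normalize_metadata(metadata)
  structure(
    list(metadata = md,
         peaks = cbind(mz = mz, intensity = intensity)),
    class = "ms_spectrum"
  )
}

normalize_metadata <- function(metadata) {
  if (length(metadata) == 0) return(structure(list(), names = character()))
  keys <- names(metadata)
  if (is.null(keys) || any(!nzchar(keys))) {
    stop("metadata must be fully named", call. = FALSE)
  }
  vals <- lapply(metadata, function(v) as.character(v)[1])
  keys <- vapply(keys, normalize_msp_key, character(1), USE.NAMES = FALSE)
  md <- stats::setNames(vals, keys)
  # last occurrence wins for keys that collide after normalization
  md <- md[!duplicated(names(md), fromLast = TRUE)]
  md <- md[order(match(names(md), unique(keys)))]
  if (!is.null(md$ionmode)) md$ionmode <- normalize_ionmode(md$ionmode)
  md
}

#' Normalize an MSP metadata key to its canonical lower-case name
#'
#' Case-folds, converts separators to underscores, and maps the common
#' synonyms found across open libraries (`PRECURSORMZ`, `PrecursorMZ` ->
#' `precursor_mz`; `Ion_mode`, `ionization mode` -> `ionmode`;
#' `PRECURSORTYPE`, `Adduct` -> `adduct`; etc.). Idempotent and total: any
#' string yields a key.
#'
#' @param key a metadata key as found in a file.
#' @return canonical lower-case key.
#' @export
normalize_msp_key <- function(key) {
  k <- tolower(trimws(as.character(key)))
  k <- gsub("[ /\\-]+", "_", k)
  k <- gsub("_+", "_", k)
  syn <- c(
    precursormz = "precursor_mz", precursor_m_z = "precursor_mz",
    precursor_mz = "precursor_mz",
    ion_mode = "ionmode", ionization_mode = "ionmode", ionmode = "ionmode",
    ionization = "ionmode", polarity = "ionmode",
    precursortype = "adduct", precursor_type = "adduct", adduct = "adduct",
    adduct_type = "adduct",
    exactmass = "exact_mass", exact_mass = "exact_mass",
    monoisotopic_mass = "exact_mass",
    molecular_formula = "formula", formula = "formula",
    compound_name = "name", name = "name",
    inchikey = "inchikey", smiles = "smiles", inchi = "inchi",
    num_peaks = "num_peaks", numpeaks = "num_peaks"
  )
  if (k %in% names(syn)) unname(syn[[k]]) else k
}

#' Normalize an ionization-mode string
#'
#' Total mapping into the three-valued vocabulary used by all matching
#' operations: `{P, pos, positive, +, 1}` (any case) map to `"positive"`,
#' `{N, neg, negative, -}` to `"negative"`, everything else (including `NA`
#' and empty strings) to `"unknown"`.
#'
#' @param x character vector of raw ion-mode strings.
#' @return character vector over `{"positive", "negative", "unknown"}`.
#' @export
normalize_ionmode <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("−", "-", x)  # unicode minus
  out <- rep("unknown", length(x))
  out[x %in% c("p", "pos", "positive", "+", "1", "positive mode")] <- "positive"
  out[x %in% c("n", "neg", "negative", "-", "negative mode")] <- "negative"
  out[is.na(x)] <- "unknown"
  out
}

#' Construct a spectral library
#'
#' An ordered collection of spectra with a provenance label.
#'
#' @param spectra list of [spectrum_record()] objects.
#' @param name non-empty provenance label.
#' @return object of class `spectral_library` with elements `name`, `spectra`.
#' @export
spectral_library <- function(spectra = list(), name = "library") {
  if (!nzchar(name)) stop("library name must be non-empty", call. = FALSE)
  ok <- vapply(spectra, inherits, logical(1), what = "ms_spectrum")
  if (length(spectra) && !all(ok)) {
    stop("all elements must be ms_spectrum objects", call. = FALSE)
  }
  structure(list(name = name, spectra = spectra), class = "spectral_library")
}

#' @export
length.spectral_library <- function(x) length(x$spectra)

#' @export
`[.spectral_library` <- function(x, i) {
  spectral_library(x$spectra[i], name = x$name)
}

#' Concatenate spectral libraries
#'
#' Integration of subject libraries is plain concatenation with provenance
#' kept in each spectrum's `source_library` field (set when absent).
#'
#' @param ... `spectral_library` objects.
#' @param name label of the combined library.
#' @return a `spectral_library`.
#' @export
concat_libraries <- function(..., name = "integrated") {
  libs <- list(...)
  if (length(libs) == 1 && is.list(libs[[1]]) &&
      !inherits(libs[[1]], "spectral_library")) {
    libs <- libs[[1]]
  }
  spectra <- list()
  for (lib in libs) {
    stopifnot(inherits(lib, "spectral_library"))
    sp <- lapply(lib$spectra, function(s) {
      if (is.null(s$metadata$source_library)) {
        s$metadata$source_library <- lib$name
      }
      s
    })
    spectra <- c(spectra, sp)
  }
  spectral_library(spectra, name = name)
}

#' @export
print.ms_spectrum <- function(x, ...) {
  nm <- x$metadata$name
  cat(sprintf("<ms_spectrum> %s | %d peaks\n",
              if (is.null(nm)) "(unnamed)" else nm, nrow(x$peaks)))
  keys <- setdiff(names(x$metadata), "name")
  if (length(keys)) {
    cat("  ", paste(sprintf("%s=%s", keys,
                            unlist(x$metadata[keys], use.names = FALSE)),
                    collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> '%s': %d spectra\n", x$name,
              length(x$spectra)))
  invisible(x)
}

# single metadata value (or NA) -- tolerant accessor used throughout
meta_field <- function(spectrum, key) {
  v <- spectrum$metadata[[key]]
  if (is.null(v) || !nzchar(v)) NA_character_ else v
}

meta_number <- function(spectrum, key) {
  v <- meta_field(spectrum, key)
  if (is.na(v)) return(NA_real_)
  suppressWarnings(as.numeric(v))
}
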