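#' Subset a library on metadata criteria
#'
#' Conjunctive filtering: every predicate must hold. Categorical fields
#' match against an exact value set (ion modes are normalized first);
#' continuous fields (`precursor_mz`, `exact_mass`, or any numeric field)
#' match a closed interval. A spectrum missing a filtered field fails that
#' predicate.
#'
#' @param lib a [spectral_library()].
#' @param values named list: field -> character vector of accepted values.
#' @param ranges named list: field -> numeric `c(lo, hi)` closed interval.
#' @return the filtered [spectral_library()].
#' @examples
#' \dontrun{
#' subset_library(lib, values = list(ionmode = "positive"),
#'                ranges = list(precursor_mz = c(150, 200)))
#' }
#' @export
subset_library <- function(lib, values = list(), ranges = list()) {
  stopifnot(inherits(lib, "spectral_library"))
  if (length(values) == 0 && length(ranges) == 0) {
    stop("at least one predicate is required", call. = FALSE)
  }
  # standard spectral-metadata vocabulary plus whatever the library carries;
  # a standard field absent from every spectrum is a legal (empty) filter
  known <- unique(c("ionmode", "adduct", "name", "inchikey", "inchi",
                    "smiles", "formula", "source_library", "precursor_mz",
                    "exact_mass", "retention_time", "collision_energy",
                    "instrument", "instrument_type", "ms_level", "hmdb_id",
                    "spectrum_id",
                    unlist(lapply(lib$spectra, function(s) names(s$metadata)))))
  bad <- setdiff(c(names(values), names(ranges)), known)
  if (length(bad)) {
    stop("unknown field(s): ", paste(bad, collapse = ", "),
         "; known fields: ", paste(sort(known), collapse = ", "),
         call. = FALSE)
  }
  for (f in names(ranges)) {
    r <- ranges[[f]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop("range for '", f, "' must be c(lo, hi) with lo <= hi",
           call. = FALSE)
    }
  }
  keep <- vapply(lib$spectra, function(s) {
    for (f in names(values)) {
      v <- meta_field(s, f)
      accept <- values[[f]]
      if (f == "ionmode") {
        v <- normalize_ionmode(v)
        accept <- normalize_ionmode(accept)
      }
      if (is.na(v) || !v %in% accept) return(FALSE)
    }
    for (f in names(ranges)) {
      x <- meta_number(s, f)
      if (is.na(x) || x < ranges[[f]][1] || x > ranges[[f]][2]) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  spectral_library(lib$spectra[keep], name = lib$name)
}

#' Descriptive statistics of a spectral library
#'
#' The per-library summary used to characterize annotation completeness:
#' spectrum count; count and percentage of spectra with missing adducts
#' (absent key, empty string, or a placeholder such as `UNKNOWN`); the
#' ion-mode distribution at the spectrum level and at the identifier
#' (InChIKey) level (`positive only`, `negative only`, `both`, `missing`);
#' spectra-per-InChIKey distribution; and the adduct-form frequency table
#' (canonical forms).
#'
#' @param lib a [spectral_library()].
#' @return list of class `library_stats`.
#' @export
library_stats <- function(lib) {
  n <- length(lib)
  adducts <- vapply(lib$spectra, function(s) {
    safe_canonical_adduct(meta_field(s, "adduct"))
  }, character(1))
  missing_adduct <- sum(adducts == "UNKNOWN")
  modes <- vapply(lib$spectra, function(s) {
    normalize_ionmode(meta_field(s, "ionmode"))
  }, character(1))
  keys <- vapply(lib$spectra, function(s) meta_field(s, "inchikey"),
                 character(1))
  mode_tab <- table(factor(modes, levels = c("positive", "negative",
                                             "unknown")))
  key_modes <- if (any(!is.na(keys))) {
    tapply(modes[!is.na(keys)], keys[!is.na(keys)], function(m) {
      has_p <- "positive" %in% m
      has_n <- "negative" %in% m
      if (has_p && has_n) "both"
      else if (has_p) "positive only"
      else if (has_n) "negative only"
      else "missing"
    })
  } else {
    character(0)
  }
  key_mode_tab <- table(factor(key_modes,
                               levels = c("positive only", "negative only",
                                          "both", "missing")))
  per_key <- if (any(!is.na(keys))) table(keys[!is.na(keys)]) else table(NULL)
  adduct_tab <- sort(table(adducts[adducts != "UNKNOWN"]), decreasing = TRUE)
  structure(list(
    n_spectra = n,
    missing_adduct = missing_adduct,
    missing_adduct_pct = if (n > 0) 100 * missing_adduct / n else 0,
    ionmode_spectra = mode_tab,
    ionmode_identifiers = key_mode_tab,
    n_identifiers = length(per_key),
    spectra_per_identifier = if (length(per_key)) {
      c(mean = mean(per_key), max = max(per_key))
    } else {
      c(mean = 0, max = 0)
    },
    adduct_frequency = adduct_tab
  ), class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("<library_stats> %d spectra | %d (%.1f%%) missing adduct\n",
              x$n_spectra, x$missing_adduct, x$missing_adduct_pct))
  cat("  ion modes (spectra):    ",
      paste(names(x$ionmode_spectra), as.integer(x$ionmode_spectra),
            sep = "=", collapse = "  "), "\n")
  cat("  ion modes (identifiers):",
      paste(names(x$ionmode_identifiers), as.integer(x$ionmode_identifiers),
            sep = "=", collapse = "  "), "\n")
  cat(sprintf("  %d identifiers | spectra per identifier mean %.1f max %d\n",
              x$n_identifiers, x$spectra_per_identifier[["mean"]],
              as.integer(x$spectra_per_identifier[["max"]])))
  invisible(x)
}

#' Pairwise-exclusion query/subject pairs
#'
#' The benchmarking design in which each library is compared against the
#' integration of the remaining ones: for every library L, the query set is
#' L restricted to the InChIKeys shared by all libraries, and the subject
#' is the concatenation of the others. The intersection uses full
#' 27-character InChIKeys.
#'
#' @param libraries list of at least two spectral libraries.
#' @return list of elements `(query, subject)`, one per input library, with
#'   attribute `"intersection"` (the shared InChIKey set). An empty
#'   intersection yields empty query sets with a warning.
#' @export
pairwise_exclusion_sets <- function(libraries) {
  stopifnot(length(libraries) >= 2)
  keysets <- lapply(libraries, function(lib) {
    k <- vapply(lib$spectra, function(s) meta_field(s, "inchikey"),
                character(1))
    unique(k[!is.na(k)])
  })
  shared <- Reduce(intersect, keysets)
  if (length(shared) == 0) {
    warning("no InChIKey shared by all libraries; query sets are empty",
            call. = FALSE)
  }
  out <- lapply(seq_along(libraries), function(i) {
    lib <- libraries[[i]]
    keep <- vapply(lib$spectra, function(s) {
      k <- meta_field(s, "inchikey")
      !is.na(k) && k %in% shared
    }, logical(1))
    query <- spectral_library(lib$spectra[keep], name = lib$name)
    subject <- concat_libraries(libraries[-i],
                                name = paste0("all-but-", lib$name))
    list(query = query, subject = subject)
  })
  names(out) <- vapply(libraries, function(l) l$name, character(1))
  attr(out, "intersection") <- shared
  out
}
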