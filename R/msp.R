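#' Read an MSP spectral library
#'
#' Parses NIST-style MSP text: repeated blocks of `KEY: VALUE` lines (the
#' `=` separator is also accepted), a `Num Peaks: N` line, then `N` peak
#' lines with m/z and intensity separated by whitespace or tabs; blocks are
#' separated by blank lines. Metadata keys are normalized through
#' [normalize_msp_key()] and ion modes through [normalize_ionmode()]. A block
#' whose declared peak count disagrees with the number of parsable peak
#' lines, or that cannot be parsed, is skipped with a warning — peaks are
#' never silently dropped.
#'
#' @param path path to an MSP file (UTF-8).
#' @param name provenance label of the returned library; defaults to the
#'   file name without extension.
#' @return a [spectral_library()]. Skipped-block diagnostics are attached as
#'   the `"errors"` attribute (character vector, one message per bad block).
#' @seealso [write_msp()]
#' @export
read_msp <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blocks <- split_blocks(lines)
  spectra <- list()
  errors <- character()
  for (b in seq_along(blocks)) {
    res <- tryCatch(parse_msp_block(blocks[[b]]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      msg <- sprintf("MSP block %d skipped: %s", b, res)
      errors <- c(errors, msg)
      warning(msg, call. = FALSE)
    } else {
      spectra[[length(spectra) + 1L]] <- res
    }
  }
  lib <- spectral_library(spectra, name = name)
  attr(lib, "errors") <- errors
  lib
}

split_blocks <- function(lines) {
  blank <- !nzchar(trimws(lines))
  if (all(blank)) return(list())
  grp <- cumsum(blank)
  keep <- !blank
  unname(split(lines[keep], grp[keep]))
}

parse_msp_block <- function(lines) {
  md <- list()
  npeaks <- NA_integer_
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    m <- regmatches(ln, regexec("^([^:=]+)[:=](.*)$", ln))[[1]]
    if (length(m) == 0) stop("unparsable metadata line: '", ln, "'")
    key <- normalize_msp_key(m[2])
    val <- trimws(m[3])
    i <- i + 1L
    if (key == "num_peaks") {
      npeaks <- suppressWarnings(as.integer(val))
      if (is.na(npeaks)) stop("bad Num Peaks value: '", val, "'")
      break
    }
    md[[key]] <- val
  }
  if (is.na(npeaks)) stop("missing Num Peaks line")
  peak_lines <- if (i > length(lines)) character() else lines[i:length(lines)]
  if (length(peak_lines) != npeaks) {
    stop(sprintf("declared %d peaks but found %d peak lines",
                 npeaks, length(peak_lines)))
  }
  mz <- numeric(npeaks)
  it <- numeric(npeaks)
  for (k in seq_len(npeaks)) {
    parts <- strsplit(trimws(peak_lines[k]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts[1:2]))
    if (length(parts) < 2 || any(is.na(vals))) {
      stop("unparsable peak line: '", peak_lines[k], "'")
    }
    mz[k] <- vals[1]
    it[k] <- vals[2]
  }
  spectrum_record(mz, it, md)
}

#' Write a spectral library in MSP format
#'
#' Emits the canonical dialect: upper-snake metadata keys, a `NUM PEAKS`
#' line, tab-separated peak lines with m/z printed to 6 decimal places, and a
#' blank line between blocks. `read_msp(write_msp(lib))` reproduces the
#' library exactly on metadata strings and to 1e-6 on peak values.
#'
#' @param lib a [spectral_library()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (sp in lib$spectra) {
    md <- sp$metadata
    for (key in names(md)) {
      writeLines(sprintf("%s: %s", toupper(key), md[[key]]), con)
    }
    writeLines(sprintf("NUM PEAKS: %d", nrow(sp$peaks)), con)
    if (nrow(sp$peaks)) {
      writeLines(sprintf("%.6f\t%.6f", sp$peaks[, "mz"],
                         sp$peaks[, "intensity"]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Per-block validation diagnostics for an MSP file
#'
#' Convenience wrapper used by the command-line `io validate` entry point:
#' parses the file and returns counts plus any block-level error messages.
#'
#' @param path MSP file path.
#' @return list with `n_spectra`, `n_skipped`, `errors`.
#' @export
validate_msp <- function(path) {
  lib <- suppressWarnings(read_msp(path))
  errs <- attr(lib, "errors")
  list(n_spectra = length(lib), n_skipped = length(errs), errors = errs)
}
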