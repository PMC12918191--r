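#' Monoisotopic ion-component mass table
#'
#' Masses (Da) of the neutral fragments that may be gained or lost when a
#' molecule M ionizes in ESI; the electron mass is handled separately in the
#' m/z arithmetic. The table ships as a delimited file
#' (`inst/extdata/ion_masses.tsv`) so users can extend the vocabulary, in the
#' spirit of the community adduct dictionaries it emulates.
#'
#' @param path optional path to a two-plus-column TSV with columns `token`
#'   and `mass`; defaults to the table shipped with the package.
#' @return named numeric vector: token -> monoisotopic mass (Da).
#' @export
ion_mass_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ion_masses.tsv", package = "msrepair")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(as.numeric(tab$mass), tab$token)
}

#' Electron rest mass in Da
#' @export
ELECTRON_MASS <- 0.000548579909

the_ion_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ion_mass_table()
    cache
  }
})

missing_adduct <- function(raw = "") {
  structure(list(raw = raw), class = "missing_adduct")
}

#' Is this a missing-adduct sentinel?
#'
#' Placeholder annotations (`""`, `"UNKNOWN"`, `"?"`, `"N/A"`, ...) parse to
#' a sentinel rather than erroring, because the repair workflow must route
#' them to adduct prediction instead of rejecting the spectrum.
#'
#' @param x any object.
#' @return logical scalar.
#' @export
is_missing_adduct <- function(x) inherits(x, "missing_adduct")

adduct_parse_error <- function(offending, msg) {
  stop(structure(
    class = c("adduct_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse adduct: %s ('%s')", msg, offending),
         call = NULL, offending = offending)
  ))
}

#' Parse an adduct string into its structured form
#'
#' Tolerant grammar over ESI adduct notation: accepts missing brackets,
#' whitespace, unicode minus signs, a leading `nM` multiplier, count
#' prefixes on ions (`2H`), and the charge notations `+`, `-`, `++`, `2+`,
#' `+2`. Ion tokens must appear in the [ion_mass_table()]. Placeholder
#' strings (`""`, `"unknown"`, `"?"`, `"n/a"`, `"none"`, `"null"`, `"nan"`)
#' return a missing-adduct sentinel (see [is_missing_adduct()]).
#'
#' @param s an adduct string, e.g. `"[M + H2O + H] +"`.
#' @param ions named numeric vector of token masses; defaults to the shipped
#'   table.
#' @return object of class `adduct_form` with fields `multiplier` (count of
#'   M), `gains` and `losses` (named integer vectors: token -> count) and
#'   `charge` (signed non-zero integer); or a `missing_adduct` sentinel.
#'   Unknown tokens, zero charge or unparsable residues signal an
#'   `adduct_parse_error` carrying the offending substring.
#' @examples
#' parse_adduct("[M+H]+")
#' parse_adduct("[2M-H]-")$multiplier
#' @export
parse_adduct <- function(s, ions = the_ion_table()) {
  raw <- s
  s <- gsub("[−–—]", "-", as.character(s)[1])
  s <- gsub("\\s+", "", s)
  if (is.na(s) ||
      tolower(s) %in% c("", "unknown", "?", "n/a", "na", "none", "null",
                        "nan", "unk")) {
    return(missing_adduct(raw))
  }
  s <- gsub("^\\[+", "", s)
  # molecule part: optional multiplier then M (case-tolerant)
  m <- regexec("^([0-9]*)[Mm]", s)[[1]]
  if (m[1] == -1) adduct_parse_error(raw, "no molecule symbol M")
  mult <- regmatches(s, regexec("^([0-9]*)[Mm]", s))[[1]][2]
  multiplier <- if (nzchar(mult)) as.integer(mult) else 1L
  if (multiplier < 1) adduct_parse_error(raw, "multiplier must be >= 1")
  rest <- substring(s, attr(m, "match.length")[1] + 1L)

  tokens <- names(ions)[order(-nchar(names(ions)))]
  tok_re <- paste0("^([+-])([0-9]*)(", paste(tokens, collapse = "|"), ")")
  gains <- integer()
  losses <- integer()
  repeat {
    hit <- regmatches(rest, regexec(tok_re, rest))[[1]]
    if (length(hit) == 0) break
    sign <- hit[2]
    cnt <- if (nzchar(hit[3])) as.integer(hit[3]) else 1L
    tok <- hit[4]
    if (sign == "+") {
      gains[tok] <- (if (tok %in% names(gains)) gains[[tok]] else 0L) + cnt
    } else {
      losses[tok] <- (if (tok %in% names(losses)) losses[[tok]] else 0L) + cnt
    }
    rest <- substring(rest, nchar(hit[1]) + 1L)
  }
  rest <- sub("^\\]+", "", rest)
  charge <- parse_charge(rest, raw)
  if (is.null(charge)) {
    # residue is neither a charge nor empty -> name the offending part
    bad <- sub("^[+-]", "", rest)
    bad <- if (nzchar(bad)) sub("[]+-].*$", "", bad) else rest
    adduct_parse_error(if (nzchar(bad)) bad else raw, "unparsable residue")
  }
  new_adduct_form(multiplier, gains, losses, charge)
}

# charge grammar: "+", "-", "++", "--", "2+", "+2"; NULL when unparsable
parse_charge <- function(s, raw) {
  if (s == "") adduct_parse_error(raw, "missing charge")
  if (grepl("^\\++$", s)) return(nchar(s))
  if (grepl("^-+$", s)) return(-nchar(s))
  m <- regmatches(s, regexec("^([0-9]+)([+-])$", s))[[1]]
  if (length(m)) {
    n <- as.integer(m[2])
    if (n == 0) adduct_parse_error(raw, "zero charge")
    return(if (m[3] == "+") n else -n)
  }
  m <- regmatches(s, regexec("^([+-])([0-9]+)$", s))[[1]]
  if (length(m)) {
    n <- as.integer(m[3])
    if (n == 0) adduct_parse_error(raw, "zero charge")
    return(if (m[2] == "+") n else -n)
  }
  NULL
}

new_adduct_form <- function(multiplier, gains, losses, charge) {
  sort_ions <- function(v) {
    if (length(v) == 0) return(stats::setNames(integer(), character()))
    v[order(names(v) != "H", names(v), method = "radix")]
  }
  structure(list(multiplier = as.integer(multiplier),
                 gains = sort_ions(gains),
                 losses = sort_ions(losses),
                 charge = as.integer(charge)),
            class = "adduct_form")
}

#' @export
print.adduct_form <- function(x, ...) {
  cat("<adduct_form>", canonical_string(x), "\n")
  invisible(x)
}

#' @export
print.missing_adduct <- function(x, ...) {
  cat("<missing adduct> raw:", sQuote(x$raw), "\n")
  invisible(x)
}

#' Canonical adduct label
#'
#' Deterministic canonical rendering of an adduct form:
#' `[{n}M{gains}{losses}]{charge}` with gains before losses, `H` first in
#' each group then remaining tokens alphabetically, repeated ions collapsed
#' to a count prefix (`2H`), and charge rendered `+`, `-`, `2+`, ... The
#' rendering is idempotent: `canonical_string(parse_adduct(x))` is a fixed
#' point of the grammar.
#'
#' @param a an `adduct_form` (or a `missing_adduct`, rendered `"UNKNOWN"`).
#' @return canonical adduct string.
#' @examples
#' canonical_string(parse_adduct("[M+H2O+H]+"))  # "[M+H+H2O]+"
#' @export
canonical_string <- function(a) {
  if (is_missing_adduct(a)) return("UNKNOWN")
  stopifnot(inherits(a, "adduct_form"))
  fmt_group <- function(v, sign) {
    if (length(v) == 0) return("")
    ord <- order(names(v) != "H", names(v), method = "radix")
    v <- v[ord]
    paste0(vapply(seq_along(v), function(i) {
      paste0(sign, if (v[[i]] > 1) v[[i]] else "", names(v)[i])
    }, character(1)), collapse = "")
  }
  mult <- if (a$multiplier > 1) a$multiplier else ""
  n <- abs(a$charge)
  chg <- paste0(if (n > 1) n else "", if (a$charge > 0) "+" else "-")
  paste0("[", mult, "M", fmt_group(a$gains, "+"), fmt_group(a$losses, "-"),
         "]", chg)
}

#' Enumerate positional permutations of an adduct's ions
#'
#' All orderings of the signed ion sequence rendered as strings (distinct
#' strings only). Every member parses back to the same canonical form: the
#' permutations are notational variants of one chemical species, the
#' ambiguity the corrector is trained to collapse.
#'
#' @param a an `adduct_form` or an adduct string.
#' @return character vector of adduct strings (includes the canonical one).
#' @examples
#' enumerate_permutations("[M+H+H2O]+")
#' @export
enumerate_permutations <- function(a) {
  if (is.character(a)) a <- parse_adduct(a)
  stopifnot(inherits(a, "adduct_form"))
  item_of <- function(v, sign) {
    vapply(seq_along(v), function(i) {
      paste0(sign, if (v[[i]] > 1) v[[i]] else "", names(v)[i])
    }, character(1))
  }
  items <- c(item_of(a$gains, "+"), item_of(a$losses, "-"))
  mult <- if (a$multiplier > 1) a$multiplier else ""
  n <- abs(a$charge)
  chg <- paste0(if (n > 1) n else "", if (a$charge > 0) "+" else "-")
  if (length(items) == 0) {
    return(paste0("[", mult, "M]", chg))
  }
  perms <- permutations_of(seq_along(items))
  out <- vapply(perms, function(p) {
    paste0("[", mult, "M", paste(items[p], collapse = ""), "]", chg)
  }, character(1))
  unique(out)
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Theoretical precursor m/z of an adduct
#'
#' `(multiplier * M + sum(gain masses) - sum(loss masses) - charge * m_e)
#' / |charge|`, with component masses from the [ion_mass_table()] and the
#' electron mass included per unit charge (so `[M+H]+` uses the proton mass
#' 1.0072765 Da).
#'
#' @param a an `adduct_form` or adduct string.
#' @param neutral_mass neutral monoisotopic mass of M in Da (> 0).
#' @param ions named mass table; defaults to the shipped table.
#' @return precursor m/z in Da.
#' @examples
#' theoretical_precursor_mz("[M+H]+", 180.063388)   # 181.070664
#' theoretical_precursor_mz("[M+2H]2+", 180.063388) # 91.038971
#' @export
theoretical_precursor_mz <- function(a, neutral_mass,
                                     ions = the_ion_table()) {
  if (is.character(a)) a <- parse_adduct(a, ions)
  if (is_missing_adduct(a)) {
    stop("cannot compute precursor m/z for a missing adduct", call. = FALSE)
  }
  stopifnot(inherits(a, "adduct_form"), neutral_mass > 0)
  mass_of <- function(v) {
    if (length(v) == 0) return(0)
    unknown <- setdiff(names(v), names(ions))
    if (length(unknown)) {
      stop("token(s) missing from ion mass table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    sum(ions[names(v)] * unlist(v))
  }
  num <- a$multiplier * neutral_mass + mass_of(a$gains) - mass_of(a$losses) -
    a$charge * ELECTRON_MASS
  num / abs(a$charge)
}

#' The shipped adduct dictionary
#'
#' Canonical adduct labels with charge, multiplier, composition and the mass
#' shift of the m/z numerator relative to `multiplier * M`
#' (`sum gains - sum losses - charge * m_e`, Da). A superset of the common
#' ESI adducts; user-extensible via `path`.
#'
#' @param path optional TSV with columns `canonical`, `charge`, `multiplier`,
#'   `composition`, `mass_shift`.
#' @return data.frame with those columns.
#' @export
adduct_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "adduct_dictionary.tsv",
                        package = "msrepair")
  }
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

# canonical string or "UNKNOWN" for any raw annotation; never errors
safe_canonical_adduct <- function(s) {
  if (is.null(s) || is.na(s)) return("UNKNOWN")
  out <- tryCatch(canonical_string(parse_adduct(preprocess_adduct_text(s))),
                  adduct_parse_error = function(e) "UNKNOWN",
                  error = function(e) "UNKNOWN")
  out
}
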