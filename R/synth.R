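#' Corruption plan for synthetic libraries
#'
#' Describes how a generated library deviates from its planted ground
#' truth. Corruption counts are exact (`round(fraction * n)` spectra are
#' selected deterministically under the seed) rather than Bernoulli, so
#' tests can assert them exactly. Defaults are the package's study
#' conditions: 20% of adducts blanked and a 0.002 Da m/z jitter, with a 5%
#' multiplicative intensity jitter.
#'
#' @param fraction_blank_adduct fraction of spectra whose adduct is blanked.
#' @param fraction_permuted_adduct fraction annotated with a non-canonical
#'   positional permutation of the true adduct.
#' @param fraction_malformed_adduct fraction annotated with a formatting
#'   corruption of the true adduct.
#' @param fraction_noncanonical_smiles fraction carrying the variant (non
#'   canonical) SMILES string of their compound.
#' @param mz_jitter_sd per-peak m/z noise SD in Da.
#' @param intensity_jitter_sd SD of the multiplicative (log-normal)
#'   intensity noise.
#' @param seed integer seed; all generation is deterministic under it.
#' @return list of class `corruption_plan`.
#' @export
corruption_plan <- function(fraction_blank_adduct = 0.2,
                            fraction_permuted_adduct = 0,
                            fraction_malformed_adduct = 0,
                            fraction_noncanonical_smiles = 0,
                            mz_jitter_sd = 0.002,
                            intensity_jitter_sd = 0.05,
                            seed = 1L) {
  fr <- c(fraction_blank_adduct, fraction_permuted_adduct,
          fraction_malformed_adduct, fraction_noncanonical_smiles)
  stopifnot(all(fr >= 0 & fr <= 1), mz_jitter_sd >= 0,
            intensity_jitter_sd >= 0)
  structure(list(fraction_blank_adduct = fraction_blank_adduct,
                 fraction_permuted_adduct = fraction_permuted_adduct,
                 fraction_malformed_adduct = fraction_malformed_adduct,
                 fraction_noncanonical_smiles = fraction_noncanonical_smiles,
                 mz_jitter_sd = mz_jitter_sd,
                 intensity_jitter_sd = intensity_jitter_sd,
                 seed = as.integer(seed)),
            class = "corruption_plan")
}

#' Generate synthetic compounds
#'
#' Deterministic pseudo-compounds: a format-valid 27-character
#' pseudo-InChIKey, a pseudo-SMILES string plus a non-canonical variant
#' mapping to the same compound, a CHNOS molecular formula, and the
#' formula's monoisotopic mass (constrained to 80-900 Da). Isomer pairs
#' (same formula and mass, different identity) are planted for every run
#' with `n >= 4` to exercise the looseness of formula-based identifiers.
#'
#' @param n number of compounds (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `inchikey`, `smiles`, `smiles_variant`,
#'   `formula`, `exact_mass`, `name`, `hmdb_id`.
#' @export
make_compounds <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  masses <- c(C = 12, H = 1.007825032, N = 14.003074005, O = 15.994914620,
              S = 31.972071174)
  draw_formula <- function() {
    repeat {
      cnt <- c(C = sample(4:30, 1), H = sample(4:48, 1),
               N = sample(0:4, 1), O = sample(0:10, 1), S = sample(0:1, 1))
      m <- sum(cnt * masses)
      if (m >= 80 && m <= 900) return(list(cnt = cnt, mass = m))
    }
  }
  fmt_formula <- function(cnt) {
    paste0(vapply(names(cnt)[cnt > 0], function(el) {
      paste0(el, if (cnt[[el]] > 1) cnt[[el]] else "")
    }, character(1)), collapse = "")
  }
  keys <- character(0)
  draw_key <- function() {
    repeat {
      k <- paste0(paste(sample(LETTERS, 14, replace = TRUE), collapse = ""),
                  "-",
                  paste(sample(LETTERS, 10, replace = TRUE), collapse = ""),
                  "-N")
      if (!k %in% keys) return(k)
    }
  }
  draw_smiles <- function(cnt) {
    atoms <- rep(names(cnt), pmin(cnt, 8))
    paste0(paste(sample(atoms), collapse = ""), "(",
           paste(sample(c("C", "O", "N", "=", "1"), 4, replace = TRUE),
                 collapse = ""), ")")
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    # plant isomer pairs: compounds 2 and 4 reuse the previous formula
    if (i %in% c(2L, 4L) && i <= n && i > 1) {
      f <- out[[i - 1]]$f
    } else {
      f <- draw_formula()
    }
    key <- draw_key()
    keys <- c(keys, key)
    smi <- draw_smiles(f$cnt)
    out[[i]] <- list(f = f, key = key, smi = smi)
  }
  data.frame(
    inchikey = vapply(out, `[[`, character(1), "key"),
    smiles = vapply(out, `[[`, character(1), "smi"),
    smiles_variant = vapply(out, function(x) chartr("CON", "con", x$smi),
                            character(1)),
    formula = vapply(out, function(x) fmt_formula(x$f$cnt), character(1)),
    exact_mass = vapply(out, function(x) x$f$mass, numeric(1)),
    name = sprintf("SYN-%04d", seq_len(n)),
    hmdb_id = sprintf("HMDB%07d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

# Park-Miller stream keyed by a string: the base fragmentation pattern must
# be a pure function of (compound, adduct) so that the same species yields
# the same pattern in every generated library.
string_stream <- function(key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  state <- if (h == 0) 42 else h
  function() {
    state <<- (16807 * state) %% 2147483647
    state / 2147483647
  }
}

# Deterministic pseudo-spectrum of a compound ionized as `adduct`: an
# adduct-specific ion series (fragment neutral masses shifted like the
# precursor) plus the precursor ion itself. Fragment chemistry is not
# modelled -- only peak-list similarity matters downstream.
base_pattern <- function(compound, adduct, n_peaks = 20L) {
  a <- parse_adduct(adduct)
  pre <- theoretical_precursor_mz(a, compound$exact_mass)
  rng <- string_stream(paste0(compound$inchikey, "|", adduct))
  k <- max(1L, n_peaks - 1L)
  frag_neutral <- vapply(seq_len(k), function(i) {
    40 + rng() * max(10, compound$exact_mass - 50)
  }, numeric(1))
  shift <- pre - compound$exact_mass / abs(a$charge) * a$multiplier
  mz <- c(frag_neutral / abs(a$charge) + shift, pre)
  intensity <- c(vapply(seq_len(k), function(i) 5 + 95 * rng(), numeric(1)),
                 100)
  o <- order(mz)
  cbind(mz = mz[o], intensity = intensity[o])
}

#' Generate a synthetic spectral library with planted ground truth
#'
#' Per compound x adduct x replicate, a deterministic base fragmentation
#' pattern (a pure function of compound identity and adduct) is jittered
#' according to the plan; the precursor m/z metadata is the theoretical
#' value for the adduct plus jitter. Corruptions (blanked, permuted or
#' malformed adduct annotations; non-canonical SMILES) are applied to
#' exactly `round(fraction * n)` spectra each. Ground truth is total: every
#' spectrum has a truth record, including corrupted ones.
#'
#' @param compounds a [make_compounds()] data.frame (or subset).
#' @param adducts character vector of canonical adduct labels applied to
#'   every compound.
#' @param peaks_per_spectrum peaks per spectrum (including the precursor
#'   ion).
#' @param replicates replicate spectra per compound-adduct pair.
#' @param plan a [corruption_plan()].
#' @param name provenance label.
#' @return list with `library` (a [spectral_library()]) and `truth`
#'   (data.frame: `spectrum_id`, `inchikey`, `true_adduct`, `blanked`,
#'   `permuted`, `malformed`, `noncanonical_smiles`).
#' @export
make_library <- function(compounds, adducts = c("[M+H]+", "[M-H]-"),
                         peaks_per_spectrum = 20L, replicates = 2L,
                         plan = corruption_plan(), name = "synthetic") {
  stopifnot(inherits(plan, "corruption_plan"))
  set.seed(plan$seed)
  combos <- expand.grid(ci = seq_len(nrow(compounds)),
                        ai = seq_along(adducts),
                        rep = seq_len(replicates))
  n <- nrow(combos)
  # exact-count corruption assignment (blank takes precedence)
  n_blank <- round(plan$fraction_blank_adduct * n)
  n_perm <- round(plan$fraction_permuted_adduct * n)
  n_mal <- round(plan$fraction_malformed_adduct * n)
  n_smi <- round(plan$fraction_noncanonical_smiles * n)
  shuffled <- sample(n)
  blank_idx <- shuffled[seq_len(n_blank)]
  perm_idx <- shuffled[n_blank + seq_len(n_perm)]
  mal_idx <- shuffled[n_blank + n_perm + seq_len(n_mal)]
  smi_idx <- sample(n, n_smi)
  spectra <- vector("list", n)
  truth <- vector("list", n)
  for (r in seq_len(n)) {
    cmp <- compounds[combos$ci[r], ]
    adduct <- adducts[combos$ai[r]]
    base <- base_pattern(cmp, adduct, peaks_per_spectrum)
    mz <- base[, "mz"] + stats::rnorm(nrow(base), 0, plan$mz_jitter_sd)
    it <- base[, "intensity"] *
      exp(stats::rnorm(nrow(base), 0, plan$intensity_jitter_sd))
    pre <- theoretical_precursor_mz(adduct, cmp$exact_mass) +
      stats::rnorm(1, 0, plan$mz_jitter_sd)
    charge <- parse_adduct(adduct)$charge
    blanked <- r %in% blank_idx
    permuted <- r %in% perm_idx
    malformed <- r %in% mal_idx
    annotated <- if (blanked) {
      ""
    } else if (permuted) {
      perms <- setdiff(enumerate_permutations(adduct), adduct)
      if (length(perms)) perms[1 + floor(stats::runif(1) * length(perms))]
      else adduct
    } else if (malformed) {
      crs <- corrupt_adduct_string(adduct)
      crs[1 + floor(stats::runif(1) * length(crs))]
    } else {
      adduct
    }
    noncanon <- r %in% smi_idx
    sid <- sprintf("%s:%04d", name, r)
    spectra[[r]] <- spectrum_record(mz, it, list(
      name = cmp$name,
      spectrum_id = sid,
      inchikey = cmp$inchikey,
      smiles = if (noncanon) cmp$smiles_variant else cmp$smiles,
      formula = cmp$formula,
      exact_mass = format(cmp$exact_mass, digits = 10),
      adduct = annotated,
      precursor_mz = sprintf("%.6f", pre),
      ionmode = if (charge > 0) "positive" else "negative",
      source_library = name
    ))
    truth[[r]] <- data.frame(
      spectrum_id = sid, inchikey = cmp$inchikey, true_adduct = adduct,
      blanked = blanked, permuted = permuted, malformed = malformed,
      noncanonical_smiles = noncanon, stringsAsFactors = FALSE)
  }
  list(library = spectral_library(spectra, name = name),
       truth = do.call(rbind, truth))
}

#' Generate the full benchmark suite
#'
#' Emulates, at fixture scale, the topology of the public-library
#' benchmark: four overlapping subject libraries sharing a planted
#' InChIKey intersection (with heterogeneous adduct formatting — one
#' library annotates a third of its spectra with permuted adduct forms),
#' plus an HMDB-like library in which half of the adduct annotations are
#' blanked (its ground truth retains them).
#'
#' @param seed integer seed.
#' @param n_compounds total compound pool (>= 30); the first 25 are shared
#'   by all libraries.
#' @return list with `libraries` (named list of four subject libraries),
#'   `hmdb` (the annotation-deficient library), `truth` (combined truth
#'   table), `compounds`, and `shared_inchikeys`.
#' @export
make_benchmark_suite <- function(seed = 1L, n_compounds = 37L) {
  stopifnot(n_compounds >= 30)
  compounds <- make_compounds(n_compounds, seed)
  shared <- compounds[1:25, ]
  extras <- split(26:n_compounds,
                  rep(1:4, length.out = max(0, n_compounds - 25)))
  lib_specs <- list(
    GNPS = list(adducts = c("[M+H]+", "[M+H+ACN]+", "[M-H-H2O]-"),
                plan = corruption_plan(fraction_blank_adduct = 0,
                                       fraction_permuted_adduct = 1 / 3,
                                       seed = seed + 1L)),
    MassBank = list(adducts = c("[M+H]+", "[M+Na]+", "[M-H]-"),
                    plan = corruption_plan(fraction_blank_adduct = 0,
                                           seed = seed + 2L)),
    MoNA = list(adducts = c("[M+H]+", "[M+NH4]+", "[M-H]-"),
                plan = corruption_plan(fraction_blank_adduct = 0,
                                       seed = seed + 3L)),
    MSDIAL = list(adducts = c("[M+H]+", "[M+Na]+", "[M+HCOO]-"),
                  plan = corruption_plan(fraction_blank_adduct = 0,
                                         seed = seed + 4L))
  )
  libraries <- list()
  truths <- list()
  for (i in seq_along(lib_specs)) {
    nm <- names(lib_specs)[i]
    pool <- rbind(shared,
                  compounds[extras[[min(i, length(extras))]], , drop = FALSE])
    gen <- make_library(pool, adducts = lib_specs[[i]]$adducts,
                        replicates = 2L, plan = lib_specs[[i]]$plan,
                        name = nm)
    libraries[[nm]] <- gen$library
    truths[[nm]] <- gen$truth
  }
  hm <- make_library(shared, adducts = c("[M+H]+", "[M-H]-"),
                     replicates = 2L,
                     plan = corruption_plan(fraction_blank_adduct = 0.5,
                                            seed = seed + 5L),
                     name = "HMDB")
  truths$HMDB <- hm$truth
  list(libraries = libraries, hmdb = hm$library,
       truth = do.call(rbind, c(truths, make.row.names = FALSE)),
       compounds = compounds,
       shared_inchikeys = shared$inchikey)
}

#' Write HMDB-style XML/CSV fixtures for a set of compounds
#'
#' Emits one spectrum XML per compound-adduct pair plus the compound
#' metadata CSV, in the schema read by [read_hmdb_xml()] and
#' [read_compound_csv()]. Used to exercise the library-construction
#' workflow without downloads.
#'
#' @param compounds a [make_compounds()] data.frame.
#' @param dir output directory (created if needed).
#' @param adducts adduct labels realized as spectra (the XML itself carries
#'   only ion mode, not the adduct — the deficiency under study).
#' @param drop_compound_rows indices of compounds omitted from the CSV (to
#'   exercise the join-drop report).
#' @param seed integer seed for jitter.
#' @return list with `xml_dir` and `csv` paths.
#' @export
write_hmdb_fixtures <- function(compounds, dir,
                                adducts = c("[M+H]+", "[M-H]-"),
                                drop_compound_rows = integer(),
                                seed = 1L) {
  dir.create(file.path(dir, "xml"), recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  k <- 0L
  for (i in seq_len(nrow(compounds))) {
    for (ad in adducts) {
      k <- k + 1L
      cmp <- compounds[i, ]
      base <- base_pattern(cmp, ad, 12L)
      mode <- if (parse_adduct(ad)$charge > 0) "Positive" else "Negative"
      peaks <- paste(sprintf(
        "    <ms-ms-peak>\n      <mass-charge>%.6f</mass-charge>\n      <intensity>%.4f</intensity>\n    </ms-ms-peak>",
        base[, "mz"], base[, "intensity"]), collapse = "\n")
      xml <- sprintf(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n<ms-ms>\n  <database-id>%s</database-id>\n  <ionization-mode>%s</ionization-mode>\n  <collision-energy>%d</collision-energy>\n  <ms-ms-peaks>\n%s\n  </ms-ms-peaks>\n</ms-ms>\n",
        cmp$hmdb_id, mode, sample(c(10L, 20L, 40L), 1), peaks)
      writeLines(xml, file.path(dir, "xml", sprintf("spectrum_%04d.xml", k)))
    }
  }
  csv_rows <- compounds[setdiff(seq_len(nrow(compounds)), drop_compound_rows),
                        c("hmdb_id", "name", "formula", "inchikey", "smiles",
                          "exact_mass")]
  csv <- file.path(dir, "compounds.csv")
  utils::write.csv(csv_rows, csv, row.names = FALSE)
  list(xml_dir = file.path(dir, "xml"), csv = csv)
}
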