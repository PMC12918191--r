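#' Greedy cosine similarity between two spectra
#'
#' Pairs peaks whose m/z values agree within `tolerance`, greedily in order
#' of descending intensity product with each peak used at most once, then
#' scores `(sum qi*sj)^2 / (sum qi^2 * sum sj^2)` on max-normalized
#' intensities (the square of the matchms-style greedy cosine). Identical
#' spectra score 1; spectra with no pairable peaks score 0. The default
#' tolerance follows the matchms CosineGreedy convention (0.1 Da).
#'
#' @param qs,ss spectra or two-column peak matrices (sorted ascending m/z).
#' @param tolerance pairing tolerance in Da.
#' @return similarity in \[0, 1\].
#' @export
cosine_greedy <- function(qs, ss, tolerance = 0.1) {
  qp <- as_peaks(qs)
  sp <- as_peaks(ss)
  cpp_cosine_greedy(qp[, "mz"], qp[, "intensity"],
                    sp[, "mz"], sp[, "intensity"], tolerance)
}

#' Spectral-entropy similarity between two spectra
#'
#' Peaks within `tolerance` are consolidated within each spectrum, the
#' intensities normalized to sum 1, and the similarity computed as
#' `1 - (2*S_mix - S_q - S_s) / ln 4`, where `S = -sum p log p` is the
#' Shannon entropy and `S_mix` the entropy of the half-weight merged
#' spectrum. Clipped to \[0, 1\]: identical spectra give 1, single disjoint
#' peaks give 0. Default tolerance follows the ms_entropy MS2 convention
#' (0.05 Da).
#'
#' @inheritParams cosine_greedy
#' @return similarity in \[0, 1\].
#' @export
entropy_similarity <- function(qs, ss, tolerance = 0.05) {
  qp <- as_peaks(qs)
  sp <- as_peaks(ss)
  cpp_entropy_similarity(qp[, "mz"], qp[, "intensity"],
                         sp[, "mz"], sp[, "intensity"], tolerance)
}

#' Bin a spectrum onto a fixed m/z grid
#'
#' Sums intensities per half-open bin `[k*w, (k+1)*w)` so that a value
#' exactly on a bin edge belongs to the upper bin. This is how spectra of
#' unequal peak counts become equal-length vectors for the generic
#' vector-space distances; paired spectra must be binned over their union
#' range (see [binned_pair()]).
#'
#' @param x spectrum or peak matrix.
#' @param bin_width bin width in Da (> 0); 0.01 Da is the package default.
#' @param range numeric length-2 vector (lo, hi) of the m/z range to cover;
#'   defaults to the spectrum's own range.
#' @return numeric vector of binned intensities (zero vector for an empty
#'   spectrum).
#' @export
bin_spectrum <- function(x, bin_width = 0.01, range = NULL) {
  stopifnot(bin_width > 0)
  p <- as_peaks(x)
  if (is.null(range)) {
    if (nrow(p) == 0) return(numeric(0))
    range <- c(min(p[, "mz"]), max(p[, "mz"]))
  }
  k0 <- floor(range[1] / bin_width)
  k1 <- floor(range[2] / bin_width)
  out <- numeric(k1 - k0 + 1)
  if (nrow(p)) {
    idx <- floor(p[, "mz"] / bin_width) - k0 + 1
    keep <- idx >= 1 & idx <= length(out)
    for (r in which(keep)) out[idx[r]] <- out[idx[r]] + p[r, "intensity"]
  }
  out
}

#' Bin two spectra over their shared m/z range
#'
#' @inheritParams bin_spectrum
#' @param qs,ss spectra or peak matrices.
#' @return list of two equal-length intensity vectors `q`, `s`.
#' @export
binned_pair <- function(qs, ss, bin_width = 0.01) {
  qp <- as_peaks(qs)
  sp <- as_peaks(ss)
  allmz <- c(qp[, "mz"], sp[, "mz"])
  if (length(allmz) == 0) return(list(q = numeric(0), s = numeric(0)))
  rng <- c(min(allmz), max(allmz))
  list(q = bin_spectrum(qp, bin_width, rng),
       s = bin_spectrum(sp, bin_width, rng))
}

#' Vector-space distances over binned spectra
#'
#' Textbook definitions of the ten generic distances used alongside the
#' spectral metrics: city-block, Euclidean, squared Euclidean, Chebyshev,
#' Minkowski (order 3 by default), Bray-Curtis, Canberra, cosine distance,
#' correlation distance, and Jensen-Shannon distance (square root of the
#' natural-log Jensen-Shannon divergence on sum-normalized vectors).
#' Identical vectors give 0 for every metric; an all-zero vector makes
#' cosine/correlation/Jensen-Shannon undefined and is reported as the
#' maximal distance with a warning.
#'
#' @param name one of `"cityblock"`, `"euclidean"`, `"sqeuclidean"`,
#'   `"chebyshev"`, `"minkowski"`, `"braycurtis"`, `"canberra"`,
#'   `"cosine"`, `"correlation"`, `"jensenshannon"`.
#' @param u,v equal-length non-negative numeric vectors.
#' @param p Minkowski order.
#' @return distance (>= 0).
#' @export
vector_distance <- function(name, u, v, p = 3) {
  if (length(u) != length(v)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  name <- match.arg(name, vector_metric_names())
  if (length(u) == 0) return(0)
  if (identical(u, v) && any(u != 0) &&
      name %in% c("cosine", "correlation", "jensenshannon")) {
    return(0)
  }
  d <- u - v
  switch(name,
    cityblock = sum(abs(d)),
    euclidean = sqrt(sum(d^2)),
    sqeuclidean = sum(d^2),
    chebyshev = max(abs(d)),
    minkowski = sum(abs(d)^p)^(1 / p),
    braycurtis = {
      den <- sum(abs(u + v))
      if (den == 0) 0 else sum(abs(d)) / den
    },
    canberra = {
      den <- abs(u) + abs(v)
      ok <- den > 0
      sum(abs(d[ok]) / den[ok])
    },
    cosine = {
      nu <- sqrt(sum(u^2))
      nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) {
        warning("all-zero vector: cosine distance undefined, reporting 1",
                call. = FALSE)
        return(1)
      }
      1 - sum(u * v) / (nu * nv)
    },
    correlation = {
      if (stats::sd(u) == 0 || stats::sd(v) == 0) {
        warning("constant vector: correlation distance undefined, reporting 1",
                call. = FALSE)
        return(1)
      }
      1 - stats::cor(u, v)
    },
    jensenshannon = {
      su <- sum(u)
      sv <- sum(v)
      if (su == 0 || sv == 0) {
        warning("all-zero vector: Jensen-Shannon undefined, reporting sqrt(ln 2)",
                call. = FALSE)
        return(sqrt(log(2)))
      }
      pu <- u / su
      pv <- v / sv
      mm <- (pu + pv) / 2
      kl <- function(a, b) {
        ok <- a > 0
        sum(a[ok] * log(a[ok] / b[ok]))
      }
      sqrt(pmax(0, (kl(pu, mm) + kl(pv, mm)) / 2))
    }
  )
}

vector_metric_names <- function() {
  c("cityblock", "braycurtis", "canberra", "euclidean", "sqeuclidean",
    "minkowski", "chebyshev", "correlation", "cosine", "jensenshannon")
}

#' The metric registry
#'
#' All comparison methods addressable by name: the three spectral metrics
#' (`osa`, `cosine_greedy`, `entropy`) that operate on peak lists and can
#' use intensities, and the ten generic vector distances computed on binned
#' spectra (0.01 Da bins by default). Similarity metrics select a best match
#' by maximum score, distance metrics by minimum.
#'
#' @return data.frame with columns `name`, `kind` (`"similarity"` or
#'   `"distance"`), `uses_intensity`.
#' @export
metric_registry <- function() {
  data.frame(
    name = c("osa", "cosine_greedy", "entropy", vector_metric_names()),
    kind = c("similarity", "similarity", "similarity",
             rep("distance", length(vector_metric_names()))),
    uses_intensity = c(TRUE, TRUE, TRUE,
                       rep(FALSE, length(vector_metric_names()))),
    stringsAsFactors = FALSE
  )
}

#' Specify a comparison metric
#'
#' @param name a metric name from [metric_registry()].
#' @param tolerance m/z tolerance in Da for the spectral metrics; `NULL`
#'   uses each metric's own default (0.005 for `osa`, 0.1 for
#'   `cosine_greedy`, 0.05 for `entropy`).
#' @param bin_width bin width in Da for the vector distances.
#' @param use_intensities whether OSA scores intensities (the spectral
#'   similarity metrics always use the intensities they are given).
#' @return list of class `metric_spec` with a resolved `kind`.
#' @export
metric_spec <- function(name, tolerance = NULL, bin_width = 0.01,
                        use_intensities = TRUE) {
  reg <- metric_registry()
  name <- match.arg(name, reg$name)
  structure(list(name = name, kind = reg$kind[reg$name == name],
                 tolerance = tolerance, bin_width = bin_width,
                 use_intensities = use_intensities),
            class = "metric_spec")
}

#' Score one spectrum pair under a named metric
#'
#' Dispatcher used by matching and benchmarking: similarity metrics return
#' larger-is-better scores, distance metrics smaller-is-better (see the
#' `kind` field of the spec).
#'
#' @param qs,ss spectra or peak matrices.
#' @param spec a [metric_spec()] (or metric name).
#' @return numeric score.
#' @export
metric_score <- function(qs, ss, spec) {
  if (is.character(spec)) spec <- metric_spec(spec)
  switch(spec$name,
    osa = {
      tol <- if (is.null(spec$tolerance)) 0.005 else spec$tolerance
      osa_score(qs, ss, osa_params(mz_tolerance = tol,
                                   use_intensities = spec$use_intensities)
                )$normalized_score
    },
    cosine_greedy = {
      tol <- if (is.null(spec$tolerance)) 0.1 else spec$tolerance
      cosine_greedy(qs, ss, tol)
    },
    entropy = {
      tol <- if (is.null(spec$tolerance)) 0.05 else spec$tolerance
      entropy_similarity(qs, ss, tol)
    },
    {
      b <- binned_pair(qs, ss, spec$bin_width)
      vector_distance(spec$name, b$q, b$s)
    }
  )
}
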