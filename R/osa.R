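#' Parameters for optimized spectral alignment (OSA)
#'
#' Defaults follow the method's published operating point: an m/z match
#' tolerance of 0.005 Da, a gap penalty of -0.1 (intentionally smaller in
#' magnitude than the fixed mismatch penalty of -1, reflecting the lower
#' cost of gap events), and optional intensity scoring.
#'
#' @param mz_tolerance match tolerance in Da (> 0).
#' @param gap_penalty gap score (< 0, smaller in magnitude than 1).
#' @param use_intensities logical; when `TRUE` an in-tolerance match scores
#'   `1 / (1 + (qi - sj)^2)` on max-normalized intensities, otherwise 1.
#' @return list of class `osa_params`.
#' @export
osa_params <- function(mz_tolerance = 0.005, gap_penalty = -0.1,
                       use_intensities = FALSE) {
  stopifnot(mz_tolerance > 0, gap_penalty < 0, abs(gap_penalty) < 1)
  structure(list(mz_tolerance = mz_tolerance, gap_penalty = gap_penalty,
                 mismatch_score = -1, use_intensities = use_intensities),
            class = "osa_params")
}

#' Intensity component of the OSA match score
#'
#' `1 / (1 + |qi - sj|^2)` on intensities normalized to \[0, 1\] by each
#' spectrum's maximum: the score is 1 exactly when the two intensities are
#' equal and decays smoothly with their absolute difference (the local
#' city-block distance).
#'
#' @param qi,sj normalized intensities in \[0, 1\].
#' @return score in (0, 1\].
#' @export
intensity_score <- function(qi, sj) 1 / (1 + abs(qi - sj)^2)

as_peaks <- function(x) {
  if (inherits(x, "ms_spectrum")) return(x$peaks)
  if (is.matrix(x) && ncol(x) >= 2) {
    m <- cbind(mz = as.numeric(x[, 1]), intensity = as.numeric(x[, 2]))
    return(m)
  }
  stop("expected an ms_spectrum or a two-column (mz, intensity) matrix",
       call. = FALSE)
}

check_sorted <- function(p, what) {
  if (nrow(p) > 1 && any(diff(p[, "mz"]) <= 0)) {
    stop(what, " peaks must be strictly ascending in m/z", call. = FALSE)
  }
}

norm_by_max <- function(v) if (length(v) && max(v) > 0) v / max(v) else v

#' Optimized spectral alignment score
#'
#' Dynamic-programming alignment of two sorted peak lists. A
#' `(m+1) x (n+1)` score matrix is initialized to zero and filled with the
#' recurrence `dp[i,j] = max(dp[i-1,j-1] + final_score, dp[i-1,j] + gap,
#' dp[i,j-1] + gap)` where `final_score` is the [intensity_score()] when
#' `|qs_mz_i - ss_mz_j| <= mz_tolerance` and -1 otherwise (identically 1
#' when intensities are not used). When several tracebacks achieve the
#' optimal score, the one minimizing the summed `|qs_mz - ss_mz|` over its
#' aligned pairs (the global city-block distance, accumulated without
#' tolerance gating) is chosen; residual ties resolve diagonal, then up,
#' then left.
#'
#' @param qs,ss query and subject: `ms_spectrum` objects or two-column
#'   `(mz, intensity)` matrices sorted strictly ascending in m/z.
#' @param params an [osa_params()] object.
#' @return object of class `osa_alignment`: `raw_score` (the DP optimum,
#'   at most `min(m, n)`), `normalized_score` (`raw_score / max(m, n)`
#'   clipped to \[0, 1\]; 0 for empty input), `pairs` (k x 2 matrix of
#'   1-based aligned query/subject indices, strictly increasing in both),
#'   and `global_cityblock` (Da).
#' @examples
#' a <- cbind(c(100, 200), c(1, 1))
#' osa_score(a, a)$raw_score  # 2
#' @export
osa_score <- function(qs, ss, params = osa_params()) {
  qp <- as_peaks(qs)
  sp <- as_peaks(ss)
  check_sorted(qp, "query")
  check_sorted(sp, "subject")
  qint <- norm_by_max(qp[, "intensity"])
  sint <- norm_by_max(sp[, "intensity"])
  res <- cpp_osa(qp[, "mz"], qint, sp[, "mz"], sint,
                 params$mz_tolerance, params$gap_penalty,
                 params$use_intensities)
  m <- nrow(qp)
  n <- nrow(sp)
  norm <- if (max(m, n) > 0) res$raw_score / max(m, n) else 0
  structure(list(raw_score = res$raw_score,
                 normalized_score = min(1, max(0, norm)),
                 pairs = res$pairs,
                 global_cityblock = res$global_cityblock,
                 params = params),
            class = "osa_alignment")
}

#' @export
print.osa_alignment <- function(x, ...) {
  cat(sprintf(
    "<osa_alignment> raw %.4f | normalized %.4f | %d pairs | cityblock %.4g\n",
    x$raw_score, x$normalized_score, nrow(x$pairs), x$global_cityblock))
  invisible(x)
}

#' Exhaustive-alignment oracle for the OSA score
#'
#' Independent reference used in testing: enumerates every monotone matching
#' (each subset of index pairs strictly increasing in both coordinates) and
#' scores it directly — matched pairs get their threshold/intensity score;
#' unmatched peaks are charged one gap each except that, matching the
#' zero-initialized DP boundary, the leading unmatched run on one side
#' (whichever is larger) is free. Limited to peak lists of length <= 8.
#'
#' @inheritParams osa_score
#' @return the maximal total score over all matchings.
#' @export
osa_brute_force <- function(qs, ss, params = osa_params()) {
  qp <- as_peaks(qs)
  sp <- as_peaks(ss)
  m <- nrow(qp)
  n <- nrow(sp)
  if (m > 8 || n > 8) stop("brute-force oracle limited to <= 8 peaks",
                           call. = FALSE)
  if (m == 0 || n == 0) return(0)
  qint <- norm_by_max(qp[, "intensity"])
  sint <- norm_by_max(sp[, "intensity"])
  pair_score <- function(i, j) {
    if (abs(qp[i, "mz"] - sp[j, "mz"]) <= params$mz_tolerance) {
      if (params$use_intensities) intensity_score(qint[i], sint[j]) else 1
    } else {
      -1
    }
  }
  gp <- params$gap_penalty
  score_matching <- function(pairs) {
    k <- nrow(pairs)
    if (k == 0) return(gp * min(m, n))
    ps <- sum(vapply(seq_len(k),
                     function(r) pair_score(pairs[r, 1], pairs[r, 2]),
                     numeric(1)))
    lead_q <- pairs[1, 1] - 1
    lead_s <- pairs[1, 2] - 1
    unmatched <- (m - k) + (n - k)
    ps + gp * (unmatched - max(lead_q, lead_s))
  }
  best <- -Inf
  recurse <- function(i0, j0, acc) {
    sc <- score_matching(acc)
    if (sc > best) best <<- sc
    if (i0 > m || j0 > n) return(invisible())
    for (i in i0:m) {
      for (j in j0:n) {
        recurse(i + 1L, j + 1L, rbind(acc, c(i, j)))
      }
    }
    invisible()
  }
  recurse(1L, 1L, matrix(integer(), 0, 2))
  best
}
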