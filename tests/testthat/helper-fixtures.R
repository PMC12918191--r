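# shared fixtures and independent oracles for the test suite

pk <- function(mz, intensity = rep(1, length(mz))) {
  cbind(mz = mz, intensity = intensity)
}

# one trained corrector shared across test files (training is the slow step)
.corrector_cache <- new.env(parent = emptyenv())

default_corrector <- function() {
  if (is.null(.corrector_cache$model)) {
    .corrector_cache$corpus <- build_corpus()
    .corrector_cache$model <-
      train_adduct_corrector(.corrector_cache$corpus, seed = 7)
  }
  .corrector_cache$model
}

default_corpus <- function() {
  default_corrector()
  .corrector_cache$corpus
}

# Independent enumeration oracle over monotone matchings: returns the
# optimal total score and, among score-optimal matchings, the minimal
# summed |dmz| over matched pairs. Encodes the zero-initialized boundary
# (the larger leading unmatched run is free) by direct scoring, no DP.
enumerate_alignments <- function(q, s, params = osa_params()) {
  m <- nrow(q)
  n <- nrow(s)
  qi <- if (m && max(q[, 2]) > 0) q[, 2] / max(q[, 2]) else q[, 2]
  si <- if (n && max(s[, 2]) > 0) s[, 2] / max(s[, 2]) else s[, 2]
  pair_score <- function(i, j) {
    if (abs(q[i, 1] - s[j, 1]) <= params$mz_tolerance) {
      if (params$use_intensities) 1 / (1 + (qi[i] - si[j])^2) else 1
    } else {
      -1
    }
  }
  best <- -Inf
  best_cb <- Inf
  consider <- function(pairs) {
    k <- nrow(pairs)
    if (k == 0) {
      sc <- params$gap_penalty * min(m, n)
      cb <- 0
    } else {
      sc <- sum(vapply(seq_len(k),
                       function(r) pair_score(pairs[r, 1], pairs[r, 2]),
                       numeric(1)))
      lead <- max(pairs[1, 1] - 1, pairs[1, 2] - 1)
      sc <- sc + params$gap_penalty * ((m - k) + (n - k) - lead)
      cb <- sum(abs(q[pairs[, 1], 1] - s[pairs[, 2], 1]))
    }
    if (sc > best + 1e-12) {
      best <<- sc
      best_cb <<- cb
    } else if (abs(sc - best) <= 1e-12 && cb < best_cb) {
      best_cb <<- cb
    }
  }
  recurse <- function(i0, j0, acc) {
    consider(acc)
    if (i0 > m || j0 > n) return(invisible())
    for (i in i0:m) {
      for (j in j0:n) {
        recurse(i + 1L, j + 1L, rbind(acc, c(i, j)))
      }
    }
    invisible()
  }
  recurse(1L, 1L, matrix(integer(), 0, 2))
  list(score = best, min_cityblock = best_cb)
}

# seeded random peak-list pair with planted near-matches
random_peak_pair <- function(max_len = 6) {
  m <- sample(0:max_len, 1)
  n <- sample(0:max_len, 1)
  qmz <- sort(runif(m, 100, 110))
  smz <- sort(runif(n, 100, 110))
  if (m > 0 && n > 0 && runif(1) < 0.7) {
    k <- sample(min(m, n), 1)
    smz[1:k] <- qmz[sample(m, k)] + rnorm(k, 0, 0.004)
    smz <- sort(smz)
  }
  list(q = pk(qmz, runif(max(m, 1))[seq_len(m)]),
       s = pk(smz, runif(max(n, 1))[seq_len(n)]))
}

# tiny two-spectrum library for matching tests
tiny_spectrum <- function(id, inchikey, ionmode = "positive",
                          adduct = "[M+H]+", mz = c(100, 150, 200),
                          intensity = c(10, 50, 100), ...) {
  spectrum_record(mz, intensity,
                  c(list(spectrum_id = id, inchikey = inchikey,
                         ionmode = ionmode, adduct = adduct), list(...)))
}
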