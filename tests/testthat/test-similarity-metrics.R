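test_that("greedy cosine satisfies its contract", {
  a <- pk(c(100, 200), c(1, 0.5))
  expect_equal(cosine_greedy(a, a), 1)
  expect_equal(cosine_greedy(pk(100), pk(200)), 0)
  # one pairable peak: (1*1)^2 / ((1^2 + 0.5^2) * 1^2)
  expect_equal(cosine_greedy(a, pk(100, 1)), 0.8)
  # symmetric
  b <- pk(c(100.05, 200), c(0.7, 1))
  expect_equal(cosine_greedy(a, b), cosine_greedy(b, a))
  # greedy pairing is one-to-one: two query peaks cannot share a subject peak
  q <- pk(c(100.00, 100.05), c(1, 1))
  s <- pk(100.02, 1)
  expect_equal(cosine_greedy(q, s, tolerance = 0.1), (1 * 1)^2 / (2 * 1))
})

test_that("entropy similarity matches its direct-evaluation oracle", {
  a <- pk(c(100, 200), c(3, 1))
  expect_equal(entropy_similarity(a, a), 1)
  expect_equal(entropy_similarity(pk(100), pk(200)), 0)
  # 1 peak vs 2 peaks: S_q = 0, S_s = ln 2, mixture (0.75, 0.25)
  smix <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expected <- 1 - (2 * smix - 0 - log(2)) / log(4)
  expect_equal(entropy_similarity(pk(100), pk(c(100, 200), c(1, 1))),
               expected, tolerance = 1e-9)
  expect_equal(round(expected, 5), 0.68872)
  # symmetry on random spectra
  set.seed(9)
  for (t in 1:20) {
    pair <- random_peak_pair()
    if (nrow(pair$q) == 0 || nrow(pair$s) == 0) next
    expect_equal(entropy_similarity(pair$q, pair$s),
                 entropy_similarity(pair$s, pair$q), tolerance = 1e-12)
  }
})

test_that("entropy and cosine match independent R oracles on random input", {
  # oracles written directly from the definitions, independent of the C++
  entropy_oracle <- function(q, s, tol = 0.05) {
    merge_tol <- function(p) {
      out <- matrix(numeric(0), 0, 2)
      i <- 1
      while (i <= nrow(p)) {
        j <- i
        while (j < nrow(p) && p[j + 1, 1] - p[j, 1] <= tol) j <- j + 1
        w <- p[i:j, 2]
        out <- rbind(out, c(sum(p[i:j, 1] * w) / sum(w), sum(w)))
        i <- j + 1
      }
      out
    }
    q <- merge_tol(q)
    s <- merge_tol(s)
    qn <- q[, 2] / sum(q[, 2])
    sn <- s[, 2] / sum(s[, 2])
    H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
    u <- rbind(cbind(q[, 1], qn / 2), cbind(s[, 1], sn / 2))
    u <- u[order(u[, 1]), , drop = FALSE]
    mix <- merge_tol(u)
    max(0, min(1, 1 - (2 * H(mix[, 2]) - H(qn) - H(sn)) / log(4)))
  }
  cosine_oracle <- function(q, s, tol = 0.1) {
    qi <- q[, 2] / max(q[, 2])
    si <- s[, 2] / max(s[, 2])
    cand <- expand.grid(i = seq_len(nrow(q)), j = seq_len(nrow(s)))
    cand <- cand[abs(q[cand$i, 1] - s[cand$j, 1]) <= tol, , drop = FALSE]
    cand <- cand[order(-(qi[cand$i] * si[cand$j])), , drop = FALSE]
    qu <- logical(nrow(q))
    su <- logical(nrow(s))
    dot <- 0
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]
      j <- cand$j[r]
      if (!qu[i] && !su[j]) {
        qu[i] <- su[j] <- TRUE
        dot <- dot + qi[i] * si[j]
      }
    }
    as.numeric(dot^2 / (sum(qi^2) * sum(si^2)))
  }
  set.seed(31)
  for (t in 1:100) {
    pair <- random_peak_pair()
    if (nrow(pair$q) == 0 || nrow(pair$s) == 0) next
    expect_equal(entropy_similarity(pair$q, pair$s),
                 entropy_oracle(pair$q, pair$s), tolerance = 1e-9)
    expect_equal(cosine_greedy(pair$q, pair$s),
                 cosine_oracle(pair$q, pair$s), tolerance = 1e-9)
  }
})

test_that("binning uses half-open bins over the union range", {
  expect_equal(bin_spectrum(pk(c(100.001, 100.004), c(1, 2)), 0.01),
               3)
  expect_equal(bin_spectrum(pk(numeric(0)), 0.01, range = c(100, 100.05)),
               rep(0, 6))
  # a value exactly on a bin edge belongs to the upper bin (width 0.25 is
  # exactly representable, so the edge test is float-safe)
  v <- bin_spectrum(pk(c(100.00, 100.25), c(1, 5)), 0.25)
  expect_equal(v, c(1, 5))
  b <- binned_pair(pk(100), pk(100.10))
  expect_length(b$q, length(b$s))
  expect_equal(sum(b$q), 1)
  expect_equal(sum(b$s), 1)
})

test_that("vector distances match independent oracles to 1e-9", {
  set.seed(17)
  for (t in 1:100) {
    n <- sample(3:12, 1)
    u <- runif(n)
    v <- runif(n)
    d <- function(nm) vector_distance(nm, u, v)
    D <- function(method, p = 2) {
      as.numeric(stats::dist(rbind(u, v), method = method, p = p))
    }
    expect_equal(d("cityblock"), D("manhattan"), tolerance = 1e-9)
    expect_equal(d("euclidean"), D("euclidean"), tolerance = 1e-9)
    expect_equal(d("sqeuclidean"), D("euclidean")^2, tolerance = 1e-9)
    expect_equal(d("chebyshev"), D("maximum"), tolerance = 1e-9)
    expect_equal(d("minkowski"), D("minkowski", p = 3), tolerance = 1e-9)
    expect_equal(d("canberra"), D("canberra"), tolerance = 1e-9)
    expect_equal(d("braycurtis"),
                 as.numeric(vegan::vegdist(rbind(u, v), method = "bray")),
                 tolerance = 1e-9)
    # cosine via vector norms; correlation as cosine of centered vectors
    expect_equal(d("cosine"),
                 1 - crossprod(u, v)[1] / (norm(u, "2") * norm(v, "2")),
                 tolerance = 1e-9)
    uc <- u - mean(u)
    vc <- v - mean(v)
    expect_equal(d("correlation"),
                 1 - crossprod(uc, vc)[1] / (norm(uc, "2") * norm(vc, "2")),
                 tolerance = 1e-9)
    # Jensen-Shannon via the entropy (not KL) formulation
    pu <- u / sum(u)
    pv <- v / sum(v)
    H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
    js <- sqrt(H((pu + pv) / 2) - (H(pu) + H(pv)) / 2)
    expect_equal(d("jensenshannon"), js, tolerance = 1e-9)
  }
})

test_that("vector distances handle ties, zeros and length mismatch", {
  expect_equal(vector_distance("cityblock", c(1, 2), c(1, 2)), 0)
  expect_equal(vector_distance("cityblock", c(1, 0), c(0, 1)), 2)
  expect_equal(round(vector_distance("jensenshannon", c(1, 0), c(0.5, 0.5)),
                     4), 0.4645)
  expect_error(vector_distance("cityblock", 1:3, 1:2), "equal length")
  expect_equal(vector_distance("cosine", c(1, 2), c(1, 2)), 0)
  expect_equal(vector_distance("correlation", c(1, 2), c(1, 2)), 0)
  expect_warning(z <- vector_distance("cosine", c(0, 0), c(1, 1)),
                 "undefined")
  expect_equal(z, 1)
  expect_warning(vector_distance("jensenshannon", c(0, 0), c(1, 1)),
                 "undefined")
})

test_that("every registry metric is extremal on self-comparison", {
  reg <- metric_registry()
  sp <- pk(c(100, 150.02, 280.5), c(10, 99, 45))
  for (i in seq_len(nrow(reg))) {
    spec <- metric_spec(reg$name[i])
    sc <- metric_score(sp, sp, spec)
    if (reg$kind[i] == "similarity") {
      expect_equal(sc, 1, tolerance = 1e-12, label = reg$name[i])
    } else {
      expect_equal(sc, 0, tolerance = 1e-12, label = reg$name[i])
    }
  }
})
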