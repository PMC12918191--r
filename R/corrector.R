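#' Normalize the text of an adduct annotation
#'
#' Deterministic, idempotent best-effort cleanup applied before both the
#' grammar and the learned corrector: strips whitespace, converts unicode
#' minus/dash variants to `-`, collapses repeated brackets, moves a charge
#' sign written inside the bracket to the outside, restores the enclosing
#' brackets, normalizes a lower-case molecule symbol `m`, and rewrites
#' numeric charge suffixes (`+1` -> `+`, `]1-` -> `]-`). No charge is ever
#' guessed: `"M+H"` becomes `"[M+H]"` (still missing its charge), not
#' `"[M+H]+"`. Unparsable text passes through stripped.
#'
#' @param s character vector of raw adduct annotations.
#' @return normalized strings, same length.
#' @examples
#' preprocess_adduct_text("[M + H2O + H] +")  # "[M+H2O+H]+"
#' @export
preprocess_adduct_text <- function(s) {
  vapply(as.character(s), preprocess_one, character(1), USE.NAMES = FALSE)
}

preprocess_one <- function(x) {
  if (is.na(x)) return("")
  x <- gsub("[−–—]", "-", x)  # unicode minus / dashes
  x <- gsub("\\s+", "", x)
  if (!nzchar(x)) return(x)
  x <- gsub("\\[+", "[", x)
  x <- gsub("\\]+", "]", x)
  # lower-case molecule symbol: "m" directly before +/-/] or after [ or digit
  x <- gsub("^m", "M", x)
  x <- gsub("\\[m", "[M", x)
  x <- gsub("(^|\\[)([0-9]*)m", "\\1\\2M", x)
  # charge written inside the bracket: "[M+H+]" -> "[M+H]+"
  m <- regmatches(x, regexec("^(.*?)([0-9]*[+-]+[0-9]*)\\]$", x))[[1]]
  if (length(m) && nzchar(m[3])) {
    # keep a trailing ion intact: only move a pure charge tail
    x <- paste0(m[2], "]", m[3])
  }
  # numeric charge suffix "1+"/"+1" with n = 1 collapses to the bare sign
  x <- sub("\\]1([+-])$", "]\\1", x)
  x <- sub("\\]([+-])1$", "]\\1", x)
  # restore enclosing brackets around the molecule expression
  if (!grepl("\\[", x) && grepl("^[0-9]*M", x)) {
    chg <- regmatches(x, regexec("([0-9]*[+-]+[0-9]*)$", x))[[1]]
    body <- x
    tail <- ""
    if (length(chg) && nzchar(chg[2])) {
      cand <- substr(x, 1, nchar(x) - nchar(chg[2]))
      # the trailing sign run is a charge only if the body ends in a token
      if (grepl("[A-Za-z0-9]$", cand)) {
        body <- cand
        tail <- chg[2]
      }
    }
    x <- paste0("[", body, "]", tail)
  }
  x
}

#' Build a labeled corpus of adduct-string variants
#'
#' For every canonical label in the dictionary the corpus contains the label
#' itself, all positional permutations of its ions
#' ([enumerate_permutations()]), and a documented set of systematic
#' corruptions of each (spaces around delimiters and the charge, dropped and
#' doubled brackets, charge inside the bracket, unicode minus, lower-case
#' molecule symbol, numeric charge suffix, padding whitespace). Observed
#' strings are mapped to their canonical label through the grammar; strings
#' that map to no dictionary label are routed to the `"UNKNOWN"` bucket.
#'
#' @param dictionary data.frame with a `canonical` column
#'   ([adduct_dictionary()] by default).
#' @param observed optional character vector of annotations seen in
#'   libraries.
#' @return data.frame of class `adduct_corpus` with columns `raw`, `label`,
#'   `provenance` (`dictionary`, `permutation` or `observed`).
#' @export
build_corpus <- function(dictionary = adduct_dictionary(),
                         observed = character()) {
  labels <- dictionary$canonical
  rows <- list()
  add <- function(raw, label, prov) {
    rows[[length(rows) + 1L]] <<- data.frame(
      raw = raw, label = label, provenance = prov, stringsAsFactors = FALSE)
  }
  for (lab in labels) {
    perms <- enumerate_permutations(lab)
    add(lab, lab, "dictionary")
    for (p in setdiff(perms, lab)) add(p, lab, "permutation")
    for (p in perms) {
      for (cr in corrupt_adduct_string(p)) add(cr, lab, "permutation")
    }
  }
  for (ob in observed) {
    lab <- safe_canonical_adduct(ob)
    if (!lab %in% c(labels, "UNKNOWN")) lab <- "UNKNOWN"
    add(ob, lab, "observed")
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("raw", "label", "provenance")]), ]
  rownames(out) <- NULL
  class(out) <- c("adduct_corpus", "data.frame")
  out
}

# The documented corruption set: every transform is a formatting error
# actually seen across open libraries. Applied to a well-formed string.
corrupt_adduct_string <- function(s) {
  chg <- sub("^.*\\]", "", s)
  body <- sub("\\]..*$|\\]$", "]", s)  # up to and including "]"
  out <- c(
    gsub("([+-])", " \\1 ", s),                    # spaces around delimiters
    gsub("\\[|\\]", "", s),                        # dropped brackets
    gsub("\\[", "[[", gsub("\\]", "]]", s)),       # doubled brackets
    sub("\\]([0-9]*[+-]+)$", "\\1]", s),           # charge inside bracket
    gsub("-", "−", s),                        # unicode minus
    sub("M", "m", s),                              # lower-case molecule
    paste0("  ", s, "  "),                         # padding whitespace
    sub("\\]", "] ", s),                           # space before charge
    numeric_charge_variant(s),                     # "+" -> "+1", "2+" -> "+2"
    gsub("\\[", "[ ", gsub("\\]", " ]", s))        # padded brackets
  )
  unique(out[nzchar(out) & out != s])
}

numeric_charge_variant <- function(s) {
  if (grepl("\\]\\+$", s)) return(sub("\\]\\+$", "]+1", s))
  if (grepl("\\]-$", s)) return(sub("\\]-$", "]-1", s))
  m <- regmatches(s, regexec("\\]([0-9]+)([+-])$", s))[[1]]
  if (length(m)) return(sub("\\][0-9]+[+-]$",
                            paste0("]", m[3], m[2]), s))
  s
}

# ---- character n-gram TF-IDF -------------------------------------------

char_ngrams <- function(s, nmin = 1L, nmax = 3L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- character(0)
  for (k in nmin:nmax) {
    if (n >= k) {
      idx <- seq_len(n - k + 1L)
      out <- c(out, vapply(idx, function(i) {
        paste(ch[i:(i + k - 1L)], collapse = "")
      }, character(1)))
    }
  }
  out
}

tfidf_fit <- function(docs, nmin = 1L, nmax = 3L) {
  grams <- lapply(docs, char_ngrams, nmin = nmin, nmax = nmax)
  vocab <- sort(unique(unlist(grams)), method = "radix")
  X <- matrix(0, length(docs), length(vocab))
  for (i in seq_along(grams)) {
    tab <- table(grams[[i]])
    X[i, match(names(tab), vocab)] <- as.numeric(tab)
  }
  df <- colSums(X > 0)
  idf <- log((1 + nrow(X)) / (1 + df)) + 1  # smooth idf
  list(vocab = vocab, idf = idf, nmin = nmin, nmax = nmax,
       X = tfidf_weight(X, idf))
}

tfidf_weight <- function(X, idf) {
  X <- sweep(X, 2, idf, "*")
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

tfidf_transform <- function(vec, docs) {
  X <- matrix(0, length(docs), length(vec$vocab))
  for (i in seq_along(docs)) {
    tab <- table(char_ngrams(docs[i], vec$nmin, vec$nmax))
    hit <- match(names(tab), vec$vocab)
    ok <- !is.na(hit)
    X[i, hit[ok]] <- as.numeric(tab)[ok]
  }
  tfidf_weight(X, vec$idf)
}

# ---- single-hidden-layer softmax network -------------------------------
# Full-batch Adam on cross-entropy; ReLU hidden layer. Deterministic under
# the supplied seed. The iteration cap plays the role of the usual MLP
# max-iterations parameter.

mlp_fit <- function(X, y, hidden = 200L, maxit = 500L, lr = 5e-3,
                    seed = 1L) {
  set.seed(seed)
  n <- nrow(X)
  d <- ncol(X)
  K <- nlevels(y)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  W1 <- matrix(stats::rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * K, 0, sqrt(2 / hidden)), hidden, K)
  b2 <- numeric(K)
  mom <- list(W1 = W1 * 0, b1 = b1, W2 = W2 * 0, b2 = b2)
  vel <- mom
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  for (t in seq_len(maxit)) {
    H <- pmax(X %*% W1 + rep(b1, each = n), 0)
    Z <- H %*% W2 + rep(b2, each = n)
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z)
    P <- P / rowSums(P)
    dZ <- (P - Y) / n
    grad <- list(W1 = NULL, b1 = NULL, W2 = crossprod(H, dZ),
                 b2 = colSums(dZ))
    dH <- dZ %*% t(W2)
    dH[H <= 0] <- 0
    grad$W1 <- crossprod(X, dH)
    grad$b1 <- colSums(dH)
    for (nm in names(grad)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grad[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grad[[nm]]^2
      upd <- lr * (mom[[nm]] / (1 - beta1^t)) /
        (sqrt(vel[[nm]] / (1 - beta2^t)) + eps)
      if (nm == "W1") W1 <- W1 - upd
      else if (nm == "b1") b1 <- b1 - upd
      else if (nm == "W2") W2 <- W2 - upd
      else b2 <- b2 - upd
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, levels = levels(y))
}

mlp_prob <- function(fit, X) {
  n <- nrow(X)
  H <- pmax(X %*% fit$W1 + rep(fit$b1, each = n), 0)
  Z <- H %*% fit$W2 + rep(fit$b2, each = n)
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P / rowSums(P)
}

# ---- training and prediction -------------------------------------------

#' Train the adduct-string corrector
#'
#' Fits the learned half of the correction pipeline: preprocessed strings
#' are vectorized with character-level 1-3-gram TF-IDF and classified by a
#' single-hidden-layer network (200 hidden units, at most 500 training
#' iterations, deterministic under `seed`). Labels with fewer than two
#' examples are excluded from the stratified hold-out split with a warning.
#'
#' @param corpus a [build_corpus()] data.frame (columns `raw`, `label`).
#' @param seed integer RNG seed controlling the split and the weights.
#' @param split hold-out fraction for evaluation (stratified by label).
#' @param hidden,maxit network width and iteration cap.
#' @return object of class `adduct_corrector` with the vectorizer state, the
#'   network weights, the label set and an evaluation `report` (overall
#'   hold-out accuracy plus per-label precision/recall).
#' @seealso [correct_adduct()], [predict.adduct_corrector()]
#' @export
train_adduct_corrector <- function(corpus, seed = 7L, split = 0.2,
                                   hidden = 200L, maxit = 500L) {
  stopifnot(is.data.frame(corpus), all(c("raw", "label") %in% names(corpus)))
  docs <- preprocess_adduct_text(corpus$raw)
  y <- factor(corpus$label)
  singletons <- names(which(table(y) < 2))
  if (length(singletons)) {
    warning("label(s) with a single example excluded from the split: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (lab in levels(y)) {
    idx <- which(y == lab)
    if (length(idx) < 2) next
    k <- max(1L, round(split * length(idx)))
    test_idx <- c(test_idx, sample(idx, k))
  }
  train_idx <- setdiff(seq_along(docs), test_idx)
  vec <- tfidf_fit(docs[train_idx])
  ytr <- droplevels(y[train_idx])
  fit <- mlp_fit(vec$X, ytr, hidden = hidden, maxit = maxit, seed = seed)

  model <- structure(
    list(vectorizer = vec[c("vocab", "idf", "nmin", "nmax")],
         net = fit, labels = fit$levels, seed = seed),
    class = "adduct_corrector")

  Xte <- tfidf_transform(model$vectorizer, docs[test_idx])
  pred <- predict(model, corpus$raw[test_idx], preprocessed = Xte)
  truth <- as.character(y[test_idx])
  acc <- mean(pred$label == truth)
  per_label <- do.call(rbind, lapply(sort(unique(truth)), function(lab) {
    tp <- sum(pred$label == lab & truth == lab)
    data.frame(label = lab,
               n = sum(truth == lab),
               precision = if (sum(pred$label == lab) > 0)
                 tp / sum(pred$label == lab) else NA_real_,
               recall = tp / sum(truth == lab),
               stringsAsFactors = FALSE)
  }))
  model$report <- list(holdout_accuracy = acc, n_train = length(train_idx),
                       n_test = length(test_idx), per_label = per_label)
  model
}

#' @export
print.adduct_corrector <- function(x, ...) {
  cat(sprintf(
    "<adduct_corrector> %d labels | %d n-gram features | hold-out accuracy %.3f\n",
    length(x$labels), length(x$vectorizer$vocab),
    x$report$holdout_accuracy))
  invisible(x)
}

#' @export
summary.adduct_corrector <- function(object, ...) {
  cat("Adduct corrector\n")
  cat(sprintf("  labels: %d; features: %d; train/test: %d/%d\n",
              length(object$labels), length(object$vectorizer$vocab),
              object$report$n_train, object$report$n_test))
  cat(sprintf("  hold-out accuracy: %.4f\n", object$report$holdout_accuracy))
  worst <- object$report$per_label
  worst <- worst[order(worst$recall), , drop = FALSE]
  cat("  lowest-recall labels:\n")
  print(utils::head(worst, 5), row.names = FALSE)
  invisible(object$report)
}

#' Predict canonical labels for adduct strings
#'
#' Applies the preprocessing and the trained network; the label set is
#' closed (no novel labels at inference). Defined for any string.
#'
#' @param object a trained [train_adduct_corrector()] model.
#' @param newdata character vector of raw adduct strings.
#' @param preprocessed optional pre-computed TF-IDF matrix (internal use).
#' @param ... unused.
#' @return data.frame with columns `label` and `confidence` (softmax
#'   probability of the winning label).
#' @export
predict.adduct_corrector <- function(object, newdata, preprocessed = NULL,
                                     ...) {
  X <- if (is.null(preprocessed)) {
    tfidf_transform(object$vectorizer, preprocess_adduct_text(newdata))
  } else {
    preprocessed
  }
  P <- mlp_prob(object$net, X)
  w <- max.col(P, ties.method = "first")
  data.frame(label = object$net$levels[w],
             confidence = P[cbind(seq_len(nrow(P)), w)],
             stringsAsFactors = FALSE)
}

#' Correct an adduct annotation (rule first, model second)
#'
#' The deterministic grammar takes precedence: if the preprocessed string
#' parses, its canonical form is returned with confidence 1, so the learned
#' component can never contradict the grammar on parsable input. Otherwise
#' the classifier predicts a canonical label; predictions whose confidence
#' falls below `floor` are reported uncorrected.
#'
#' @param model a trained [train_adduct_corrector()].
#' @param s character vector of adduct annotations.
#' @param floor confidence floor below which the input is left unchanged.
#' @return data.frame with columns `input`, `label`, `confidence`,
#'   `corrected` (logical; `FALSE` when below the floor or missing) and
#'   `source` (`"grammar"`, `"model"` or `"uncorrected"`).
#' @export
correct_adduct <- function(model, s, floor = 0.5) {
  s <- as.character(s)
  out <- data.frame(input = s, label = NA_character_, confidence = NA_real_,
                    corrected = FALSE, source = "uncorrected",
                    stringsAsFactors = FALSE)
  pre <- preprocess_adduct_text(s)
  parsed <- lapply(pre, function(p) {
    tryCatch(parse_adduct(p), adduct_parse_error = function(e) NULL,
             error = function(e) NULL)
  })
  grammar_ok <- !vapply(parsed, is.null, logical(1))
  for (i in which(grammar_ok)) {
    if (is_missing_adduct(parsed[[i]])) {
      out$label[i] <- "UNKNOWN"
      out$confidence[i] <- 1
      out$source[i] <- "grammar"
    } else {
      out$label[i] <- canonical_string(parsed[[i]])
      out$confidence[i] <- 1
      out$corrected[i] <- TRUE
      out$source[i] <- "grammar"
    }
  }
  rest <- which(!grammar_ok)
  if (length(rest)) {
    pr <- predict(model, s[rest])
    keep <- pr$confidence >= floor & pr$label != "UNKNOWN"
    out$label[rest] <- pr$label
    out$confidence[rest] <- pr$confidence
    out$corrected[rest] <- keep
    out$source[rest] <- ifelse(keep, "model", "uncorrected")
  }
  out
}

#' Correct every adduct annotation in a library
#'
#' Applies [correct_adduct()] to the `adduct` field of each spectrum and
#' returns the rewritten library together with a change log.
#'
#' @param model a trained corrector.
#' @param lib a [spectral_library()].
#' @param floor confidence floor.
#' @return list with `library` (corrected) and `changes` (data.frame
#'   `index`, `old`, `new`, `confidence` for rewritten spectra).
#' @export
correct_library_adducts <- function(model, lib, floor = 0.5) {
  old <- vapply(lib$spectra, function(s) {
    v <- meta_field(s, "adduct")
    if (is.na(v)) "" else v
  }, character(1))
  res <- correct_adduct(model, old, floor = floor)
  changed <- which(res$corrected & res$label != old)
  for (i in changed) lib$spectra[[i]]$metadata$adduct <- res$label[i]
  list(library = lib,
       changes = data.frame(index = changed, old = old[changed],
                            new = res$label[changed],
                            confidence = res$confidence[changed],
                            stringsAsFactors = FALSE))
}
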