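#' Fit a template-matching decoder
#'
#' Stores, for each stimulus, the arithmetic mean of the training response
#' vectors as that stimulus's template. Classification assigns a test vector
#' to the stimulus whose template is nearest under the chosen metric:
#' Euclidean distance (`TMPEUC`) or angular distance `1 - cos` (`TMPCOS`).
#'
#' @param x Numeric matrix of training responses, rows = trials,
#'   cols = neurons (spikes/s or counts).
#' @param y Stimulus label per row (integer or factor).
#' @param metric `"euclidean"` or `"angular"`.
#' @return An object of class `decoder_model`.
#' @export
fit_template <- function(x, y, metric = c("euclidean", "angular")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) < 1) stop("no training classes")
  tm <- vapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(ncol(x)))
  templates <- if (is.matrix(tm)) t(tm) else matrix(tm, ncol = 1)
  structure(list(method = if (metric == "euclidean") "TMPEUC" else "TMPCOS",
                 templates = templates, classes = classes),
            class = "decoder_model")
}

#' Fit a PCA + linear discriminant decoder
#'
#' Principal components are fit on the training trials (neurons are the
#' dimensions) and the smallest number of components reaching at least
#' `var_retained` of the variance is kept. Fisher linear discriminant axes
#' (at most `n_classes - 1`) are then computed in PCA space; when the
#' within-class scatter is singular it is ridge-regularised by adding
#' `reg_eps * trace/dim` to its diagonal. Class means are stored in
#' discriminant space and classification is by the nearest class mean. Test
#' samples are always projected with the PCA and LDA transforms determined
#' from the training set.
#'
#' @inheritParams fit_template
#' @param var_retained Fraction of training variance the PCA must retain.
#' @param reg_eps Relative ridge added to a singular within-class scatter.
#' @return An object of class `decoder_model` with `method = "LDA"`.
#' @export
fit_lda <- function(x, y, var_retained = 0.90, reg_eps = 1e-9) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  k <- length(classes)
  if (k < 2) stop("LDA needs at least 2 classes")
  if (any(table(y) < 2)) stop("LDA needs at least 2 training trials per class")

  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- La.svd(xc, nu = 0)
  ev <- sv$d^2
  pos <- ev > max(ev) * 1e-12
  cum <- cumsum(ev[pos]) / sum(ev[pos])
  ncomp <- which(cum >= var_retained)[1]
  rotation <- t(sv$vt)[, seq_len(ncomp), drop = FALSE]
  z <- xc %*% rotation

  gm <- colMeans(z)
  sw <- matrix(0, ncomp, ncomp)
  sb <- matrix(0, ncomp, ncomp)
  for (cl in classes) {
    zi <- z[y == cl, , drop = FALSE]
    mi <- colMeans(zi)
    zic <- sweep(zi, 2, mi)
    sw <- sw + crossprod(zic)
    sb <- sb + nrow(zi) * tcrossprod(mi - gm)
  }
  if (!is.finite(rcond(sw)) || rcond(sw) < 1e-12)
    sw <- sw + diag(reg_eps * sum(diag(sw)) / ncomp + 1e-300, ncomp)
  eg <- eigen(solve(sw, sb))
  naxes <- min(k - 1L, sum(abs(Re(eg$values)) > 1e-12 * max(abs(Re(eg$values)))))
  naxes <- max(naxes, 1L)
  w <- Re(eg$vectors[, seq_len(naxes), drop = FALSE])
  dz <- z %*% w
  mm <- vapply(classes, function(cl)
    colMeans(dz[y == cl, , drop = FALSE]), numeric(naxes))
  means <- if (is.matrix(mm)) t(mm) else matrix(mm, ncol = 1)
  structure(list(method = "LDA", classes = classes, center = center,
                 rotation = rotation, w = w, templates = means,
                 n_components = ncomp),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %s, %d classes, %d dims%s\n", x$method,
              length(x$classes), ncol(x$templates),
              if (x$method == "LDA")
                sprintf(" (%d PCs)", x$n_components) else ""))
  invisible(x)
}

# pairwise squared Euclidean distances between rows of a and rows of b
.sqdist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

#' Classify response vectors
#'
#' Assigns each row of `x` to the stimulus with the smallest model distance
#' (Euclidean to the template, angular distance `1 - cos`, or Euclidean to
#' the class mean in discriminant space after the stored PCA + LDA
#' projection). Ties are broken deterministically in favour of the lowest
#' stimulus index. Under the angular metric a zero-norm (spike-free) test
#' vector is assigned distance 1 to every template, so it resolves to the
#' first class.
#'
#' @param model A `decoder_model` from [fit_template()] or [fit_lda()].
#' @param x Numeric matrix of test responses (rows = trials), or a single
#'   vector.
#' @return Vector of predicted stimulus labels, one per row.
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "decoder_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  d <- switch(model$method,
    TMPEUC = .sqdist(x, model$templates),
    TMPCOS = {
      xn <- sqrt(rowSums(x^2))
      tn <- sqrt(rowSums(model$templates^2))
      cosine <- tcrossprod(x, model$templates) /
        outer(pmax(xn, 1e-300), pmax(tn, 1e-300))
      cosine[xn == 0 | is.na(cosine)] <- 0
      cosine[, tn == 0] <- 0
      1 - cosine
    },
    LDA = {
      z <- sweep(x, 2, model$center) %*% model$rotation %*% model$w
      .sqdist(z, model$templates)
    },
    stop("unknown decoder method: ", model$method))
  model$classes[apply(d, 1, which.min)]
}

# fit + predict dispatcher used by the cross-validation drivers
.fit_decoder <- function(x, y, method) {
  switch(method,
         LDA = fit_lda(x, y),
         TMPEUC = fit_template(x, y, "euclidean"),
         TMPCOS = fit_template(x, y, "angular"),
         stop("unknown decoder method: ", method))
}

# contiguous per-stimulus fold assignment: trials 1..5 -> fold 1, etc.
.fold_of_trial <- function(trial, n_trials, n_folds) {
  per <- n_trials %/% n_folds
  (trial - 1L) %/% per + 1L
}

#' Cross-validated decoding from labelled response vectors
#'
#' K-fold cross-validation over trials: each fold holds out a contiguous
#' block of trials per stimulus (trials 1-5, 6-10, ... for the default
#' 20-trial, 4-fold scheme), fits the decoder on the remainder and scores
#' the held-out trials. Accuracy is the mean fraction correct across folds.
#'
#' @param x Numeric response matrix (rows = trials, cols = neurons).
#' @param y Stimulus label per row.
#' @param trial Trial number (1-based) per row, used to build folds.
#' @param method `"LDA"`, `"TMPEUC"` or `"TMPCOS"`.
#' @param n_folds Number of folds; `max(trial)` must be divisible by it.
#' @return An object of class `decoding_result`: list with `accuracy`,
#'   `fold_accuracy`, `confusion` (true x predicted counts), `n_test`.
#' @export
decode_cv <- function(x, y, trial, method = c("TMPEUC", "LDA", "TMPCOS"),
                      n_folds = 4) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n_trials <- max(trial)
  if (n_trials < n_folds) stop("fewer trials than folds")
  if (n_trials %% n_folds != 0)
    stop("n_trials (", n_trials, ") is not divisible into ", n_folds, " folds")
  fold <- .fold_of_trial(trial, n_trials, n_folds)
  classes <- sort(unique(y))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold == f
    model <- .fit_decoder(x[!te, , drop = FALSE], y[!te], method)
    pred <- classify(model, x[te, , drop = FALSE])
    acc[f] <- mean(pred == y[te])
    for (i in seq_along(pred)) {
      r <- match(y[te][i], classes)
      c <- match(pred[i], classes)
      conf[r, c] <- conf[r, c] + 1L
    }
  }
  structure(list(accuracy = mean(acc), fold_accuracy = acc,
                 confusion = conf, n_test = sum(conf), method = method),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s accuracy %.3f (%d folds, %d test trials)\n",
              x$method, x$accuracy, length(x$fold_accuracy), x$n_test))
  invisible(x)
}

#' Cross-validated population decoding in one window
#'
#' Extracts single-trial population rate vectors for the window and runs
#' [decode_cv()].
#'
#' @param data A [spike_train_set()].
#' @param window A [time_window()].
#' @param method `"LDA"`, `"TMPEUC"` or `"TMPCOS"`.
#' @param n_folds Number of cross-validation folds.
#' @return A `decoding_result`.
#' @export
cross_validated_accuracy <- function(data, window,
                                     method = c("TMPEUC", "LDA", "TMPCOS"),
                                     n_folds = 4) {
  pr <- population_response(data, window)
  decode_cv(pr$rates, pr$stimulus, pr$trial, match.arg(method), n_folds)
}

#' Decoding accuracy over random train/test splits
#'
#' Repeatedly splits the trials of each stimulus at random into a training
#' and a testing set (without replacement), fits the decoder on the training
#' split and scores the testing split. Quantifies the uncertainty of the
#' accuracy estimate due to the particular data split.
#'
#' @inheritParams cross_validated_accuracy
#' @param n_runs Number of random splits.
#' @param n_train Training trials per stimulus; the rest are tested.
#' @param seed Seed; identical seeds reproduce the run sequence.
#' @return List with `mean`, `sd` and the per-run `accuracies`.
#' @export
random_split_accuracy <- function(data, window,
                                  method = c("TMPEUC", "LDA", "TMPCOS"),
                                  n_runs = 1000, n_train = 15, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(data, "spike_train_set"))
  if (n_train >= data$n_trials) stop("'n_train' must leave trials for testing")
  pr <- population_response(data, window)
  set.seed(seed)
  ns <- n_stimuli(data)
  acc <- vapply(seq_len(n_runs), function(run) {
    tr <- logical(nrow(pr$rates))
    for (s in seq_len(ns)) {
      rows <- which(pr$stimulus == s)
      tr[rows[sample.int(length(rows), n_train)]] <- TRUE
    }
    model <- .fit_decoder(pr$rates[tr, , drop = FALSE], pr$stimulus[tr],
                          method)
    pred <- classify(model, pr$rates[!tr, , drop = FALSE])
    mean(pred == pr$stimulus[!tr])
  }, numeric(1))
  list(mean = mean(acc), sd = sd(acc), accuracies = acc)
}

#' Cross-validated single-neuron decoding
#'
#' Template matching on scalar single-trial rates of one neuron (the
#' Euclidean distance reduces to the absolute difference), with the same
#' fold scheme as the population decoders.
#'
#' @inheritParams cross_validated_accuracy
#' @param neuron Neuron id.
#' @return A `decoding_result`.
#' @export
single_neuron_accuracy <- function(data, neuron, window, n_folds = 4) {
  ni <- match(neuron, data$neurons)
  if (is.na(ni)) stop("unknown neuron id: ", neuron)
  pr <- population_response(data, window)
  decode_cv(pr$rates[, ni, drop = FALSE], pr$stimulus, pr$trial,
            "TMPEUC", n_folds)
}
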