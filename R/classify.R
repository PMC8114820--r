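#' Stratified k-fold assignment
#'
#' Partitions observations into `k` folds preserving class proportions:
#' within each class, shuffled members are dealt to folds round-robin, with
#' the starting fold rotated between classes so that global fold sizes stay
#' within `floor(n/k)` and `ceiling(n/k)`.  Deterministic given `seed`.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @return Integer vector of fold ids (1..k), one per observation.
#' @examples
#' f <- stratified_kfold(rep(1:2, each = 870), k = 10, seed = 1)
#' table(f)  # ten folds of 174
#' @export
stratified_kfold <- function(labels, k = 10, seed = NULL) {
  n <- length(labels)
  if (k < 2 || k != round(k)) stop("k must be an integer >= 2")
  tab <- table(labels)
  if (any(tab < k))
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(tab)[which.min(tab)], k))
  old <- local_seed(seed); on.exit(restore_seed(old))
  fold <- integer(n)
  offset <- 0L
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}

#' Train a classifier and predict held-out labels
#'
#' The three classifiers of the evaluation grid:
#' * `"lda"` -- two-class linear discriminant with pooled covariance
#'   (pseudo-inverted, so rank-deficient feature tables are handled) and
#'   training-proportion priors;
#' * `"svm_linear"` -- soft-margin linear support vector machine with
#'   `C = 1` ([e1071::svm]);
#' * `"knn1"` -- single nearest neighbor in Euclidean distance, with
#'   distance ties broken by the lower training-row index.
#'
#' @param classifier One of `"lda"`, `"svm_linear"`, `"knn1"`.
#' @param train,test [feature_table]s; `train` must contain both classes.
#' @param cost SVM soft-margin constant.
#' @return Integer vector of predicted labels for the rows of `test`.
#' @export
fit_predict <- function(classifier = c("lda", "svm_linear", "knn1"),
                        train, test, cost = 1) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(train, "feature_table"), inherits(test, "feature_table"))
  if (length(unique(train$y)) < 2)
    stop("training data must contain both classes")
  switch(classifier,
         lda = predict_lda(train$X, train$y, test$X),
         svm_linear = predict_svm_linear(train$X, train$y, test$X, cost),
         knn1 = predict_knn1(train$X, train$y, test$X))
}

# pooled-covariance two-class LDA; ginv tolerates singular pooled covariance
predict_lda <- function(X, y, Xt) {
  i1 <- y == 1L; i2 <- y == 2L
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  n1 <- sum(i1); n2 <- sum(i2); n <- n1 + n2
  C1 <- stats::cov(X[i1, , drop = FALSE]) * (n1 - 1)
  C2 <- stats::cov(X[i2, , drop = FALSE]) * (n2 - 1)
  Sp <- (C1 + C2) / (n - 2)
  w <- MASS::ginv(Sp) %*% (m1 - m2)
  thresh <- sum((m1 + m2) / 2 * w) - log(n1 / n2)
  score <- as.numeric(Xt %*% w)
  ifelse(score >= thresh, 1L, 2L)
}

predict_svm_linear <- function(X, y, Xt, cost) {
  fit <- e1071::svm(X, factor(y, levels = c(1, 2)),
                    kernel = "linear", cost = cost, scale = FALSE,
                    type = "C-classification")
  as.integer(as.character(stats::predict(fit, Xt)))
}

predict_knn1 <- function(X, y, Xt) {
  # squared distances via the expansion |t - x|^2 = |t|^2 - 2 t.x + |x|^2;
  # which.min returns the first (lowest-index) minimizer, the tie rule
  G <- tcrossprod(Xt, X)              # n_test x n_train
  d2 <- sweep(-2 * G, 2, rowSums(X^2), `+`)
  y[apply(d2, 1, which.min)]
}

#' Confusion counts for binary labels
#'
#' Class 1 is the positive class by convention.
#'
#' @param truth,predicted Equal-length vectors with values in `{1, 2}`.
#' @return Object of class `confusion_counts` with fields `TP`, `TN`, `FP`,
#'   `FN` summing to the number of observations.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  if (!all(c(truth, predicted) %in% c(1L, 2L)))
    stop("labels must be 1 (positive) or 2 (negative)")
  structure(list(TP = sum(truth == 1L & predicted == 1L),
                 TN = sum(truth == 2L & predicted == 2L),
                 FP = sum(truth == 2L & predicted == 1L),
                 FN = sum(truth == 1L & predicted == 2L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Computes the evaluation suite reported per grid cell: accuracy in
#' percent, sensitivity, false-positive rate, precision, Cohen's kappa,
#' error rate and a binomial confidence interval on the error.
#'
#' Standard definitions are used: `ACC% = 100 (TP+TN)/total`,
#' `Sens = TP/(TP+FN)`, `FPR = FP/(FP+TN)`, `PRC = TP/(TP+FP)`;
#' `kappa = (acc - racc) / (1 - racc)` with chance agreement
#' `racc = p1 p2 + (1-p1)(1-p2)`, `p1 = (TP+FN)/total` the positive
#' prevalence and `p2 = (TP+FP)/total` the positive prediction rate;
#' `error = (FP+FN)/total` and `CI = z * sqrt(error (1-error) / n)` with
#' `z = 1.96` at 95% confidence, `n` being the number of observations used
#' to develop the model (defaults to the evaluated total).
#' `printed_formulas = TRUE` switches accuracy and FPR to the variants
#' `100 (TP+FP)/total` and `FP/(TP+TN)` for compatibility with one
#' published presentation of these formulas; the standard forms are the
#' default because only they satisfy the usual identities (e.g.
#' `ACC/100 + error = 1`).
#'
#' Metrics with a zero denominator (e.g. precision when nothing is
#' predicted positive) are reported as `NA` rather than 0.
#'
#' @param counts A [confusion] result.
#' @param n Observation count for the confidence interval; defaults to the
#'   total in `counts`.
#' @param confidence Confidence level (0.95 gives `z = 1.96`).
#' @param printed_formulas Use the printed accuracy/FPR variants.
#' @return List of class `metric_cell`: `acc` (percent), `sens`, `fpr`,
#'   `prc`, `kappa`, `error`, `ci` (half-width), `n`, plus the counts.
#' @examples
#' confusion_metrics(confusion(rep(1:2, each = 5), rep(1:2, each = 5)))
#' @export
confusion_metrics <- function(counts, n = NULL, confidence = 0.95,
                              printed_formulas = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("confusion counts are empty")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- if (printed_formulas) 100 * (TP + FP) / total else 100 * (TP + TN) / total
  sens <- rat(TP, TP + FN)
  fpr <- if (printed_formulas) rat(FP, TP + TN) else rat(FP, FP + TN)
  prc <- rat(TP, TP + FP)
  p1 <- (TP + FN) / total
  p2 <- (TP + FP) / total
  racc <- p1 * p2 + (1 - p1) * (1 - p2)
  kappa <- if (abs(1 - racc) < .Machine$double.eps * 4) NA_real_
           else ((TP + TN) / total - racc) / (1 - racc)
  error <- (FP + FN) / total
  if (is.null(n)) n <- total
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  ci <- z * sqrt(error * (1 - error) / n)
  structure(list(acc = acc, sens = sens, fpr = fpr, prc = prc,
                 kappa = kappa, error = error, ci = ci, n = n,
                 counts = counts),
            class = "metric_cell")
}

#' @export
print.metric_cell <- function(x, ...) {
  cat(sprintf("ACC %.3f%% | Sens %.3f | FPR %.3f | PRC %.3f | Kappa %.3f | error %.3f +/- %.3f\n",
              x$acc, x$sens, x$fpr, x$prc, x$kappa, x$error, x$ci))
  invisible(x)
}
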