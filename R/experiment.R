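#' Subset a feature table by row
#' @param table A [feature_table].
#' @param idx Integer or logical row index.
#' @return The subsetted [feature_table].
#' @export
subset_table <- function(table, idx) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(table$X[idx, , drop = FALSE], table$y[idx], set = table$set,
                meta = if (is.null(table$meta)) NULL
                       else table$meta[idx, , drop = FALSE])
}

#' Cross-validated evaluation of one grid cell
#'
#' Evaluates one (feature set, classifier, weighting) combination under
#' stratified k-fold cross-validation and pools the held-out confusion
#' counts across folds.
#'
#' Weighting placement depends on `mode`:
#' * `mode = "faithful"`: weights are fitted on the *full* table and applied
#'   with each observation's own label *before* folding, replicating the
#'   original protocol.  Because held-out rows are transformed with their
#'   true labels, this leaks label information and inflates accuracy (see
#'   vignette).
#' * `mode = "global"`: within each training fold, weights are fitted on
#'   the training rows only and the label-free averaged weight vector is
#'   applied to both the training and the held-out rows -- the leakage-free
#'   protocol.
#'
#' @param table A [feature_table].
#' @param classifier `"knn1"`, `"lda"` or `"svm_linear"`.
#' @param weighting `"none"`, `"kmcc"` or `"kmccd"`.
#' @param mode `"faithful"` or `"global"` (ignored for `weighting = "none"`).
#' @param folds Number of CV folds.
#' @param seed Integer seed driving fold assignment and weight clustering.
#' @param n Observation count used in the confidence-interval formula;
#'   defaults to the table's row count.
#' @param cost SVM soft-margin constant.
#' @return List of class `cv_result`: `metrics` (a [confusion_metrics]
#'   cell), `fold_acc` (per-fold accuracies, percent), `folds`, and the cell
#'   coordinates.
#' @export
cv_classify <- function(table, classifier = c("knn1", "lda", "svm_linear"),
                        weighting = c("none", "kmcc", "kmccd"),
                        mode = c("faithful", "global"),
                        folds = 10, seed = 1, n = NULL, cost = 1) {
  classifier <- match.arg(classifier)
  weighting <- match.arg(weighting)
  mode <- match.arg(mode)
  stopifnot(inherits(table, "feature_table"))
  weigh <- switch(weighting, none = NULL,
                  kmcc = kmcc_weights, kmccd = kmccd_weights)

  if (!is.null(weigh) && mode == "faithful") {
    cw <- weigh(table, seed = seed + 1000L)
    table <- apply_weights(table, cw, mode = "faithful")
  }
  fold <- stratified_kfold(table$y, k = folds, seed = seed)
  pred <- integer(length(table$y))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- subset_table(table, fold != f)
    te <- subset_table(table, fold == f)
    if (!is.null(weigh) && mode == "global") {
      cw <- weigh(tr, seed = seed + 1000L + f)
      tr <- apply_weights(tr, cw, mode = "global")
      te <- apply_weights(te, cw, mode = "global")
    }
    p <- fit_predict(classifier, tr, te, cost = cost)
    pred[fold == f] <- p
    fold_acc[f] <- 100 * mean(p == te$y)
  }
  cc <- confusion(table$y, pred)
  structure(list(metrics = confusion_metrics(cc, n = n %||% length(table$y)),
                 fold_acc = fold_acc, folds = folds,
                 set = table$set, classifier = classifier,
                 weighting = weighting, mode = mode, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s | %s | %s (%s, %d-fold)\n  ",
              x$set, x$classifier, x$weighting, x$mode, x$folds))
  print(x$metrics)
  invisible(x)
}

#' Run the feature-set x classifier x weighting experiment grid
#'
#' Evaluates every combination of the supplied feature tables, classifiers
#' and weighting schemes under stratified k-fold cross-validation (6 sets x
#' 3 classifiers x 3 weightings = 54 cells with the defaults) and collects
#' the pooled-confusion metric suite per cell.
#'
#' @param tables Named list of [feature_table]s sharing labels and ordering.
#' @param classifiers Character vector from
#'   `c("knn1", "lda", "svm_linear")`.
#' @param weightings Character vector from `c("none", "kmcc", "kmccd")`.
#' @param mode Weighting placement, `"faithful"` or `"global"`; see
#'   [cv_classify()].
#' @param folds,seed,cost,n Passed to [cv_classify()].
#' @return Object of class `eval_report`: `cells` (nested list
#'   set -> classifier -> weighting), `grid` (flat data frame with one row
#'   per cell: ACC %, SENS, FPR, PRC, Kappa, error, CI), and the config.
#' @export
run_experiment <- function(tables,
                           classifiers = c("knn1", "lda", "svm_linear"),
                           weightings = c("none", "kmcc", "kmccd"),
                           mode = "faithful",
                           folds = 10, seed = 1, cost = 1, n = NULL) {
  stopifnot(is.list(tables), length(tables) > 0)
  y0 <- tables[[1]]$y
  for (tb in tables)
    if (!identical(tb$y, y0))
      stop("all tables must share labels and trial ordering")
  cells <- list()
  rows <- list()
  for (set in names(tables))
    for (clf in classifiers)
      for (wgt in weightings) {
        res <- cv_classify(tables[[set]], clf, wgt, mode = mode,
                           folds = folds, seed = seed, cost = cost, n = n)
        cells[[set]][[clf]][[wgt]] <- res
        m <- res$metrics
        rows[[length(rows) + 1L]] <-
          data.frame(set = set, classifier = clf, weighting = wgt,
                     mode = mode, acc = m$acc, sens = m$sens, fpr = m$fpr,
                     prc = m$prc, kappa = m$kappa, error = m$error,
                     ci = m$ci, stringsAsFactors = FALSE)
      }
  structure(list(cells = cells, grid = do.call(rbind, rows),
                 config = list(classifiers = classifiers,
                               weightings = weightings, mode = mode,
                               folds = folds, seed = seed, cost = cost,
                               n = n %||% length(y0))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d cells (%d-fold CV, mode %s, seed %d)\n",
              nrow(x$grid), x$config$folds, x$config$mode, x$config$seed))
  g <- x$grid
  g$acc <- sprintf("%.3f", g$acc)
  g$`error±ci` <- sprintf("%.3f ± %.3f", x$grid$error, x$grid$ci)
  print(g[, c("set", "classifier", "weighting", "acc", "error±ci")],
        row.names = FALSE)
  invisible(x)
}
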