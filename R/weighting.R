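#' Two-cluster k-means (Lloyd's algorithm)
#'
#' The k = 2 clustering core of the attribute-weighting transforms.
#' Initial centers are two distinct points sampled from the data; Lloyd
#' iterations then alternate (1) assigning each point to the nearer center
#' in Euclidean distance, with equidistant ties going to cluster 1, and
#' (2) recomputing each center as its cluster mean, until the largest
#' center movement falls below `tol`.  If a cluster empties mid-iteration
#' its center is reseeded with the point farthest from the other center.
#' With `nstart > 1` the best of several seeded starts (lowest
#' within-cluster sum of squares) is returned, which in practice recovers
#' the global optimum on small instances.
#'
#' @param points Numeric matrix `n x d` (a vector is treated as `n x 1`)
#'   with at least two distinct rows.
#' @param tol Convergence threshold on center movement.
#' @param max_iter Iteration cap.
#' @param seed Optional integer seed for the initialization draws.
#' @param nstart Number of random restarts.
#' @return List of class `kmeans2_result`: `centers` (2 x d), `assignments`
#'   (1/2 per point), `n_iter`, `converged`, `tot_withinss`.
#' @examples
#' kmeans2(c(0, 1, 10, 11), seed = 1)$centers  # 0.5 and 10.5
#' @export
kmeans2 <- function(points, tol = 1e-6, max_iter = 300, seed = NULL,
                    nstart = 10) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (n < 2) stop("at least 2 points are required")
  if (all(apply(points, 2, function(col) max(col) - min(col) == 0)))
    stop("all points are identical: 2-means is degenerate")
  old <- local_seed(seed); on.exit(restore_seed(old))

  best <- NULL
  for (s in seq_len(nstart)) {
    res <- kmeans2_once(points, tol, max_iter)
    if (is.null(best) || res$tot_withinss < best$tot_withinss) best <- res
  }
  class(best) <- "kmeans2_result"
  best
}

kmeans2_once <- function(points, tol, max_iter) {
  n <- nrow(points)
  # two distinct initial points
  repeat {
    init <- sample.int(n, 2)
    if (any(points[init[1], ] != points[init[2], ])) break
  }
  centers <- points[init, , drop = FALSE]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- rowSums(sweep(points, 2, centers[1, ])^2)
    d2 <- rowSums(sweep(points, 2, centers[2, ])^2)
    assignment <- ifelse(d1 <= d2, 1L, 2L)  # ties to cluster 1
    for (j in 1:2) {
      if (!any(assignment == j)) {
        # reseed an empty cluster with the point farthest from the other center
        other <- if (j == 1) d2 else d1
        far <- which.max(other)
        assignment[far] <- j
        warning("empty cluster reseeded with the farthest point")
      }
    }
    new_centers <- rbind(colMeans(points[assignment == 1L, , drop = FALSE]),
                         colMeans(points[assignment == 2L, , drop = FALSE]))
    move <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (move < tol) { converged <- TRUE; break }
  }
  d1 <- rowSums(sweep(points, 2, centers[1, ])^2)
  d2 <- rowSums(sweep(points, 2, centers[2, ])^2)
  assignment <- ifelse(d1 <= d2, 1L, 2L)
  list(centers = centers, assignments = assignment, n_iter = it,
       converged = converged,
       tot_withinss = sum(pmin(d1, d2)))
}

#' Per-class center from within-class 2-means
#'
#' The weighting transforms need a single center vector per class, but the
#' clustering core returns two.  This function runs [kmeans2] within one
#' class's feature matrix and returns the componentwise mean of the two
#' resulting centers; for symmetric within-class structure this coincides
#' with the class mean.  A degenerate class (all rows identical) falls back
#' to the class mean with a warning.
#'
#' @param class_matrix Numeric matrix `n_i x d` of one class's observations
#'   (`n_i >= 2`), or a vector treated as one feature.
#' @param seed,nstart Passed to [kmeans2].
#' @return Numeric length-`d` center vector.
#' @examples
#' class_center(c(0, 1, 10, 11))  # mean of centers 0.5 and 10.5 -> 5.5
#' @export
class_center <- function(class_matrix, seed = NULL, nstart = 10) {
  if (!is.matrix(class_matrix)) class_matrix <- matrix(class_matrix, ncol = 1)
  if (nrow(class_matrix) < 2) stop("a class needs at least 2 observations")
  z <- tryCatch(
    colMeans(kmeans2(class_matrix, seed = seed, nstart = nstart)$centers),
    error = function(e) {
      warning("degenerate class (all points identical): using the class mean")
      colMeans(class_matrix)
    })
  z
}

#' Cluster-center attribute weights
#'
#' Computes the per-class, per-feature weights of the k-means cluster-center
#' weighting (KMCC) or its distance variant (KMCCD) from a labeled feature
#' table.
#'
#' For each class `i`, a center vector `z[i, ]` is obtained with
#' [class_center()] on the class's rows.  KMCC then sets
#' `w[i, j] = mu[i, j] / z[i, j]` where `mu[i, j]` is the class mean of
#' feature `j`.  KMCCD instead computes each observation's distance to the
#' class center per feature, `d = |c[i, j] - z[i, j]|`, and divides the mean
#' distance by the center: `w[i, j] = mean(d) / z[i, j]`.  Features whose
#' center magnitude falls below `zero_tol` get the method's identity value
#' (1 for KMCC, 0 for KMCCD) with a warning.
#'
#' Both weight maps are scale-equivariant: multiplying a feature by `a > 0`
#' rescales `mu` and `z` alike and leaves `w` unchanged.
#'
#' By default the within-class clustering runs on the full class matrix, so
#' one partition per class determines every component of `z[i, ]`;
#' `per_feature = TRUE` instead clusters each feature column separately
#' (1-D k-means per feature), which decouples the center components at the
#' cost of `d` clustering runs per class.
#'
#' @param table A [feature_table] containing both classes with at least two
#'   observations each.
#' @param seed,nstart Passed to the within-class clustering.
#' @param zero_tol Guard threshold on `|z|`.
#' @param per_feature Cluster each feature independently in 1-D.
#' @return Object of class `class_weights`: `w`, `z`, `mu` (2 x n_features)
#'   and `method`.
#' @export
kmcc_weights <- function(table, seed = NULL, nstart = 10, zero_tol = 1e-12,
                         per_feature = FALSE) {
  cluster_weights(table, "kmcc", seed, nstart, zero_tol, per_feature)
}

#' @rdname kmcc_weights
#' @export
kmccd_weights <- function(table, seed = NULL, nstart = 10, zero_tol = 1e-12,
                          per_feature = FALSE) {
  cluster_weights(table, "kmccd", seed, nstart, zero_tol, per_feature)
}

cluster_weights <- function(table, method, seed, nstart, zero_tol,
                            per_feature = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  classes <- sort(unique(table$y))
  if (!identical(classes, c(1L, 2L)))
    stop("both classes (1 and 2) must be present")
  d <- ncol(table$X)
  w <- z <- mu <- matrix(0, 2, d,
                         dimnames = list(c("class1", "class2"),
                                         colnames(table$X)))
  for (i in 1:2) {
    ci <- table$X[table$y == i, , drop = FALSE]
    if (nrow(ci) < 2) stop("each class needs at least 2 observations")
    si <- if (is.null(seed)) NULL else seed + i
    z[i, ] <- if (per_feature) {
      vapply(seq_len(d), function(j)
        suppressWarnings(class_center(ci[, j], seed = si, nstart = nstart)),
        numeric(1))
    } else {
      class_center(ci, seed = si, nstart = nstart)
    }
    mu[i, ] <- if (method == "kmcc") colMeans(ci)
               else colMeans(abs(sweep(ci, 2, z[i, ])))
    ok <- abs(z[i, ]) > zero_tol
    w[i, ok] <- mu[i, ok] / z[i, ok]
    if (any(!ok)) {
      w[i, !ok] <- if (method == "kmcc") 1 else 0
      warning(sprintf("%d near-zero class centers: identity weight substituted",
                      sum(!ok)))
    }
  }
  structure(list(w = w, z = z, mu = mu, method = method),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("<class_weights> %s: 2 classes x %d features (weight range %.3g .. %.3g)\n",
              toupper(x$method), ncol(x$w), min(x$w), max(x$w)))
  invisible(x)
}

#' Apply class weights to a feature table
#'
#' Two application modes differing in what they assume about labels:
#'
#' * `"faithful"` multiplies each observation's features by the weight
#'   vector of that observation's *own* class, exactly as the weighting
#'   pseudo-code prescribes (`data_weighted[i] = c[i, j] * w[i, j]`).  This
#'   requires labels on every row -- including what will later serve as test
#'   data -- and therefore leaks label information into the features.  It
#'   reproduces the original evaluation protocol and its optimistic
#'   accuracies; see the package vignette for the demonstration that it
#'   drives pure-noise features to near-perfect cross-validated accuracy.
#' * `"global"` multiplies every observation by the label-free average
#'   weight vector `(w[1, ] + w[2, ]) / 2` and is safe to fit on training
#'   folds and apply to held-out data.
#'
#' @param table A [feature_table].
#' @param cw A `class_weights` object with matching feature count.
#' @param mode `"faithful"` or `"global"`.
#' @return The weighted [feature_table].
#' @export
apply_weights <- function(table, cw, mode = c("faithful", "global")) {
  stopifnot(inherits(table, "feature_table"), inherits(cw, "class_weights"))
  mode <- match.arg(mode)
  if (ncol(table$X) != ncol(cw$w))
    stop("feature counts of table and weights differ")
  X <- table$X
  if (mode == "faithful") {
    if (anyNA(table$y))
      stop("faithful mode requires a label on every observation")
    for (i in 1:2) {
      rows <- table$y == i
      X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, cw$w[i, ], `*`)
    }
  } else {
    X <- sweep(X, 2, colMeans(cw$w), `*`)
  }
  feature_table(X, table$y, set = table$set, meta = table$meta)
}
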