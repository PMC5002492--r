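#' Discretize fruit yield into diagnostic classes
#'
#' Specimens at or above the cutoff are "high" yielders (the diagnostic
#' negatives: nutritionally balanced); below-cutoff specimens are "low"
#' yielders (the positives, suspected misbalanced). A yield exactly at the
#' cutoff is classified high.
#'
#' @param yields numeric vector of fruit yields (Mg ha^-1), >= 0.
#' @param cutoff yield threshold, > 0.
#' @return Factor with levels \code{c("low", "high")}.
#' @export
discretize_yield <- function(yields, cutoff) {
  if (any(yields < 0)) stop("yields must be >= 0")
  if (cutoff <= 0) stop("'cutoff' must be > 0")
  factor(ifelse(yields >= cutoff, "high", "low"), levels = c("low", "high"))
}

# Samworth-style rank weights for the "optimal" kernel in d dimensions.
optimal_weights <- function(k, d) {
  i <- seq_len(k)
  w <- 1 + d / 2 - d / (2 * k^(2 / d)) * (i^(1 + 2 / d) - (i - 1)^(1 + 2 / d))
  pmax(w, 0)
}

minkowski_dist <- function(query, train, p) {
  out <- matrix(0, nrow(query), nrow(train))
  for (i in seq_len(nrow(query))) {
    df <- abs(sweep(train, 2, query[i, ], `-`))
    out[i, ] <- if (is.infinite(p)) apply(df, 1, max) else rowSums(df^p)^(1 / p)
  }
  out
}

#' Weighted k-nearest-neighbour classification in balance space
#'
#' Classifies query specimens from their ilr coordinates by a distance-
#' weighted vote among the k nearest training specimens. Distances are
#' Minkowski with exponent \code{p}; the kernel sets the neighbour weights:
#' \describe{
#'   \item{rectangular}{equal weights (plain majority vote);}
#'   \item{triangular}{\code{1 - d_i/d_(k+1)}, distances standardized by the
#'     (k+1)-th neighbour;}
#'   \item{optimal}{rank-based Samworth weight sequence for the coordinate
#'     dimension.}
#' }
#' A tied vote goes to the class of the single nearest neighbour (then to the
#' first class level), so predictions are deterministic.
#'
#' @param train matrix of training ilr coordinates (rows = specimens).
#' @param cl factor (or vector) of training classes.
#' @param query matrix of query coordinates with the same columns.
#' @param k number of neighbours, \code{1 <= k <= nrow(train)}.
#' @param p Minkowski exponent, >= 1 (2 = Euclidean).
#' @param kernel one of \code{"rectangular"}, \code{"triangular"},
#'   \code{"optimal"}.
#' @return Factor of predicted classes, one per query row.
#' @export
knn_classify <- function(train, cl, query, k = 10, p = 2,
                         kernel = c("optimal", "rectangular", "triangular")) {
  kernel <- match.arg(kernel)
  train <- as.matrix(train); query <- as.matrix(query)
  cl <- factor(cl)
  n <- nrow(train)
  if (k < 1 || k > n) stop(sprintf("'k' must be between 1 and the training size (%d)", n))
  if (p < 1) stop("'p' must be >= 1")
  if (ncol(query) != ncol(train)) stop("coordinate dimension mismatch")
  d <- minkowski_dist(query, train, p)
  lev <- levels(cl)
  pred <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    ord <- order(d[i, ])
    nb <- ord[seq_len(k)]
    w <- switch(kernel,
      rectangular = rep(1, k),
      triangular = {
        dk1 <- if (k < n) d[i, ord[k + 1]] else d[i, ord[k]] * (1 + 1e-9)
        if (dk1 == 0) rep(1, k) else pmax(1 - d[i, nb] / dk1, 0)
      },
      optimal = optimal_weights(k, ncol(train)))
    votes <- vapply(lev, function(L) sum(w[cl[nb] == L]), 0)
    top <- lev[votes == max(votes)]
    pred[i] <- if (length(top) == 1) top else {
      nn <- as.character(cl[nb[1]])
      if (nn %in% top) nn else top[1]
    }
  }
  factor(pred, levels = lev)
}

stratified_folds <- function(cl, folds, seed) {
  cl <- factor(cl)
  fold <- integer(length(cl))
  rng <- local_rng(seed)
  for (L in levels(cl)) {
    idx <- which(cl == L)
    idx <- idx[rng$sample(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# seed-scoped RNG that does not disturb the global stream
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    force(expr)
  }
  list(sample = function(n) with_state(sample.int(n)),
       runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
       rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)))
}

#' Tune the knn diagnosis by cross-validation
#'
#' Grid search over (k, p, kernel) using stratified \code{folds}-fold
#' cross-validation; the selected configuration maximizes pooled CV accuracy,
#' with ties broken toward smaller k then smaller p.
#'
#' @param x matrix of ilr coordinates.
#' @param cl factor of observed classes.
#' @param grid data.frame with columns \code{k}, \code{p}, \code{kernel}.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @return List with \code{best} (one-row data.frame), \code{cv_accuracy}
#'   (of the best configuration), and \code{grid} with an \code{accuracy}
#'   column.
#' @export
tune_knn <- function(x, cl, grid = knn_grid(), folds = 10, seed = 1) {
  x <- as.matrix(x); cl <- factor(cl)
  if (nrow(x) < folds) stop("fewer specimens than folds")
  if (nrow(grid) < 1) stop("empty tuning grid")
  fold <- stratified_folds(cl, folds, seed)
  for (f in unique(fold)) {
    if (nlevels(droplevels(cl[fold != f])) < nlevels(cl))
      stop(sprintf("fold %d leaves a class absent from its training split; use fewer folds", f))
  }
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pred <- factor(rep(NA_character_, length(cl)), levels = levels(cl))
    ok <- TRUE
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (grid$k[g] > sum(tr)) { ok <- FALSE; break }
      pred[!tr] <- knn_classify(x[tr, , drop = FALSE], cl[tr],
                                x[!tr, , drop = FALSE],
                                k = grid$k[g], p = grid$p[g],
                                kernel = as.character(grid$kernel[g]))
    }
    acc[g] <- if (ok) mean(pred == cl) else NA_real_
  }
  grid$accuracy <- acc
  ord <- order(-acc, grid$k, grid$p)
  best <- grid[ord[1], , drop = FALSE]
  list(best = best, cv_accuracy = best$accuracy, grid = grid)
}

#' @rdname tune_knn
#' @param k,p,kernel vectors crossed into the default grid.
#' @export
knn_grid <- function(k = c(5, 10, 15), p = c(2, 4), kernel = "optimal") {
  expand.grid(k = k, p = p, kernel = kernel, stringsAsFactors = FALSE)
}

#' Confusion partition of diagnosed specimens
#'
#' Crosses true and predicted yield classes into the four diagnostic
#' sub-populations: TN (high yield, predicted high: balanced and productive),
#' TP (low yield, predicted low: misbalanced), FN (low yield but predicted
#' high: balanced yet limited by other growth factors), FP (high yield but
#' predicted low: luxury consumption or contamination). "Positive" means low
#' yielder.
#'
#' @param truth,predicted factors/vectors of classes in \{"low","high"\}, equal
#'   length.
#' @return Object of class \code{"confusion_partition"}: list with
#'   \code{counts} (named TN, FN, TP, FP) and \code{members} (index lists).
#' @export
partition_confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch between truth and predictions")
  truth <- as.character(truth); predicted <- as.character(predicted)
  cat4 <- ifelse(truth == "high",
                 ifelse(predicted == "high", "TN", "FP"),
                 ifelse(predicted == "low", "TP", "FN"))
  members <- split(seq_along(cat4), factor(cat4, levels = c("TN", "FN", "TP", "FP")))
  counts <- lengths(members)
  structure(list(counts = counts, members = members, category = cat4),
            class = "confusion_partition")
}

#' @rdname partition_confusion
#' @param TN,FN,TP,FP counts, for building a partition from published totals.
#' @export
confusion_counts <- function(TN, FN, TP, FP) {
  counts <- c(TN = TN, FN = FN, TP = TP, FP = FP)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be nonnegative integers")
  structure(list(counts = counts, members = NULL, category = NULL),
            class = "confusion_partition")
}

#' @export
print.confusion_partition <- function(x, ...) {
  cat("Diagnostic confusion partition (positive = low yielder):\n")
  print(x$counts)
  invisible(x)
}

#' Diagnostic performance metrics
#'
#' accuracy = (TN+TP)/total; npv = TN/(TN+FN); ppv = TP/(TP+FP);
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP). A ratio with zero
#' denominator is reported as \code{NA}, never 0.
#'
#' @param cp a \code{"confusion_partition"} (see
#'   \code{\link{partition_confusion}} or \code{\link{confusion_counts}}).
#' @return Named numeric vector of the five metrics.
#' @examples
#' diagnostic_metrics(confusion_counts(TN = 96, FN = 4, TP = 85, FP = 10))
#' @export
diagnostic_metrics <- function(cp) {
  ct <- cp$counts
  total <- sum(ct)
  if (total == 0) stop("empty confusion partition")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = (ct[["TN"]] + ct[["TP"]]) / total,
    npv = ratio(ct[["TN"]], ct[["TN"]] + ct[["FN"]]),
    ppv = ratio(ct[["TP"]], ct[["TP"]] + ct[["FP"]]),
    sensitivity = ratio(ct[["TP"]], ct[["TP"]] + ct[["FN"]]),
    specificity = ratio(ct[["TN"]], ct[["TN"]] + ct[["FP"]]))
}
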