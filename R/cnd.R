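#' Compositional nutrient diagnosis by knn in balance space
#'
#' Fits the full diagnostic model to a set of tissue specimens: computes ilr
#' balances under the supplied SBP, discretizes yield into high/low classes
#' at \code{cutoff}, tunes a weighted knn classifier by stratified
#' cross-validation over \code{grid}, classifies every specimen with the
#' selected configuration, and partitions specimens into the TN/FN/TP/FP
#' diagnostic groups (positive = low yielder).
#'
#' @param comp matrix or data.frame of tissue concentrations, one specimen
#'   per row, columns covering the SBP parts (g kg^-1 on scale \code{kappa};
#'   use \code{\link{filling_value}} beforehand if Fv is absent).
#' @param yield numeric vector of fruit yields (Mg ha^-1), one per specimen.
#' @param sbp balance design, an \code{"sbp"} (default \code{sbp_guava()}).
#' @param cutoff yield threshold separating low from high yielders; default
#'   is the median observed yield.
#' @param kappa closure scale (default 1000 g kg^-1).
#' @param grid knn tuning grid (see \code{\link{knn_grid}}).
#' @param folds cross-validation folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param tune logical; \code{FALSE} skips the grid search and uses the
#'   first grid row as the configuration.
#' @return Object of class \code{"cnd"} with components \code{basis},
#'   \code{balances}, \code{classes}, \code{predicted}, \code{config},
#'   \code{cv_accuracy}, \code{tuning}, \code{confusion}, \code{metrics},
#'   \code{cutoff}, \code{kappa}, \code{yield}.
#' @examples
#' set.seed(1)
#' ds <- generate_orchard(orchard_config(seed = 1))
#' fit <- cnd(ds$specimens[, parts_guava()], ds$specimens$yield, seed = 1)
#' fit
#' @export
cnd <- function(comp, yield, sbp = sbp_guava(), cutoff = NULL, kappa = 1000,
                grid = knn_grid(), folds = 10, seed = 1, tune = TRUE) {
  basis <- as_basis(sbp)
  b <- ilr(comp, basis)
  if (length(yield) != nrow(b)) stop("'yield' length must match the number of specimens")
  if (is.null(cutoff)) cutoff <- stats::median(yield)
  classes <- discretize_yield(yield, cutoff)
  if (nlevels(droplevels(classes)) < 2)
    stop("only one yield class at this cutoff; diagnosis needs both")
  if (tune) {
    tn <- tune_knn(b, classes, grid = grid, folds = folds, seed = seed)
  } else {
    tn <- list(best = grid[1, , drop = FALSE], cv_accuracy = NA_real_, grid = grid)
    cvp <- cv_predictions(b, classes, tn$best, folds, seed)
    tn$cv_accuracy <- mean(cvp == classes)
  }
  cfg <- tn$best
  predicted <- knn_classify(b, classes, b, k = cfg$k, p = cfg$p,
                            kernel = as.character(cfg$kernel))
  cp <- partition_confusion(classes, predicted)
  structure(list(basis = basis, balances = b, classes = classes,
                 predicted = predicted, config = cfg,
                 cv_accuracy = tn$cv_accuracy, tuning = tn$grid,
                 confusion = cp, metrics = diagnostic_metrics(cp),
                 cutoff = cutoff, kappa = kappa, yield = yield,
                 seed = seed),
            class = "cnd")
}

cv_predictions <- function(b, classes, cfg, folds, seed) {
  fold <- stratified_folds(classes, folds, seed)
  pred <- factor(rep(NA_character_, length(classes)), levels = levels(classes))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    pred[!tr] <- knn_classify(b[tr, , drop = FALSE], classes[tr],
                              b[!tr, , drop = FALSE],
                              k = cfg$k, p = cfg$p, kernel = as.character(cfg$kernel))
  }
  pred
}

#' @export
print.cnd <- function(x, ...) {
  cat("Compositional nutrient diagnosis (knn on ilr balances)\n")
  cat(sprintf("  %d specimens, %d balances; yield cutoff %.2f Mg ha^-1\n",
              length(x$classes), ncol(x$balances), x$cutoff))
  cat(sprintf("  knn: k = %d, Minkowski p = %g, kernel = %s\n",
              x$config$k, x$config$p, x$config$kernel))
  cat(sprintf("  accuracy: %.3f (cross-validated %.3f)\n",
              x$metrics[["accuracy"]], x$cv_accuracy))
  print(x$confusion$counts)
  invisible(x)
}

#' @export
summary.cnd <- function(object, alpha = 0.05, ...) {
  cis <- lapply(c(TN = "TN", TP = "TP"), function(g) {
    idx <- object$confusion$members[[g]]
    if (length(idx) >= 2)
      balance_ci(object$balances[idx, , drop = FALSE], alpha = alpha, group = g)
    else NULL
  })
  out <- list(call_config = object$config, metrics = object$metrics,
              cv_accuracy = object$cv_accuracy,
              confusion = object$confusion$counts, balance_ci = cis,
              cutoff = object$cutoff)
  class(out) <- "summary.cnd"
  out
}

#' @export
print.summary.cnd <- function(x, ...) {
  cat("Compositional nutrient diagnosis - summary\n\nConfusion partition:\n")
  print(x$confusion)
  cat("\nDiagnostic metrics:\n")
  print(round(x$metrics, 3))
  cat(sprintf("Cross-validated accuracy: %.3f\n", x$cv_accuracy))
  for (g in names(x$balance_ci)) {
    if (is.null(x$balance_ci[[g]])) next
    cat(sprintf("\n%s balance confidence intervals:\n", g))
    print(transform(x$balance_ci[[g]], mean = round(mean, 4),
                    lower = round(lower, 4), upper = round(upper, 4)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
predict.cnd <- function(object, newdata, ...) {
  b <- if (is.matrix(newdata) && identical(colnames(newdata), object$basis$labels))
    newdata else ilr(newdata, object$basis)
  knn_classify(object$balances, object$classes, b,
               k = object$config$k, p = object$config$p,
               kernel = as.character(object$config$kernel))
}

#' @export
coef.cnd <- function(object, ...) {
  groups <- split(seq_along(object$classes), object$confusion$category)
  t(vapply(groups, function(idx) colMeans(object$balances[idx, , drop = FALSE]),
           numeric(ncol(object$balances))))
}

#' Plot the balance domain of a fitted diagnosis
#'
#' Draws per-balance mean and confidence-interval segments for the TN and TP
#' groups side by side — a flat rendering of the fulcrum statistics of the
#' mobile design.
#'
#' @param x a fitted \code{"cnd"}.
#' @param alpha interval error rate.
#' @param ... passed to \code{plot}.
#' @export
plot.cnd <- function(x, alpha = 0.05, ...) {
  s <- summary(x, alpha = alpha)
  cis <- Filter(Negate(is.null), s$balance_ci)
  R <- ncol(x$balances)
  ylim <- range(unlist(lapply(cis, function(ci) c(ci$lower, ci$upper))))
  plot(NA, xlim = c(0.5, R + 0.5), ylim = ylim, xaxt = "n",
       xlab = "", ylab = "ilr balance", ...)
  graphics::axis(1, at = seq_len(R), labels = colnames(x$balances), las = 2, cex.axis = 0.7)
  graphics::abline(h = 0, col = "grey80")
  off <- c(TN = -0.12, TP = 0.12)
  cols <- c(TN = "forestgreen", TP = "firebrick")
  for (g in names(cis)) {
    ci <- cis[[g]]
    xs <- seq_len(R) + off[[g]]
    graphics::segments(xs, ci$lower, xs, ci$upper, col = cols[[g]], lwd = 2)
    graphics::points(xs, ci$mean, pch = 19, col = cols[[g]])
  }
  graphics::legend("topleft", legend = names(cis), col = cols[names(cis)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Concentration ranges from a fitted diagnosis
#'
#' Convenience wrapper: Student-t confidence intervals on the TN (and TP)
#' group balances, Monte-Carlo back-transformation to concentration ranges,
#' and critical values where the group ranges do not overlap.
#'
#' @param object a fitted \code{"cnd"} with a complete basis.
#' @param groups diagnostic groups to summarize (default TN and TP).
#' @param alpha interval error rate.
#' @inheritParams mc_conc_ranges
#' @return List with one \code{"conc_range"} per group and, when both TN and
#'   TP are present, a \code{critical} data.frame.
#' @export
concentration_ranges <- function(object, groups = c("TN", "TP"), alpha = 0.05,
                                 n_draws = 1e5, seed = 1, quantiles = NULL) {
  stopifnot(inherits(object, "cnd"))
  out <- list()
  for (g in groups) {
    idx <- object$confusion$members[[g]]
    if (length(idx) < 2) { out[[g]] <- NULL; next }
    ci <- balance_ci(object$balances[idx, , drop = FALSE], alpha = alpha, group = g)
    out[[g]] <- mc_conc_ranges(ci, object$basis, kappa = object$kappa,
                               n_draws = n_draws, seed = seed, quantiles = quantiles)
  }
  if (!is.null(out$TN) && !is.null(out$TP))
    out$critical <- critical_values(out$TN, out$TP)
  out
}

#' @rdname cnd
#' @export
parts_guava <- function() c("N", "P", "K", "Ca", "Mg", "S", "B", "Fv")
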