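#' Confidence intervals on group balances
#'
#' Two-sided Student-t confidence intervals, one per balance (an axis-aligned
#' box in ilr space): mean +/- t(1-alpha/2, n-1) * s / sqrt(n).
#'
#' @param balances matrix of ilr coordinates for the specimens of one
#'   diagnostic group (rows = specimens, columns = balances).
#' @param alpha two-sided error rate (default 0.05).
#' @param group optional group label (e.g. \code{"TN"}).
#' @return Object of class \code{"balance_ci"}: data.frame with columns
#'   \code{balance}, \code{mean}, \code{lower}, \code{upper}, \code{n}.
#' @export
balance_ci <- function(balances, alpha = 0.05, group = NA) {
  balances <- as.matrix(balances)
  if (is.null(colnames(balances)))
    colnames(balances) <- paste0("bal", seq_len(ncol(balances)))
  n <- nrow(balances)
  if (n < 2) stop("need at least 2 specimens per group for a confidence interval")
  m <- colMeans(balances)
  s <- apply(balances, 2, stats::sd)
  half <- stats::qt(1 - alpha / 2, n - 1) * s / sqrt(n)
  out <- data.frame(balance = colnames(balances), mean = m,
                    lower = m - half, upper = m + half, n = n,
                    row.names = NULL)
  attr(out, "group") <- group
  attr(out, "alpha") <- alpha
  class(out) <- c("balance_ci", "data.frame")
  out
}

#' Monte-Carlo nutrient concentration ranges
#'
#' Samples balance vectors coordinate-wise uniformly over the confidence-
#' interval box, back-transforms every draw to concentrations, and reports
#' the per-nutrient extremes; the reported mean is the back-transform of the
#' interval means (the group centroid). Coordinates are sampled
#' independently — the box, not the joint confidence ellipsoid — mirroring
#' the interval-by-interval construction of the design.
#'
#' @param ci a \code{"balance_ci"} covering every balance of \code{basis},
#'   in basis row order.
#' @param basis complete \code{"ilr_basis"}.
#' @param kappa closure scale for the concentrations.
#' @param n_draws number of Monte-Carlo draws (default 100000).
#' @param seed integer seed; identical seeds give identical ranges.
#' @param quantiles optional length-2 probabilities (e.g. \code{c(.005,
#'   .995)}) to report quantiles instead of the absolute min/max, which
#'   depend on \code{n_draws}.
#' @return Object of class \code{"conc_range"}: data.frame with columns
#'   \code{part}, \code{min}, \code{mean}, \code{max} (units of the closed
#'   composition, g kg^-1 at the default scale).
#' @export
mc_conc_ranges <- function(ci, basis, kappa = 1000, n_draws = 1e5, seed = 1,
                           quantiles = NULL) {
  basis <- as_basis(basis)
  if (!basis$complete) stop("Monte-Carlo back-transformation needs a complete basis")
  R <- nrow(basis$psi)
  if (nrow(ci) != R) stop("confidence intervals must cover every balance of the basis")
  if (any(ci$lower > ci$upper)) stop("lower bound exceeds upper bound in a balance interval")
  rng <- local_rng(seed)
  u <- matrix(rng$runif(n_draws * R), n_draws, R)
  draws <- sweep(sweep(u, 2, ci$upper - ci$lower, `*`), 2, ci$lower, `+`)
  comps <- ilr_inv(draws, basis, kappa)
  centroid <- drop(ilr_inv(ci$mean, basis, kappa))
  if (is.null(quantiles)) {
    lo <- apply(comps, 2, min); hi <- apply(comps, 2, max)
  } else {
    q <- apply(comps, 2, stats::quantile, probs = sort(quantiles))
    lo <- q[1, ]; hi <- q[2, ]
  }
  out <- data.frame(part = basis$parts, min = pmin(lo, centroid),
                    mean = centroid, max = pmax(hi, centroid), row.names = NULL)
  attr(out, "group") <- attr(ci, "group")
  attr(out, "n_draws") <- n_draws
  class(out) <- c("conc_range", "data.frame")
  out
}

#' Critical concentration values between diagnostic groups
#'
#' A nutrient admits an apparent critical value only where the TN (balanced,
#' high-yield) and TP (misbalanced, low-yield) concentration ranges do not
#' overlap; the value is then placed in the gap between the facing bounds —
#' at its midpoint by default, or at the TN-facing bound.
#'
#' @param tn,tp \code{"conc_range"} objects over the same parts.
#' @param method \code{"midpoint"} (default) or \code{"facing"} (the TN bound
#'   facing the gap).
#' @return data.frame with columns \code{part}, \code{critical} (\code{NA}
#'   where ranges overlap), and the facing bounds.
#' @export
critical_values <- function(tn, tp, method = c("midpoint", "facing")) {
  method <- match.arg(method)
  if (!setequal(tn$part, tp$part)) stop("TN and TP ranges cover different parts")
  tp <- tp[match(tn$part, tp$part), ]
  out <- data.frame(part = tn$part, critical = NA_real_,
                    tn_bound = NA_real_, tp_bound = NA_real_)
  for (i in seq_len(nrow(tn))) {
    if (tp$max[i] < tn$min[i]) {        # TP below TN
      out$tn_bound[i] <- tn$min[i]; out$tp_bound[i] <- tp$max[i]
    } else if (tn$max[i] < tp$min[i]) { # TP above TN
      out$tn_bound[i] <- tn$max[i]; out$tp_bound[i] <- tp$min[i]
    } else next
    out$critical[i] <- switch(method,
      midpoint = (out$tn_bound[i] + out$tp_bound[i]) / 2,
      facing = out$tn_bound[i])
  }
  out
}

#' N/P (Redfield) ratio range
#'
#' Summarizes the nitrogen-to-phosphorus concentration ratio — a proxy for
#' protein synthesis vs. energy requirements — across specimens or
#' Monte-Carlo draws. The ratio is invariant to the closure scale.
#'
#' @param x composition matrix (or vector) containing parts \code{N} and
#'   \code{P}.
#' @return Named vector \code{c(min, max)}.
#' @export
np_ratio_range <- function(x) {
  if (!is.matrix(x) && !is.data.frame(x)) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (!all(c("N", "P") %in% colnames(x))) stop("need parts 'N' and 'P'")
  r <- x[, "N"] / x[, "P"]
  c(min = min(r), max = max(r))
}
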