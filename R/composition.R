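#' Close a composition to a constant sum
#'
#' Tissue nutrient data carry only relative information: concentrations are
#' constrained to the measurement scale kappa (1000 g kg^-1 dry mass by
#' default). Closure rescales strictly positive values proportionally so they
#' sum to kappa.
#'
#' @param x numeric vector of positive values, or a matrix with one
#'   composition per row (named columns = parts).
#' @param kappa closure constant, > 0.
#' @return Same shape as \code{x}, each composition summing to \code{kappa}.
#' @examples
#' close_comp(c(N = 2, P = 3, K = 5), kappa = 100)
#' @export
close_comp <- function(x, kappa = 1000) {
  if (kappa <= 0) stop("'kappa' must be > 0")
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    check_positive(x)
    return(x * (kappa / rowSums(x)))
  }
  if (length(x) == 0) stop("empty composition")
  check_positive(x)
  x * (kappa / sum(x))
}

check_positive <- function(x) {
  if (length(x) == 0) stop("empty composition")
  if (anyNA(x)) stop("missing values in composition")
  bad <- which(x <= 0)
  if (length(bad)) {
    nm <- if (is.matrix(x)) colnames(x)[((bad[1] - 1) %/% nrow(x)) + 1] else names(x)[bad[1]]
    stop(sprintf("nonpositive value in part '%s'",
                 if (is.null(nm) || is.na(nm)) as.character(bad[1]) else nm))
  }
  invisible(TRUE)
}

#' Append the filling value to measured concentrations
#'
#' The filling value Fv is the difference between the measurement scale and
#' the sum of analyzed nutrients; it closes the composition to kappa without
#' rescaling the measured values. Parts listed in \code{mg_parts} (boron by
#' default) are converted from mg kg^-1 to g kg^-1 before summation — the
#' usual unit mix in tissue reports.
#'
#' @param measured named numeric vector, or matrix/data.frame with one
#'   specimen per row; macro nutrients in g kg^-1.
#' @param kappa measurement scale (default 1000 g kg^-1).
#' @param mg_parts names of parts reported in mg kg^-1 (default \code{"B"});
#'   set \code{character(0)} if everything is already in g kg^-1.
#' @param fv name of the appended filling-value part.
#' @return Vector or matrix including the \code{fv} part, summing to kappa.
#' @examples
#' filling_value(c(N = 12.2, P = 2.2, K = 2.42, Ca = 0.86, Mg = 0.96,
#'                 S = 1.26, B = 10.8))
#' @export
filling_value <- function(measured, kappa = 1000, mg_parts = "B", fv = "Fv") {
  if (is.matrix(measured) || is.data.frame(measured)) {
    m <- as.matrix(measured)
    conv <- intersect(colnames(m), mg_parts)
    m[, conv] <- m[, conv] / 1000
    check_positive(m)
    s <- rowSums(m)
    if (any(s >= kappa))
      stop(sprintf("measured parts sum to >= kappa in row %d; check units (mg vs g kg^-1)",
                   which(s >= kappa)[1]))
    out <- cbind(m, s)
    colnames(out)[ncol(out)] <- fv
    out[, fv] <- kappa - s
    return(out)
  }
  m <- measured
  conv <- intersect(names(m), mg_parts)
  m[conv] <- m[conv] / 1000
  check_positive(m)
  s <- sum(m)
  if (s >= kappa)
    stop("measured parts sum to >= kappa; check units (mg vs g kg^-1)")
  c(m, stats::setNames(kappa - s, fv))
}

as_comp_matrix <- function(x, parts) {
  if (!is.matrix(x) && !is.data.frame(x)) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  missing <- setdiff(parts, colnames(x))
  if (length(missing))
    stop("composition lacks part(s): ", paste(missing, collapse = ", "))
  x <- x[, parts, drop = FALSE]
  check_positive(x)
  x
}

#' Isometric log-ratio coordinates of compositions
#'
#' Projects compositions into the Euclidean space of balances defined by an
#' SBP-derived orthonormal basis. Coordinate j is
#' \code{a_j * ln(g(numerator)/g(denominator))}; it increases when the
#' numerator geometric mean grows and is invariant to the closure scale.
#'
#' @param x composition vector or matrix (rows = specimens) with named parts
#'   covering the basis parts; extra parts are ignored.
#' @param basis an \code{"ilr_basis"} (or an \code{"sbp"}, converted on the
#'   fly).
#' @return Matrix of ilr coordinates (rows = specimens, columns = balance
#'   labels); a vector input returns a 1-row matrix.
#' @examples
#' b <- ilr_basis(sbp_table(rbind(c(1, -1)), parts = c("N", "P")))
#' ilr(c(N = 12.2, P = 2.2), b)   # sqrt(1/2) * log(12.2/2.2)
#' @export
ilr <- function(x, basis) {
  basis <- as_basis(basis)
  m <- as_comp_matrix(x, basis$parts)
  out <- log(m) %*% t(basis$psi)
  colnames(out) <- basis$labels
  out
}

as_basis <- function(basis) {
  if (inherits(basis, "ilr_basis")) basis else ilr_basis(basis)
}

#' Back-transform balances to concentrations
#'
#' Inverse of \code{\link{ilr}}: \code{close(exp(t(psi) \%*\% b), kappa)}.
#' Requires a complete basis (D-1 balances); a partial design does not
#' determine the composition.
#'
#' @param b numeric vector of balance coordinates, or matrix with one
#'   coordinate vector per row.
#' @param basis complete \code{"ilr_basis"}.
#' @param kappa closure constant for the returned concentrations.
#' @return Composition matrix (rows = inputs) closed to \code{kappa}.
#' @examples
#' bs <- ilr_basis(sbp_guava())
#' ilr_inv(rep(0, 7), bs)   # uniform composition 125 per part
#' @export
ilr_inv <- function(b, basis, kappa = 1000) {
  basis <- as_basis(basis)
  if (!basis$complete)
    stop("back-transform needs a complete SBP (D-1 balances); this basis is partial")
  if (!is.matrix(b)) b <- matrix(b, 1)
  if (ncol(b) != nrow(basis$psi)) stop("coordinate dimension does not match basis")
  close_comp(exp(b %*% basis$psi), kappa)
}

#' Compositional mean
#'
#' The centroid of a set of compositions: arithmetic mean in ilr space,
#' back-transformed to concentrations. Equals the closed per-part geometric
#' mean and does not depend on which complete SBP is used.
#'
#' @param x composition matrix, one specimen per row.
#' @inheritParams ilr_inv
#' @return Named composition vector closed to \code{kappa}.
#' @export
comp_mean <- function(x, basis, kappa = 1000) {
  basis <- as_basis(basis)
  b <- ilr(x, basis)
  if (nrow(b) < 1) stop("need at least one composition")
  drop(ilr_inv(colMeans(b), basis, kappa))
}

#' Aitchison distance between compositions
#'
#' Euclidean distance between ilr coordinates; identical for every complete
#' SBP of the same parts (the ilr map is an isometry).
#'
#' @param p,q compositions (named vectors) over the basis parts.
#' @param basis complete \code{"ilr_basis"}.
#' @return Nonnegative scalar.
#' @export
aitchison_dist <- function(p, q, basis) {
  basis <- as_basis(basis)
  if (!basis$complete) stop("Aitchison distance needs a complete basis")
  sqrt(sum((ilr(p, basis) - ilr(q, basis))^2))
}
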