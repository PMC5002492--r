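#' Sequential binary partition tables
#'
#' A sequential binary partition (SBP) encodes a system of nutrient balances:
#' each row contrasts a numerator group of parts (coded \code{+1}) against a
#' denominator group (coded \code{-1}); parts coded \code{0} are excluded from
#' that balance. Rows must be mutually compatible: the nonzero parts of any row
#' are either disjoint from those of another row, or contained entirely within
#' the numerator or the denominator group of that row, so that the rows form a
#' nested (laminar) hierarchy of splits. A \emph{complete} SBP over D parts has
#' D-1 rows, its root split uses every part, and every group of two or more
#' parts is itself split by exactly one row, which is the condition under which
#' the derived ilr basis is orthonormal and invertible.
#'
#' @param codes numeric matrix with one row per balance and one column per
#'   part; entries in \{-1, 0, 1\}. Column names are the part names.
#' @param parts optional character vector of part names overriding
#'   \code{colnames(codes)}.
#' @return An object of class \code{"sbp"}: the validated code matrix with row
#'   names in \code{"[denominator | numerator]"} notation and attribute
#'   \code{complete}.
#' @examples
#' sbp_table(rbind(c(1, -1, 0), c(1, 1, -1)), parts = c("N", "P", "K"))
#' @export
sbp_table <- function(codes, parts = colnames(codes)) {
  codes <- as.matrix(codes)
  if (is.null(parts)) stop("part names are required (colnames(codes) or 'parts')")
  if (length(parts) != ncol(codes)) stop("'parts' length must match ncol(codes)")
  if (anyDuplicated(parts)) stop("duplicated part names")
  if (!all(codes %in% c(-1, 0, 1))) stop("SBP codes must be -1, 0 or 1")
  colnames(codes) <- parts
  validate_sbp(codes)
  rownames(codes) <- apply(codes, 1, balance_label, parts = parts)
  structure(codes, class = "sbp", complete = sbp_is_complete(codes))
}

balance_label <- function(row, parts) {
  paste0("[", paste(parts[row == -1], collapse = ","), " | ",
         paste(parts[row == 1], collapse = ","), "]")
}

# laminar-hierarchy validation; stops naming the first offending row
validate_sbp <- function(codes) {
  R <- nrow(codes)
  if (R < 1) stop("SBP needs at least one row")
  for (j in seq_len(R)) {
    if (!any(codes[j, ] == 1) || !any(codes[j, ] == -1))
      stop(sprintf("SBP row %d must have at least one +1 and one -1 code", j))
  }
  if (anyDuplicated(codes)) stop("duplicated SBP rows")
  nz <- lapply(seq_len(R), function(j) which(codes[j, ] != 0))
  for (j in seq_len(R)[-1]) {
    for (i in seq_len(j - 1)) {
      zi <- nz[[i]]; zj <- nz[[j]]
      if (length(intersect(zi, zj)) == 0) next
      ok <- in_side(zj, codes[i, ]) || in_side(zi, codes[j, ])
      if (!ok)
        stop(sprintf(
          "SBP row %d is not a sequential refinement: its parts overlap row %d without nesting in its numerator or denominator group",
          j, i))
    }
  }
  invisible(TRUE)
}

in_side <- function(z, code_row) {
  all(code_row[z] == 1) || all(code_row[z] == -1)
}

sbp_is_complete <- function(codes) {
  D <- ncol(codes)
  if (nrow(codes) != D - 1) return(FALSE)
  nz <- lapply(seq_len(nrow(codes)), function(j) which(codes[j, ] != 0))
  sizes <- lengths(nz)
  root <- which(sizes == D)
  if (length(root) != 1) return(FALSE)
  # every group of >= 2 parts appearing as a side must be split by exactly one row
  key <- vapply(nz, function(z) paste(sort(z), collapse = ","), "")
  for (j in seq_len(nrow(codes))) {
    for (s in c(1, -1)) {
      grp <- which(codes[j, ] == s)
      if (length(grp) >= 2) {
        hit <- sum(key == paste(sort(grp), collapse = ","))
        if (hit != 1) return(FALSE)
      }
    }
  }
  TRUE
}

#' @export
print.sbp <- function(x, ...) {
  cat(sprintf("Sequential binary partition: %d balance(s) over %d parts (%s)\n",
              nrow(x), ncol(x), if (attr(x, "complete")) "complete" else "partial"))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Default balance design for guava tissue diagnosis
#'
#' The packaged SBP contrasts six macronutrients, boron and the filling value
#' Fv (the unanalyzed remainder of tissue dry mass): protein synthesis vs.
#' energy through \code{[P | N]}, the K-Mg cation competition, mobile
#' (N,P,K,Mg) vs. the immobile S then Ca,B groups, \code{[B | Ca]}, and
#' nutrient accumulation vs. dilution through \code{[Fv | nutrients]}. The
#' seven rows form a complete SBP of the eight parts, so the basis is
#' invertible; \code{complete = FALSE} returns the six-row variant without the
#' \code{[Ca,B | N,P,K,Mg,S]} split (forward ilr only).
#'
#' @param complete logical; return the invertible 7-balance design (default)
#'   or the 6-balance partial variant.
#' @return An \code{"sbp"} object over parts N, P, K, Ca, Mg, S, B, Fv.
#' @examples
#' sbp_guava()
#' @export
sbp_guava <- function(complete = TRUE) {
  parts <- c("N", "P", "K", "Ca", "Mg", "S", "B", "Fv")
  rows <- rbind(
    c( 1, -1,  0,  0,  0,  0,  0,  0),   # [P | N]
    c( 0,  0,  1,  0, -1,  0,  0,  0),   # [Mg | K]
    c(-1, -1,  1,  0,  1,  0,  0,  0),   # [N,P | K,Mg]
    c( 1,  1,  1,  0,  1, -1,  0,  0),   # [S | N,P,K,Mg]
    c( 1,  1,  1, -1,  1,  1, -1,  0),   # [Ca,B | N,P,K,Mg,S]
    c( 0,  0,  0,  1,  0,  0, -1,  0),   # [B | Ca]
    c( 1,  1,  1,  1,  1,  1,  1, -1))   # [Fv | N,P,K,Ca,Mg,S,B]
  if (!complete) rows <- rows[-5, , drop = FALSE]
  sbp_table(rows, parts = parts)
}

#' Orthonormal ilr basis from an SBP
#'
#' Row j of the contrast matrix carries \code{+a_j/n_j+} on numerator parts
#' and \code{-a_j/n_j-} on denominator parts, with normalization coefficient
#' \code{a_j = sqrt(n_j+ * n_j- / (n_j+ + n_j-))}, so that each ilr coordinate
#' equals \code{a_j * ln(g(numerator)/g(denominator))} with \code{g} the
#' geometric mean. Rows sum to zero and are mutually orthogonal; for a
#' complete SBP the basis satisfies \code{psi \%*\% t(psi) = I}.
#'
#' @param sbp an \code{"sbp"} object (or a code matrix accepted by
#'   \code{\link{sbp_table}}).
#' @return Object of class \code{"ilr_basis"}: list with \code{psi} (R x D
#'   contrast matrix), \code{coef} (the a_j), \code{parts}, \code{labels},
#'   \code{complete} and the originating \code{sbp}.
#' @examples
#' b <- ilr_basis(sbp_guava())
#' round(b$psi %*% t(b$psi), 12)   # identity
#' @export
ilr_basis <- function(sbp) {
  if (!inherits(sbp, "sbp")) sbp <- sbp_table(sbp)
  R <- nrow(sbp); D <- ncol(sbp)
  psi <- matrix(0, R, D, dimnames = dimnames(sbp))
  a <- numeric(R)
  for (j in seq_len(R)) {
    np <- sum(sbp[j, ] == 1); nm <- sum(sbp[j, ] == -1)
    a[j] <- sqrt(np * nm / (np + nm))
    psi[j, sbp[j, ] == 1] <- a[j] / np
    psi[j, sbp[j, ] == -1] <- -a[j] / nm
  }
  structure(list(psi = psi, coef = a, parts = colnames(sbp),
                 labels = rownames(sbp), complete = attr(sbp, "complete"),
                 sbp = sbp),
            class = "ilr_basis")
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat(sprintf("ilr basis: %d balance(s), %d parts (%s)\n",
              nrow(x$psi), length(x$parts),
              if (x$complete) "complete, invertible" else "partial, forward only"))
  print(round(x$psi, 4))
  invisible(x)
}

#' Number of possible sequential binary partitions
#'
#' Counts the ordered sequences of binary splits that fully resolve a
#' D-part composition: \code{D! (D-1)! / 2^(D-1)}.
#'
#' @param D integer number of parts, \code{D >= 2}.
#' @return The count as a double (exact for the D of practical interest).
#' @examples
#' count_sbps(4)  # 18
#' @export
count_sbps <- function(D) {
  if (length(D) != 1 || D < 2 || D != round(D)) stop("'D' must be an integer >= 2")
  factorial(D) * factorial(D - 1) / 2^(D - 1)
}

#' Read / write SBP tables as CSV
#'
#' Layout: header of part names, one row per balance, entries in \{-1,0,1\};
#' an optional first column \code{label} is ignored on read (labels are
#' regenerated from the codes).
#'
#' @param path file path.
#' @param sbp an \code{"sbp"} object (for writing).
#' @return \code{read_sbp} returns an \code{"sbp"} object.
#' @export
read_sbp <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] %in% c("label", "balance")) df <- df[, -1, drop = FALSE]
  sbp_table(as.matrix(df))
}

#' @rdname read_sbp
#' @export
write_sbp <- function(sbp, path) {
  df <- data.frame(label = rownames(sbp), unclass(sbp), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
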