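#' Positive semidefiniteness test
#'
#' @param A square symmetric numeric matrix (symmetry checked to
#'   `sym_tol`; worse inputs are rejected, not silently symmetrized).
#' @param tol eigenvalue tolerance: PSD means smallest eigenvalue
#'   `>= -tol`.
#' @param sym_tol maximum allowed asymmetry `max|A - t(A)|`.
#' @return logical scalar.
#' @export
is_psd <- function(A, tol = 1e-8, sym_tol = 1e-8) {
  A <- check_square_symmetric(A, sym_tol)
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol
}

check_square_symmetric <- function(A, sym_tol = 1e-8) {
  A <- unclass(as.matrix(A))
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  if (!all(is.finite(A))) stop("matrix contains non-finite entries")
  if (max(abs(A - t(A))) > sym_tol)
    stop("matrix is not symmetric within tolerance ", sym_tol)
  A
}

#' Nearest positive semidefinite matrix (Frobenius norm)
#'
#' Projects a symmetric matrix onto the PSD cone by eigenvalue clipping:
#' symmetrize as `(A + t(A))/2`, eigendecompose, set negative eigenvalues
#' to zero, reconstruct. Among symmetric PSD matrices this minimizes the
#' Frobenius distance to the symmetrized input. If finite-precision
#' round-off leaves a marginally negative eigenvalue, a minimal diagonal
#' jitter is added and the clip repeated. The unit diagonal of a
#' correlation matrix is deliberately NOT restored (the downstream
#' eigen-analysis consumes the clipped matrix as-is); any diagonal drift
#' is reported via the `diag_drift` attribute.
#'
#' @param A square numeric matrix with finite entries.
#' @return the projected matrix; for `assoc_matrix` input the `method`
#'   attribute is carried over and `repaired = TRUE` is set.
#' @export
nearest_psd <- function(A) {
  method <- attr(A, "method")
  ids <- rownames(A)
  A <- unclass(as.matrix(A))
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  if (!all(is.finite(A))) stop("matrix contains non-finite entries")
  S <- (A + t(A)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= 0) {
    out <- S
  } else {
    lam <- pmax(e$values, 0)
    out <- e$vectors %*% (lam * t(e$vectors))
    out <- (out + t(out)) / 2
    # guard against round-off reintroducing tiny negative mass
    k <- 0L
    while (k < 10L) {
      mn <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
      if (mn >= -1e-12 * max(1, max(abs(out)))) break
      out <- out + diag(2 * abs(mn), nrow(out))
      k <- k + 1L
    }
  }
  dimnames(out) <- list(ids, ids)
  drift <- max(abs(diag(out) - diag(S)))
  structure(out,
            method = method,
            repaired = TRUE,
            diag_drift = drift,
            class = c("assoc_matrix", "matrix", "array"))
}

#' Eigenvalue spectrum of an association matrix
#'
#' Full symmetric eigendecomposition with small-eigenvalue flooring:
#' eigenvalues below `floor` (default 1e-12) are set to zero. Values are
#' returned sorted in decreasing order (the cumulative-variance rule
#' needs the largest first).
#'
#' @param A square symmetric matrix (usually a repaired association
#'   matrix).
#' @param floor eigenvalues strictly below this are zeroed.
#' @param sym_tol symmetry rejection tolerance.
#' @return an `eigen_spectrum`: list with `values` (decreasing), `M`,
#'   `floor_applied` (how many eigenvalues were floored) and `floor`.
#' @export
eigen_spectrum <- function(A, floor = 1e-12, sym_tol = 1e-8) {
  A <- check_square_symmetric(A, sym_tol)
  lam <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  floored <- sum(lam < floor)
  lam[lam < floor] <- 0
  structure(list(values = sort(lam, decreasing = TRUE),
                 M = length(lam),
                 floor_applied = floored,
                 floor = floor),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("<eigen_spectrum> M = %d, floored = %d, trace = %.6g\n",
              x$M, x$floor_applied, sum(x$values)))
  invisible(x)
}

as_eigen_spectrum <- function(x) {
  if (inherits(x, "eigen_spectrum")) return(x)
  if (is.numeric(x))
    return(structure(list(values = sort(as.numeric(x), decreasing = TRUE),
                          M = length(x), floor_applied = 0L, floor = 0),
                     class = "eigen_spectrum"))
  stop("cannot interpret input as an eigenvalue spectrum")
}
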