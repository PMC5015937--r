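#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.formula coef cor cov lm model.matrix na.omit optimize
#'   pt rbinom rnorm runif sd setNames var vcov complete.cases logLik qt
#'   median resid fitted
#' @importFrom utils read.csv write.csv head
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Force a symmetric matrix to be positive definite by eigenvalue bending
#'
#' Eigenvalues below `floor_frac * mean(diag(M))` are raised to that floor and
#' the matrix is reconstructed. Used to keep estimated genetic and residual
#' covariance matrices inside the parameter space between REML updates, and to
#' repair correlation matrices assembled from pairwise published values.
#'
#' @param M symmetric numeric matrix.
#' @param floor_frac eigenvalue floor as a fraction of the mean diagonal.
#' @return a symmetric positive definite matrix of the same dimension.
#' @export
bend_pd <- function(M, floor_frac = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  floor_val <- floor_frac * max(mean(diag(M)), .Machine$double.eps)
  if (all(e$values >= floor_val)) return(M)
  vals <- pmax(e$values, floor_val)
  M2 <- e$vectors %*% (vals * t(e$vectors))
  dimnames(M2) <- dimnames(M)
  (M2 + t(M2)) / 2
}

#' Check that a matrix is a valid relationship kernel
#'
#' Validates symmetry (max |K - t(K)| below `tol`), matching row/column
#' labels, and near positive semi-definiteness (smallest eigenvalue no less
#' than -1e-8 times the largest).
#'
#' @param K square numeric matrix with line IDs as dimnames.
#' @param tol symmetry tolerance.
#' @return `K`, invisibly, after validation.
#' @export
check_relationship <- function(K, tol = 1e-8) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stopf("relationship matrix must be square")
  if (is.null(rownames(K)) || is.null(colnames(K)) ||
      !identical(rownames(K), colnames(K)))
    stopf("relationship matrix must carry identical row and column line IDs")
  asym <- max(abs(K - t(K)))
  if (asym > tol)
    stopf("relationship matrix asymmetric beyond tolerance (max |K - K'| = %g)", asym)
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev, 0) - 1e-12)
    stopf("relationship matrix is not positive semi-definite (min eigenvalue %g)", min(ev))
  invisible(K)
}

# Align a kernel to a set of line IDs by exact string match; any mismatch is
# an error, never silent dropping.
align_kernel <- function(K, ids) {
  missing_ids <- setdiff(ids, rownames(K))
  if (length(missing_ids) > 0L)
    stopf("lines absent from relationship matrix: %s",
          paste(head(missing_ids, 5L), collapse = ", "))
  K[ids, ids, drop = FALSE]
}

# Small helper: named identity kernel
identity_kernel <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  K
}
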