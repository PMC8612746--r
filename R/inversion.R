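# Spatially regularized Tikhonov pseudo-inverse of the Rytov Jacobian,
#   A# = L^-1 (Ahat^T Ahat + lambda1 I)^-1 Ahat^T,   Ahat = A L^-1,
#   diag(L) = diag(A^T A) + lambda2^2,
# evaluated in measurement space as A# = L^-2 A^T (A L^-2 A^T + lambda1 I)^-1,
# which is algebraically identical and avoids voxel-space matrices.

#' Regularization parameters
#'
#' `lambda1_rel` scales the Tikhonov parameter relative to the maximum
#' singular value of `Ahat^T Ahat`; `lambda2_rel` scales the spatially
#' variant parameter relative to the maximum singular value of `A^T A`.
#'
#' @param lambda1_rel Relative Tikhonov parameter (default 0.01).
#' @param lambda2_rel Relative spatially variant parameter (default 0.1).
#' @param form `"sqrt"` (default) uses the standard spatially variant
#'   scaling `diag(L) = sqrt(diag(A^T A) + lambda2 * max diag)`, which is
#'   homogeneous in the data scale and compensates sensitivity with depth;
#'   `"literal"` uses `diag(L) = diag(A^T A) + lambda2^2` with
#'   `lambda2 = lambda2_rel * max singular value of A^T A`, a form whose
#'   additive term dominates every diagonal entry and so degenerates to a
#'   near-uniform scaling (see the methods vignette).
#' @return A `dot_reg` list.
#' @export
regularization_params <- function(lambda1_rel = 0.01, lambda2_rel = 0.1,
                                  form = c("sqrt", "literal")) {
  if (lambda1_rel <= 0 || lambda2_rel <= 0) stop("regularization parameters must be positive")
  structure(list(lambda1_rel = lambda1_rel, lambda2_rel = lambda2_rel,
                 form = match.arg(form)), class = "dot_reg")
}

#' Largest eigenvalue of A^T A (= squared top singular value of A)
#'
#' Power iteration in voxel space with a fixed deterministic start vector;
#' no random state is consumed.
#' @keywords internal
power_max_eig <- function(A, col_weight = NULL, tol = 1e-6, max_iter = 500) {
  nv <- ncol(A)
  v <- sin(seq_len(nv)) + 1   # fixed, nonzero start
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(max_iter)) {
    u <- if (is.null(col_weight)) v else col_weight * v
    w <- as.vector(crossprod(A, A %*% u))
    if (!is.null(col_weight)) w <- col_weight * w
    lam_new <- sqrt(sum(w^2))
    if (lam_new == 0) return(0)
    v <- w / lam_new
    if (abs(lam_new - lam) <= tol * lam_new && it > 2) return(lam_new)
    lam <- lam_new
  }
  lam
}

#' Build the regularized inverse operator
#'
#' @param jacobian A `dot_jacobian` or plain numeric matrix (rows =
#'   measurements, columns = voxels).
#' @param reg A `dot_reg` from [regularization_params()].
#' @return A `dot_inverse_operator` holding the factorized measurement-space
#'   form; apply it with [reconstruct()].
#' @export
build_inverse_operator <- function(jacobian, reg = regularization_params()) {
  A <- if (inherits(jacobian, "dot_jacobian")) jacobian$J else jacobian
  if (!is.matrix(A) || nrow(A) < 1) stop("Jacobian must be a non-empty matrix")
  dAtA <- colSums(A^2)
  if (max(dAtA) == 0) stop("degenerate Jacobian: all entries zero")

  smax_AtA <- power_max_eig(A)                    # max singular value of A^T A
  if (reg$form == "literal") {
    lambda2 <- reg$lambda2_rel * smax_AtA
    ell <- dAtA + lambda2^2
  } else {
    lambda2 <- reg$lambda2_rel
    ell <- sqrt(dAtA + lambda2 * max(dAtA))
  }
  wL2 <- 1 / ell^2
  smax_hat <- power_max_eig(A, col_weight = 1 / ell) # max sv of Ahat^T Ahat
  lambda1 <- reg$lambda1_rel * smax_hat

  M <- A %*% (wL2 * t(A))
  diag(M) <- diag(M) + lambda1
  R <- chol(M)
  structure(list(A = A, wL2 = wL2, ell = ell, chol = R, lambda1 = lambda1,
                 lambda2 = lambda2, reg = reg,
                 frequency = if (inherits(jacobian, "dot_jacobian")) jacobian$frequency else NA,
                 wavelength = if (inherits(jacobian, "dot_jacobian")) jacobian$wavelength else NA,
                 n_rows = nrow(A), n_voxels = ncol(A)),
            class = "dot_inverse_operator")
}

#' @export
print.dot_inverse_operator <- function(x, ...) {
  cat("Inverse operator:", x$n_voxels, "voxels x", x$n_rows, "rows",
      "(lambda1 =", signif(x$lambda1, 4), ", lambda2 =", signif(x$lambda2, 4), ")\n")
  invisible(x)
}

#' Reconstruct absorption-perturbation images from measurement data
#'
#' Applies the regularized pseudo-inverse: `x = A# y`. Accepts a matrix of
#' column vectors for batched reconstruction.
#'
#' @param op A `dot_inverse_operator`.
#' @param y Measurement vector (length = operator rows) or matrix (rows =
#'   operator rows).
#' @return Voxel vector (or matrix, one column per input column) over the
#'   ROI.
#' @export
reconstruct <- function(op, y) {
  y <- as.matrix(y)
  if (nrow(y) != op$n_rows) {
    stop("contract error: y has ", nrow(y), " rows, operator expects ", op$n_rows)
  }
  t_ <- backsolve(op$chol, forwardsolve(t(op$chol), y))
  x <- op$wL2 * crossprod(op$A, t_)
  if (ncol(x) == 1L) drop(x) else x
}

#' Dense literal evaluation of the regularized pseudo-inverse
#'
#' Voxel-space form `A# = L^-1 (Ahat^T Ahat + lambda1 I)^-1 Ahat^T`
#' evaluated with dense linear algebra. Quadratic in the voxel count, so
#' only usable on small systems; retained as the reference the fast
#' measurement-space operator is checked against.
#'
#' @param A Numeric matrix.
#' @param reg A `dot_reg`.
#' @param ell,lambda1 Optional precomputed voxel scaling diag(L) and
#'   Tikhonov parameter; when supplied, the literal form is evaluated at
#'   exactly those values (so the check isolates the pseudo-inverse algebra
#'   from the eigenvalue estimation); when NULL they are recomputed with
#'   dense eigendecompositions.
#' @return The dense `A#` matrix (voxels x rows).
#' @export
pseudo_inverse_literal <- function(A, reg = regularization_params(),
                                   ell = NULL, lambda1 = NULL) {
  dAtA <- colSums(A^2)
  if (is.null(ell)) {
    smax_AtA <- max(eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values)
    if (reg$form == "literal") {
      lambda2 <- reg$lambda2_rel * smax_AtA
      ell <- dAtA + lambda2^2
    } else {
      ell <- sqrt(dAtA + reg$lambda2_rel * max(dAtA))
    }
  }
  Ahat <- sweep(A, 2, ell, "/")
  AtA_hat <- crossprod(Ahat)
  if (is.null(lambda1)) {
    lambda1 <- reg$lambda1_rel *
      max(eigen(AtA_hat, symmetric = TRUE, only.values = TRUE)$values)
  }
  diag(1 / ell) %*% solve(AtA_hat + diag(lambda1, ncol(A)), t(Ahat))
}
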