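# Per-voxel diffusion tensor estimation and scalar metric derivation.
#
# The fitting chain is: log-linear ordinary least squares on ln(S) as the
# initializer, refined by Levenberg-Marquardt nonlinear least squares on the
# raw signals, then symmetric eigendecomposition and FA/MD/AD/RD.

# Design matrix for the log-linearised model
#   ln S = ln S0 - b g^T D g
# with parameter order (ln S0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
dti_design <- function(scheme) {
  g <- scheme$bvecs; b <- scheme$bvals
  cbind(1,
        -b * g[, 1]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -b * g[, 2]^2,
        -2 * b * g[, 2] * g[, 3],
        -b * g[, 3]^2)
}

tensor_fit <- function(d, s0_est, residual_sse, converged, n_iter) {
  names(d) <- c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")
  structure(list(d = d, s0_est = s0_est, residual_sse = residual_sse,
                 converged = converged, n_iter = n_iter),
            class = "tensor_fit")
}

#' Reconstruct the symmetric 3x3 tensor matrix
#'
#' @param fit A `tensor_fit` object or a length-6 numeric vector in
#'   component order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @return A symmetric 3x3 matrix in mm^2/s.
#' @export
tensor_matrix <- function(fit) {
  d <- if (inherits(fit, "tensor_fit")) fit$d else as.numeric(fit)
  matrix(c(d[1], d[2], d[3],
           d[2], d[4], d[5],
           d[3], d[5], d[6]), 3L, 3L)
}

# Nonlinear (signal-domain) sum of squared residuals for a parameter vector
# p = (s0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz); Xd is design[, -1].
nlls_sse <- function(p, signals, Xd) {
  sum((signals - p[1] * exp(Xd %*% p[-1]))^2)
}

#' Log-linear (OLS) tensor fit
#'
#' Fits the diffusion tensor by ordinary least squares of `ln(S)` on the
#' 7-column design implied by the Stejskal-Tanner model. This is exact for
#' noise-free data and is the standard initializer for the nonlinear fit.
#' Signals at or below zero (possible for magnitude data under noise) are
#' floored at `1e-6` times the mean b = 0 signal before the log transform.
#'
#' @param signals Numeric signal vector, one entry per scheme volume.
#' @param scheme An [acquisition_scheme()]; must contain at least 7 volumes
#'   of which at least one has b = 0.
#' @return A `tensor_fit`: list with `d` (6 tensor components, mm^2/s),
#'   `s0_est`, `residual_sse` (sum of squared residuals under the
#'   signal-domain nonlinear objective, so it is directly comparable with
#'   [fit_nlls()]), `converged`, `n_iter`.
#' @export
fit_loglinear <- function(signals, scheme) {
  signals <- as.numeric(signals)
  if (length(signals) != length(scheme$bvals))
    stop_data("signal vector length does not match the scheme")
  if (any(!is.finite(signals))) stop_data("signals contain non-finite values")
  if (length(signals) < 7L)
    stop_data("at least 7 measurements are required to identify the tensor")
  b0 <- scheme$bvals == 0
  if (!any(b0)) stop_data("at least one b = 0 measurement is required")
  eps <- 1e-6 * mean(signals[b0])
  if (!is.finite(eps) || eps <= 0) eps <- .Machine$double.eps
  X <- dti_design(scheme)
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop_data("degenerate gradient direction set: design matrix is rank ",
              qrX$rank, " < 7")
  beta <- qr.coef(qrX, log(pmax(signals, eps)))
  d <- unname(beta[-1])
  s0 <- exp(unname(beta[1]))
  sse <- nlls_sse(c(s0, d), signals, X[, -1, drop = FALSE])
  tensor_fit(d, s0, sse, converged = TRUE, n_iter = 0L)
}

#' Nonlinear least-squares tensor fit
#'
#' Minimizes the signal-domain objective
#' \eqn{\sum_i (S_i - S_0 \exp(-b_i g_i^T D g_i))^2} jointly over the six
#' tensor components and \eqn{S_0} with the Levenberg-Marquardt algorithm
#' (analytic Jacobian, tolerances 1e-10, at most `max_iter` iterations).
#' The returned objective is never worse than that of the initializer: if
#' the optimizer fails to improve, the initializer is returned with
#' `converged = FALSE`. Non-convergence never raises an error.
#'
#' @inheritParams fit_loglinear
#' @param init Initial `tensor_fit`; defaults to [fit_loglinear()].
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A `tensor_fit` (see [fit_loglinear()] for fields).
#' @export
fit_nlls <- function(signals, scheme, init = NULL, max_iter = 200L) {
  signals <- as.numeric(signals)
  if (any(!is.finite(signals))) stop_data("signals contain non-finite values")
  if (is.null(init)) init <- fit_loglinear(signals, scheme)
  Xd <- dti_design(scheme)[, -1, drop = FALSE]
  p0 <- c(init$s0_est, init$d)
  resid_fn <- function(p) signals - p[1] * exp(Xd %*% p[-1])
  jac_fn <- function(p) {
    e <- as.vector(exp(Xd %*% p[-1]))
    cbind(-e, -p[1] * e * Xd)
  }
  out <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = as.integer(max_iter), ftol = 1e-10, ptol = 1e-10,
      gtol = 1e-10))
  p <- out$par
  sse <- nlls_sse(p, signals, Xd)
  init_sse <- nlls_sse(p0, signals, Xd)
  converged <- out$info %in% c(1L, 2L, 3L, 4L)
  if (!is.finite(sse) || sse > init_sse) {
    # Defensive: LM should never worsen the objective, but guarantee it.
    return(tensor_fit(init$d, init$s0_est, init_sse,
                      converged = FALSE, n_iter = out$niter))
  }
  tensor_fit(unname(p[-1]), unname(p[1]), sse, converged, out$niter)
}

#' Symmetric eigendecomposition of a tensor fit
#'
#' Eigenvalues are returned sorted in non-increasing order; negative
#' eigenvalues (possible for noisy fits) are passed through unchanged here
#' and only clamped at metric-derivation time inside [fit_volume()].
#' Eigenvector signs follow the convention that the first non-zero
#' component of each vector is non-negative, for deterministic output.
#'
#' @param fit A `tensor_fit`, a symmetric 3x3 matrix, or 6 components in
#'   order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @return List of class `eigen_system` with `values` (length 3, sorted
#'   descending) and `vectors` (3x3 orthonormal, columns matching values).
#' @export
eigensystem <- function(fit) {
  M <- if (is.matrix(fit)) fit else tensor_matrix(fit)
  if (any(!is.finite(M))) stop_data("tensor components must be finite")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (j in 1:3) {
    nz <- which(abs(V[, j]) > 1e-12)
    if (length(nz) && V[nz[1], j] < 0) V[, j] <- -V[, j]
  }
  structure(list(values = e$values, vectors = V), class = "eigen_system")
}

#' Scalar diffusion metrics from eigenvalues
#'
#' Derives the four standard DTI metrics from sorted tensor eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}:
#' \itemize{
#'   \item AD (axial diffusivity) \eqn{= \lambda_1}
#'   \item RD (radial diffusivity) \eqn{= (\lambda_2 + \lambda_3)/2}
#'   \item MD (mean diffusivity) \eqn{= (AD + 2\,RD)/3}, computed in exactly
#'     that form so the identity holds to the last bit
#'   \item FA \eqn{= \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i - \bar\lambda)^2} /
#'     \sqrt{\sum_i \lambda_i^2}}, with FA defined as 0 for the all-zero
#'     tensor. FA is 0 for an isotropic tensor (a sphere) and 1 at the
#'     theoretical maximum of anisotropy (a single non-zero eigenvalue).
#' }
#' When all eigenvalues are non-negative, FA is clamped into `[0, 1]`
#' against floating-point overshoot.
#'
#' @param eig An `eigen_system` from [eigensystem()], or a numeric vector of
#'   3 eigenvalues sorted in non-increasing order (mm^2/s).
#' @return Named list with `fa` (dimensionless), `md`, `ad`, `rd` (mm^2/s).
#' @examples
#' scalar_metrics(c(1.7e-3, 0.3e-3, 0.2e-3))
#' @export
scalar_metrics <- function(eig) {
  l <- if (inherits(eig, "eigen_system")) eig$values else as.numeric(eig)
  if (length(l) != 3L || any(!is.finite(l)))
    stop_data("three finite eigenvalues are required")
  if (l[1] < l[2] - 1e-15 || l[2] < l[3] - 1e-15)
    stop_data("eigenvalues must be sorted in non-increasing order")
  ad <- l[1]
  rd <- (l[2] + l[3]) / 2
  md <- (ad + 2 * rd) / 3
  ss <- l[1]^2 + l[2]^2 + l[3]^2
  if (ss == 0) {
    fa <- 0
  } else {
    fa <- sqrt(1.5 * ((l[1] - md)^2 + (l[2] - md)^2 + (l[3] - md)^2) / ss)
    if (all(l >= 0)) fa <- min(max(fa, 0), 1)
  }
  list(fa = fa, md = md, ad = ad, rd = rd)
}

#' Fit tensors over a 4D volume and derive scalar maps
#'
#' Applies the full per-voxel chain (log-linear initializer, nonlinear
#' refinement, eigendecomposition, scalar metrics) to every voxel inside a
#' mask. Negative eigenvalues are clamped to 0 for metric derivation only;
#' the stored tensor field keeps the unclamped estimates. Voxels outside
#' the mask are 0 in every output.
#'
#' The default mask keeps voxels whose mean b = 0 signal exceeds 10% of the
#' volume-wise 99th percentile of mean b = 0 signal, a deterministic rule
#' that removes background air in the absence of an anatomical mask.
#'
#' @param dwi 4D numeric array (x, y, z, volume); the 4th extent must equal
#'   the scheme length.
#' @param scheme An [acquisition_scheme()].
#' @param mask Optional logical 3D array; `NULL` for the default b0 mask.
#' @param method `"nlls"` (default; log-linear initialization refined by
#'   Levenberg-Marquardt) or `"loglinear"` (initializer only).
#' @return List with 3D arrays `fa`, `md`, `ad`, `rd`, `s0`, the logical
#'   `mask` used, a 4D `tensor` array with 6 components per voxel in order
#'   (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), and `n_nonconverged`, the count of
#'   masked voxels whose nonlinear fit did not meet the convergence
#'   tolerance.
#' @export
fit_volume <- function(dwi, scheme, mask = NULL,
                       method = c("nlls", "loglinear")) {
  method <- match.arg(method)
  dims <- dim(dwi)
  if (length(dims) != 4L) stop_data("dwi must be a 4D array")
  if (dims[4] != length(scheme$bvals))
    stop_data("4th dimension of dwi (", dims[4],
              ") does not match the scheme length (", length(scheme$bvals), ")")
  grid <- dims[1:3]
  nvox <- prod(grid)
  S <- matrix(dwi, nvox, dims[4])
  b0 <- scheme$bvals == 0
  b0mean <- rowMeans(S[, b0, drop = FALSE])
  if (is.null(mask)) {
    thr <- 0.1 * stats::quantile(b0mean, 0.99, names = FALSE)
    mask <- array(b0mean > thr, dim = grid)
  } else {
    if (!identical(dim(mask), as.integer(grid)) &&
        !identical(dim(mask), grid))
      stop_data("mask shape does not match the image grid")
    mask <- array(as.logical(mask), dim = grid)
  }
  fa <- md <- ad <- rd <- s0 <- array(0, dim = grid)
  tensor <- array(0, dim = c(grid, 6L))
  tmat <- matrix(0, nvox, 6L)
  idx <- which(mask)
  n_nonconv <- 0L
  for (v in idx) {
    fit <- fit_loglinear(S[v, ], scheme)
    if (method == "nlls") {
      fit <- fit_nlls(S[v, ], scheme, init = fit)
      if (!fit$converged) n_nonconv <- n_nonconv + 1L
    }
    tmat[v, ] <- fit$d
    s0[v] <- fit$s0_est
    lam <- eigensystem(fit)$values
    m <- scalar_metrics(pmax(lam, 0))
    fa[v] <- m$fa; md[v] <- m$md; ad[v] <- m$ad; rd[v] <- m$rd
  }
  tensor[] <- tmat
  if (method == "nlls")
    message(sprintf("fit_volume: %d/%d masked voxels did not converge",
                    n_nonconv, length(idx)))
  list(fa = fa, md = md, ad = ad, rd = rd, s0 = s0, mask = mask,
       tensor = tensor, n_nonconverged = n_nonconv)
}
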