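# Diffusion acquisition schemes: b-values, gradient directions, and the
# forward Stejskal-Tanner signal model.

#' Construct an acquisition scheme
#'
#' An acquisition scheme pairs each measured volume with a diffusion
#' weighting `b` (s/mm\eqn{^2}) and a unit gradient direction. Volumes with
#' `b = 0` carry a zero direction vector.
#'
#' @param bvals Numeric vector of non-negative b-values (s/mm^2).
#' @param bvecs Numeric matrix with one row per volume and columns (x, y, z).
#'   Rows with `bvals > 0` must have unit norm (within 1e-6); rows with
#'   `bvals == 0` may be the zero vector.
#' @return An object of class `acquisition_scheme` with elements `bvals` and
#'   `bvecs`.
#' @seealso [default_scheme()], [predict_signal()]
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3L)
    stop_data("bvecs must be a length(bvals) x 3 matrix")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop_data("b-values must be finite and non-negative")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(nrm[dw] - 1) > 1e-6))
    stop_data("gradient directions must be unit vectors where b > 0")
  structure(list(bvals = bvals, bvecs = bvecs), class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("Acquisition scheme: %d volumes (%d b=0, %d diffusion-weighted, max b = %g s/mm^2)\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0),
              max(x$bvals)))
  invisible(x)
}

#' Default single-shell acquisition scheme
#'
#' Generates a deterministic single-shell scheme: `n_b0` non-diffusion
#' weighted volumes followed by `n_directions` gradient directions placed
#' approximately uniformly on the sphere by the spherical-Fibonacci lattice.
#' The default (42 directions at b = 1000 s/mm^2 plus 7 b = 0 volumes)
#' matches a clinically typical 3T protocol for test-retest DTI.
#'
#' @param n_directions Number of diffusion-weighted directions (at least 6,
#'   the minimum for tensor identifiability).
#' @param n_b0 Number of b = 0 volumes.
#' @param b Diffusion weighting in s/mm^2 for the shell.
#' @return An [acquisition_scheme()].
#' @examples
#' sch <- default_scheme(42, 7, 1000)
#' length(sch$bvals)       # 49
#' sum(sch$bvals == 0)     # 7
#' @export
default_scheme <- function(n_directions = 42L, n_b0 = 7L, b = 1000) {
  if (n_directions < 6)
    stop_data("at least 6 gradient directions are required; the tensor is ",
              "not identifiable from fewer")
  if (n_b0 < 1 || b <= 0) stop_data("n_b0 must be >= 1 and b > 0")
  i <- seq_len(n_directions) - 1
  # Spherical Fibonacci lattice: near-uniform, deterministic point set.
  golden <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i + 1) / n_directions
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * i
  dirs <- cbind(r * cos(theta), r * sin(theta), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  acquisition_scheme(c(rep(0, n_b0), rep(b, n_directions)),
                     rbind(matrix(0, n_b0, 3), dirs))
}

#' Predict diffusion-weighted signals from a tensor
#'
#' Evaluates the mono-exponential Stejskal-Tanner model
#' \eqn{S_i = S_0 \exp(-b_i\, g_i^T D g_i)} for every volume of a scheme.
#'
#' @param tensor Symmetric 3x3 diffusion tensor in mm^2/s.
#' @param s0 Positive non-diffusion-weighted signal amplitude.
#' @param scheme An [acquisition_scheme()].
#' @return Numeric signal vector, one entry per scheme volume.
#' @export
predict_signal <- function(tensor, s0, scheme) {
  tensor <- as.matrix(tensor)
  if (!all(dim(tensor) == c(3L, 3L)) || any(!is.finite(tensor)))
    stop_data("tensor must be a finite 3x3 matrix")
  if (max(abs(tensor - t(tensor))) > 1e-8 * max(abs(tensor), 1e-12))
    stop_data("tensor must be symmetric")
  if (!is.finite(s0) || s0 <= 0) stop_data("s0 must be positive")
  g <- scheme$bvecs
  q <- rowSums((g %*% tensor) * g)   # g^T D g per volume
  s0 * exp(-scheme$bvals * q)
}

#' Add Rician noise to magnitude signals
#'
#' Magnitude MR data are Rician distributed: the recorded value is the
#' modulus of the complex signal after independent Gaussian noise on the
#' real and imaginary channels, \eqn{|(s + n_1) + i\,n_2|} with
#' \eqn{n_1, n_2 \sim N(0, \sigma^2)}. At low SNR this positively biases the
#' magnitude (a zero signal has mean \eqn{\sigma\sqrt{\pi/2}}).
#'
#' Draws are taken from R's global random number generator; seed with
#' [set.seed()] for reproducibility.
#'
#' @param signal Non-negative numeric vector of noise-free magnitudes.
#' @param sigma Noise standard deviation per channel, in signal units.
#'   `sigma = 0` returns the input unchanged.
#' @return Numeric vector of noisy magnitudes, same length as `signal`.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop_data("sigma must be a single non-negative number")
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Read and write FSL-dialect gradient tables
#'
#' `write_bvalbvec()` writes the b-values as a single whitespace-separated
#' row and the gradients as three rows (x, y, z components across volumes);
#' `read_bvalbvec()` reads the same layout back into an
#' [acquisition_scheme()].
#'
#' @param scheme An [acquisition_scheme()].
#' @param bval_path,bvec_path File paths for the two text tables.
#' @return `write_bvalbvec()` returns the paths invisibly;
#'   `read_bvalbvec()` returns an [acquisition_scheme()].
#' @export
write_bvalbvec <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bvalbvec
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  if (length(rows) != 3L) stop_data("bvec file must have exactly 3 rows")
  acquisition_scheme(bvals, t(do.call(rbind, rows)))
}
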