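# Grid calculus on 2D scalar fields (plain numeric matrices, unit pixel
# spacing, row-major: x = column index, y = row index) and the smoothed
# distributional functions used by every energy term.

assert_field <- function(f, name = deparse(substitute(f)), min_dim = 3L) {
  if (!is.matrix(f) || !is.numeric(f))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (nrow(f) < min_dim || ncol(f) < min_dim)
    stop(sprintf("'%s' must be at least %dx%d", name, min_dim, min_dim),
         call. = FALSE)
  if (!all(is.finite(f)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(f)
}

assert_same_shape <- function(a, b, na = deparse(substitute(a)),
                              nb = deparse(substitute(b))) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("'%s' (%s) and '%s' (%s) must share one shape",
                 na, paste(dim(a), collapse = "x"),
                 nb, paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(NULL)
}

#' Mirror the image border so the normal derivative vanishes
#'
#' Copies the second interior row/column onto the border (first row becomes
#' the third row, etc.), the standard Neumann boundary treatment applied
#' before every finite-difference stencil in the level set evolution.
#'
#' @param f numeric matrix (at least 3x3, all finite).
#' @return a matrix of the same shape with mirrored borders.
#' @export
neumann_extend <- function(f) {
  assert_field(f)
  h <- nrow(f); w <- ncol(f)
  f[1, ] <- f[3, ]
  f[h, ] <- f[h - 2L, ]
  f[, 1] <- f[, 3]
  f[, w] <- f[, w - 2L]
  f
}

#' Gradient of a scalar field
#'
#' Central differences in the interior, one-sided differences at the
#' borders (the same stencil as MATLAB's `gradient`).  The x component
#' differentiates along columns, the y component along rows.
#'
#' @param f numeric matrix.
#' @return a list with components `x` and `y`, matrices of the shape of `f`.
#' @export
field_gradient <- function(f) {
  assert_field(f)
  h <- nrow(f); w <- ncol(f)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (f[, 3:w] - f[, 1:(w - 2)]) / 2
  gx[, 1] <- f[, 2] - f[, 1]
  gx[, w] <- f[, w] - f[, w - 1]
  gy[2:(h - 1), ] <- (f[3:h, ] - f[1:(h - 2), ]) / 2
  gy[1, ] <- f[2, ] - f[1, ]
  gy[h, ] <- f[h, ] - f[h - 1, ]
  list(x = gx, y = gy)
}

#' Divergence of a vector field
#'
#' `d vx/dx + d vy/dy` with the same stencil conventions as
#' [field_gradient()].
#'
#' @param vx,vy numeric matrices of identical shape (x and y components).
#' @return a matrix of the same shape.
#' @export
field_divergence <- function(vx, vy) {
  assert_field(vx); assert_field(vy)
  assert_same_shape(vx, vy)
  field_gradient(vx)$x + field_gradient(vy)$y
}

#' Smoothed Heaviside function
#'
#' Two differentiable step surrogates of width `eps`:
#' `"sine"` (default elsewhere in the package) is the compactly supported
#' ramp `0.5 * (1 + x/eps + sin(pi*x/eps)/pi)` clamped to 0 below `-eps`
#' and 1 above `+eps`; `"arctan"` is
#' `0.5 * (1 + (2/pi) * atan(x/eps))`, positive on all of the real line.
#'
#' @param x numeric vector or matrix.
#' @param eps positive width of the smoothed step.
#' @param pair `"sine"` or `"arctan"`.
#' @return values in `[0, 1]`, same shape as `x`.
#' @export
smoothed_heaviside <- function(x, eps, pair = c("sine", "arctan")) {
  pair <- match.arg(pair)
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a positive number", call. = FALSE)
  if (pair == "arctan") return(0.5 * (1 + (2 / pi) * atan(x / eps)))
  out <- 0.5 * (1 + x / eps + sin(pi * x / eps) / pi)
  out[x >= eps] <- 1
  out[x <= -eps] <- 0
  out
}

#' Smoothed Dirac delta function
#'
#' The derivative of [smoothed_heaviside()]: for `"sine"`,
#' `(1 + cos(pi*x/eps)) / (2*eps)` on `|x| <= eps` and 0 outside; for
#' `"arctan"`, the Lorentzian `eps / (pi * (eps^2 + x^2))`.
#'
#' @inheritParams smoothed_heaviside
#' @return non-negative values, same shape as `x`.
#' @export
smoothed_dirac <- function(x, eps, pair = c("sine", "arctan")) {
  pair <- match.arg(pair)
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a positive number", call. = FALSE)
  if (pair == "arctan") return((1 / pi) * eps / (eps^2 + x^2))
  out <- (1 + cos(pi * x / eps)) / (2 * eps)
  out[abs(x) >= eps] <- 0
  out
}

#' Double-well potential diffusion rate
#'
#' Returns `p'(s)/s` for the double-well potential with minima at gradient
#' magnitudes 0 and 1:
#' `p(s) = (1 - cos(2*pi*s)) / (2*pi)^2` for `s <= 1` and
#' `p(s) = (s - 1)^2 / 2` for `s >= 1`.  The removable singularity at
#' `s = 0` is resolved to its limit 1, so the distance-regularizing flow
#' behaves like plain diffusion on flat plateaus and vanishes where
#' `|grad phi| = 1`.
#'
#' @param s non-negative numeric vector or matrix (gradient magnitudes).
#' @return same shape as `s`.
#' @export
double_well_dp <- function(s) {
  if (!is.numeric(s)) stop("'s' must be numeric", call. = FALSE)
  if (any(!is.finite(s)) || any(s < 0))
    stop("'s' must be finite and non-negative", call. = FALSE)
  out <- s
  lo <- s <= 1
  v <- s[lo]
  out[lo] <- ifelse(v < 1e-10, 1, sin(2 * pi * v) / (2 * pi * v))
  hi <- !lo
  out[hi] <- (s[hi] - 1) / s[hi]
  out
}

# value of the double-well potential itself (used by the energy monitor)
double_well_p <- function(s) {
  out <- s
  lo <- s <= 1
  out[lo] <- (1 - cos(2 * pi * s[lo])) / (2 * pi)^2
  out[!lo] <- (s[!lo] - 1)^2 / 2
  out
}

#' Truncated, normalized 2D Gaussian kernel
#'
#' @param sigma positive standard deviation in pixels.
#' @param ksize odd kernel width (>= 3).
#' @return a `ksize` x `ksize` matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, ksize) {
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  check_ksize(ksize)
  r <- (ksize - 1) / 2
  g1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

check_ksize <- function(ksize) {
  if (length(ksize) != 1L || ksize < 3 || ksize %% 2 != 1)
    stop("'ksize' must be an odd integer >= 3", call. = FALSE)
  invisible(ksize)
}

# 2D convolution with replicated (clamped) borders.  Separable kernels
# (Gaussian, box) are convolved directly by shifted sums along each axis,
# which is both faster in the evolution loop and free of FFT round-off;
# non-separable kernels fall back to EBImage's filter2.
conv2 <- function(f, k) {
  sv <- svd(k, nu = 1, nv = 1)
  if (length(sv$d) > 1 && sv$d[2] > 1e-12 * sv$d[1]) {
    out <- EBImage::filter2(f, k, boundary = "replicate")
    return(matrix(as.numeric(out), nrow(f), ncol(f)))
  }
  kc <- sv$u[, 1] * sqrt(sv$d[1])   # column (row-direction) factor
  kr <- sv$v[, 1] * sqrt(sv$d[1])
  h <- nrow(f); w <- ncol(f)
  r <- (nrow(k) - 1) %/% 2
  idx_r <- pmin(pmax(seq_len(h + 2 * r) - r, 1), h)
  idx_c <- pmin(pmax(seq_len(w + 2 * r) - r, 1), w)
  fp <- f[idx_r, , drop = FALSE]
  out <- matrix(0, h, w)
  tmp <- matrix(0, h, w + 2 * r)
  fpc <- fp[, idx_c, drop = FALSE]
  for (j in seq_along(kc))
    tmp <- tmp + kc[j] * fpc[j:(j + h - 1), , drop = FALSE]
  for (j in seq_along(kr))
    out <- out + kr[j] * tmp[, j:(j + w - 1), drop = FALSE]
  out
}
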