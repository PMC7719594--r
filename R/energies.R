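# The three energy ingredients of the combined model: the DRLSE distance
# regularizer, the edge indicator, and the region-scalable fitting (RSF)
# intensity terms, plus the single explicit evolution step that descends
# the combined energy
#
#   E(phi) = mu * R_p(phi)
#          + lambda * int g (I - f1)^2 M1(phi)
#          + alpha  * int g (I - f2)^2 M2(phi)
#          [+ curvature_weight * int g delta(phi) |grad phi|]
#
# with M1 = H_eps(-phi) (inside-negative convention), M2 = 1 - M1.

#' Parameters of the combined level set evolution
#'
#' Bundles every tunable constant of the evolution.  Defaults are the
#' tuned values for ventricle-like targets: `alpha = 2`, `lam = 1`,
#' `eps = 2`, `dt = 1.5`, Gaussian edge kernel with `sigma = 2.5` and
#' `ksize = 15`.
#'
#' @param alpha weight of the outside-region intensity term (the term that
#'   anchors pixels resembling the outside fit; positive).
#' @param lam weight of the inside-region intensity term (`lambda > 0`).
#' @param eps width of the smoothed Heaviside/Dirac pair (pixels).
#' @param dt explicit Euler time step.
#' @param sigma standard deviation of the smoothing kernel used for the
#'   edge indicator and the region-scalable fits (pixels).
#' @param ksize odd width of that kernel in pixels.
#' @param mu weight of the distance-regularizing term; the default
#'   `0.2 / dt` satisfies the stability guard `dt * mu < 0.25`.
#' @param c0 magnitude of the binary initialization plateau.
#' @param curvature_weight weight of the optional edge-weighted
#'   contour-length penalty (set to 0 for the plain combined flow).
#' @param max_iter iteration cap for [run_segmentation()].
#' @param pre_sigma standard deviation of the light Gaussian denoising
#'   applied to the image copy that feeds the region intensity terms
#'   (0 disables it).  The edge indicator always uses `sigma`.
#' @param heaviside which smoothed step pair to use: `"sine"` (compactly
#'   supported; default) or `"arctan"`.
#' @param kernel pre-smoothing kernel family for the edge indicator:
#'   `"gaussian"`, `"average"` or `"median"`.
#' @param fits_kernel how the regional fits are localized: `"gaussian"`
#'   (kernel-weighted local means; default) or `"edge_weighted_global"`
#'   (single global means weighted by the edge indicator).
#' @return an object of class `evolution_params`.
#' @export
evolution_params <- function(alpha = 2, lam = 1, eps = 2, dt = 1.5,
                             sigma = 2.5, ksize = 15, mu = 0.2 / dt,
                             c0 = 2, curvature_weight = lam / 2,
                             max_iter = 1000, pre_sigma = 1.5,
                             heaviside = c("sine", "arctan"),
                             kernel = c("gaussian", "average", "median"),
                             fits_kernel = c("gaussian",
                                             "edge_weighted_global")) {
  heaviside <- match.arg(heaviside)
  kernel <- match.arg(kernel)
  fits_kernel <- match.arg(fits_kernel)
  for (nm in c("alpha", "lam", "eps", "dt", "sigma", "mu", "c0",
               "curvature_weight", "pre_sigma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a finite number", nm), call. = FALSE)
  }
  if (lam <= 0) stop("'lam' must be positive", call. = FALSE)
  if (eps <= 0) stop("'eps' must be positive", call. = FALSE)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (mu <= 0) stop("'mu' must be positive", call. = FALSE)
  if (c0 <= 0) stop("'c0' must be positive", call. = FALSE)
  if (curvature_weight < 0)
    stop("'curvature_weight' must be non-negative", call. = FALSE)
  if (pre_sigma < 0) stop("'pre_sigma' must be non-negative", call. = FALSE)
  check_ksize(ksize)
  if (dt * mu >= 0.25)
    stop(sprintf("stability guard violated: dt * mu = %.3f must be < 0.25",
                 dt * mu), call. = FALSE)
  if (max_iter < 0 || max_iter != round(max_iter))
    stop("'max_iter' must be a non-negative integer", call. = FALSE)
  structure(list(alpha = alpha, lam = lam, eps = eps, dt = dt,
                 sigma = sigma, ksize = as.integer(ksize), mu = mu, c0 = c0,
                 curvature_weight = curvature_weight,
                 max_iter = as.integer(max_iter), pre_sigma = pre_sigma,
                 heaviside = heaviside, kernel = kernel,
                 fits_kernel = fits_kernel),
            class = "evolution_params")
}

#' @export
print.evolution_params <- function(x, ...) {
  cat("Level set evolution parameters\n")
  cat(sprintf("  alpha=%g lambda=%g eps=%g dt=%g mu=%g\n",
              x$alpha, x$lam, x$eps, x$dt, x$mu))
  cat(sprintf("  edge kernel: %s (sigma=%g, ksize=%d); fits: %s\n",
              x$kernel, x$sigma, x$ksize, x$fits_kernel))
  cat(sprintf("  heaviside=%s c0=%g curvature_weight=%g pre_sigma=%g max_iter=%d\n",
              x$heaviside, x$c0, x$curvature_weight, x$pre_sigma, x$max_iter))
  invisible(x)
}

# replace fields of an evolution_params, re-validating
update_params <- function(p, ...) {
  upd <- list(...)
  base <- unclass(p)
  base[names(upd)] <- upd
  do.call(evolution_params, base)
}

smooth_image <- function(I, sigma, ksize, kernel = "gaussian") {
  switch(kernel,
    gaussian = conv2(I, gaussian_kernel(sigma, ksize)),
    average = conv2(I, matrix(1 / ksize^2, ksize, ksize)),
    median = {
      r <- (ksize - 1) / 2
      rng <- range(I)
      span <- if (diff(rng) < 1e-12) 1 else diff(rng)
      sc <- (I - rng[1]) / span
      out <- EBImage::medianFilter(sc, size = r)
      matrix(as.numeric(out), nrow(I), ncol(I)) * span + rng[1]
    },
    stop("unknown smoothing kernel: ", kernel, call. = FALSE))
}

#' Edge indicator function
#'
#' `g = 1 / (1 + |grad(S * I)|^2)` where `S` is a smoothing kernel
#' (Gaussian by default) that suppresses noise before differentiation.
#' `g` is close to 1 in flat regions and drops towards 0 at strong edges,
#' slowing the contour there.
#'
#' @param I numeric image matrix.
#' @param sigma,ksize smoothing kernel parameters (see [gaussian_kernel()]).
#' @param kernel `"gaussian"`, `"average"` or `"median"` pre-smoother.
#' @return matrix of values in `(0, 1]`, same shape as `I`.
#' @export
edge_indicator <- function(I, sigma = 2.5, ksize = 15,
                           kernel = c("gaussian", "average", "median")) {
  kernel <- match.arg(kernel)
  assert_field(I)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  check_ksize(ksize)
  s <- smooth_image(I, sigma, ksize, kernel)
  gr <- field_gradient(s)
  1 / (1 + gr$x^2 + gr$y^2)
}

#' Distance-regularizing flow
#'
#' `div(d_p(|grad phi|) * grad phi)` with the double-well rate
#' [double_well_dp()]: diffuses the level set function towards a signed
#' distance profile (`|grad phi| = 1`) near the contour and towards a flat
#' plateau far from it, which is what removes the classical
#' re-initialization step.  A signed distance function is a fixed point.
#'
#' @param phi level set function (numeric matrix).
#' @return the flow field, same shape as `phi`.
#' @export
distance_regularizer_flow <- function(phi) {
  phi <- neumann_extend(phi)
  g <- field_gradient(phi)
  s <- sqrt(g$x^2 + g$y^2)
  dps <- double_well_dp(s)
  field_divergence(dps * g$x, dps * g$y)
}

#' Region-scalable intensity fits
#'
#' Kernel-weighted local means of the image inside and outside the
#' contour: with inside membership `M1 = H_eps(-phi)` and `M2 = 1 - M1`,
#' `f_i = K * (M_i I) / (K * M_i)` where `K` is the truncated Gaussian of
#' [edge_indicator()].  Where a membership has (locally) no mass the fit
#' falls back to the global membership-weighted mean.
#'
#' @param I image matrix.
#' @param phi level set function, same shape.
#' @param eps Heaviside width.
#' @param sigma,ksize Gaussian kernel parameters.
#' @param heaviside smoothed step pair, `"sine"` or `"arctan"`.
#' @param fits_kernel `"gaussian"` for local fits (default) or
#'   `"edge_weighted_global"` for global means weighted by the edge map
#'   `g` (which must then be supplied).
#' @param g edge indicator, only used by `"edge_weighted_global"`.
#' @return an object of class `regional_fits`: list with matrices `f1`
#'   (inside approximation) and `f2` (outside approximation).
#' @export
regional_fits <- function(I, phi, eps = 2, sigma = 2.5, ksize = 15,
                          heaviside = c("sine", "arctan"),
                          fits_kernel = c("gaussian", "edge_weighted_global"),
                          g = NULL) {
  heaviside <- match.arg(heaviside)
  fits_kernel <- match.arg(fits_kernel)
  assert_field(I); assert_field(phi)
  assert_same_shape(I, phi)
  m1 <- smoothed_heaviside(-phi, eps, heaviside)
  m2 <- 1 - m1
  s1 <- sum(m1); s2 <- sum(m2)
  if (s1 < 1e-10 || s2 < 1e-10)
    stop("degenerate level set function: one region membership vanishes ",
         "everywhere (contour lost)", call. = FALSE)
  if (fits_kernel == "edge_weighted_global") {
    if (is.null(g)) stop("'g' is required for edge_weighted_global fits",
                         call. = FALSE)
    assert_same_shape(I, g)
    f1 <- matrix(sum(g * m1 * I) / sum(g * m1), nrow(I), ncol(I))
    f2 <- matrix(sum(g * m2 * I) / sum(g * m2), nrow(I), ncol(I))
  } else {
    k <- gaussian_kernel(sigma, ksize)
    den1 <- conv2(m1, k); den2 <- conv2(m2, k)
    num1 <- conv2(m1 * I, k); num2 <- conv2(m2 * I, k)
    gm1 <- sum(m1 * I) / s1
    gm2 <- sum(m2 * I) / s2
    f1 <- ifelse(den1 < 1e-10, gm1, num1 / den1)
    f2 <- ifelse(den2 < 1e-10, gm2, num2 / den2)
  }
  structure(list(f1 = f1, f2 = f2), class = "regional_fits")
}

#' Squared-residual data terms
#'
#' `e1 = (I - f1)^2` and `e2 = (I - f2)^2`, the pointwise squared
#' deviations of each pixel from the inside and outside intensity fits.
#'
#' @param I image matrix.
#' @param fits a `regional_fits` object (or list with `f1`, `f2`).
#' @return list with matrices `e1` and `e2` (both non-negative).
#' @export
data_terms <- function(I, fits) {
  assert_field(I)
  assert_same_shape(I, fits$f1)
  list(e1 = (I - fits$f1)^2, e2 = (I - fits$f2)^2)
}

#' One explicit step of the combined level set evolution
#'
#' Advances the level set function by one explicit Euler step of the
#' gradient descent of the combined energy:
#' \deqn{\phi \leftarrow \phi + \Delta t\,[\mu R(\phi)
#'   + \delta_\epsilon(\phi)\, g\, (\lambda e_1 - \alpha e_2)
#'   + c_w\, \delta_\epsilon(\phi)\,
#'     \mathrm{div}(g \nabla\phi / |\nabla\phi|)]}
#' The regional fits are recomputed from the current `phi` before the
#' data terms, so the fits track the contour.
#'
#' @param phi level set function.
#' @param I image matrix driving the region terms.
#' @param g edge indicator of the image (see [edge_indicator()]).
#' @param params an [evolution_params()] object.
#' @return the advanced level set function; errors if the step produces
#'   non-finite values (instability: reduce `dt`).
#' @export
evolution_step <- function(phi, I, g, params = evolution_params()) {
  assert_field(phi); assert_field(I); assert_field(g)
  assert_same_shape(phi, I); assert_same_shape(phi, g)
  p <- params
  phi <- neumann_extend(phi)
  gr <- field_gradient(phi)
  s <- sqrt(gr$x^2 + gr$y^2)
  reg <- field_divergence(double_well_dp(s) * gr$x, double_well_dp(s) * gr$y)
  fits <- regional_fits(I, phi, p$eps, p$sigma, p$ksize, p$heaviside,
                        p$fits_kernel, g = g)
  e <- data_terms(I, fits)
  dlt <- smoothed_dirac(phi, p$eps, p$heaviside)
  flow <- p$mu * reg + dlt * g * (p$lam * e$e1 - p$alpha * e$e2)
  if (p$curvature_weight > 0) {
    sreg <- sqrt(s^2 + 1e-10)
    curv <- field_divergence(g * gr$x / sreg, g * gr$y / sreg)
    flow <- flow + p$curvature_weight * dlt * curv
  }
  out <- phi + p$dt * flow
  if (!all(is.finite(out)))
    stop("evolution step produced non-finite values (numerical ",
         "instability; consider reducing dt)", call. = FALSE)
  out
}

# One explicit step of the classic edge-only DRLSE flow (the baseline the
# combined model is compared against): mu*R + lam*delta*div(g N) +
# alpha*g*delta, i.e. geodesic length plus weighted-area balloon.
drlse_step <- function(phi, g, params) {
  p <- params
  phi <- neumann_extend(phi)
  gr <- field_gradient(phi)
  s <- sqrt(gr$x^2 + gr$y^2)
  reg <- field_divergence(double_well_dp(s) * gr$x, double_well_dp(s) * gr$y)
  sreg <- sqrt(s^2 + 1e-10)
  curv <- field_divergence(g * gr$x / sreg, g * gr$y / sreg)
  dlt <- smoothed_dirac(phi, p$eps, p$heaviside)
  out <- phi + p$dt * (p$mu * reg + p$lam * dlt * curv + p$alpha * g * dlt)
  if (!all(is.finite(out)))
    stop("evolution step produced non-finite values (numerical ",
         "instability; consider reducing dt)", call. = FALSE)
  out
}

#' Discrete combined energy
#'
#' Evaluates the energy the evolution descends (distance-regularizing
#' penalty, edge-weighted region terms, optional length term) for
#' monitoring convergence.
#'
#' @inheritParams evolution_step
#' @return a single number.
#' @export
level_set_energy <- function(phi, I, g, params = evolution_params()) {
  p <- params
  gr <- field_gradient(neumann_extend(phi))
  s <- sqrt(gr$x^2 + gr$y^2)
  m1 <- smoothed_heaviside(-phi, p$eps, p$heaviside)
  m2 <- 1 - m1
  fits <- regional_fits(I, phi, p$eps, p$sigma, p$ksize, p$heaviside,
                        p$fits_kernel, g = g)
  e <- data_terms(I, fits)
  en <- p$mu * sum(double_well_p(s)) +
    p$lam * sum(g * e$e1 * m1) + p$alpha * sum(g * e$e2 * m2)
  if (p$curvature_weight > 0)
    en <- en + p$curvature_weight *
      sum(g * smoothed_dirac(phi, p$eps, p$heaviside) * s)
  en
}
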