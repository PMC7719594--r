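# End-to-end segmentation: bounding-box initialization, the evolution
# loop with stopping logic, mask extraction, and the skull-strip
# preprocessing used for real head images.

#' Rectangular bounding box
#'
#' Pixel index ranges in half-open convention: rows `row_min` to
#' `row_max - 1` and columns `col_min` to `col_max - 1` are covered
#' (1-based indices).
#'
#' @param row_min,row_max,col_min,col_max integer pixel bounds.
#' @return an object of class `bounding_box`.
#' @export
bounding_box <- function(row_min, row_max, col_min, col_max) {
  v <- c(row_min, row_max, col_min, col_max)
  if (any(!is.finite(v)) || any(v != round(v)))
    stop("bounding box limits must be integers", call. = FALSE)
  if (row_max <= row_min || col_max <= col_min)
    stop("bounding box must be non-empty", call. = FALSE)
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max)),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("bounding_box rows [%d, %d) cols [%d, %d)\n",
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

#' Centered box covering a fraction of the image
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param fraction side fraction in `(0, 1)`.
#' @return a [bounding_box()].
#' @export
centered_box <- function(shape, fraction = 0.6) {
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  half <- pmax(1, floor(shape / 2 * fraction))
  ctr <- floor(shape / 2) + 1L
  bounding_box(max(2L, ctr[1] - half[1]), min(shape[1], ctr[1] + half[1]),
               max(2L, ctr[2] - half[2]), min(shape[2], ctr[2] + half[2]))
}

box_mask <- function(box, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[box$row_min:(box$row_max - 1L), box$col_min:(box$col_max - 1L)] <- TRUE
  m
}

check_box_inside <- function(box, shape) {
  if (box$row_min < 2L || box$col_min < 2L ||
      box$row_max > shape[1] || box$col_max > shape[2])
    stop("bounding box must lie strictly inside the image (it may not ",
         "touch the border)", call. = FALSE)
  invisible(box)
}

#' Binary level set initialization from a bounding box
#'
#' `phi = -c0` inside the box and `+c0` outside (inside-negative
#' convention), the standard DRLSE binary-step initialization.
#'
#' @param box a [bounding_box()], strictly inside the image.
#' @param shape image dimensions `c(rows, cols)`.
#' @param c0 positive plateau magnitude (default 2).
#' @return a level set function matrix.
#' @export
initialize_lsf <- function(box, shape, c0 = 2) {
  if (!inherits(box, "bounding_box")) stop("'box' must be a bounding_box",
                                           call. = FALSE)
  if (c0 <= 0) stop("'c0' must be positive", call. = FALSE)
  check_box_inside(box, shape)
  phi <- matrix(c0, shape[1], shape[2])
  phi[box_mask(box, shape)] <- -c0
  phi
}

#' Foreground mask of a level set function
#'
#' @param phi level set function.
#' @return binary matrix, 1 where `phi < 0` (inside), else 0.
#' @export
extract_mask <- function(phi) {
  assert_field(phi)
  (phi < 0) * 1
}

#' Segment an image with the region-augmented DRLSE
#'
#' Runs the full evolution: computes the edge indicator once, lightly
#' denoises the copy of the image that drives the region terms, evolves
#' the level set from the binary box initialization until the zero-set
#' area is stable or `max_iter` is reached, and extracts the final mask.
#'
#' Two initialization modes are supported.  In `"around"` mode (default)
#' the box encloses the target, the contour peels inward, and the box
#' acts as a hard search domain: after each step `phi` is projected to be
#' non-negative outside the box, so the segmentation can never leave the
#' operator's box.  In `"seed"` mode the box is placed inside the target
#' and the region grows outward without constraint.
#'
#' @param I image matrix.  Intensities are expected in `[0, 255]`; images
#'   outside that range are min-max rescaled to it.
#' @param box a [bounding_box()].
#' @param params an [evolution_params()] object.
#' @param method `"modified"` (region-augmented; default) or `"drlse"`
#'   (classic edge-only baseline with the weighted-area balloon).
#' @param box_mode `"around"` or `"seed"` (see Details).
#' @param convergence_tol relative zero-set area change below which the
#'   run is declared converged (default 0.001, i.e. 0.1%).
#' @param convergence_window number of iterations over which the area
#'   change is measured (default 10).
#' @param keep_history record per-iteration area and update size.
#' @return an object of class `ventseg_fit`: list with `mask` (binary
#'   matrix), `phi`, `iterations`, `converged`, `status` (`"converged"`,
#'   `"max_iter"` or `"contour_vanished"`), `history` (tibble), `params`,
#'   `method`, `box`, `box_mode`.
#' @export
run_segmentation <- function(I, box, params = evolution_params(),
                             method = c("modified", "drlse"),
                             box_mode = c("around", "seed"),
                             convergence_tol = 0.001,
                             convergence_window = 10,
                             keep_history = TRUE) {
  method <- match.arg(method)
  box_mode <- match.arg(box_mode)
  assert_field(I)
  p <- params
  rng <- range(I)
  if (rng[1] < 0 || rng[2] > 255) {
    span <- if (diff(rng) < 1e-12) 1 else diff(rng)
    I <- (I - rng[1]) / span * 255
  }
  g <- edge_indicator(I, p$sigma, p$ksize, p$kernel)
  Id <- if (p$pre_sigma > 0) {
    kw <- 2L * ceiling(3 * p$pre_sigma) + 1L
    conv2(I, gaussian_kernel(p$pre_sigma, kw))
  } else I
  phi <- initialize_lsf(box, dim(I), p$c0)
  outside <- !box_mask(box, dim(I))
  areas <- numeric(p$max_iter)
  max_dphi <- numeric(p$max_iter)
  it <- 0L
  converged <- FALSE
  status <- "max_iter"
  while (it < p$max_iter) {
    it <- it + 1L
    phi_new <- tryCatch(
      if (method == "modified") evolution_step(phi, Id, g, p)
      else drlse_step(phi, g, p),
      error = function(e) stop(sprintf("iteration %d: %s", it,
                                       conditionMessage(e)), call. = FALSE))
    if (box_mode == "around") phi_new[outside] <- pmax(phi_new[outside], 0)
    max_dphi[it] <- max(abs(phi_new - phi))
    phi <- phi_new
    areas[it] <- sum(phi < 0)
    if (areas[it] == 0 || areas[it] == length(phi)) {
      status <- "contour_vanished"
      warning("contour vanished: level set function has a single sign",
              call. = FALSE)
      break
    }
    if (it > convergence_window &&
        abs(areas[it] - areas[it - convergence_window]) <
          convergence_tol * max(areas[it], 1)) {
      converged <- TRUE
      status <- "converged"
      break
    }
  }
  if (p$max_iter == 0L) status <- "max_iter"
  history <- if (keep_history && it > 0L)
    tibble::tibble(iteration = seq_len(it), area = areas[seq_len(it)],
                   max_dphi = max_dphi[seq_len(it)])
  else tibble::tibble(iteration = integer(), area = numeric(),
                      max_dphi = numeric())
  structure(list(mask = extract_mask(phi), phi = phi, iterations = it,
                 converged = converged, status = status, history = history,
                 params = p, method = method, box = box,
                 box_mode = box_mode),
            class = "ventseg_fit")
}

#' @export
print.ventseg_fit <- function(x, ...) {
  cat(sprintf("ventseg_fit (%s, box_mode=%s): %s after %d iterations\n",
              x$method, x$box_mode, x$status, x$iterations))
  cat(sprintf("  foreground: %d of %d pixels\n",
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Plot a segmentation result
#'
#' Displays the image with the segmentation boundary overlaid in red
#' (and the initial box in yellow).
#'
#' @param x a `ventseg_fit`.
#' @param I the image that was segmented.
#' @param ... ignored.
#' @export
plot.ventseg_fit <- function(x, I = NULL, ...) {
  m <- x$mask
  if (is.null(I)) I <- matrix(0.5, nrow(m), ncol(m)) * 255
  rgb <- overlay_array(I, m)
  op <- graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(c(0, ncol(m)), c(0, nrow(m)), type = "n", axes = FALSE,
                 xlab = "", ylab = "", asp = 1,
                 main = sprintf("%s (%s, %d it.)", x$method, x$status,
                                x$iterations))
  graphics::rasterImage(rgb, 0, 0, ncol(m), nrow(m))
  invisible(x)
}

mask_boundary <- function(mask) {
  k <- matrix(1, 3, 3)
  dil <- (conv2(mask, k) > 0.5) * 1
  (dil - mask) > 0.5 | (mask > 0.5 & conv2(1 - mask, k) > 0.5)
}

overlay_array <- function(I, mask) {
  sc <- pmin(pmax(I / 255, 0), 1)
  arr <- array(rep(sc, 3), dim = c(nrow(I), ncol(I), 3))
  b <- mask_boundary(mask)
  arr[, , 1][b] <- 1
  arr[, , 2][b] <- 0
  arr[, , 3][b] <- 0
  arr
}

#' Skull stripping by thresholding and morphology
#'
#' Extracts a brain mask from a head image: Otsu binarization, 8-connected
#' component labeling, retention of the largest component, morphological
#' closing with a disc of radius 3, and hole filling.
#'
#' @param I head image matrix (values in `[0, 255]`).
#' @return binary brain mask matrix.
#' @export
skull_strip <- function(I) {
  assert_field(I)
  rng <- range(I)
  span <- if (diff(rng) < 1e-12) 1 else diff(rng)
  sc <- (I - rng[1]) / span
  thr <- EBImage::otsu(EBImage::Image(sc))
  bw <- sc > thr
  if (!any(bw))
    stop("empty foreground after binarization: no brain-like structure ",
         "found", call. = FALSE)
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  keep <- (lab == which.max(sizes)) * 1
  brush <- EBImage::makeBrush(7, shape = "disc")
  closed <- EBImage::closing(keep, brush)
  filled <- EBImage::fillHull(closed)
  matrix(as.numeric(filled > 0.5), nrow(I), ncol(I))
}

#' Pixels near the zero level set
#'
#' Returns a logical matrix marking pixels whose distance to the
#' sign-change interface of `phi` is at most `radius` (computed
#' symmetrically by morphological dilation and erosion of the foreground
#' mask with a disc of that radius).  Used to assess how close the level
#' set function stays to a signed distance function near the contour.
#'
#' @param phi level set function.
#' @param radius band half-width in pixels.
#' @return logical matrix of the shape of `phi`.
#' @export
zero_set_band <- function(phi, radius = 3) {
  m <- extract_mask(phi)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  dil <- EBImage::dilate(m, brush)
  ero <- EBImage::erode(m, brush)
  matrix(as.numeric(dil) - as.numeric(ero), nrow(m), ncol(m)) > 0
}
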