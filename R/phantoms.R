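# Synthetic phantoms emulating the clinical inputs: dark ventricle-like
# structures on brighter brain tissue, with a mix of sharp and weak
# (blurred, contrast-reduced) boundary segments, additive Gaussian noise
# and paired ground truth.  Every other module is testable on these
# without any data download.

new_phantom <- function(image, truth, box, meta) {
  structure(list(image = image, truth = truth, box = box, meta = meta),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom %s (%dx%d): truth area %d px\n",
              x$meta$type, nrow(x$image), ncol(x$image), sum(x$truth)))
  invisible(x)
}

add_noise_clip <- function(I, noise_sigma, seed) {
  if (noise_sigma > 0) {
    I <- I + withr::with_seed(seed,
                              matrix(rnorm(length(I), 0, noise_sigma),
                                     nrow(I), ncol(I)))
  }
  pmin(pmax(I, 0), 255)
}

#' Disk phantom
#'
#' A centered dark disk on a brighter background, the minimal convergence
#' test object.  The suggested `box` is a centered seed square inside the
#' disk (`box_mode = "seed"`).
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param radius disk radius in pixels (must leave a margin of at least 5
#'   pixels to the border).
#' @param inside_val,outside_val intensities of disk and background.
#' @param noise_sigma SD of additive Gaussian noise (clipped to
#'   `[0, 255]`).
#' @param seed RNG seed for the noise; identical seeds give identical
#'   phantoms.
#' @return a `phantom`: list with `image`, `truth`, `box` and `meta`.
#' @export
make_disk_phantom <- function(shape = c(64, 64), radius = 18,
                              inside_val = 40, outside_val = 120,
                              noise_sigma = 0, seed = 1) {
  if (radius + 5 > min(shape) / 2)
    stop("radius too large: the disk must fit with a margin of 5 pixels",
         call. = FALSE)
  ctr <- (shape + 1) / 2
  dd <- sqrt(outer((seq_len(shape[1]) - ctr[1])^2,
                   (seq_len(shape[2]) - ctr[2])^2, "+"))
  truth <- (dd < radius) * 1
  I <- ifelse(truth == 1, inside_val, outside_val)
  I <- add_noise_clip(I, noise_sigma, seed)
  half <- max(2L, floor(0.55 * radius))
  box <- bounding_box(round(ctr[1]) - half, round(ctr[1]) + half,
                      round(ctr[2]) - half, round(ctr[2]) + half)
  new_phantom(I, truth, box,
              list(type = "disk", radius = radius,
                   inside_val = inside_val, outside_val = outside_val,
                   contrast = abs(outside_val - inside_val),
                   noise_sigma = noise_sigma, seed = seed,
                   box_mode = "seed"))
}

# membership test for one rotated crescent (main ellipse minus a shifted
# carving ellipse); geometry in units of the grid passed in
crescent_mask <- function(rows, cols, ctr, side, soff, tilt, ax, carve,
                          cshift) {
  th <- side * tilt * pi / 180
  dr <- rows - ctr[1]
  dc <- cols - (ctr[2] + side * soff)
  u <- cos(th) * dr + sin(th) * dc
  v <- -sin(th) * dr + cos(th) * dc
  e1 <- (u / ax[1])^2 + (v / ax[2])^2
  dc2 <- cols - (ctr[2] + side * cshift)
  u2 <- cos(th) * dr + sin(th) * dc2
  v2 <- -sin(th) * dr + cos(th) * dc2
  e2 <- (u2 / carve[1])^2 + (v2 / carve[2])^2
  e1 < 1 & e2 > 1
}

#' Ventricle phantom
#'
#' Emulates an axial head slice: background 160, elliptical brain at 120,
#' and two mirrored crescent-shaped dark regions (value
#' `120 - contrast`) forming a lateral-ventricle-like pair.  Along
#' `weak_arc_deg` degrees of each crescent's lateral boundary the
#' transition is Gaussian-blurred and its contrast halved (a weak
#' boundary); elsewhere the transition is a hard step.  Gaussian noise is
#' added and the image clipped to `[0, 255]`.  The ground truth is the
#' unblurred generating mask and the suggested `box` is its bounding box
#' padded by 2 pixels (`box_mode = "around"`).
#'
#' @param shape image dimensions, at least 64x64; the geometry scales
#'   with `min(shape)`.
#' @param contrast intensity gap between brain and ventricle (positive).
#' @param weak_arc_deg angular extent (degrees) of the weak boundary on
#'   each crescent; 0 for all-sharp boundaries.
#' @param blur_sigma Gaussian SD of the weak-boundary blur.
#' @param noise_sigma SD of additive Gaussian noise.
#' @param seed RNG seed for the noise.
#' @return a `phantom` (see [make_disk_phantom()]).
#' @export
make_ventricle_phantom <- function(shape = c(128, 128), contrast = 60,
                                   weak_arc_deg = 60, blur_sigma = 3,
                                   noise_sigma = 4, seed = 1) {
  if (min(shape) < 64) stop("shape must be at least 64x64", call. = FALSE)
  if (contrast <= 0) stop("'contrast' must be positive", call. = FALSE)
  if (noise_sigma > 0 && contrast <= 6 * noise_sigma)
    warning("contrast <= 6 * noise_sigma: structure is statistically ",
            "invisible", call. = FALSE)
  sc <- min(shape) / 128
  ctr <- (shape + 1) / 2
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  geo <- list(soff = 15 * sc, tilt = 18, ax = c(26, 14) * sc,
              carve = c(22, 6) * sc, cshift = 4 * sc)
  m <- crescent_mask(rows, cols, ctr, -1, geo$soff, geo$tilt, geo$ax,
                     geo$carve, geo$cshift) |
    crescent_mask(rows, cols, ctr, 1, geo$soff, geo$tilt, geo$ax,
                  geo$carve, geo$cshift)
  brain <- sqrt(((rows - ctr[1]) / (58 * sc))^2 +
                ((cols - ctr[2]) / (54 * sc))^2) < 1
  compose <- function(vent_val) {
    I <- matrix(160, shape[1], shape[2])
    I[brain] <- 120
    I[m] <- vent_val
    I
  }
  I <- compose(120 - contrast)
  if (weak_arc_deg > 0) {
    wedge <- matrix(FALSE, shape[1], shape[2])
    for (side in c(-1, 1)) {
      ang <- atan2(rows - ctr[1], cols - (ctr[2] + side * geo$soff)) *
        180 / pi
      a0 <- if (side > 0) 0 else 180
      d <- (ang - a0 + 180) %% 360 - 180
      wedge <- wedge | (abs(d) <= weak_arc_deg / 2)
    }
    bw <- 2L * ceiling(5 * sc) + 1L
    band <- conv2(m, matrix(1, bw, bw)) > 0.5 &
      conv2(1 - m, matrix(1, bw, bw)) > 0.5
    kb <- gaussian_kernel(blur_sigma, 2L * ceiling(3 * blur_sigma) + 1L)
    weak_img <- conv2(compose(120 - 0.5 * contrast), kb)
    w <- pmin(conv2((wedge & band) * 1, kb), 1)
    I <- (1 - w) * I + w * weak_img
  }
  I <- add_noise_clip(I, noise_sigma, seed)
  rr <- range(which(rowSums(m) > 0))
  cc <- range(which(colSums(m) > 0))
  box <- bounding_box(max(2L, rr[1] - 2L), min(shape[1], rr[2] + 3L),
                      max(2L, cc[1] - 2L), min(shape[2], cc[2] + 3L))
  new_phantom(I, m * 1, box,
              list(type = "ventricle", contrast = contrast,
                   weak_arc_deg = weak_arc_deg, blur_sigma = blur_sigma,
                   noise_sigma = noise_sigma, seed = seed,
                   box_mode = "around"))
}

#' Write a phantom to disk
#'
#' Writes `<name>_image.png` (8-bit grayscale), `<name>_truth.png`
#' (binary) and `<name>_meta.json` into `dir`.
#'
#' @param ph a `phantom`.
#' @param dir output directory (created if missing).
#' @param name file name stem.
#' @return named character vector of the three paths, invisibly.
#' @export
write_phantom <- function(ph, dir, name = ph$meta$type) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(name, "_image.png")),
             truth = file.path(dir, paste0(name, "_truth.png")),
             meta = file.path(dir, paste0(name, "_meta.json")))
  png::writePNG(round(ph$image) / 255, paths[["image"]])
  png::writePNG(ph$truth, paths[["truth"]])
  meta <- ph$meta
  meta$box <- ph$box[c("row_min", "row_max", "col_min", "col_max")]
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE)
  invisible(paths)
}
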