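# Independent brute-force oracles, coded as plain loops so they share no
# machinery with the implementation they check.

# central differences inside, one-sided at the borders
oracle_gradient <- function(f) {
  h <- nrow(f); w <- ncol(f)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    gx[r, c] <- if (c == 1) f[r, 2] - f[r, 1]
                else if (c == w) f[r, w] - f[r, w - 1]
                else (f[r, c + 1] - f[r, c - 1]) / 2
    gy[r, c] <- if (r == 1) f[2, c] - f[1, c]
                else if (r == h) f[h, c] - f[h - 1, c]
                else (f[r + 1, c] - f[r - 1, c]) / 2
  }
  list(x = gx, y = gy)
}

oracle_divergence <- function(vx, vy) {
  oracle_gradient(vx)$x + oracle_gradient(vy)$y
}

# direct convolution with replicated borders
oracle_conv <- function(f, k) {
  h <- nrow(f); w <- ncol(f)
  r <- (nrow(k) - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      acc <- acc + f[ii, jj] * k[di + r + 1, dj + r + 1]
    }
    out[i, j] <- acc
  }
  out
}

oracle_edge_indicator <- function(I, sigma, ksize) {
  k <- gaussian_kernel(sigma, ksize)
  s <- oracle_conv(I, k)
  g <- oracle_gradient(s)
  1 / (1 + g$x^2 + g$y^2)
}

# membership-weighted local means by direct double loops
oracle_regional_fits <- function(I, phi, eps, sigma, ksize) {
  k <- gaussian_kernel(sigma, ksize)
  m1 <- smoothed_heaviside(-phi, eps, "sine")
  m2 <- 1 - m1
  num1 <- oracle_conv(m1 * I, k); den1 <- oracle_conv(m1, k)
  num2 <- oracle_conv(m2 * I, k); den2 <- oracle_conv(m2, k)
  gm1 <- sum(m1 * I) / sum(m1); gm2 <- sum(m2 * I) / sum(m2)
  list(f1 = ifelse(den1 < 1e-10, gm1, num1 / den1),
       f2 = ifelse(den2 < 1e-10, gm2, num2 / den2))
}

# signed distance to a centered circle of radius r
sdf_circle <- function(shape, radius) {
  ctr <- (shape + 1) / 2
  dd <- sqrt(outer((seq_len(shape[1]) - ctr[1])^2,
                   (seq_len(shape[2]) - ctr[2])^2, "+"))
  dd - radius
}

# signed distance to a vertical line at column x0 (exactly |grad| = 1)
sdf_line <- function(shape, x0) {
  matrix(rep(seq_len(shape[2]) - x0, each = shape[1]),
         shape[1], shape[2])
}

random_field <- function(shape, seed, lo = 0, hi = 100) {
  withr::with_seed(seed,
                   matrix(runif(prod(shape), lo, hi), shape[1], shape[2]))
}

# --- tiny synthetic DICOM writer (explicit VR little endian) -------------

uint_le <- function(x, nbytes) {
  as.raw((x %/% 256^(0:(nbytes - 1))) %% 256)
}

dicom_element <- function(group, elem, vr, value_raw) {
  head <- c(uint_le(group, 2), uint_le(elem, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), uint_le(length(value_raw), 4), value_raw)
  } else {
    c(head, uint_le(length(value_raw), 2), value_raw)
  }
}

even_string <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
  r
}

# writes a minimal single-frame 16-bit unsigned DICOM with the given
# pixel matrix (row-major), rescale slope/intercept
write_synthetic_dicom <- function(path, pixels, slope = 1, intercept = 0) {
  ts <- even_string("1.2.840.10008.1.2.1")
  meta <- dicom_element(0x0002, 0x0010, "UI", ts)
  px <- as.integer(t(pixels))
  px_raw <- writeBin(px, raw(), size = 2, endian = "little")
  body <- c(
    dicom_element(0x0028, 0x0010, "US", uint_le(nrow(pixels), 2)),
    dicom_element(0x0028, 0x0011, "US", uint_le(ncol(pixels), 2)),
    dicom_element(0x0028, 0x0100, "US", uint_le(16, 2)),
    dicom_element(0x0028, 0x0103, "US", uint_le(0, 2)),
    dicom_element(0x0028, 0x1052, "DS", even_string(as.character(intercept))),
    dicom_element(0x0028, 0x1053, "DS", even_string(as.character(slope))),
    dicom_element(0x7fe0, 0x0010, "OW", px_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
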