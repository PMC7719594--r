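# Evaluation measures between a segmentation mask and a ground-truth
# mask: pixelwise confusion counts, overlap coefficients (Dice, Jaccard),
# rate metrics in two definition modes, PSNR and SSIM.

assert_binary <- function(m, name = deparse(substitute(m))) {
  assert_field(m, name, min_dim = 1L)
  if (!all(m %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (0/1)", name), call. = FALSE)
  invisible(m)
}

#' Pixelwise confusion counts
#'
#' Counts true/false positives/negatives between a binary segmentation
#' and a binary ground truth (foreground = 1).
#'
#' @param mask,truth binary matrices of identical shape.
#' @return an object of class `confusion_counts`: list with `tp`, `tn`,
#'   `fp`, `fn` and `n` (total pixels).
#' @export
confusion <- function(mask, truth) {
  assert_binary(mask); assert_binary(truth)
  assert_same_shape(mask, truth)
  tp <- sum(mask == 1 & truth == 1)
  tn <- sum(mask == 0 & truth == 0)
  fp <- sum(mask == 1 & truth == 0)
  fn <- sum(mask == 0 & truth == 1)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = length(mask)),
            class = "confusion_counts")
}

as_counts <- function(x, truth = NULL) {
  if (inherits(x, "confusion_counts")) return(x)
  if (is.null(truth))
    stop("supply either confusion counts or both mask and truth",
         call. = FALSE)
  confusion(x, truth)
}

#' Dice similarity coefficient
#'
#' `DI = 2 TP / (2 TP + FP + FN)`.  Two empty masks agree perfectly and
#' give 1 by convention.
#'
#' @param x a `confusion_counts` object or a binary mask.
#' @param truth binary ground truth (when `x` is a mask).
#' @return a number in `[0, 1]`.
#' @export
dice <- function(x, truth = NULL) {
  c <- as_counts(x, truth)
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Jaccard similarity index
#'
#' `JI = TP / (TP + FP + FN)`; equals `DI / (2 - DI)`.  Two empty masks
#' give 1 by convention.
#'
#' @inheritParams dice
#' @return a number in `[0, 1]`.
#' @export
jaccard <- function(x, truth = NULL) {
  c <- as_counts(x, truth)
  den <- c$tp + c$fp + c$fn
  if (den == 0) return(1)
  c$tp / den
}

#' Sensitivity, specificity and accuracy
#'
#' In `"standard"` mode: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`.  In `"as_printed"` mode the literal nonstandard formulas
#' some reports use are applied instead: sensitivity `TP/(TP+FP)` and
#' specificity `TP/(TN+FP)`.  Accuracy is `(TP+TN)/total` in both modes.
#' A zero denominator yields `NA` rather than an error.
#'
#' @inheritParams dice
#' @param mode `"standard"` (default) or `"as_printed"`.
#' @return named list with `sensitivity`, `specificity`, `accuracy`.
#' @export
sens_spec_acc <- function(x, truth = NULL,
                          mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  c <- as_counts(x, truth)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  if (mode == "standard") {
    sens <- safe_div(c$tp, c$tp + c$fn)
    spec <- safe_div(c$tn, c$tn + c$fp)
  } else {
    sens <- safe_div(c$tp, c$tp + c$fp)
    spec <- safe_div(c$tp, c$tn + c$fp)
  }
  list(sensitivity = sens, specificity = spec,
       accuracy = safe_div(c$tp + c$tn, c$n))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in decibels; identical inputs (MSE = 0)
#' return `Inf`.
#'
#' @param a,b numeric matrices of identical shape.
#' @param peak positive peak value (1 for binary masks, 255 for 8-bit
#'   images).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, peak = 1) {
  assert_field(a, min_dim = 1L); assert_field(b, min_dim = 1L)
  assert_same_shape(a, b)
  if (peak <= 0) stop("'peak' must be positive", call. = FALSE)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with a Gaussian window (sigma 1.5, size 11) and the
#' standard stabilizers `C1 = (0.01 peak)^2`, `C2 = (0.03 peak)^2`.
#' Symmetric in its arguments; 1 for identical images.
#'
#' @param a,b numeric matrices of identical shape, at least 11x11.
#' @param peak positive dynamic range of the data.
#' @param sigma,ksize Gaussian window parameters.
#' @return a number in `[-1, 1]`.
#' @export
ssim <- function(a, b, peak = 1, sigma = 1.5, ksize = 11) {
  assert_field(a, min_dim = 1L); assert_field(b, min_dim = 1L)
  assert_same_shape(a, b)
  if (nrow(a) < ksize || ncol(a) < ksize)
    stop(sprintf("images must be at least %dx%d for the SSIM window",
                 ksize, ksize), call. = FALSE)
  if (peak <= 0) stop("'peak' must be positive", call. = FALSE)
  k <- gaussian_kernel(sigma, ksize)
  c1 <- (0.01 * peak)^2
  c2 <- (0.03 * peak)^2
  mu_a <- conv2(a, k); mu_b <- conv2(b, k)
  var_a <- conv2(a * a, k) - mu_a^2
  var_b <- conv2(b * b, k) - mu_b^2
  cov_ab <- conv2(a * b, k) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(s)
}

#' Full metric report for one segmentation
#'
#' Computes every evaluation measure between a mask and its ground truth
#' and returns them as a single tibble row, suitable for binding across
#' images and for CSV/JSON serialization.
#'
#' @param mask,truth binary matrices of identical shape.
#' @param mode definition mode for sensitivity/specificity (see
#'   [sens_spec_acc()]).
#' @param peak peak value used for PSNR and SSIM (1 for binary masks).
#' @return a one-row tibble with columns `dice`, `jaccard`,
#'   `sensitivity`, `specificity`, `accuracy`, `psnr_db`, `ssim` and
#'   `definition_mode`.
#' @export
segmentation_report <- function(mask, truth,
                                mode = c("standard", "as_printed"),
                                peak = 1) {
  mode <- match.arg(mode)
  cc <- confusion(mask, truth)
  r <- sens_spec_acc(cc, mode = mode)
  tibble::tibble(
    dice = dice(cc), jaccard = jaccard(cc),
    sensitivity = r$sensitivity, specificity = r$specificity,
    accuracy = r$accuracy,
    psnr_db = psnr(mask, truth, peak = peak),
    ssim = if (nrow(mask) >= 11 && ncol(mask) >= 11)
      ssim(mask, truth, peak = peak) else NA_real_,
    definition_mode = mode)
}
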