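# File readers and writers: PNG/TIFF images, NIfTI slices, single-slice
# uncompressed DICOM, binary mask PNGs, contour overlays, and the YAML
# run configuration.

#' Read a 2D grayscale image
#'
#' Dispatches on the file extension: PNG and TIFF are read directly
#' (8/16-bit integer data are mapped to `[0, 255]`); NIfTI volumes
#' require a `slice` index and the extracted plane is min-max rescaled to
#' `[0, 255]`; single-slice uncompressed little-endian DICOM is read with
#' rescale slope/intercept applied and then min-max windowed to
#' `[0, 255]`.  RGB images are rejected: convert to grayscale first.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, `.dcm`, `.nii`,
#'   `.nii.gz`).
#' @param slice 1-based slice index along the third axis, required for
#'   3D NIfTI volumes.
#' @return a numeric matrix with values in `[0, 255]`.
#' @export
read_image <- function(path, slice = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  low <- tolower(path)
  if (grepl("\\.png$", low)) {
    img <- png::readPNG(path)
    from_unit_image(img, "PNG")
  } else if (grepl("\\.tiff?$", low)) {
    img <- tiff::readTIFF(path)
    from_unit_image(img, "TIFF")
  } else if (grepl("\\.nii(\\.gz)?$", low)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 3) {
      if (dim(arr)[3] == 1) {
        arr <- arr[, , 1]
      } else if (is.null(slice)) {
        stop("NIfTI volume is 3D: supply a slice index", call. = FALSE)
      } else {
        if (slice < 1 || slice > dim(arr)[3])
          stop(sprintf("slice %d out of range (volume has %d slices)",
                       slice, dim(arr)[3]), call. = FALSE)
        arr <- arr[, , slice]
      }
    } else if (length(dim(arr)) != 2) {
      stop("unsupported NIfTI dimensionality: ",
           length(dim(arr)), "D", call. = FALSE)
    }
    rescale_255(arr)
  } else if (grepl("\\.dcm$", low)) {
    read_dicom_slice(path)
  } else {
    stop("unsupported image format: ", path,
         " (expected png, tif/tiff, dcm, nii or nii.gz)", call. = FALSE)
  }
}

from_unit_image <- function(img, fmt) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      stop(fmt, " image is RGB: convert to grayscale first", call. = FALSE)
    img <- img[, , 1]
  }
  if (min(img) >= 0 && max(img) <= 1) img * 255 else rescale_255(img)
}

rescale_255 <- function(x) {
  x <- x * 1.0
  rng <- range(x)
  if (diff(rng) < 1e-12) return(matrix(0, nrow(x), ncol(x)))
  (x - rng[1]) / diff(rng) * 255
}

# --- minimal DICOM reader -------------------------------------------------
# Single-frame, uncompressed, little-endian DICOM part-10 files (implicit
# or explicit VR).  No R DICOM reader is available to the package, so the
# subset needed for single axial CT/MR slices is parsed directly.

read_uint <- function(raw, little = TRUE) {
  sum(as.numeric(raw) * 256^(if (little) seq_along(raw) - 1
                             else rev(seq_along(raw)) - 1))
}

#' Read a single-slice DICOM file
#'
#' Supports uncompressed little-endian transfer syntaxes (implicit and
#' explicit VR), 8- or 16-bit single-frame grayscale pixel data.  The
#' rescale slope and intercept are applied, then the slice is min-max
#' windowed to `[0, 255]`.
#'
#' @param path path to a `.dcm` file.
#' @return numeric matrix in `[0, 255]`.
#' @export
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  explicit <- TRUE   # the meta group is always explicit VR
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- read_uint(raw[pos:(pos + 1L)])
    elem <- read_uint(raw[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- read_uint(raw[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- read_uint(raw[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- read_uint(raw[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM elements are not supported",
           call. = FALSE)
    val <- if (len > 0) raw[pos:(pos + len - 1L)] else raw[0]
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "0002,0010") {
      ts <- gsub("[\\0 ]+$", "", rawToChar(val))
      if (ts == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (ts != "1.2.840.10008.1.2.1") {
        stop("unsupported DICOM transfer syntax: ", ts,
             " (only uncompressed little endian is supported)",
             call. = FALSE)
      }
    }
    if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103",
                   "0028,1052", "0028,1053", "7fe0,0010"))
      tags[[key]] <- val
    pos <- pos + len
    if (key == "7fe0,0010") break
  }
  need <- c("0028,0010", "0028,0011", "0028,0100", "7fe0,0010")
  if (!all(need %in% names(tags)))
    stop("DICOM file is missing required image tags", call. = FALSE)
  rows <- read_uint(tags[["0028,0010"]])
  cols <- read_uint(tags[["0028,0011"]])
  bits <- read_uint(tags[["0028,0100"]])
  signed <- !is.null(tags[["0028,0103"]]) &&
    read_uint(tags[["0028,0103"]]) == 1
  ds_num <- function(key, default) {
    if (is.null(tags[[key]])) return(default)
    as.numeric(gsub("[\\0 ]+$", "", rawToChar(tags[[key]])))
  }
  slope <- ds_num("0028,1053", 1)
  intercept <- ds_num("0028,1052", 0)
  px <- tags[["7fe0,0010"]]
  vals <- if (bits == 8) {
    as.numeric(px)
  } else if (bits == 16) {
    readBin(px, "integer", n = rows * cols, size = 2, signed = signed,
            endian = "little")
  } else {
    stop("unsupported DICOM bit depth: ", bits, call. = FALSE)
  }
  if (length(vals) < rows * cols)
    stop("DICOM pixel data shorter than Rows x Columns ",
         "(multi-frame files are not supported)", call. = FALSE)
  # DICOM pixel data is row-major (first row first)
  m <- matrix(vals[seq_len(rows * cols)], nrow = rows, ncol = cols,
              byrow = TRUE)
  rescale_255(slope * m + intercept)
}

# --- writers --------------------------------------------------------------

#' Write a binary mask as an 8-bit PNG
#'
#' Round-trips exactly through [read_image()] (0 maps to 0 and 1 to 255).
#'
#' @param mask binary matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  assert_binary(mask)
  png::writePNG(mask, path)
  invisible(path)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param I matrix with values in `[0, 255]`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gray_png <- function(I, path) {
  png::writePNG(pmin(pmax(I / 255, 0), 1), path)
  invisible(path)
}

#' Write a contour overlay PNG
#'
#' The image in grayscale with the mask boundary drawn in red.
#'
#' @param I image matrix in `[0, 255]`.
#' @param mask binary segmentation mask.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_overlay_png <- function(I, mask, path) {
  png::writePNG(overlay_array(I, mask), path)
  invisible(path)
}

# --- run configuration ----------------------------------------------------

#' Read and write run configurations
#'
#' A run configuration is a named list holding [evolution_params()]
#' fields plus run options (`method`, `box_mode`, `definition_mode`,
#' `box`, paths...).  It round-trips losslessly through YAML.
#'
#' @param cfg named list.
#' @param path YAML file path.
#' @return `read_run_config` returns the list; `write_run_config` the
#'   path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  yaml::read_yaml(path)
}

#' Build evolution parameters from a configuration list
#'
#' Unknown fields are ignored; missing fields take the
#' [evolution_params()] defaults.
#'
#' @param cfg named list (e.g. from [read_run_config()]).
#' @return an [evolution_params()] object.
#' @export
params_from_config <- function(cfg) {
  keep <- intersect(names(cfg), names(formals(evolution_params)))
  do.call(evolution_params, cfg[keep])
}
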