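#' Read a grayscale intensity image
#'
#' Reads an 8- or 16-bit grayscale PNG, or a NIfTI volume, into a numeric
#' matrix of nonnegative intensities indexed `[row, col]` with row 1 at the
#' top (rows increase inferiorly in the sagittal convention used throughout
#' the package). PNG intensities are returned on their stored integer scale
#' (0-255 for 8-bit, 0-65535 for 16-bit); they are never rescaled. A NIfTI
#' volume with more than one slice yields a single sagittal slice, by default
#' the middle one (`floor(n/2) + 1`).
#'
#' @param path Path to a `.png`, `.nii` or `.nii.gz` file.
#' @param slice For multi-slice NIfTI input, the 1-based slice index along
#'   the third dimension; `NULL` selects the middle slice.
#' @return Numeric matrix of intensities.
#' @export
read_image <- function(path, slice = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (length(dim(img)) == 3L) {
      ch <- dim(img)[3]
      rgb <- img[, , seq_len(min(3L, ch)), drop = FALSE]
      rng <- apply(rgb, c(1, 2), function(v) diff(range(v)))
      if (max(rng) > 1e-6) {
        stop("format error: '", path, "' is RGB with distinct channels; ",
             "a grayscale image is required")
      }
      img <- rgb[, , 1]
    }
    return(img * (2^depth - 1))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) >= 3L && dim(arr)[3] > 1L) {
      n <- dim(arr)[3]
      if (is.null(slice)) slice <- n %/% 2 + 1L
      if (slice < 1L || slice > n) stop("slice index out of range: ", slice)
      arr <- arr[, , slice]
    } else if (length(dim(arr)) >= 3L) {
      arr <- arr[, , 1]
    }
    if (min(arr) < 0) arr <- arr - min(arr)
    return(matrix(as.numeric(arr), nrow = nrow(arr), ncol = ncol(arr)))
  }
  stop("format error: unsupported image format for '", path, "'")
}

#' Read and validate a 14-class label mask
#'
#' @param path Path to an integer-valued PNG or NIfTI label image whose pixel
#'   values are class ids of `class_map`.
#' @param class_map An [ivd_class_map()].
#' @param slice Passed to [read_image()] for NIfTI input.
#' @return An `ivd_label_mask`: an integer matrix with the class map attached
#'   as attribute `class_map` (and optional `spacing_mm`).
#' @export
read_label_mask <- function(path, class_map = ivd_class_map(), slice = NULL) {
  px <- round(read_image(path, slice = slice))
  label_mask(px, class_map)
}

#' Construct a label mask from an integer matrix
#'
#' @param pixels Integer matrix of class ids.
#' @param class_map An [ivd_class_map()].
#' @param spacing_mm Optional `(row, col)` physical pixel spacing in mm.
#' @export
label_mask <- function(pixels, class_map = ivd_class_map(),
                       spacing_mm = NULL) {
  pixels <- matrix(as.integer(pixels), nrow = nrow(pixels))
  bad <- setdiff(unique(as.vector(pixels)), as.integer(class_map))
  if (length(bad)) {
    stop("validation error: mask contains undeclared class ids: ",
         paste(sort(bad), collapse = ", "))
  }
  if (!is.null(spacing_mm)) {
    if (any(spacing_mm <= 0)) stop("pixel spacing must be positive")
    attr(pixels, "spacing_mm") <- as.numeric(spacing_mm)
  }
  attr(pixels, "class_map") <- class_map
  class(pixels) <- c("ivd_label_mask", class(pixels))
  pixels
}

#' Write a label mask as an 8-bit grayscale PNG of class ids
#'
#' @param mask An `ivd_label_mask` (or integer matrix).
#' @param path Output `.png` path.
#' @export
write_label_mask <- function(mask, path) {
  png::writePNG(matrix(as.integer(mask), nrow = nrow(mask)) / 255, path)
  invisible(path)
}

#' Write an intensity image as PNG
#'
#' Images whose values fit 0-255 are written as 8-bit grayscale PNG;
#' deeper images are written as 16-bit grayscale PNG, so reading the file
#' back recovers the rounded integer intensities either way.
#'
#' @param image Numeric matrix of nonnegative intensities.
#' @param path Output `.png` path.
#' @param bit_depth 8 or 16; default chooses by the data range.
#' @export
write_image <- function(image, path, bit_depth = NULL) {
  if (is.null(bit_depth)) bit_depth <- if (max(image) <= 255) 8 else 16
  if (bit_depth == 8) {
    png::writePNG(pmin(pmax(round(image), 0), 255) / 255, path)
  } else {
    write_png16(image, path)
  }
  invisible(path)
}

#' Remove segmentation burrs by per-class morphological opening
#'
#' Fragmented or spurious boundary pixels ("burrs") in a predicted mask
#' disturb downstream corner detection. Each class is opened independently
#' (erosion then dilation with a disc-shaped structuring element) and the
#' cleaned classes are recomposed; where cleaned classes would overlap, the
#' pixel keeps the first claiming class in id order (openings of disjoint
#' sets rarely overlap, only dilation rounding can collide).
#'
#' @param mask An `ivd_label_mask`.
#' @param radius Structuring-element radius in pixels (disc of diameter
#'   `2*radius + 1`), default 1.
#' @return Cleaned `ivd_label_mask`.
#' @export
clean_mask <- function(mask, radius = 1) {
  stopifnot(radius >= 1)
  cm <- attr(mask, "class_map")
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- matrix(0L, nrow(mask), ncol(mask))
  ids <- sort(setdiff(unique(as.vector(mask)), 0L))
  for (id in ids) {
    bin <- matrix(as.numeric(mask == id), nrow(mask))
    opened <- EBImage::opening(bin, kern)
    sel <- opened > 0.5 & out == 0L
    out[sel] <- id
  }
  label_mask(out, cm, spacing_mm = attr(mask, "spacing_mm"))
}

#' Extract one anatomical structure from a mask
#'
#' Returns the binary region of a class. If the class splits into several
#' connected components (8-connectivity), only the largest is kept and a
#' warning is emitted; fragmented predictions otherwise corrupt area-based
#' measurements.
#'
#' @param mask An `ivd_label_mask`.
#' @param class_id Integer class id, or a role name from the attached class
#'   map (e.g. `"VB_L3"`).
#' @return Logical matrix (the region), with attributes `class_id` and
#'   `n_components`.
#' @export
extract_structure <- function(mask, class_id) {
  cm <- attr(mask, "class_map")
  if (is.character(class_id)) {
    if (!class_id %in% names(cm)) stop("unknown role: ", class_id)
    class_id <- cm[[class_id]]
  }
  class_id <- as.integer(class_id)
  if (!class_id %in% as.integer(cm)) {
    stop("class id ", class_id, " is not in the class map")
  }
  bin <- matrix(as.integer(mask) == class_id, nrow(mask))
  if (!any(bin)) {
    stop("absent-structure error: class ", class_id, " not present in mask")
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin)))
  ncomp <- max(lab)
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    keep <- which.max(sizes)
    bin <- lab == keep
    warning("class ", class_id, " has ", ncomp,
            " connected components; keeping the largest (",
            sizes[keep], " px)")
  }
  structure(bin, class_id = class_id, n_components = as.integer(ncomp))
}
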