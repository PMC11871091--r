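#' CT image container
#'
#' A 2-D slice or 3-D axial stack of Hounsfield units with physical spacing
#' metadata. Slices in a stack are stored in fixed axial order: the slice
#' index increases superior to inferior.
#'
#' @param values Numeric matrix (H x W) or 3-D array (H x W x S) of HU.
#' @param pixel_spacing Numeric length-2, mm per pixel (row, col). A scalar is
#'   recycled. May be `NA` (spacing unknown); physical measurements will then
#'   be unavailable downstream.
#' @param slice_thickness Slice thickness in mm (default 3, the acquisition
#'   protocol value).
#' @param origin Free-text provenance tag.
#' @return Object of class `ct_image`.
#' @export
ct_image <- function(values, pixel_spacing, slice_thickness = 3,
                     origin = "unknown") {
  if (!(is.matrix(values) || (is.array(values) && length(dim(values)) == 3)))
    stop("values must be a matrix or 3-D array")
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("HU values must be finite")
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2)
    stop("pixel_spacing must have length 1 or 2")
  if (!all(is.na(pixel_spacing)) && any(pixel_spacing <= 0, na.rm = TRUE))
    stop("pixel_spacing must be positive")
  if (!is.na(slice_thickness) && slice_thickness <= 0)
    stop("slice_thickness must be positive")
  structure(
    list(values = values, pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = as.numeric(slice_thickness), origin = origin),
    class = "ct_image")
}

#' Label mask container
#'
#' Integer tissue classes aligned with a [ct_image()]; codes as in
#' [tissue_classes()].
#'
#' @param classes Integer matrix or 3-D array with values in 0..7.
#' @inheritParams ct_image
#' @return Object of class `label_mask`.
#' @export
label_mask <- function(classes, pixel_spacing, slice_thickness = 3) {
  if (!(is.matrix(classes) || (is.array(classes) && length(dim(classes)) == 3)))
    stop("classes must be a matrix or 3-D array")
  storage.mode(classes) <- "integer"
  if (anyNA(classes) || any(classes < 0L) || any(classes > 7L))
    stop("class codes must lie in 0..7")
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2)
    stop("pixel_spacing must have length 1 or 2")
  structure(
    list(classes = classes, pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = as.numeric(slice_thickness)),
    class = "label_mask")
}

#' @export
print.ct_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_image> %s px, spacing %s mm, thickness %s mm [%s]\n",
              paste(d, collapse = "x"),
              paste(signif(x$pixel_spacing, 4), collapse = "x"),
              signif(x$slice_thickness, 4), x$origin))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$classes)
  cat(sprintf("<label_mask> %s px, spacing %s mm\n",
              paste(d, collapse = "x"),
              paste(signif(x$pixel_spacing, 4), collapse = "x")))
  tab <- table(factor(x$classes, levels = 0:7,
                      labels = names(tissue_classes())))
  print(tab)
  invisible(x)
}

# n-th axial slice of an image or mask as a 2-D object
#' Extract one axial slice from a 3-D image or mask
#' @param x A `ct_image` or `label_mask`.
#' @param s Slice index.
#' @return 2-D object of the same class.
#' @export
get_slice <- function(x, s) {
  grid <- if (inherits(x, "ct_image")) x$values else x$classes
  if (is.matrix(grid)) {
    if (s != 1L) stop("2-D object has a single slice")
    return(x)
  }
  if (s < 1 || s > dim(grid)[3]) stop("slice index out of range")
  if (inherits(x, "ct_image"))
    ct_image(grid[, , s], x$pixel_spacing, x$slice_thickness, x$origin)
  else
    label_mask(grid[, , s], x$pixel_spacing, x$slice_thickness)
}

#' Number of axial slices
#' @param x A `ct_image` or `label_mask`.
#' @return Integer slice count (1 for a 2-D object).
#' @export
n_slices <- function(x) {
  grid <- if (inherits(x, "ct_image")) x$values else x$classes
  if (is.matrix(grid)) 1L else dim(grid)[3]
}
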