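#' Construct a voxel label map
#'
#' A `label_map` is the anatomical substrate of all volume computations: a 3-D
#' integer array of tissue-class codes on a regular grid in RAS millimetre
#' coordinates, voxel-center convention. The physical position of voxel
#' `(i,j,k)` (1-based indices) is `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param grid 3-D integer array of tissue codes (see [tissue_classes()]).
#' @param spacing_mm Positive numeric length-3, voxel size per axis in mm.
#' @param origin_mm Numeric length-3, physical position of the first voxel
#'   center in mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(grid, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L)
    stop("grid must be a 3-D array")
  storage.mode(grid) <- "integer"
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be three positive finite numbers")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be three finite numbers")
  bad <- setdiff(unique(as.vector(grid)), tissue_classes()$code)
  if (length(bad))
    stop("grid contains undefined tissue codes: ", paste(sort(bad), collapse = ", "))
  structure(
    list(grid = grid, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$grid), collapse = " x "),
      " voxels @ ", paste(format(x$spacing_mm), collapse = " x "),
      " mm, origin (", paste(format(x$origin_mm), collapse = ", "), ") mm\n", sep = "")
  tab <- table(factor(as.vector(x$grid), levels = tissue_classes()$code,
                      labels = tissue_classes()$name))
  print(tab[tab > 0])
  invisible(x)
}

#' Voxel volume of a label map in cubic millimetres
#'
#' @param labelmap A [label_map()].
#' @return Scalar voxel volume (product of the per-axis spacings), mm^3.
#' @export
voxel_volume <- function(labelmap) prod(labelmap$spacing_mm)

#' Physical bounds of a label map
#'
#' Lower and upper voxel-center coordinates per axis, in mm.
#'
#' @param labelmap A [label_map()].
#' @return 2 x 3 matrix with rows `lower`, `upper`.
#' @export
labelmap_bounds <- function(labelmap) {
  lo <- labelmap$origin_mm
  hi <- labelmap$origin_mm + (dim(labelmap$grid) - 1L) * labelmap$spacing_mm
  rbind(lower = lo, upper = hi)
}

#' Read / write a label map as NIfTI-1
#'
#' `write_labelmap()` stores the grid as int16 with spacing in `pixdim` and the
#' origin as the qform offset (RAS, code 2). `read_labelmap()` reverses this
#' and validates that all voxel values are defined tissue codes.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param labelmap A [label_map()].
#' @return `read_labelmap()` returns a [label_map()]; `write_labelmap()`
#'   returns `path` invisibly.
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path)) stop("label map file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D NIfTI volume: ", path)
  if (any(abs(arr - round(arr)) > 0))
    stop("non-integer voxel data in ", path)
  arr <- array(as.integer(round(arr)), dim = dim(arr))
  bad <- setdiff(unique(as.vector(arr)), tissue_classes()$code)
  if (length(bad))
    stop("label map ", path, " contains unknown tissue codes: ",
         paste(sort(bad), collapse = ", "))
  x <- RNifti::xform(img)
  label_map(arr, spacing_mm = RNifti::pixdim(img)[1:3], origin_mm = x[1:3, 4])
}

#' @rdname read_labelmap
#' @export
write_labelmap <- function(labelmap, path) {
  stopifnot(inherits(labelmap, "label_map"))
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(1, labelmap$spacing_mm, 0, 0, 0, 0),
    qoffset_x = labelmap$origin_mm[1],
    qoffset_y = labelmap$origin_mm[2],
    qoffset_z = labelmap$origin_mm[3],
    qform_code = 2
  ))
  img <- RNifti::asNifti(labelmap$grid, reference = hdr, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}
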