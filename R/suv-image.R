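#' SUV image container
#'
#' A minimal 3D scalar image holding standardized uptake values (SUV) on a
#' regular grid. Voxel centers are at `origin + (index - 1) * spacing`, all in
#' millimetres.
#'
#' @param data Numeric 3D array of SUV values.
#' @param spacing Voxel spacing in mm, length 3, all positive.
#' @param origin Physical position (mm) of the center of voxel `[1, 1, 1]`.
#' @return An object of class `suv_image`.
#' @export
suv_image <- function(data, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive finite numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite numbers (mm)")
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "suv_image")
}

#' @export
print.suv_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<suv_image> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  SUV range [%.3g, %.3g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.suv_image <- function(x) dim(x$data)

# volume of one voxel in mL
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

# physical (mm) coordinates of voxel centers given an n x 3 index matrix
voxel_centers_mm <- function(x, idx) {
  sweep(sweep(idx - 1, 2, x$spacing, "*"), 2, x$origin, "+")
}

#' Read and write SUV images and label maps as NIfTI
#'
#' Images are stored with the voxel spacing in the NIfTI `pixdim` field;
#' the origin is kept in the qform translation.
#'
#' @param image A [suv_image()] (or an integer label array for label maps).
#' @param path File path, conventionally ending in `.nii.gz`.
#' @return `read_suv_image()` returns a [suv_image()]; the writers return
#'   `path` invisibly.
#' @export
write_suv_image <- function(image, path) {
  a <- image$data
  attr(a, "pixdim") <- image$spacing
  RNifti::writeNifti(a, path, datatype = "double")
  invisible(path)
}

#' @rdname write_suv_image
#' @export
read_suv_image <- function(path) {
  nii <- RNifti::readNifti(path)
  suv_image(array(as.numeric(nii), dim = dim(nii)),
            spacing = RNifti::pixdim(nii)[1:3])
}

#' @rdname write_suv_image
#' @param lesions A [lesion_set] whose label map should be written.
#' @export
write_label_map <- function(lesions, path) {
  a <- lesions$label_map
  attr(a, "pixdim") <- lesions$spacing
  RNifti::writeNifti(a, path, datatype = "int16")
  invisible(path)
}

#' Maximum-intensity-projection plot of an SUV image
#'
#' Projects the maximum SUV along one axis and draws it as a raster; a quick
#' look at phantom patients and delineations.
#'
#' @param image A [suv_image()].
#' @param axis Axis to project along (1, 2 or 3).
#' @return A ggplot object.
#' @export
plot_suv_mip <- function(image, axis = 3) {
  mip <- apply(image$data, setdiff(1:3, axis), max)
  df <- expand.grid(x = seq_len(nrow(mip)), y = seq_len(ncol(mip)))
  df$suv <- c(mip)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$suv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "SUV") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Maximum intensity projection (axis %d)", axis)) +
    ggplot2::theme_minimal()
}
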