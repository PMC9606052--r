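#' Resample an SUV image and mask to a common voxel size
#'
#' Tri-linear interpolation on a centered grid: the output grid has voxel
#' size `spacing` (default 2 x 2 x 2 mm) and its physical center coincides
#' with the center of the input grid, so an image already at the target
#' spacing is returned unchanged. The mask is interpolated tri-linearly and
#' thresholded at 0.5. Sample points outside the input support take the value
#' of the nearest edge voxel.
#'
#' @param image A [suv_image()] (typically a cropped lesion neighbourhood).
#' @param mask Logical array with the same dimensions as the image.
#' @param spacing Target spacing in mm.
#' @return A `resampled_volume`: list with `data`, `mask`, `spacing` and a
#'   `provenance` record (original spacing, interpolation used).
#' @export
resample_volume <- function(image, mask, spacing = c(2, 2, 2)) {
  stopifnot(inherits(image, "suv_image"))
  if (!identical(dim(mask), dim(image$data))) abort("mask and image dimensions differ")
  if (!any(mask)) abort("mask is empty")
  d_in <- dim(image$data)
  s_in <- image$spacing
  s_out <- as.numeric(spacing)
  d_out <- pmax(1L, as.integer(ceiling(d_in * s_in / s_out)))

  # per-axis sample coordinates, in input voxel-index units (1-based)
  axis_coords <- function(ax) {
    center_in <- (d_in[ax] + 1) / 2              # in input index units
    idx_out <- seq_len(d_out[ax]) - (d_out[ax] + 1) / 2
    center_in + idx_out * s_out[ax] / s_in[ax]
  }
  interp_grid <- function(a) {
    res <- array(0, d_out)
    parts <- vector("list", 3)
    for (ax in 1:3) {
      x <- axis_coords(ax)
      x <- pmin(pmax(x, 1), d_in[ax])            # nearest-edge extrapolation
      i0 <- pmin(floor(x), d_in[ax] - ifelse(d_in[ax] > 1, 1, 0))
      i0 <- pmax(i0, 1)
      frac <- x - i0
      parts[[ax]] <- list(i0 = as.integer(i0),
                          i1 = as.integer(pmin(i0 + 1, d_in[ax])), f = frac)
    }
    for (a1 in 0:1) for (a2 in 0:1) for (a3 in 0:1) {
      ii <- if (a1 == 0) parts[[1]]$i0 else parts[[1]]$i1
      jj <- if (a2 == 0) parts[[2]]$i0 else parts[[2]]$i1
      kk <- if (a3 == 0) parts[[3]]$i0 else parts[[3]]$i1
      w1 <- if (a1 == 0) 1 - parts[[1]]$f else parts[[1]]$f
      w2 <- if (a2 == 0) 1 - parts[[2]]$f else parts[[2]]$f
      w3 <- if (a3 == 0) 1 - parts[[3]]$f else parts[[3]]$f
      w <- outer(outer(w1, w2), w3)
      if (any(w > 0)) res <- res + w * a[ii, jj, kk, drop = FALSE]
    }
    res
  }
  out_data <- interp_grid(image$data)
  out_mask <- interp_grid(array(as.numeric(mask), d_in)) >= 0.5
  if (!any(out_mask)) {
    # very small masks can vanish under the 0.5 threshold; fall back to the
    # voxel nearest the mask centroid so downstream features stay defined
    ai <- arrayInd(which(mask), d_in)
    cen <- colMeans(ai)
    near <- round((cen - (d_in + 1) / 2) * s_in / s_out + (d_out + 1) / 2)
    near <- pmin(pmax(near, 1), d_out)
    out_mask[near[1], near[2], near[3]] <- TRUE
  }
  structure(list(data = out_data, mask = out_mask, spacing = s_out,
                 provenance = list(original_spacing = s_in,
                                   original_dim = d_in,
                                   interpolation = "trilinear-centered",
                                   mask_threshold = 0.5)),
            class = "resampled_volume")
}

#' Fixed-bin-size discretization of a resampled volume
#'
#' Grey level of an in-mask voxel with SUV `x` is
#' `floor((x - anchor) / bin_width) + 1`. The anchor defaults to SUV 0 so
#' that grey levels are comparable across lesions and patients.
#'
#' @param volume A [resample_volume()] result.
#' @param bin_width Bin size in SUV, default 0.25.
#' @param anchor Lower edge of the first bin, default 0.
#' @return A `discretized_volume`: list with `levels` (integer array, `NA`
#'   outside mask), `mask`, `n_levels`, `bin_width`, `anchor`, `spacing`.
#' @export
discretize <- function(volume, bin_width = 0.25, anchor = 0.0) {
  stopifnot(inherits(volume, "resampled_volume"))
  if (bin_width <= 0) abort("bin_width must be positive")
  vals <- volume$data[volume$mask]
  if (any(!is.finite(vals))) abort("non-finite SUV inside the mask")
  if (any(vals <= anchor - bin_width)) {
    abort("in-mask SUV at or below anchor - bin_width; grey levels would be < 1")
  }
  lv <- array(NA_integer_, dim(volume$data))
  lv[volume$mask] <- pmax(1L, as.integer(floor((vals - anchor) / bin_width)) + 1L)
  structure(list(levels = lv, mask = volume$mask,
                 n_levels = max(lv, na.rm = TRUE),
                 bin_width = bin_width, anchor = anchor,
                 spacing = volume$spacing),
            class = "discretized_volume")
}
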