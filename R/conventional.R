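#' Conventional PET features on the original image grid
#'
#' The five conventional features are computed without resampling: metabolic
#' tumor volume (MTV, mL), SUVmax, SUVpeak, SUVmean and total lesion
#' glycolysis (TLG = MTV x SUVmean). SUVpeak is the largest mean SUV in a
#' 1-mL sphere centered on any in-VOI voxel; the sphere may extend outside
#' the VOI (but not outside the image).
#'
#' @param image A [suv_image()].
#' @param voi A `lesion_set` (the union of its lesions is used), a logical
#'   mask array, or a single lesion id when `lesions` is given.
#' @return A one-row tibble: `conv_mtv_ml`, `conv_suv_max`, `conv_suv_peak`,
#'   `conv_suv_mean`, `conv_tlg`.
#' @export
conventional_pet <- function(image, voi) {
  stopifnot(inherits(image, "suv_image"))
  mask <- if (inherits(voi, "lesion_set")) voi$label_map > 0 else as.array(voi)
  if (!any(mask)) abort("empty VOI")
  idx <- which(mask)
  x <- image$data[idx]
  mtv <- length(idx) * voxel_volume_ml(image)
  ai <- arrayInd(idx, dim(mask))
  offs <- sphere_offsets(image$spacing, 1)
  pk <- max(sphere_mean_at(image$data, ai, offs))
  mu <- mean(x)
  tibble(conv_mtv_ml = mtv, conv_suv_max = max(x), conv_suv_peak = pk,
         conv_suv_mean = mu, conv_tlg = mtv * mu)
}
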