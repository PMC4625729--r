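#' Segment the lungs from a calibrated CT volume
#'
#' Threshold-and-connectivity lung segmentation: voxels below `air_hu` are
#' air-like; connected components (6-connectivity) touching the volume
#' border are outside air or trachea/main bronchi and are discarded; of the
#' interior components, the largest (and any comparable second component)
#' are kept as the lung fields. A morphological closing followed by 3-D
#' hole filling re-includes embedded dense structure — intrapulmonary
#' vessels and ground-glass above the air threshold — so that vessels sit
#' inside the mask and are excluded from the HAA numerator only by the HU
#' window, consistent with how blood attenuation (~ +40 HU) is handled in
#' lung densitometry.
#'
#' @param vol a [ct_volume()].
#' @param air_hu HU threshold below which a voxel is considered air-like.
#' @param closing_radius radius (voxels) of the ball used for closing.
#' @return A list of class `lung_mask` with elements `mask` (logical 3-D
#'   array) and `provenance` (`"segmented"`).
#' @export
segment_lungs <- function(vol, air_hu = -320, closing_radius = 2) {
  stopifnot(inherits(vol, "ct_volume"))
  dims <- dim(vol$voxels)
  air <- vol$voxels < air_hu
  if (!any(air)) stop_named("no lung detected: no air-like voxels below %g HU",
                            air_hu)
  lab <- .cc_label_3d(air, dims)
  border <- border_labels(lab)
  sizes <- tabulate(lab[lab > 0L])
  interior <- setdiff(which(sizes > 0L), border)
  if (length(interior) == 0L)
    stop_named("no lung detected: all air components touch the volume border")
  sizes_int <- sizes[interior]
  biggest <- max(sizes_int)
  # keep up to two components comparable in size to the largest (the lungs
  # may be one fused component or two separate ones)
  keep <- interior[sizes_int >= 0.2 * biggest]
  if (length(keep) > 2L) keep <- keep[order(sizes[keep], decreasing = TRUE)][1:2]
  if (biggest < 64L)
    stop_named("no lung detected: largest interior air component is only %d voxels",
               biggest)
  mask <- array(lab %in% keep, dim = dims)
  if (closing_radius > 0) {
    off <- ball_offsets(closing_radius)
    mask <- .morph_3d(mask, dims, off, TRUE)
    mask <- .morph_3d(mask, dims, off, FALSE)
  }
  mask <- fill_holes_3d(mask)
  structure(list(mask = mask, provenance = "segmented"), class = "lung_mask")
}

# Labels of connected components touching any face of the volume.
border_labels <- function(lab) {
  d <- dim(lab)
  faces <- c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
             lab[, , 1], lab[, , d[3]])
  unique(faces[faces > 0L])
}

# Fill cavities: background components not connected to the volume border.
fill_holes_3d <- function(mask) {
  dims <- dim(mask)
  bg <- .cc_label_3d(!mask, dims)
  outside <- border_labels(bg)
  holes <- bg > 0L & !(bg %in% outside)
  mask | array(holes, dim = dims)
}

#' Wrap a ground-truth lung labelling as a lung mask
#'
#' @param mask logical 3-D array.
#' @return A `lung_mask` with provenance `"ground_truth"`.
#' @export
ground_truth_mask <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  structure(list(mask = as.array(mask > 0), provenance = "ground_truth"),
            class = "lung_mask")
}

as_mask_array <- function(mask, vol) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  if (!identical(dim(m), dim(vol$voxels)))
    stop_named("mask shape %s does not match volume shape %s",
               paste(dim(m), collapse = "x"),
               paste(dim(vol$voxels), collapse = "x"))
  m <- m > 0
  if (!any(m)) stop_named("empty lung mask")
  m
}

#' High attenuation area fraction
#'
#' Fraction of lung-mask voxels whose HU lies inside the high-attenuation
#' window (default \[-600, -250\], both endpoints inclusive). Multiplied by
#' 100 this is the HAA% used as the quantitative ILA metric.
#'
#' @param vol a [ct_volume()].
#' @param mask a `lung_mask` or logical array of matching shape.
#' @param window length-2 HU interval (low, high).
#' @return Fraction in \[0, 1\].
#' @export
compute_haa <- function(vol, mask, window = c(-600, -250)) {
  stopifnot(inherits(vol, "ct_volume"))
  if (length(window) != 2L || window[1] > window[2])
    stop_named("inverted HU window: low (%g) > high (%g)", window[1], window[2])
  m <- as_mask_array(mask, vol)
  v <- vol$voxels[m]
  sum(v >= window[1] & v <= window[2]) / length(v)
}

#' LAA-950 emphysema fraction
#'
#' Fraction of lung-mask voxels strictly below the emphysema threshold
#' (default -950 HU), the standard low-attenuation-area emphysema metric.
#'
#' @inheritParams compute_haa
#' @param threshold_hu HU threshold.
#' @return Fraction in \[0, 1\].
#' @export
compute_emphysema <- function(vol, mask, threshold_hu = -950) {
  stopifnot(inherits(vol, "ct_volume"))
  m <- as_mask_array(mask, vol)
  v <- vol$voxels[m]
  sum(v < threshold_hu) / length(v)
}

#' CT-derived total lung capacity
#'
#' Lung-mask voxel count times the physical voxel volume, in litres.
#'
#' @inheritParams compute_haa
#' @return TLC in litres.
#' @export
compute_tlc <- function(vol, mask) {
  stopifnot(inherits(vol, "ct_volume"))
  if (any(vol$spacing_mm <= 0)) stop_named("nonpositive voxel spacing")
  m <- as_mask_array(mask, vol)
  sum(m) * prod(vol$spacing_mm) / 1e6
}

#' Full densitometry panel for one scan
#'
#' Convenience wrapper computing HAA fraction, LAA-950 fraction, TLC and
#' the lung voxel count in one call.
#'
#' @inheritParams compute_haa
#' @param emph_threshold_hu emphysema HU threshold.
#' @return A list of class `densitometry_result` with fields `haa_fraction`,
#'   `emph_fraction`, `tlc_l`, `lung_voxel_count`, `hu_window`,
#'   `emph_threshold_hu`.
#' @export
densitometry <- function(vol, mask, window = c(-600, -250),
                         emph_threshold_hu = -950) {
  m <- as_mask_array(mask, vol)
  structure(list(
    haa_fraction = compute_haa(vol, m, window),
    emph_fraction = compute_emphysema(vol, m, emph_threshold_hu),
    tlc_l = compute_tlc(vol, m),
    lung_voxel_count = sum(m),
    hu_window = window,
    emph_threshold_hu = emph_threshold_hu
  ), class = "densitometry_result")
}

#' @export
print.densitometry_result <- function(x, ...) {
  cat(sprintf(
    "<densitometry> HAA %.2f%%  LAA-950 %.2f%%  TLC %.2f L  (%d lung voxels)\n",
    100 * x$haa_fraction, 100 * x$emph_fraction, x$tlc_l, x$lung_voxel_count))
  invisible(x)
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical arrays (or `lung_mask` objects) of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "lung_mask")) a <- a$mask
  if (inherits(b, "lung_mask")) b <- b$mask
  stopifnot(identical(dim(a), dim(b)))
  a <- a > 0; b <- b > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
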