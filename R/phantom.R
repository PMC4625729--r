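#' CT volume container
#'
#' A minimal container for a calibrated chest-CT volume: a 3-D array of
#' Hounsfield Unit (HU) values plus the physical voxel spacing in mm.
#' HU values must lie in the representable CT range \[-1024, 3071\].
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing_mm numeric length-3, voxel spacing in mm per axis (> 0).
#' @param origin numeric length-3 physical offset, informational only.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_named("'voxels' must be a 3-D array")
  if (any(voxels < -1024 | voxels > 3071, na.rm = TRUE))
    stop_named("HU values must lie in [-1024, 3071]")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop_named("'spacing_mm' must be 3 positive numbers")
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, HU [%d, %d]\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x "),
              round(min(x$voxels)), round(max(x$voxels))))
  invisible(x)
}

# Tissue classes used by the phantom truth label map.
PHANTOM_CLASSES <- c("air", "body", "airway", "parenchyma", "ggo",
                     "emphysema", "vessel")

#' Phantom specification
#'
#' Parameters of the synthetic chest phantom: grid geometry, the HU assigned
#' to each tissue class, the target fractions of lung voxels occupied by
#' ground-glass (HAA-window) material, emphysematous lung and intrapulmonary
#' vessels, and the additive image noise level. Noise acts as a proxy for
#' the image-quality degradation seen with increasing BMI.
#'
#' @param grid_shape integer length-3, voxel counts per axis (each >= 16).
#' @param voxel_spacing numeric length-3, mm per axis.
#' @param body_hu HU of non-lung soft tissue (~ +40, the attenuation of blood).
#' @param lung_base_hu mean aerated-parenchyma HU (~ -850).
#' @param ggo_fraction target fraction of lung voxels filled with ground-glass
#'   material whose HU lies in the high-attenuation-area window.
#' @param ggo_hu_range HU interval for ground-glass blobs; must be contained
#'   in \[-600, -250\].
#' @param emph_fraction target fraction of lung voxels below -950 HU.
#' @param vessel_fraction target fraction of lung voxels set to blood
#'   attenuation (`body_hu`).
#' @param noise_sd SD of additive Gaussian noise in HU (applied everywhere,
#'   then clipped to the CT range).
#' @param seed RNG seed governing blob placement and noise.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128),
                         voxel_spacing = c(2.5, 2.5, 2.5),
                         body_hu = 40,
                         lung_base_hu = -850,
                         ggo_fraction = 0.04,
                         ggo_hu_range = c(-600, -250),
                         emph_fraction = 0.02,
                         vessel_fraction = 0.03,
                         noise_sd = 20,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop_named("grid too small: each axis needs >= 16 voxels to place a lung")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop_named("'voxel_spacing' must be 3 positive numbers")
  check_number(ggo_fraction, "ggo_fraction", 0, 1)
  check_number(emph_fraction, "emph_fraction", 0, 1)
  check_number(vessel_fraction, "vessel_fraction", 0, 1)
  if (ggo_fraction + emph_fraction + vessel_fraction > 1)
    stop_named("impossible fraction combination: ggo + emphysema + vessel > 1")
  if (length(ggo_hu_range) != 2L || ggo_hu_range[1] > ggo_hu_range[2] ||
      ggo_hu_range[1] < -600 || ggo_hu_range[2] > -250)
    stop_named("'ggo_hu_range' must be an interval within [-600, -250]")
  check_number(body_hu, "body_hu", -1024, 3071)
  check_number(lung_base_hu, "lung_base_hu", -1024, 3071)
  check_number(noise_sd, "noise_sd", 0, Inf)
  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 body_hu = body_hu, lung_base_hu = lung_base_hu,
                 ggo_fraction = ggo_fraction, ggo_hu_range = ggo_hu_range,
                 emph_fraction = emph_fraction,
                 vessel_fraction = vessel_fraction,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

# Grow quasi-spherical blobs inside `avail` (logical 3-D array) until exactly
# `target` voxels are selected; the last blob is trimmed centre-outwards so
# the selected count is exact. Returns linear voxel indices.
place_blobs <- function(avail, target, radius_range, dims) {
  if (target <= 0) return(integer(0))
  sel <- integer(0)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  guard <- 0L
  while (length(sel) < target) {
    guard <- guard + 1L
    if (guard > 10000L)
      stop_named("blob placement failed to reach the requested fraction")
    pool <- which(avail)
    if (length(pool) == 0L) break
    centre <- pool[sample.int(length(pool), 1L)]
    r <- runif(1, radius_range[1], radius_range[2])
    off <- ball_offsets(r)
    cc <- arrayInd(centre, dims)
    xx <- cc[1] + off[, 1]; yy <- cc[2] + off[, 2]; zz <- cc[3] + off[, 3]
    ok <- xx >= 1 & xx <= dims[1] & yy >= 1 & yy <= dims[2] &
      zz >= 1 & zz <= dims[3]
    idx <- (xx[ok] - 1L) * strides[1] + (yy[ok] - 1L) * strides[2] +
      (zz[ok] - 1L) * strides[3] + 1L
    d2 <- (xx[ok] - cc[1])^2 + (yy[ok] - cc[2])^2 + (zz[ok] - cc[3])^2
    keep <- avail[idx]
    idx <- idx[keep]; d2 <- d2[keep]
    if (length(idx) == 0L) next
    need <- target - length(sel)
    if (length(idx) > need) idx <- idx[order(d2)][seq_len(need)]
    avail[idx] <- FALSE
    sel <- c(sel, idx)
  }
  sel
}

# Vessel-like capsules: spheres swept along random line segments.
place_vessels <- function(avail, target, dims) {
  if (target <= 0) return(integer(0))
  sel <- integer(0)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  guard <- 0L
  while (length(sel) < target) {
    guard <- guard + 1L
    if (guard > 10000L)
      stop_named("vessel placement failed to reach the requested fraction")
    pool <- which(avail)
    if (length(pool) == 0L) break
    start <- arrayInd(pool[sample.int(length(pool), 1L)], dims)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    len <- runif(1, 8, 24)
    r <- runif(1, 1, 2)
    t <- seq(0, len, by = 0.5)
    pts <- unique(round(cbind(start[1] + t * dir[1], start[2] + t * dir[2],
                              start[3] + t * dir[3])))
    off <- ball_offsets(r)
    xx <- rep(pts[, 1], each = nrow(off)) + off[, 1]
    yy <- rep(pts[, 2], each = nrow(off)) + off[, 2]
    zz <- rep(pts[, 3], each = nrow(off)) + off[, 3]
    ok <- xx >= 1 & xx <= dims[1] & yy >= 1 & yy <= dims[2] &
      zz >= 1 & zz <= dims[3]
    idx <- unique((xx[ok] - 1L) * strides[1] + (yy[ok] - 1L) * strides[2] +
                    (zz[ok] - 1L) * strides[3] + 1L)
    idx <- idx[avail[idx]]
    if (length(idx) == 0L) next
    need <- target - length(sel)
    if (length(idx) > need) {
      ai <- arrayInd(idx, dims)
      d2 <- (ai[, 1] - start[1])^2 + (ai[, 2] - start[2])^2 +
        (ai[, 3] - start[3])^2
      idx <- idx[order(d2)][seq_len(need)]
    }
    avail[idx] <- FALSE
    sel <- c(sel, idx)
  }
  sel
}

#' Generate a synthetic chest-CT phantom with ground truth
#'
#' Builds a torso of soft tissue containing two ellipsoidal lung fields and
#' a tracheal air column, then fills the requested fractions of lung voxels
#' with ground-glass blobs (HU inside the HAA window), emphysematous blobs
#' (HU below -950) and vessel capsules (blood attenuation), adds Gaussian
#' noise, and rounds to integer HU. Truth fractions are obtained by counting
#' labelled voxels, so blob rasterisation error is absorbed into the truth,
#' not into validation tolerances. Placement and noise are fully determined
#' by `spec$seed`; the RNG stream order is ground-glass blobs, emphysema
#' blobs, vessels, then noise.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [ct_volume()]) and `truth`, the
#'   latter holding `lung_mask` (logical array; parenchyma, ground-glass,
#'   emphysema and intrapulmonary vessels are all inside the mask),
#'   `label_map` (integer array with a `classes` attribute),
#'   `true_haa_fraction`, `true_emph_fraction` and `true_lung_volume_l`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dims <- spec$grid_shape
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    x <- seq_len(nx); y <- seq_len(ny); z <- seq_len(nz)
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2

    lab <- array(1L, dim = dims)  # 1 = air

    # Torso: elliptical cylinder along z.
    xb <- ((x - cx) / (0.45 * nx))^2
    yb <- ((y - cy) / (0.38 * ny))^2
    body2d <- outer(xb, yb, "+") <= 1
    lab[rep(body2d, nz)] <- 2L

    # Two ellipsoidal lungs.
    lung <- array(FALSE, dim = dims)
    for (sgn in c(-1, 1)) {
      lx <- ((x - (cx + sgn * 0.22 * nx)) / (0.16 * nx))^2
      ly <- ((y - cy) / (0.26 * ny))^2
      lz <- ((z - cz) / (0.36 * nz))^2
      e <- outer(outer(lx, ly, "+"), lz, "+") <= 1
      lung <- lung | e
    }
    lab[lung] <- 4L  # parenchyma

    # Trachea: air column entering from the top slice, anterior of centre.
    tr <- max(2, round(0.025 * nx))
    tx <- (x - cx)^2
    ty <- (y - (cy - 0.1 * ny))^2
    tr2d <- outer(tx, ty, "+") <= tr^2
    zmask <- z >= round(0.55 * nz)
    trachea <- array(rep(tr2d, nz), dim = dims) &
      array(rep(zmask, each = nx * ny), dim = dims) & !lung
    lab[trachea] <- 3L

    n_lung <- sum(lung)
    if (n_lung == 0L) stop_named("grid too small to place any lung")

    avail <- lab == 4L
    ggo_idx <- place_blobs(avail, round(spec$ggo_fraction * n_lung),
                           c(2.5, 5.5), dims)
    lab[ggo_idx] <- 5L
    avail[ggo_idx] <- FALSE
    emph_idx <- place_blobs(avail, round(spec$emph_fraction * n_lung),
                            c(2.5, 5.5), dims)
    lab[emph_idx] <- 6L
    avail[emph_idx] <- FALSE
    ves_idx <- place_vessels(avail, round(spec$vessel_fraction * n_lung), dims)
    lab[ves_idx] <- 7L

    hu <- array(-1000, dim = dims)
    hu[lab == 2L] <- spec$body_hu
    hu[lab == 4L] <- spec$lung_base_hu
    if (length(ggo_idx))
      hu[ggo_idx] <- runif(length(ggo_idx), spec$ggo_hu_range[1],
                           spec$ggo_hu_range[2])
    if (length(emph_idx)) hu[emph_idx] <- runif(length(emph_idx), -1000, -960)
    hu[ves_idx] <- spec$body_hu
    if (spec$noise_sd > 0)
      hu <- hu + rnorm(length(hu), 0, spec$noise_sd)
    hu <- round(pmin(pmax(hu, -1024), 3071))

    lung_mask <- lab >= 4L  # parenchyma + ggo + emphysema + vessels
    attr(lab, "classes") <- PHANTOM_CLASSES
    vol_mm3 <- prod(spec$voxel_spacing)
    truth <- list(
      lung_mask = lung_mask,
      label_map = lab,
      true_haa_fraction = sum(lab == 5L) / n_lung,
      true_emph_fraction = sum(lab == 6L) / n_lung,
      true_lung_volume_l = n_lung * vol_mm3 / 1e6
    )
    list(volume = ct_volume(hu, spec$voxel_spacing), truth = truth)
  })
}

#' Read and write CT volumes as NIfTI
#'
#' Volumes are stored as single-file NIfTI with int16 HU values and the
#' voxel spacing in the header, so a write/read round trip preserves the
#' integer HU array exactly and the spacing to float precision.
#'
#' @param vol a [ct_volume()].
#' @param path file path (conventionally `.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [ct_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  arr <- array(as.integer(round(vol$voxels)), dim = dim(vol$voxels))
  attr(arr, "pixdim") <- vol$spacing_mm
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_named("no such file: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_named("expected a 3-D volume, got %d dimension(s)", length(d))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop_named("volume header is missing a positive voxel spacing (pixdim)")
  ct_volume(array(as.numeric(img), dim = d), sp[1:3])
}
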