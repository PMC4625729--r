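test_that("phantom truth fractions hit the requested composition", {
  sp <- small_phantom_spec(ggo_fraction = 0.10, emph_fraction = 0.04,
                           noise_sd = 0, seed = 3)
  ph <- generate_phantom(sp)
  expect_lt(abs(ph$truth$true_haa_fraction - 0.10), 0.01)
  expect_lt(abs(ph$truth$true_emph_fraction - 0.04), 0.01)

  # no HAA material placed -> exact zero
  ph0 <- generate_phantom(small_phantom_spec(ggo_fraction = 0,
                                             emph_fraction = 0,
                                             noise_sd = 0, seed = 1))
  expect_identical(ph0$truth$true_haa_fraction, 0)
  expect_identical(ph0$truth$true_emph_fraction, 0)
})

test_that("phantom generation is deterministic given the seed", {
  sp <- small_phantom_spec(seed = 9)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$label_map, b$truth$label_map)
  c <- generate_phantom(small_phantom_spec(seed = 10))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("phantom label classes partition the grid and HU stays in range", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 40, seed = 5))
  lab <- ph$truth$label_map
  expect_true(all(lab %in% seq_along(attr(lab, "classes"))))
  expect_true(all(ph$volume$voxels >= -1024 & ph$volume$voxels <= 3071))
  # lung mask = parenchyma + ggo + emphysema + vessels
  expect_identical(ph$truth$lung_mask, array(lab >= 4L, dim = dim(lab)))
})

test_that("truth fractions are invariant to voxel spacing; lung volume scales", {
  a <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                     voxel_spacing = c(1, 1, 1), seed = 4))
  b <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                     voxel_spacing = c(3, 3, 3), seed = 4))
  expect_identical(a$truth$true_haa_fraction, b$truth$true_haa_fraction)
  expect_identical(a$truth$true_emph_fraction, b$truth$true_emph_fraction)
  expect_equal(b$truth$true_lung_volume_l, 27 * a$truth$true_lung_volume_l)
})

test_that("image noise can only inflate measured HAA on ground-glass-free lungs", {
  for (seed in 1:3) {
    haa <- vapply(c(0, 50, 100, 150), function(sd) {
      ph <- generate_phantom(small_phantom_spec(ggo_fraction = 0,
                                                emph_fraction = 0,
                                                noise_sd = sd, seed = seed))
      compute_haa(ph$volume, ground_truth_mask(ph$truth$lung_mask))
    }, numeric(1))
    expect_true(all(diff(haa) >= 0))
    expect_gt(haa[4], 0)  # heavy noise pushes parenchyma into the window
  }
})

test_that("impossible specs are rejected with informative errors", {
  expect_error(phantom_spec(ggo_fraction = 0.6, emph_fraction = 0.3,
                            vessel_fraction = 0.2),
               "impossible fraction")
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), "grid too small")
  expect_error(phantom_spec(ggo_hu_range = c(-700, -250)), "ggo_hu_range")
  expect_error(phantom_spec(ggo_hu_range = c(-250, -600)), "ggo_hu_range")
})

test_that("volumes round-trip through NIfTI exactly", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                      voxel_spacing = c(0.7, 0.7, 1.25),
                                      seed = 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, f)
  v2 <- read_volume(f)
  expect_identical(as.numeric(v2$voxels), as.numeric(ph$volume$voxels))
  expect_equal(v2$spacing_mm, ph$volume$spacing_mm, tolerance = 1e-6)
})

test_that("reading malformed volumes fails with a format diagnostic", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img2d <- RNifti::asNifti(matrix(0L, 10, 10), datatype = "int16")
  RNifti::writeNifti(img2d, f)
  expect_error(read_volume(f), "3-D")
  expect_error(read_volume(file.path(tempdir(), "does-not-exist.nii")),
               "no such file")
})
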