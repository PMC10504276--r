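flat_volume <- function(nz = 40, nx = 16, ny = 12, z0 = 10, tissue_db = 10,
                        noise_db = -20) {
  v <- array(noise_db, c(nz, nx, ny))
  v[z0:nz, , ] <- tissue_db
  oct_volume(v, contrast = "dB")
}

test_that("a flat high-contrast surface is recovered exactly", {
  vol <- flat_volume(z0 = 10)
  s <- segment_surface(vol, noise_floor_db = -20)
  expect_true(all(s$valid))
  expect_true(all(s$height == 10))
})

test_that("an all-noise volume yields no valid columns", {
  set.seed(30)
  v <- array(rnorm(40 * 16 * 12, mean = -20, sd = 1), c(40, 16, 12))
  s <- segment_surface(oct_volume(v), noise_floor_db = -20)
  expect_false(any(s$valid))
})

test_that("phantom surfaces are recovered within 2 pixels RMS", {
  ph <- build_kidney_phantom("obstructed_2w", grid_shape = c(48, 64, 16),
                             seed = 31)
  db_imgs <- lapply(1:16, function(y) {
    st <- simulate_frame_stack(ph, y, protocol_timestamps(liv_protocol(), y))
    rowMeans(to_db_intensity(st), dims = 2)
  })
  vol <- volume_assemble(db_imgs, pitch_um = ph$pixel_pitch_um)
  s <- segment_surface(vol, noise_floor_db = 10 * log10(ph$noise_variance))
  expect_gt(mean(s$valid), 0.95)
  err <- (s$height - ph$surface_height)[s$valid]
  expect_lte(sqrt(mean(err^2)), 2)
})

test_that("slab extraction pads the bottom with exclusion, not zeros", {
  vol <- flat_volume(nz = 30, z0 = 20, tissue_db = 5)
  s <- segment_surface(vol, noise_floor_db = -20)
  slab <- extract_slab(vol, s, slab_pixels = 20)
  expect_equal(attr(slab, "slab_um"), 20 * 7.24)
  # only 11 tissue pixels exist below the surface; the rest must be NA
  expect_true(all(is.na(slab[12:20, , ])))
  proj <- slab_average_projection(vol, s, 20)
  expect_true(all(abs(proj$image - 5) < 1e-12))  # mean unaffected by the pad
})

test_that("slab projection basics: physical extent, constant volumes, slab of 1", {
  vol <- flat_volume(z0 = 5, tissue_db = 7)
  s <- segment_surface(vol, noise_floor_db = -20)
  proj <- slab_average_projection(vol, s, 100 %/% 3)
  expect_equal(proj$slab_um, (100 %/% 3) * 7.24)
  expect_true(all(proj$image == 7))

  p1 <- slab_average_projection(vol, s, 1)
  expect_true(all(p1$image == 7))
  expect_error(extract_slab(vol, s, 0), "slab_pixels")

  # 100 px at the 7.24 um axial pitch is 724 um
  deep <- flat_volume(nz = 120, z0 = 5)
  sd_ <- segment_surface(deep, noise_floor_db = -20)
  expect_equal(slab_average_projection(deep, sd_, 100)$slab_um, 724)
})

test_that("projection is linear in the volume on valid columns", {
  set.seed(32)
  v <- array(abs(rnorm(40 * 16 * 12)) + 5, c(40, 16, 12))
  v[1:8, , ] <- -30
  vol <- oct_volume(v)
  s <- segment_surface(vol, noise_floor_db = -30, margin_db = 10)
  p1 <- slab_average_projection(vol, s, 10)
  vol3 <- oct_volume(3 * v)
  p3 <- slab_average_projection(vol3, s, 10)
  expect_equal(p3$image[p3$valid], 3 * p1$image[p1$valid], tolerance = 1e-12)
})

test_that("invalid surface columns propagate as invalid in projections", {
  vol <- flat_volume(z0 = 10)
  vol$values[, 3, 4] <- -20  # one column with no tissue
  s <- segment_surface(vol, noise_floor_db = -20, smooth_window = 1)
  expect_false(s$valid[3, 4])
  proj <- slab_average_projection(vol, s, 10)
  expect_false(proj$valid[3, 4])
  expect_true(is.na(proj$image[3, 4]))
  comp <- liv_composite(proj$image * 0, proj$image, value_window = c(-5, 15))
  expect_equal(comp$rgb[3, 4, ], c(0, 0, 0))  # rendered black
})

test_that("en face slices address depths in um or index consistently", {
  set.seed(33)
  v <- array(rnorm(60 * 8 * 8), c(60, 8, 8))
  vol <- oct_volume(v)  # axial pitch 7.24 um
  sl <- en_face_slice(vol, depth_um = 282)
  expect_identical(attr(sl, "depth_index"), 40L)  # offset round(282/7.24)=39
  expect_equal(sl, en_face_slice(vol, depth_index = 40), tolerance = 0)
  top <- en_face_slice(vol, depth_um = 0)
  expect_equal(unclass(top)[, ], v[1, , ], ignore_attr = TRUE)
  expect_error(en_face_slice(vol, depth_um = 2000), "outside")
})
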