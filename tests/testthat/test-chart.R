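# Chart detection, tile extraction and occlusion QC on rendered scenes with
# known ground truth.

test_that("the chart reference table has 24 uniquely indexed tiles", {
  ref <- ref_fixture()
  expect_equal(nrow(ref$table), 24)
  expect_equal(sort(ref$table$tile_index), 1:24)
  expect_equal(dim(chart_lab(ref)), c(24, 3))
})

test_that("the chart is located to sub-pixel accuracy in a rendered scene", {
  sc <- scene_fixture()
  g <- detect_chart(sc$image)
  err <- sqrt(rowSums((g$centres - sc$truth$tile_centres)^2))
  expect_lt(max(err), 3)
  expect_gt(g$score, 0.9)
})

test_that("an image of pure noise raises chart-not-found", {
  set.seed(1)
  noise <- array(runif(120 * 160 * 3, 0, 255), dim = c(120, 160, 3))
  expect_error(detect_chart(noise), "chart not found")
})

test_that("a half-turn rotated chart is returned in canonical tile order", {
  sc <- render_scene(scene_spec(seed = 8, chart_rotation = 180))
  g <- detect_chart(sc$image)
  err <- sqrt(rowSums((g$centres - sc$truth$tile_centres)^2))
  expect_lt(max(err), 3)
})

test_that("detection is translation-equivariant", {
  base <- detect_chart(render_scene(
    scene_spec(seed = 9, chart_offset = c(x = 10, y = 20)))$image,
    scales = 1, rotations = 0)
  for (shift in list(c(4, 7), c(15, 1))) {
    g <- detect_chart(render_scene(
      scene_spec(seed = 9,
                 chart_offset = c(x = 10 + shift[1], y = 20 + shift[2])))$image,
      scales = 1, rotations = 0)
    delta <- sweep(g$centres - base$centres, 2, shift)
    expect_lt(max(abs(delta)), 1)
  }
})

test_that("noiseless tiles are extracted exactly; noisy ones within 1 unit", {
  sc <- render_scene(scene_spec(seed = 4, noise_sd = 0))
  g <- detect_chart(sc$image, scales = 1, rotations = 0)
  obs <- extract_tile_values(sc$image, g)
  expect_equal(obs$rgb_obs, sc$truth$tile_srgb, tolerance = 1e-9)

  scn <- render_scene(scene_spec(seed = 4, noise_sd = 2))
  obsn <- extract_tile_values(scn$image, detect_chart(scn$image, scales = 1,
                                                      rotations = 0))
  expect_lt(max(abs(obsn$rgb_obs - sc$truth$tile_srgb)), 1)
})

test_that("the trimmed mean resists salt-and-pepper outliers where the plain mean does not", {
  sc <- render_scene(scene_spec(seed = 4, noise_sd = 0))
  g <- detect_chart(sc$image, scales = 1, rotations = 0)
  img <- sc$image
  # corrupt 5% of the pixels of tile 1's sampled region with extreme values
  cr <- g$corners[[1]]
  xr <- range(cr[, 1]); yr <- range(cr[, 2])
  xs <- ceiling(mean(xr) - diff(xr) / 4):floor(mean(xr) + diff(xr) / 4)
  ys <- ceiling(mean(yr) - diff(yr) / 4):floor(mean(yr) + diff(yr) / 4)
  set.seed(6)
  n_out <- ceiling(0.05 * length(xs) * length(ys))
  for (ch in 1:3) {
    plane <- img[, , ch]
    pick <- cbind(sample(ys, n_out, TRUE), sample(xs, n_out, TRUE))
    plane[pick] <- 255
    img[, , ch] <- plane
  }
  obs <- extract_tile_values(img, g)
  truth <- sc$truth$tile_srgb[1, ]
  expect_lt(max(abs(obs$rgb_obs[1, ] - truth)), 1.5)
  plain <- vapply(1:3, function(ch) mean(img[ys, xs, ch]), numeric(1))
  expect_gt(max(abs(plain - truth)), max(abs(obs$rgb_obs[1, ] - truth)))
})

test_that("tile extraction is invariant to permuting tile-interior noise", {
  sc <- render_scene(scene_spec(seed = 4, noise_sd = 2))
  g <- detect_chart(sc$image, scales = 1, rotations = 0)
  img <- sc$image
  cr <- g$corners[[3]]
  xr <- range(cr[, 1]); yr <- range(cr[, 2])
  xs <- ceiling(mean(xr) - diff(xr) / 4):floor(mean(xr) + diff(xr) / 4)
  ys <- ceiling(mean(yr) - diff(yr) / 4):floor(mean(yr) + diff(yr) / 4)
  set.seed(9)
  perm <- sample(length(xs) * length(ys))
  for (ch in 1:3) {
    block <- img[ys, xs, ch]
    img[ys, xs, ch] <- matrix(as.vector(block)[perm], nrow(block))
  }
  expect_equal(extract_tile_values(img, g)$rgb_obs[3, ],
               extract_tile_values(sc$image, g)$rgb_obs[3, ],
               tolerance = 1e-9)
})

test_that("a degenerate tile polygon is rejected", {
  sc <- scene_fixture()
  g <- detect_chart(sc$image, scales = 1, rotations = 0)
  g$corners[[5]] <- cbind(x = c(10, 12, 12, 10), y = c(10, 10, 12, 12))
  expect_error(extract_tile_values(sc$image, g), "degenerate tile")
})

test_that("occlusion QC flags partial shadow but absorbs global changes", {
  ref <- ref_fixture()
  sc <- render_scene(scene_spec(seed = 11))
  g <- detect_chart(sc$image, scales = 1, rotations = 0)

  clean <- check_occlusion(extract_tile_values(sc$image, g), ref)
  expect_false(as.logical(clean))

  # uniform gain: a global illumination change, not occlusion
  img_g <- apply_illumination(sc$image, illumination_distortion(gain = 0.7))
  occ_g <- check_occlusion(
    extract_tile_values(img_g, detect_chart(img_g, scales = 1, rotations = 0)),
    ref)
  expect_false(as.logical(occ_g))

  # shadow across half the chart: spatially partial, must be flagged
  bb <- g$bbox
  img_s <- apply_illumination(sc$image, illumination_distortion(
    shadow = c(bb["x"], bb["x"] + bb["w"] / 2, bb["y"], bb["y"] + bb["h"]),
    shadow_factor = 0.4))
  occ_s <- check_occlusion(
    extract_tile_values(img_s,
                        detect_chart(img_s, scales = 1, rotations = c(0, 180))),
    ref)
  expect_true(as.logical(occ_s))
  expect_gt(length(attr(occ_s, "bad_tiles")), 3)
})

test_that("no in-gamut monotone per-channel linear map triggers the occlusion flag", {
  # gains above ~1.03 necessarily clip the brightest tiles, breaking the
  # linearity premise, so the property is checked on maps that stay in gamut
  ref <- ref_fixture()
  tiles <- chart_srgb(ref)
  set.seed(12)
  for (i in 1:10) {
    gain <- runif(3, 0.5, 1.0)
    off <- runif(3, 0, 255 * (1 - max(gain)))
    obs_rgb <- sweep(sweep(tiles, 2, gain, "*"), 2, off, "+")
    stopifnot(min(obs_rgb) >= 0, max(obs_rgb) <= 255)
    obs <- structure(list(lab_obs = srgb_to_lab(obs_rgb), rgb_obs = obs_rgb),
                     class = "chart_observation")
    expect_false(as.logical(check_occlusion(obs, ref)))
  }
})
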