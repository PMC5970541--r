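# The quadratic colour-correction model: design matrix, least-squares fit
# against a brute-force oracle, application, chart error and degree
# comparison.

test_that("design matrix rows follow the no-cross-term polynomial layout", {
  expect_equal(
    unname(build_design_matrix(matrix(c(50, 10, -10), 1), "quadratic")[1, ]),
    c(1, 50, 10, -10, 2500, 100, 100))
  zeros <- build_design_matrix(matrix(0, 8, 3), "quadratic")
  expect_equal(unname(zeros[1, ]), c(1, rep(0, 6)))
  expect_equal(dim(build_design_matrix(matrix(rnorm(72), 24, 3), "linear")),
               c(24, 4))
  expect_error(fit_correction_model(matrix(rnorm(15), 5, 3),
                                    matrix(rnorm(15), 5, 3), "quadratic"),
               "underdetermined")
})

test_that("a perfect chart fits exactly with R^2 = 1 and zero chart error", {
  ref <- ref_fixture()
  fit <- fit_correction_model(chart_lab(ref), ref)
  expect_equal(unname(fit$diagnostics$r2_per_channel), rep(1, 3),
               tolerance = 1e-9)
  expect_lt(fit$diagnostics$chart_error_after, 1e-8)
})

test_that("generating coefficients of an exact quadratic map are recovered", {
  ref <- ref_fixture()
  obs <- chart_lab(ref)
  set.seed(1)
  B_true <- rbind(runif(3, -2, 2),
                  diag(3) + matrix(runif(9, -0.05, 0.05), 3),
                  matrix(runif(9, -2e-3, 2e-3), 3))
  target <- build_design_matrix(obs, "quadratic") %*% B_true
  fit <- fit_correction_model(obs, target)
  expect_lt(max(abs(fit$coef - B_true)), 1e-6)
  corrected <- apply_correction(fit, obs)
  expect_lt(max(abs(corrected - target)), 1e-5)
})

test_that("a fitted model corrects a whole canopy distorted by an in-family map", {
  # truth defined through the generating map itself: true = B_true(distorted)
  ref <- ref_fixture()
  set.seed(2)
  B_true <- rbind(runif(3, -2, 2),
                  diag(3) + matrix(runif(9, -0.05, 0.05), 3),
                  matrix(runif(9, -2e-3, 2e-3), 3))
  distort_model <- structure(list(degree = "quadratic", working_space = "Lab",
                                  coef = B_true), class = "correction_model")
  obs_tiles <- chart_lab(ref)
  fit <- fit_correction_model(obs_tiles, apply_correction(distort_model, obs_tiles))
  canopy <- srgb_to_lab(matrix(runif(300, 30, 200), ncol = 3))
  expect_lt(max(abs(apply_correction(fit, canopy) -
                    apply_correction(distort_model, canopy))), 1e-5)
})

test_that("fitted coefficients match the normal-equations oracle", {
  set.seed(3)
  for (i in 1:20) {
    obs <- cbind(runif(24, 20, 80), runif(24, -40, 40), runif(24, -40, 40))
    target <- obs + matrix(rnorm(72, 0, 3), ncol = 3)
    X <- build_design_matrix(obs, "quadratic")
    oracle <- solve(t(X) %*% X, t(X) %*% target)   # brute-force normal equations
    expect_lt(max(abs(fit_correction_model(obs, target)$coef - oracle)), 1e-8)
  }
})

test_that("an identity model leaves colours untouched", {
  model <- structure(list(degree = "quadratic", working_space = "Lab",
                          coef = rbind(0, diag(3), matrix(0, 3, 3))),
                     class = "correction_model")
  x <- srgb_to_lab(matrix(runif(60, 0, 255), ncol = 3))
  expect_equal(apply_correction(model, x), x, tolerance = 1e-12)
})

test_that("fitting is invariant to tile order", {
  ref <- ref_fixture()
  obs <- chart_lab(ref) + matrix(rnorm(72, 0, 5), ncol = 3)
  set.seed(4)
  perm <- sample(24)
  f1 <- fit_correction_model(obs, chart_lab(ref))
  f2 <- fit_correction_model(obs[perm, ], chart_lab(ref)[perm, ])
  expect_equal(f1$coef, f2$coef, tolerance = 1e-9)
})

test_that("correction never does worse than the identity map on its tiles", {
  ref <- ref_fixture()
  tiles <- chart_srgb(ref)
  set.seed(5)
  for (i in 1:10) {
    d <- random_illumination()
    obs <- apply_illumination(tiles, d)
    fit <- fit_correction_model(srgb_to_lab(obs), ref)
    expect_lte(fit$diagnostics$chart_error_after,
               fit$diagnostics$chart_error_before + 1e-9)
  }
})

test_that("rank-deficient tile sets are rejected with a clear error", {
  obs <- matrix(rep(c(50, 0, 0), each = 24), ncol = 3)  # all tiles identical
  expect_error(fit_correction_model(obs, matrix(rnorm(72), ncol = 3)),
               "rank-deficient")
})

test_that("chart_error matches hand arithmetic and a loop oracle", {
  expect_equal(chart_error(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(chart_error(rbind(c(0, 0, 0), c(10, 10, 10)),
                           rbind(c(3, 4, 0), c(10, 10, 10))), 2.5)
  set.seed(6)
  a <- matrix(runif(72, 0, 255), ncol = 3)
  b <- matrix(runif(72, 0, 255), ncol = 3)
  oracle <- 0
  for (i in 1:24) {
    oracle <- oracle + sqrt(sum((a[i, ] - b[i, ])^2))
  }
  oracle <- oracle / 24
  expect_equal(chart_error(a, b), oracle, tolerance = 1e-12)
  expect_error(chart_error(a, b[1:10, ]), "length")
})

test_that("quadratic R^2 dominates linear R^2 and both saturate on linear data", {
  ref <- ref_fixture()
  tiles <- chart_srgb(ref)
  set.seed(7)
  for (i in 1:10) {
    obs <- apply_illumination(tiles, random_illumination()) +
      matrix(rnorm(72, 0, 0.5), ncol = 3)
    obs[obs < 0] <- 0; obs[obs > 255] <- 255
    cmp <- compare_fits(srgb_to_lab(obs), ref)
    expect_true(all(cmp$r2_quadratic >= cmp$r2_linear - 1e-12))
  }
  # exact linear map of the reference: both degrees are exact
  lin <- sweep(sweep(tiles, 2, c(0.8, 0.9, 0.85), "*"), 2, c(5, -3, 8), "+")
  cmp <- compare_fits(srgb_to_lab(lin), ref)
  expect_equal(unname(cmp$r2_linear), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(cmp$r2_quadratic), rep(1, 3), tolerance = 1e-9)
  # strongly curved map: the quadratic degree must win outright
  curved <- 255 * (tiles / 255)^2
  cmpq <- compare_fits(srgb_to_lab(curved), ref)
  expect_true(all(cmpq$r2_quadratic > cmpq$r2_linear + 1e-4))
})

test_that("models survive a JSON round trip", {
  ref <- ref_fixture()
  obs <- chart_lab(ref) + matrix(rnorm(72, 0, 5), ncol = 3)
  fit <- fit_correction_model(obs, ref)
  path <- withr::local_tempfile(fileext = ".json")
  write_correction_model(fit, path)
  back <- read_correction_model(path)
  expect_equal(back$coef, fit$coef, tolerance = 1e-12)
  expect_equal(back$degree, fit$degree)
  x <- srgb_to_lab(c(120, 80, 60))
  expect_equal(apply_correction(back, x), apply_correction(fit, x),
               tolerance = 1e-12)
})

test_that("correct_image with a mask only touches masked pixels", {
  sc <- scene_fixture()
  fit <- fit_correction_model(
    srgb_to_lab(apply_illumination(chart_srgb(ref_fixture()),
                                   illumination_distortion(gain = 0.9))),
    ref_fixture())
  mask <- sc$truth$plant_mask
  out <- correct_image(sc$image, fit, mask = mask)
  outside <- as.vector(mask) == 0
  expect_equal(matrix(out, ncol = 3)[outside, ],
               matrix(sc$image, ncol = 3)[outside, ])
  expect_false(isTRUE(all.equal(matrix(out, ncol = 3)[!outside, ],
                                matrix(sc$image, ncol = 3)[!outside, ])))
})
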