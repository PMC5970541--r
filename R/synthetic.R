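# Fully ground-truthed synthetic field scenes and time series.
#
# The generator emulates the imaging geometry of a rail-mounted phenotyping
# wagon: two bright near-vertical rails bounding the region of interest, a
# 24-tile colour checker mounted in the margin outside the rails, a plant
# canopy of known true colour rendered as ellipses on textured soil, and
# per-channel illumination distortions (gain, offset, gamma) standing in for
# bright versus overcast field days. Every scene carries its ground truth:
# tile centres, ROI mask, plant mask and true canopy colour.

#' Specify a synthetic field scene
#'
#' @param height,width Raster size in pixels.
#' @param rail_cols x-offsets of the two rails at the first row.
#' @param rail_angle Rail tilt, degrees from vertical.
#' @param rail_width Rail width in pixels.
#' @param chart_offset `(x, y)` of the chart's top-left corner; the chart
#'   sits in the margin outside the rails in the default layout.
#' @param chart_tile_px Chart tile edge length in pixels.
#' @param chart_rotation Chart rotation, quarter turns only (0/90/180/270).
#' @param canopy_color True canopy colour, 8-bit sRGB triplet.
#' @param n_ellipses Number of canopy ellipses.
#' @param soil_color Mean soil colour, sRGB triplet.
#' @param soil_texture_sd Soil texture standard deviation (sRGB units).
#' @param noise_sd Additive Gaussian sensor noise, sRGB units.
#' @param seed Integer; fully determines the rendered scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(height = 240, width = 320,
                       rail_cols = c(110, 300), rail_angle = 0,
                       rail_width = 5,
                       chart_offset = c(x = 10, y = 20), chart_tile_px = 12,
                       chart_rotation = 0,
                       canopy_color = c(70, 110, 45), n_ellipses = 6,
                       soil_color = c(120, 95, 70), soil_texture_sd = 8,
                       noise_sd = 2, seed = 1L) {
  spec <- list(height = height, width = width, rail_cols = rail_cols,
               rail_angle = rail_angle, rail_width = rail_width,
               chart_offset = chart_offset, chart_tile_px = chart_tile_px,
               chart_rotation = chart_rotation, canopy_color = canopy_color,
               n_ellipses = n_ellipses, soil_color = soil_color,
               soil_texture_sd = soil_texture_sd, noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  spec
}

#' Render a synthetic scene with ground truth
#'
#' Deterministic for a fixed spec (the spec's seed drives all randomness).
#' The returned ground truth is consistent with the raster: with
#' `noise_sd = 0` the plant mask applied to the raster recovers the true
#' canopy colour exactly.
#'
#' @param spec A [`scene_spec`][scene_spec].
#' @param ref A [`chart_reference`][chart_reference] for the rendered chart.
#' @return An object of class `scene_image`: `image` (`H x W x 3` sRGB) and
#'   `truth` (tile centres, rail lines, ROI mask, plant mask, true canopy
#'   colour, chart tile colours).
#' @export
render_scene <- function(spec = scene_spec(), ref = chart_reference()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  img <- array(0, dim = c(H, W, 3))

  # soil with texture (shared luminance texture, per design realistic enough)
  tex <- matrix(stats::rnorm(H * W, 0, spec$soil_texture_sd), H, W)
  for (ch in 1:3) img[, , ch] <- spec$soil_color[ch] + tex

  # rails: bright near-vertical bars
  lines <- lapply(spec$rail_cols, function(x0) {
    list(angle = spec$rail_angle, offset = x0)
  })
  xmat <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (ln in lines) {
    xs <- .line_x(ln, seq_len(H))
    on_rail <- abs(xmat - xs) <= spec$rail_width / 2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[on_rail] <- 215
      img[, , ch] <- plane
    }
  }
  roi <- make_roi_mask(lines, c(H, W))

  # canopy ellipses strictly between rails
  xl <- max(.line_x(lines[[1]], c(1, H))) + spec$rail_width
  xr <- min(.line_x(lines[[2]], c(1, H))) - spec$rail_width
  plant <- matrix(FALSE, H, W)
  ymat <- matrix(seq_len(H), H, W)
  for (e in seq_len(spec$n_ellipses)) {
    a <- stats::runif(1, 18, 38)             # semi-axes
    b <- stats::runif(1, 12, 28)
    cx <- stats::runif(1, xl + a + 2, xr - a - 2)
    cy <- stats::runif(1, b + 2, H - b - 2)
    plant <- plant | (((xmat - cx) / a)^2 + ((ymat - cy) / b)^2 <= 1)
  }
  plant <- plant & roi > 0
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[plant] <- spec$canopy_color[ch]
    img[, , ch] <- plane
  }

  # colour checker in the margin
  chart <- .chart_raster(ref, as.integer(spec$chart_tile_px))
  cimg <- chart$image
  rot_q <- (spec$chart_rotation %/% 90) %% 4
  if (rot_q > 0) {
    cimg <- array(NA_real_, dim = c(
      if (rot_q %% 2 == 1) dim(chart$image)[c(2, 1)] else dim(chart$image)[1:2],
      3))
    for (ch in 1:3) cimg[, , ch] <- .rotate90(chart$image[, , ch], rot_q)
  }
  x0 <- spec$chart_offset[[1]]; y0 <- spec$chart_offset[[2]]
  ch_h <- dim(cimg)[1]; ch_w <- dim(cimg)[2]
  if (x0 < 1 || y0 < 1 || x0 + ch_w - 1 > W || y0 + ch_h - 1 > H) {
    stop("chart placement falls outside the raster")
  }
  rail_x <- range(vapply(lines, function(ln) .line_x(ln, c(1, H)), numeric(2)))
  if (x0 <= max(rail_x) + spec$rail_width / 2 &&
      x0 + ch_w - 1 >= min(rail_x) - spec$rail_width / 2 &&
      any(roi[y0:(y0 + ch_h - 1), x0:(x0 + ch_w - 1)] > 0)) {
    stop("chart placement overlaps the rails/ROI")
  }
  img[y0:(y0 + ch_h - 1), x0:(x0 + ch_w - 1), ] <- cimg

  # tile centres in image coordinates under the quarter-turn rotation
  cent <- chart$geometry$centres
  gw <- chart$geometry$width; gh <- chart$geometry$height
  cent_rot <- switch(as.character(rot_q),
    "0" = cent,
    "1" = cbind(gh - cent[, 2], cent[, 1]),
    "2" = cbind(gw - cent[, 1], gh - cent[, 2]),
    "3" = cbind(cent[, 2], gw - cent[, 1]))
  centres <- cbind(x0 - 1 + cent_rot[, 1], y0 - 1 + cent_rot[, 2])

  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  }
  img[img < 0] <- 0; img[img > 255] <- 255

  structure(list(
    image = img,
    truth = list(tile_centres = centres,
                 tile_srgb = chart_srgb(ref),
                 rail_lines = lines,
                 roi_mask = roi,
                 plant_mask = plant * 1,
                 canopy_color = spec$canopy_color),
    spec = spec
  ), class = "scene_image")
}

#' Define a per-channel illumination distortion
#'
#' Applied pixelwise as `v' = clip(gain * (v/255)^gamma * 255 + offset)`,
#' per channel, emulating global illumination changes between bright and
#' overcast imaging sessions: identity at gain 1, offset 0, gamma 1, and
#' strictly monotone per channel when no shadow is present. An optional
#' shadow multiplies a rectangular region by `shadow_factor` afterwards,
#' emulating partial occlusion of the chart.
#'
#' @param gain,offset,gamma Length-3 per-channel parameters (scalars are
#'   recycled); `gain > 0`, `gamma > 0`.
#' @param shadow Optional rectangle `c(x0, x1, y0, y1)` to darken.
#' @param shadow_factor Multiplicative factor applied inside `shadow`.
#' @return An `illumination_distortion` object.
#' @export
illumination_distortion <- function(gain = 1, offset = 0, gamma = 1,
                                    shadow = NULL, shadow_factor = 0.4) {
  d <- list(gain = rep_len(gain, 3), offset = rep_len(offset, 3),
            gamma = rep_len(gamma, 3), shadow = shadow,
            shadow_factor = shadow_factor)
  if (any(d$gain <= 0) || any(d$gamma <= 0)) {
    stop("gain and gamma must be positive")
  }
  class(d) <- "illumination_distortion"
  d
}

#' Draw a random illumination distortion from the default family
#'
#' Per-channel gain in `[0.6, 1.4]`, offset in `[-15, 15]` sRGB units and
#' gamma in `[0.8, 1.25]`, drawn uniformly. The gamma term makes the
#' distortion nonlinear in the working space, the regime where a quadratic
#' correction model outperforms a linear one. Uses the current RNG state.
#'
#' @return An [`illumination_distortion`][illumination_distortion].
#' @export
random_illumination <- function() {
  illumination_distortion(gain = stats::runif(3, 0.6, 1.4),
                          offset = stats::runif(3, -15, 15),
                          gamma = stats::runif(3, 0.8, 1.25))
}

#' Apply an illumination distortion
#'
#' Chart tiles and canopy are distorted identically — the shared-illuminant
#' assumption that makes chart-anchored correction possible.
#'
#' @param image `H x W x 3` sRGB raster (or `n x 3` matrix / triplet).
#' @param d An [`illumination_distortion`][illumination_distortion].
#' @return The distorted colours, clipped to `[0, 255]`, in the shape of
#'   `image`.
#' @export
apply_illumination <- function(image, d) {
  stopifnot(inherits(d, "illumination_distortion"))
  shape <- .as_triplets(image, "image")
  m <- shape$m
  out <- sapply(1:3, function(ch) {
    d$gain[ch] * (pmax(m[, ch], 0) / 255)^d$gamma[ch] * 255 + d$offset[ch]
  })
  out <- matrix(out, ncol = 3)
  out[out < 0] <- 0; out[out > 255] <- 255
  res <- .restore_shape(out, shape)
  if (!is.null(d$shadow) && length(dim(res)) == 3) {
    s <- d$shadow
    xs <- max(1, s[1]):min(dim(res)[2], s[2])
    ys <- max(1, s[3]):min(dim(res)[1], s[4])
    res[ys, xs, ] <- res[ys, xs, ] * d$shadow_factor
  }
  res
}

# interpolate between healthy green and senesced yellow
.canopy_trajectory_color <- function(base_green, base_yellow, s) {
  (1 - s) * base_green + s * base_yellow
}

#' Generate a multi-session synthetic time series
#'
#' Builds per-plot, per-session scene specifications in which the true
#' canopy colour follows a chosen trajectory (constant, or a green-to-yellow
#' senescence ramp) while each session draws an independent illumination
#' distortion. Scenes are rendered on demand with [render_session()] to keep
#' memory bounded; all ground truth is tabulated up front.
#'
#' @param n_sessions Number of imaging sessions (at least 2).
#' @param n_plots Number of plots.
#' @param trajectory `"constant"` or `"senescence"`.
#' @param seed Integer seed for the whole series.
#' @param base_spec Template [`scene_spec`][scene_spec] for geometry/noise.
#' @param identity_illumination If `TRUE`, every session uses the identity
#'   distortion (useful as a no-op control).
#' @return An object of class `canopy_timeseries`: `truth` (data frame with
#'   plot, session, true canopy colour and distortion parameters), `specs`
#'   (scene spec per record) and `distortions`.
#' @export
generate_timeseries <- function(n_sessions, n_plots = 20,
                                trajectory = c("constant", "senescence"),
                                seed = 1L, base_spec = scene_spec(),
                                identity_illumination = FALSE) {
  trajectory <- match.arg(trajectory)
  stopifnot(n_sessions >= 2)
  set.seed(seed)
  green <- c(60, 105, 45); yellow <- c(160, 140, 50)
  plot_shade <- stats::runif(n_plots, 0, 0.35)   # plot-to-plot variation
  specs <- list(); dists <- list(); rows <- list()
  i <- 0L
  for (p in seq_len(n_plots)) {
    for (s in seq_len(n_sessions)) {
      i <- i + 1L
      frac <- if (trajectory == "constant") plot_shade[p]
              else plot_shade[p] * 0.3 + (s - 1) / (n_sessions - 1) * 0.7
      col <- .canopy_trajectory_color(green, yellow, frac)
      sp <- base_spec
      sp$canopy_color <- col
      sp$seed <- as.integer((seed * 7907L + i * 131L) %% .Machine$integer.max)
      d <- if (identity_illumination) illumination_distortion()
           else random_illumination()
      specs[[i]] <- sp
      dists[[i]] <- d
      rows[[i]] <- data.frame(
        plot_id = sprintf("plot%02d", p), session = s,
        R_true = col[1], G_true = col[2], B_true = col[3],
        gain_r = d$gain[1], gain_g = d$gain[2], gain_b = d$gain[3],
        offset_r = d$offset[1], offset_g = d$offset[2], offset_b = d$offset[3],
        gamma_r = d$gamma[1], gamma_g = d$gamma[2], gamma_b = d$gamma[3])
    }
  }
  structure(list(truth = do.call(rbind, rows), specs = specs,
                 distortions = dists, n_sessions = n_sessions,
                 n_plots = n_plots, trajectory = trajectory, seed = seed),
            class = "canopy_timeseries")
}

#' Render one plot/session record of a time series
#'
#' @param ts A [`canopy_timeseries`][generate_timeseries].
#' @param index Row index into `ts$truth`.
#' @param ref Chart reference used for rendering.
#' @return A list: the distorted `scene_image` (named `scene`), the clean
#'   scene's truth, and the distortion applied.
#' @export
render_session <- function(ts, index, ref = chart_reference()) {
  stopifnot(inherits(ts, "canopy_timeseries"))
  sc <- render_scene(ts$specs[[index]], ref = ref)
  sc$image <- apply_illumination(sc$image, ts$distortions[[index]])
  list(scene = sc, truth = ts$truth[index, ], distortion = ts$distortions[[index]])
}

#' Simulate canopy colour records through the measurement process
#'
#' A record-level emulation of the per-image pipeline used for large
#' benchmark designs: for each plot and session the true canopy colour and
#' the chart tiles are pushed through the same illumination distortion plus
#' sensor noise; the quadratic correction model is fitted on the distorted
#' tiles exactly as it would be on an image, and applied to a sample of
#' distorted canopy pixels. This exercises the fit/correct machinery per
#' record without rasterising full scenes.
#'
#' @param n_plots,n_sessions Design size.
#' @param trajectory As in [generate_timeseries()].
#' @param n_canopy_px Number of canopy pixels sampled per record.
#' @param noise_sd Sensor noise on pixels and tiles, sRGB units.
#' @param seed Integer seed.
#' @param ref Chart reference.
#' @return A data frame of canopy records: plot id, session, true / raw /
#'   corrected mean canopy colour and the per-record chart errors.
#' @export
simulate_color_records <- function(n_plots = 60, n_sessions = 5,
                                   trajectory = c("constant", "senescence"),
                                   n_canopy_px = 200, noise_sd = 2, seed = 1L,
                                   ref = chart_reference()) {
  trajectory <- match.arg(trajectory)
  set.seed(seed)
  green <- c(60, 105, 45); yellow <- c(160, 140, 50)
  plot_shade <- stats::runif(n_plots, 0, 0.6)
  tile_true <- chart_srgb(ref)
  ref_lab <- chart_lab(ref)
  rows <- vector("list", n_plots * n_sessions)
  i <- 0L
  for (p in seq_len(n_plots)) {
    for (s in seq_len(n_sessions)) {
      i <- i + 1L
      frac <- if (trajectory == "constant") plot_shade[p]
              else plot_shade[p] * 0.5 + (s - 1) / max(1, n_sessions - 1) * 0.4
      col <- .canopy_trajectory_color(green, yellow, frac)
      d <- random_illumination()
      # canopy pixels: true colour + texture noise, then distorted
      px <- matrix(rep(col, each = n_canopy_px), ncol = 3) +
        matrix(stats::rnorm(n_canopy_px * 3, 0, noise_sd), ncol = 3)
      px[px < 0] <- 0; px[px > 255] <- 255
      px_d <- apply_illumination(px, d)
      # chart tiles through the same illuminant + extraction noise
      tiles_d <- apply_illumination(tile_true, d) +
        matrix(stats::rnorm(72, 0, noise_sd / 3), ncol = 3)
      tiles_d[tiles_d < 0] <- 0; tiles_d[tiles_d > 255] <- 255
      fit <- fit_correction_model(srgb_to_lab(tiles_d), ref_lab)
      px_c <- lab_to_srgb(apply_correction(fit, srgb_to_lab(px_d)))
      raw <- colMeans(px_d); corr <- colMeans(px_c)
      rows[[i]] <- data.frame(
        plot_id = sprintf("plot%02d", p), session = s,
        n_plant_pixels = n_canopy_px,
        R_true = col[1], G_true = col[2], B_true = col[3],
        R_raw = raw[1], G_raw = raw[2], B_raw = raw[3],
        R_corr = corr[1], G_corr = corr[2], B_corr = corr[3],
        chart_error_before = fit$diagnostics$chart_error_before,
        chart_error_after = fit$diagnostics$chart_error_after)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate NDVI measurements tied to true canopy colour
#'
#' NDVI is produced as a known quadratic function of the *true* canopy
#' colour (so it is untouched by illumination distortions, mirroring the
#' illumination invariance of a real NDVI sensor) plus Gaussian noise,
#' clipped to `[-1, 1]`. The default link increases with canopy greenness
#' and decreases with redness.
#'
#' @param records A data frame with `R_true`, `G_true`, `B_true` columns
#'   (e.g. from [simulate_color_records()] or a time-series truth table).
#' @param link Coefficients of the quadratic link on `(R, G, B)/255`:
#'   named vector `(intercept, r, g, b, r2, g2, b2)`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return The records with an `ndvi_measured` column appended.
#' @export
generate_ndvi_dataset <- function(records,
                                  link = c(intercept = 0.2, r = -2.6,
                                           g = 2.5, b = -0.2, r2 = 1.0,
                                           g2 = -1.2, b2 = 0),
                                  noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  m <- as.matrix(records[, c("R_true", "G_true", "B_true")]) / 255
  mu <- link[1] + m %*% link[2:4] + m^2 %*% link[5:7]
  if (any(mu < -1 | mu > 1)) {
    stop("NDVI link produces values outside [-1, 1] before noise")
  }
  nd <- mu + stats::rnorm(nrow(m), 0, noise_sd)
  nd[nd < -1] <- -1; nd[nd > 1] <- 1
  records$ndvi_measured <- as.vector(nd)
  records
}
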