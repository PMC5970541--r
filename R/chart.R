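# Colour-checker handling: reference values, template rendering, in-image
# detection by normalized cross-correlation, tile-value extraction, and
# occlusion quality control.

#' Load a 24-tile colour-checker reference table
#'
#' By default loads the nominal CIELAB values of the classic 24-patch checker
#' (pre-2014 edition values, as commonly published) shipped with the package.
#' A user table may be supplied instead as a CSV with columns
#' `tile_index,name,L,a,b` in row-major 4 x 6 layout order (dark skin first,
#' black last, achromatic tiles on the bottom row).
#'
#' @param path Optional path to a reference CSV; `NULL` for the built-in set.
#' @return An object of class `chart_reference` with elements `table`
#'   (the data frame) and `lab` (24 x 3 matrix of reference L*, a*, b*).
#' @export
chart_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "colorchecker_classic_lab.csv",
                        package = "canopycolor", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tile_index", "name", "L", "a", "b")
  if (!all(need %in% names(tab))) {
    stop("reference CSV must have columns ", paste(need, collapse = ","))
  }
  if (nrow(tab) != 24L || anyDuplicated(tab$tile_index)) {
    stop("chart reference must contain exactly 24 uniquely indexed tiles")
  }
  tab <- tab[order(tab$tile_index), ]
  structure(list(table = tab,
                 lab = unname(as.matrix(tab[, c("L", "a", "b")]))),
            class = "chart_reference")
}

#' Reference tile colours of a chart
#'
#' @param ref A [`chart_reference`][chart_reference].
#' @return `chart_lab`: the 24 x 3 CIELAB matrix; `chart_srgb`: the same
#'   tiles rendered to 8-bit sRGB.
#' @export
chart_lab <- function(ref) .ref_lab(ref)

#' @rdname chart_lab
#' @export
chart_srgb <- function(ref) {
  out <- lab_to_srgb(.ref_lab(ref))
  attr(out, "clipped") <- NULL
  out
}

# Canonical chart geometry: 4 rows x 6 columns of square tiles separated by a
# gutter inside a dark border. Returns tile centres and corner polygons for a
# given tile size, in (x, y) pixel coordinates (x = column, y = row).
.chart_geometry <- function(tile_px, gutter = max(2L, round(tile_px / 6)),
                            border = gutter) {
  step <- tile_px + gutter
  width <- border * 2 + 6 * tile_px + 5 * gutter
  height <- border * 2 + 4 * tile_px + 3 * gutter
  centres <- matrix(NA_real_, 24, 2)
  corners <- vector("list", 24)
  for (r in 1:4) for (cl in 1:6) {
    i <- (r - 1) * 6 + cl
    x0 <- border + (cl - 1) * step
    y0 <- border + (r - 1) * step
    centres[i, ] <- c(x0 + tile_px / 2, y0 + tile_px / 2)
    corners[[i]] <- cbind(x = c(x0, x0 + tile_px, x0 + tile_px, x0),
                          y = c(y0, y0, y0 + tile_px, y0 + tile_px))
  }
  list(width = width, height = height, centres = centres, corners = corners,
       tile_px = tile_px, gutter = gutter, border = border)
}

# Render the canonical chart raster (sRGB, border/gutter dark grey).
.chart_raster <- function(ref, tile_px, frame_value = 30) {
  geom <- .chart_geometry(tile_px)
  img <- array(frame_value, dim = c(geom$height, geom$width, 3))
  cols <- chart_srgb(ref)
  for (i in 1:24) {
    cr <- geom$corners[[i]]
    xs <- (cr[1, "x"] + 1):cr[2, "x"]
    ys <- (cr[1, "y"] + 1):cr[3, "y"]
    for (ch in 1:3) img[ys, xs, ch] <- cols[i, ch]
  }
  list(image = img, geometry = geom)
}

#' Render the canonical colour-checker template
#'
#' A synthetic image of the 24-tile checker in canonical orientation (dark
#' skin top-left, achromatic row at the bottom), used as the template for
#' [detect_chart()] and by the synthetic scene renderer.
#'
#' @param ref A [`chart_reference`][chart_reference].
#' @param tile_px Tile edge length in pixels.
#' @return An object of class `chart_template`: `image` (`H x W x 3` sRGB
#'   raster) and `geometry` (tile centres and corner polygons in template
#'   coordinates).
#' @export
chart_template <- function(ref = chart_reference(), tile_px = 12L) {
  structure(.chart_raster(ref, as.integer(tile_px)),
            class = "chart_template")
}

# ---- normalized cross-correlation ------------------------------------------

# Sizes with only small prime factors keep the FFTs fast.
.good_fft_size <- function(n) {
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
    k <- k + 1
  }
}

# Normalized cross-correlation, split so that the image-side FFT and
# summed-area tables are computed once and reused across template variants
# (scales and rotations). The FFT supplies the correlation numerator; the
# summed-area tables supply windowed image mean and energy.
.ncc_prep <- function(img, max_h, max_w) {
  H <- nrow(img); W <- ncol(img)
  ph <- .good_fft_size(H + max_h - 1)
  pw <- .good_fft_size(W + max_w - 1)
  A <- matrix(0, ph, pw); A[1:H, 1:W] <- img
  sat <- function(m) {
    m <- apply(m, 2, cumsum)
    t(apply(m, 1, cumsum))
  }
  list(H = H, W = W, ph = ph, pw = pw, FA = stats::fft(A),
       S1 = sat(img), S2 = sat(img^2))
}

.ncc_score <- function(prep, tmpl) {
  H <- prep$H; W <- prep$W
  h <- nrow(tmpl); w <- ncol(tmpl)
  if (h > H || w > W) return(matrix(numeric(0), 0, 0))
  t0 <- tmpl - mean(tmpl)
  tnorm <- sqrt(sum(t0^2))
  if (tnorm < 1e-12) stop("flat template has no structure to match")
  B <- matrix(0, prep$ph, prep$pw); B[1:h, 1:w] <- t0
  num <- Re(stats::fft(prep$FA * Conj(stats::fft(B)), inverse = TRUE)) /
    (prep$ph * prep$pw)
  num <- num[1:(H - h + 1), 1:(W - w + 1), drop = FALSE]
  win <- function(S) {
    tot <- S[h:H, w:W, drop = FALSE]
    top <- rbind(0, S[seq_len(H - h), w:W, drop = FALSE])
    left <- cbind(0, S[h:H, seq_len(W - w), drop = FALSE])
    corner <- cbind(0, rbind(0, S[seq_len(H - h), seq_len(W - w),
                                  drop = FALSE]))
    tot - top - left + corner
  }
  n <- h * w
  ss <- win(prep$S2) - win(prep$S1)^2 / n
  ss[ss < 1e-9] <- Inf                      # flat image window: undefined NCC
  num / (sqrt(ss) * tnorm)
}

# one-shot NCC (kept as the simple reference entry point)
.ncc <- function(img, tmpl) {
  .ncc_score(.ncc_prep(img, nrow(tmpl), ncol(tmpl)), tmpl)
}

.rotate90 <- function(m, times) {
  times <- times %% 4
  for (i in seq_len(times)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

# mean-channel grayscale
.gray <- function(image) (image[, , 1] + image[, , 2] + image[, , 3]) / 3

#' Locate the colour checker in an image
#'
#' Normalized cross-correlation of a grayscale chart template against the
#' image over a small scale pyramid and quarter-turn rotations. The 180-degree
#' ambiguity left by grayscale matching is resolved using the achromatic
#' bottom row: of the two candidate tile orderings, the one whose extracted
#' lightness pattern better correlates with the reference is returned, so the
#' grid is always in canonical tile order.
#'
#' @param image `H x W x 3` sRGB raster.
#' @param template A [`chart_template`][chart_template].
#' @param scales Relative template scales to search.
#' @param rotations Quarter-turn rotations (degrees) to search.
#' @param min_score Minimum acceptable NCC score in `[0, 1]`; below it the
#'   chart is declared not found.
#' @return An object of class `chart_grid`: `corners` (list of 24 tile
#'   polygons, 4 x 2 `(x, y)` matrices, canonical order), `centres`
#'   (24 x 2), `score`, `scale`, `rotation` and the matched bounding box.
#' @export
detect_chart <- function(image, template = chart_template(),
                         scales = c(0.8, 0.9, 1, 1.1, 1.2),
                         rotations = c(0, 90, 180, 270),
                         min_score = 0.5) {
  stopifnot(inherits(template, "chart_template"))
  gimg <- .gray(image)
  tmpl0 <- .gray(template$image)
  variants <- list()
  for (s in scales) {
    tm <- .resize_gray(tmpl0, s)
    for (rot in rotations) {
      variants[[length(variants) + 1]] <-
        list(tmpl = .rotate90(tm, rot %/% 90), scale = s, rot = rot)
    }
  }
  prep <- .ncc_prep(gimg,
                    max(vapply(variants, function(v) nrow(v$tmpl), 1L)),
                    max(vapply(variants, function(v) ncol(v$tmpl), 1L)))
  best <- list(score = -Inf)
  for (v in variants) {
    sc <- .ncc_score(prep, v$tmpl)
    if (!length(sc)) next
    i <- which.max(sc)
    if (sc[i] > best$score) {
      best <- list(score = sc[i],
                   y = (i - 1) %% nrow(sc) + 1,
                   x = (i - 1) %/% nrow(sc) + 1,
                   scale = v$scale, rot = v$rot,
                   h = nrow(v$tmpl), w = ncol(v$tmpl))
    }
  }
  if (!is.finite(best$score) || best$score < min_score) {
    stop("chart not found: best match score ",
         signif(max(best$score, -1), 3), " below threshold ", min_score)
  }
  grid <- .grid_from_match(template, best)
  # resolve the 180-degree ambiguity with the achromatic-row lightness pattern
  flipped <- .flip_grid(grid)
  refL <- vapply(template$geometry$corners, function(cr) {
    mean(.tile_pixels(tmpl0, cr, inner = 0.5))
  }, numeric(1))
  score_orient <- function(g) {
    obsL <- vapply(seq_len(24), function(i) {
      px <- .tile_pixels(gimg, g$corners[[i]], inner = 0.5)
      mean(px)
    }, numeric(1))
    stats::cor(obsL, refL)
  }
  if (score_orient(flipped) > score_orient(grid)) grid <- flipped
  grid
}

# nearest-neighbour grayscale resize (adequate for template pyramids)
.resize_gray <- function(m, s) {
  if (s == 1) return(m)
  nh <- max(2L, round(nrow(m) * s))
  nw <- max(2L, round(ncol(m) * s))
  yi <- pmin(nrow(m), pmax(1L, round((seq_len(nh) - 0.5) / s + 0.5)))
  xi <- pmin(ncol(m), pmax(1L, round((seq_len(nw) - 0.5) / s + 0.5)))
  m[yi, xi, drop = FALSE]
}

# Map template tile geometry into image coordinates for a match (top-left
# x, y; scale; quarter-turn rotation).
.grid_from_match <- function(template, m) {
  geom <- template$geometry
  s_y <- m$h / (if (m$rot %in% c(90, 270)) geom$width else geom$height)
  s_x <- m$w / (if (m$rot %in% c(90, 270)) geom$height else geom$width)
  map_pt <- function(xy) {
    x <- xy[, 1]; y <- xy[, 2]
    # rotate within template frame, then scale and translate into the image
    if (m$rot == 0) { u <- x; v <- y }
    else if (m$rot == 90) { u <- geom$height - y; v <- x }     # clockwise
    else if (m$rot == 180) { u <- geom$width - x; v <- geom$height - y }
    else { u <- y; v <- geom$width - x }
    cbind(m$x - 1 + u * s_x, m$y - 1 + v * s_y)
  }
  corners <- lapply(geom$corners, map_pt)
  centres <- map_pt(geom$centres)
  structure(list(corners = corners, centres = centres, score = m$score,
                 scale = m$scale, rotation = m$rot,
                 bbox = c(x = m$x, y = m$y, w = m$w, h = m$h)),
            class = "chart_grid")
}

# reverse tile order: the grid seen after an extra half turn
.flip_grid <- function(grid) {
  g <- grid
  g$corners <- rev(grid$corners)
  g$centres <- grid$centres[24:1, , drop = FALSE]
  g$rotation <- (grid$rotation + 180) %% 360
  g
}

# Pixels of the central `inner` fraction of a tile polygon (tiles are
# axis-aligned rectangles under quarter-turn rotations).
.tile_pixels <- function(plane, corners, inner = 0.5) {
  xr <- range(corners[, 1]); yr <- range(corners[, 2])
  cx <- mean(xr); cy <- mean(yr)
  hw <- diff(xr) / 2 * inner; hh <- diff(yr) / 2 * inner
  xs <- max(1L, ceiling(cx - hw)):min(ncol(plane), floor(cx + hw))
  ys <- max(1L, ceiling(cy - hh)):min(nrow(plane), floor(cy + hh))
  if (length(xs) * length(ys) < 9) {
    stop("degenerate tile polygon: sampling area below 9 pixels")
  }
  plane[ys, xs]
}

#' Extract observed tile colours from a detected chart
#'
#' Samples the central region of each tile and takes a per-channel trimmed
#' mean in sRGB (robust to edge bleed and specular outliers), then converts
#' to CIELAB. Deterministic for fixed input.
#'
#' @param image `H x W x 3` sRGB raster.
#' @param grid A [`chart_grid`][detect_chart].
#' @param inner Fraction of the tile edge sampled (centred).
#' @param trim Fraction trimmed from each tail of the per-channel pixel
#'   distribution.
#' @return An object of class `chart_observation`: `grid`, `rgb_obs` and
#'   `lab_obs` (24 x 3 matrices), plus `occluded`/`per_tile_error` fields
#'   filled in by [check_occlusion()].
#' @export
extract_tile_values <- function(image, grid, inner = 0.5, trim = 0.1) {
  stopifnot(inherits(grid, "chart_grid"))
  rgb_obs <- t(vapply(seq_len(24), function(i) {
    vapply(1:3, function(ch) {
      mean(.tile_pixels(image[, , ch], grid$corners[[i]], inner), trim = trim)
    }, numeric(1))
  }, numeric(3)))
  structure(list(grid = grid, rgb_obs = rgb_obs,
                 lab_obs = srgb_to_lab(rgb_obs),
                 occluded = NA, per_tile_error = NULL),
            class = "chart_observation")
}

#' Flag a partially occluded or shadowed chart
#'
#' A chart partly covered by shadow corrupts the correction fit while a
#' uniform illumination change does not, so the test must not mistake a
#' global shift for occlusion. A provisional linear correction model is
#' fitted first; tiles whose residual Euclidean error in CIELAB exceeds
#' `tol` are flagged, and the chart is declared occluded when more than
#' `max_bad` tiles are flagged. A global monotone per-channel linear change
#' is absorbed by the provisional fit and never triggers the flag.
#'
#' @param obs A [`chart_observation`][extract_tile_values].
#' @param ref A [`chart_reference`][chart_reference].
#' @param tol Per-tile residual tolerance in CIELAB units.
#' @param max_bad Maximum number of out-of-tolerance tiles accepted. The
#'   default (half the chart) flags spatially partial corruption while
#'   tolerating the residuals a strong but global nonlinear illumination
#'   change leaves after the provisional linear fit.
#' @return `TRUE` if occluded, with attributes `per_tile_error` (24 residual
#'   norms) and `bad_tiles` (indices over tolerance). The observation's
#'   `occluded` and `per_tile_error` fields can be updated by the caller.
#' @export
check_occlusion <- function(obs, ref = chart_reference(), tol = 12,
                            max_bad = 12) {
  stopifnot(inherits(obs, "chart_observation"))
  fit <- fit_correction_model(obs, ref, degree = "linear")
  err <- sqrt(rowSums(fit$diagnostics$residuals^2))
  bad <- which(err > tol)
  structure(length(bad) > max_bad,
            per_tile_error = err, bad_tiles = bad)
}
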