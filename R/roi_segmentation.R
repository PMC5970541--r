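# Region-of-interest masking from the vehicle rails, and plant/background
# segmentation with an SVM trained on k-means cluster centres.
#
# The ROI is the strip of ground between the two rails of the phenotyping
# wagon; restricting analysis to it keeps out-of-plot weeds and the chart
# itself from contaminating canopy statistics.

# Otsu threshold on a 256-bin histogram of a [0,255] grayscale plane.
.otsu <- function(gray) {
  h <- as.numeric(tabulate(pmin(256L, pmax(1L, floor(gray) + 1L)), 256L))
  w <- cumsum(h)
  mu <- cumsum(h * (0:255))
  tot <- w[256]; mtot <- mu[256]
  between <- (mtot * w - mu * tot)^2 / (w * (tot - w))
  between[!is.finite(between)] <- 0
  which.max(between) - 1
}

# x-position of a near-vertical line at row y (1-based rows)
.line_x <- function(line, y) line$offset + tan(line$angle * pi / 180) * (y - 1)

#' Detect the two wagon rails
#'
#' Finds the two bright, near-vertical rail structures with a Hough-style
#' vote: the grayscale image is thresholded (Otsu), and every bright pixel
#' votes for the family of near-vertical lines passing through it,
#' parameterized by tilt angle and x-offset at the first row. The two
#' strongest peaks separated by at least `min_sep` of the image width are
#' returned, with the offset refined to the vote centroid around each peak.
#'
#' @param image `H x W x 3` sRGB raster.
#' @param max_angle Search range for tilt, degrees from vertical.
#' @param angle_step Angular resolution of the vote, degrees.
#' @param min_sep Minimum rail separation as a fraction of image width.
#' @param min_votes Minimum peak strength as a fraction of image height;
#'   below it a rail is not credible.
#' @return A list of two rail lines (left, right), each with fields `angle`
#'   (degrees from vertical) and `offset` (x at the first image row), plus a
#'   `votes` attribute.
#' @export
detect_rails <- function(image, max_angle = 15, angle_step = 0.5,
                         min_sep = 0.2, min_votes = 0.5) {
  H <- dim(image)[1]; W <- dim(image)[2]
  gray <- .gray(image)
  bright <- gray > .otsu(gray)
  idx <- which(bright)
  if (!length(idx)) stop("rails not found: no bright structure in image")
  ys <- (idx - 1) %% H + 1
  xs <- (idx - 1) %/% H + 1
  angles <- seq(-max_angle, max_angle, by = angle_step)
  # accumulator over (angle, x-offset at row 1)
  acc <- matrix(0L, length(angles), W)
  for (ai in seq_along(angles)) {
    x0 <- round(xs - tan(angles[ai] * pi / 180) * (ys - 1))
    ok <- x0 >= 1 & x0 <= W
    acc[ai, ] <- tabulate(x0[ok], W)
  }
  thresh <- min_votes * H
  peak <- function(acc) {
    i <- which.max(acc)
    list(ai = (i - 1) %% nrow(acc) + 1, x0 = (i - 1) %/% nrow(acc) + 1,
         votes = acc[i])
  }
  # a credible rail is both tall (near full image height) and prominent
  # against the diffuse votes of bright texture
  prominence <- 3 * stats::median(acc)
  p1 <- peak(acc)
  if (p1$votes < thresh || p1$votes < prominence) {
    stop("rails not found: strongest line too weak")
  }
  acc2 <- acc
  excl <- abs(seq_len(W) - p1$x0) < min_sep * W
  acc2[, excl] <- 0L
  p2 <- peak(acc2)
  if (p2$votes < thresh || p2$votes < prominence) {
    stop("rails not found: no second rail at least ", min_sep * W,
         " px from the first")
  }
  refine <- function(p) {
    ang <- angles[p$ai]
    x0 <- xs - tan(ang * pi / 180) * (ys - 1)
    near <- abs(x0 - p$x0) <= 4
    list(angle = ang, offset = mean(x0[near]), votes = p$votes)
  }
  lines <- list(refine(p1), refine(p2))
  lines <- lines[order(vapply(lines, `[[`, numeric(1), "offset"))]
  structure(lines, votes = c(lines[[1]]$votes, lines[[2]]$votes))
}

#' Build the between-rails region-of-interest mask
#'
#' Pixels strictly between the two rail lines are 1, everything else 0
#' (pixels on the lines themselves are excluded on both sides).
#'
#' @param lines Two rail lines as returned by [detect_rails()].
#' @param dim Image dimensions `c(H, W)` (extra elements ignored).
#' @return An `H x W` binary (0/1) matrix.
#' @export
make_roi_mask <- function(lines, dim) {
  H <- dim[1]; W <- dim[2]
  y <- seq_len(H)
  xl <- .line_x(lines[[1]], y)
  xr <- .line_x(lines[[2]], y)
  d <- xr - xl
  if (any(d == 0) || (any(d > 0) && any(d < 0))) {
    stop("rail lines cross inside the raster")
  }
  if (all(d < 0)) { tmp <- xl; xl <- xr; xr <- tmp }
  xmat <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- (xmat > xl) & (xmat < xr)
  storage.mode(mask) <- "double"
  mask
}

#' Apply a binary mask to an image (Hadamard product)
#'
#' Elementwise product of each channel with the mask: pixels inside the mask
#' are left bit-identical, pixels outside become 0.
#'
#' @param image `H x W x 3` raster.
#' @param mask `H x W` binary matrix.
#' @return The masked raster.
#' @export
apply_roi <- function(image, mask) {
  stopifnot(identical(dim(image)[1:2], dim(mask)[1:2]))
  image * as.vector(mask)
}

.seg_features <- function(rgb, feature_space) {
  luv <- srgb_to_luv(rgb)
  switch(feature_space,
         uv = luv[, 2:3, drop = FALSE],
         luv = luv,
         lab = srgb_to_lab(rgb))
}

#' Train the plant/background segmenter
#'
#' Per training image, the pixel colours are clustered with k-means (k
#' clusters of minimal within-cluster variance, in CIELUV); each cluster
#' centre is labelled plant or background by the majority ground-truth label
#' of its member pixels. The labelled centres — a compressed training set far
#' smaller than the raw pixels — are projected to the chosen feature space
#' (by default the (u, v) chromaticity plane) and an SVM is fitted on them.
#'
#' @param images List of `H x W x 3` sRGB rasters.
#' @param masks List of matching binary plant masks (1 = plant).
#' @param k Number of k-means clusters per image.
#' @param feature_space `"uv"` (default), `"luv"` or `"lab"`.
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost Soft-margin constant.
#' @param seed Integer seed making clustering reproducible.
#' @return An object of class `segmenter_model`: `points` (data frame of
#'   labelled cluster centres in feature space), the fitted `svm`, and the
#'   hyperparameters.
#' @export
train_segmenter <- function(images, masks, k = 20, feature_space = c("uv", "luv", "lab"),
                            kernel = c("linear", "radial"), cost = 1, seed = 1L) {
  feature_space <- match.arg(feature_space)
  kernel <- match.arg(kernel)
  stopifnot(length(images) == length(masks), length(images) >= 1)
  set.seed(seed)
  pts <- vector("list", length(images))
  for (j in seq_along(images)) {
    img <- images[[j]]; msk <- masks[[j]]
    stopifnot(identical(dim(img)[1:2], dim(msk)[1:2]))
    px <- matrix(img, ncol = 3)
    # clustering a subsample of pixels is ample to place 20 colour clusters
    if (nrow(px) > 20000) {
      keep <- sample.int(nrow(px), 20000)
      px <- px[keep, , drop = FALSE]
      msk <- as.vector(msk)[keep]
    }
    feats <- .seg_features(px, feature_space)
    luv <- if (feature_space == "luv") feats else srgb_to_luv(px)
    kk <- min(k, nrow(unique(round(luv, 6))))
    km <- suppressWarnings(
      stats::kmeans(luv, centers = kk, nstart = 2, iter.max = 50))
    # cluster centre in feature space = mean feature of member pixels;
    # label = majority ground-truth label of member pixels
    centre_feat <- t(vapply(seq_len(kk), function(ci) {
      colMeans(feats[km$cluster == ci, , drop = FALSE])
    }, numeric(ncol(feats))))
    centre_lab <- vapply(seq_len(kk), function(ci) {
      mean(msk[km$cluster == ci] > 0) >= 0.5
    }, logical(1))
    pts[[j]] <- data.frame(centre_feat,
                           label = ifelse(centre_lab, "plant", "background"))
  }
  pts <- do.call(rbind, pts)
  names(pts) <- c(paste0("f", seq_len(ncol(pts) - 1)), "label")
  if (length(unique(pts$label)) < 2) {
    stop("training data must contain both plant and background clusters")
  }
  # canonical ordering: training is insensitive to image order
  pts <- pts[do.call(order, pts), , drop = FALSE]
  rownames(pts) <- NULL
  x <- as.matrix(pts[, -ncol(pts), drop = FALSE])
  y <- factor(pts$label, levels = c("background", "plant"))
  # cluster centres compress each class to few points, and backgrounds
  # (soil, rails, chart tiles) outnumber plant clusters heavily; inverse
  # class weights keep the margin from collapsing onto the majority class
  fit <- e1071::svm(x, y, kernel = kernel, cost = cost, scale = TRUE,
                    class.weights = "inverse")
  structure(list(points = pts, svm = fit, k = k,
                 feature_space = feature_space, kernel = kernel, cost = cost),
            class = "segmenter_model")
}

#' Segment plant pixels from background
#'
#' Classifies every pixel (or every ROI pixel, if a mask is given) by the
#' segmenter's decision rule applied to its colour features. Pixels outside
#' the ROI are always background.
#'
#' @param image `H x W x 3` sRGB raster.
#' @param model A [`segmenter_model`][train_segmenter].
#' @param roi Optional `H x W` binary ROI mask from [make_roi_mask()].
#' @return An `H x W` binary plant mask (1 = plant).
#' @export
segment_plants <- function(image, model, roi = NULL) {
  stopifnot(inherits(model, "segmenter_model"))
  H <- dim(image)[1]; W <- dim(image)[2]
  sel <- if (is.null(roi)) rep(TRUE, H * W) else as.vector(roi > 0)
  mask <- matrix(0, H, W)
  if (!any(sel)) return(mask)
  px <- matrix(image, ncol = 3)[sel, , drop = FALSE]
  feats <- .seg_features(px, model$feature_space)
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  pred <- predict(model$svm, feats)
  mask[sel] <- as.numeric(pred == "plant")
  mask
}

#' Serialize a segmenter to JSON
#'
#' Stores the labelled cluster-centre training set and hyperparameters; the
#' SVM is refitted deterministically on load.
#'
#' @param model A [`segmenter_model`][train_segmenter].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segmenter <- function(model, path) {
  stopifnot(inherits(model, "segmenter_model"))
  jsonlite::write_json(list(points = model$points, k = model$k,
                            feature_space = model$feature_space,
                            kernel = model$kernel, cost = model$cost),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segmenter from JSON
#'
#' @param path File written by [write_segmenter()].
#' @return A `segmenter_model` with the SVM refitted on the stored centres.
#' @export
read_segmenter <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- as.data.frame(obj$points)
  x <- as.matrix(pts[, -ncol(pts), drop = FALSE])
  y <- factor(pts$label, levels = c("background", "plant"))
  fit <- e1071::svm(x, y, kernel = obj$kernel, cost = obj$cost, scale = TRUE,
                    class.weights = "inverse")
  structure(list(points = pts, svm = fit, k = obj$k,
                 feature_space = obj$feature_space, kernel = obj$kernel,
                 cost = obj$cost),
            class = "segmenter_model")
}
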