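# Canopy colour traits: per-plot mean colour, cross-session stability, and
# NDVI prediction from mean canopy colour.

#' Mean canopy colour of a segmented image
#'
#' Arithmetic per-channel mean (or median) over plant pixels of the sRGB
#' values, after applying a colour-correction model to those pixels when one
#' is supplied.
#'
#' @param image `H x W x 3` sRGB raster.
#' @param plant_mask `H x W` binary mask (1 = plant); must contain at least
#'   one plant pixel.
#' @param model Optional [`correction_model`][fit_correction_model]; when
#'   given, plant pixels are corrected before averaging.
#' @param use_median Use per-channel medians instead of means.
#' @return A length-3 sRGB triplet.
#' @export
mean_canopy_color <- function(image, plant_mask, model = NULL,
                              use_median = FALSE) {
  stopifnot(identical(dim(image)[1:2], dim(plant_mask)[1:2]))
  sel <- as.vector(plant_mask > 0)
  if (!any(sel)) stop("empty plant mask: no canopy to measure")
  px <- matrix(image, ncol = 3)[sel, , drop = FALSE]
  if (!is.null(model)) {
    px <- lab_to_srgb(apply_correction(model, srgb_to_lab(px)))
  }
  if (use_median) apply(px, 2, stats::median) else colMeans(px)
}

#' Cross-session stability of canopy colour
#'
#' For each plot with at least two sessions, the sample standard deviation
#' of each channel's mean canopy colour across sessions, before (raw) and
#' after (corrected) colour correction. A stable trait under correction —
#' corrected standard deviations below raw ones — is the signature that the
#' correction has removed session-to-session illumination, not biology.
#'
#' @param records Data frame of canopy records with columns `plot_id`,
#'   `session`, `R_raw`, `G_raw`, `B_raw`, `R_corr`, `G_corr`, `B_corr`.
#' @return A data frame, one row per plot: `sd_*_raw` and `sd_*_corr` per
#'   channel and `n_sessions`.
#' @export
session_stability <- function(records) {
  need <- c("plot_id", "session", "R_raw", "G_raw", "B_raw",
            "R_corr", "G_corr", "B_corr")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  out <- lapply(split(records, records$plot_id), function(g) {
    if (nrow(g) < 2) {
      stop("plot ", g$plot_id[1], " has fewer than 2 sessions")
    }
    data.frame(plot_id = g$plot_id[1], n_sessions = nrow(g),
               sd_R_raw = stats::sd(g$R_raw), sd_G_raw = stats::sd(g$G_raw),
               sd_B_raw = stats::sd(g$B_raw),
               sd_R_corr = stats::sd(g$R_corr),
               sd_G_corr = stats::sd(g$G_corr),
               sd_B_corr = stats::sd(g$B_corr))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalized difference vegetation index
#'
#' `(NIR - R) / (NIR + R)`, in `[-1, 1]`. The ratio form makes the index
#' invariant to a common scaling of both bands, which is why NDVI is
#' insensitive to overall illumination level.
#'
#' @param nir,red Non-negative band intensities (vectorised); `nir + red`
#'   must be positive.
#' @return NDVI values in `[-1, 1]`.
#' @export
ndvi <- function(nir, red) {
  if (any(nir < 0) || any(red < 0)) stop("band intensities must be >= 0")
  if (any(nir + red == 0)) stop("NDVI undefined where nir + red = 0")
  (nir - red) / (nir + red)
}

.ndvi_features <- function(rgb, spaces) {
  parts <- lapply(spaces, function(sp) {
    switch(sp,
           RGB = rgb / 255,
           HSV = srgb_to_hsv(rgb),
           Lab = srgb_to_lab(rgb),
           Luv = srgb_to_luv(rgb))
  })
  do.call(cbind, parts)
}

#' Fit a quadratic NDVI prediction model on canopy colour
#'
#' Least squares of measured NDVI on an intercept, the mean-canopy-colour
#' features in the requested colour spaces, and their squares (the same
#' polynomial family, without cross terms, as the colour-correction model).
#'
#' @param records Canopy records with an `ndvi_measured` column and mean
#'   colour columns.
#' @param spaces Feature spaces, subset of `c("RGB", "HSV", "Lab", "Luv")`;
#'   features are concatenated across the chosen spaces.
#' @param training_sessions Sessions used for fitting; remaining sessions
#'   are left for held-out evaluation.
#' @param use `"corrected"` (columns `*_corr`) or `"raw"` (columns `*_raw`).
#' @return An object of class `ndvi_model` with the coefficient vector, the
#'   chosen spaces and colour source, and the training sessions.
#' @export
fit_ndvi_model <- function(records, spaces = "RGB",
                           training_sessions = sort(unique(records$session)),
                           use = c("corrected", "raw")) {
  use <- match.arg(use)
  stopifnot(all(spaces %in% c("RGB", "HSV", "Lab", "Luv")))
  if (!"ndvi_measured" %in% names(records)) {
    stop("records carry no ndvi_measured column")
  }
  tr <- records[records$session %in% training_sessions, ]
  cols <- paste0(c("R", "G", "B"), if (use == "corrected") "_corr" else "_raw")
  rgb <- as.matrix(tr[, cols])
  feats <- .ndvi_features(rgb, spaces)
  X <- cbind(1, feats, feats^2)
  if (nrow(X) < ncol(X)) {
    stop("underdetermined NDVI fit: ", nrow(X), " records for ", ncol(X),
         " coefficients")
  }
  beta <- .polyfit_ls(X, matrix(tr$ndvi_measured, ncol = 1),
                      allow_deficient = TRUE)
  structure(list(coef = as.vector(beta), spaces = spaces, use = use,
                 training_sessions = training_sessions),
            class = "ndvi_model")
}

#' @export
predict.ndvi_model <- function(object, records, ...) {
  cols <- paste0(c("R", "G", "B"),
                 if (object$use == "corrected") "_corr" else "_raw")
  rgb <- as.matrix(records[, cols])
  feats <- .ndvi_features(rgb, object$spaces)
  as.vector(cbind(1, feats, feats^2) %*% object$coef)
}

#' Mean squared prediction error
#'
#' `(1/N) * sum_i (pred_i - ref_i)^2`, the error measure used for held-out
#' NDVI prediction.
#'
#' @param pred,ref Equal-length numeric vectors.
#' @return A single non-negative number.
#' @export
prediction_mse <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("prediction and reference lengths differ")
  mean((pred - ref)^2)
}
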