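# Per-channel polynomial colour correction fitted on colour-checker tiles.
#
# The model maps observed tile colours to their reference values in CIELAB.
# Each output channel is a polynomial in all three observed channels: an
# intercept, the three linear terms and (for the quadratic degree) the three
# squared terms — no cross terms. The three channels share one design matrix
# and are solved independently by least squares. Including the intercept keeps
# the identity map inside the model family, so a fitted model can never do
# worse on the fitting tiles than leaving the image untouched.

#' Build the polynomial design matrix for colour correction
#'
#' Row i of the result is `[1, L_i, a_i, b_i]` for the linear degree or
#' `[1, L_i, a_i, b_i, L_i^2, a_i^2, b_i^2]` for the quadratic degree. No
#' cross terms are used.
#'
#' @param obs Observed colours: an `n x 3` matrix (rows = tiles, columns =
#'   channels of the working space, normally CIELAB).
#' @param degree `"quadratic"` (default) or `"linear"`.
#' @return An `n x p` design matrix, `p` = 7 (quadratic) or 4 (linear).
#'   Underdetermination (`n < p`) is checked where the matrix is used for
#'   fitting.
#' @export
build_design_matrix <- function(obs, degree = c("quadratic", "linear")) {
  degree <- match.arg(degree)
  obs <- .as_triplets(obs, "observed colours")$m
  X <- cbind(1, obs)
  if (degree == "quadratic") X <- cbind(X, obs^2)
  colnames(X) <- c("intercept", "c1", "c2", "c3",
                   if (degree == "quadratic") c("c1_sq", "c2_sq", "c3_sq"))
  X
}

# Least squares with internal column centring/scaling for conditioning
# (squared Lab terms span ~[0, 1e4]); coefficients are mapped back so the
# returned values apply to the raw design matrix.
.polyfit_ls <- function(X, Y, allow_deficient = FALSE) {
  p <- ncol(X)
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  mu[1] <- 0; sdev[1] <- 1          # leave the intercept column alone
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  if (!allow_deficient) {
    qrX <- qr(Xs)
    if (qrX$rank < p) {
      stop("rank-deficient design matrix (rank ", qrX$rank, " < ", p,
           "): tile colours do not span the polynomial family ",
           "(e.g. identical or collinear tiles)")
    }
    Bs <- qr.coef(qrX, Y)
  } else {
    # duplicated features (e.g. identical lightness columns from two colour
    # spaces) make the design deficient by construction: take the truncated
    # minimum-norm solution; directions explaining < 1e-6 of the
    # standardized design variance carry no signal but explode at test time
    sv <- svd(Xs)
    keep <- sv$d > max(sv$d) * 1e-3
    Bs <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% Y) / sv$d[keep])
  }
  B <- Bs / sdev                    # undo scaling
  B[1, ] <- B[1, ] - colSums(B[-1, , drop = FALSE] * mu[-1])
  unname(B)
}

.obs_lab <- function(obs) {
  if (inherits(obs, "chart_observation")) obs$lab_obs
  else .as_triplets(obs, "observed colours")$m
}

.ref_lab <- function(ref) {
  if (inherits(ref, "chart_reference")) as.matrix(ref$table[, c("L", "a", "b")])
  else .as_triplets(ref, "reference colours")$m
}

#' Fit a colour-correction model on colour-checker tiles
#'
#' Fits the per-channel polynomial (quadratic by default, linear available as
#' the baseline used by earlier chart-based pipelines) that maps observed tile
#' colours to reference tile colours in CIELAB, independently for L*, a* and
#' b*, by least squares on a shared design matrix.
#'
#' @param obs Observed tiles: a [`chart_observation`][extract_tile_values]
#'   or an `n x 3` CIELAB matrix. The caller is responsible for screening out
#'   occluded charts first (see [check_occlusion()]).
#' @param ref Reference tiles: a [`chart_reference`][chart_reference] or an
#'   `n x 3` CIELAB matrix, paired with `obs` by tile index.
#' @param degree `"quadratic"` or `"linear"`.
#' @return An object of class `correction_model`: a list with `degree`,
#'   `working_space` (`"Lab"`), `coef` (a `p x 3` coefficient matrix, one
#'   column per output channel), and `diagnostics` holding per-channel R^2 in
#'   the working space, the `n x 3` residual matrix, and the mean Euclidean
#'   chart error in 8-bit sRGB before and after correction
#'   (see [chart_error()]).
#' @examples
#' ref <- chart_reference()
#' lab <- chart_lab(ref)
#' fit <- fit_correction_model(lab, ref)     # perfect chart: error 0, R^2 = 1
#' fit$diagnostics$chart_error_after
#' @export
fit_correction_model <- function(obs, ref, degree = c("quadratic", "linear")) {
  degree <- match.arg(degree)
  L <- .obs_lab(obs)
  R <- .ref_lab(ref)
  if (nrow(L) != nrow(R)) stop("observed and reference tile counts differ")
  p <- if (degree == "quadratic") 7L else 4L
  if (nrow(L) < p) {
    stop("underdetermined fit: ", nrow(L), " observations for ", p,
         " coefficients (", degree, " degree)")
  }
  X <- build_design_matrix(L, degree)
  B <- .polyfit_ls(X, R)
  fitted <- X %*% B
  resid <- R - fitted
  sstot <- colSums(sweep(R, 2, colMeans(R))^2)
  r2 <- 1 - colSums(resid^2) / sstot
  names(r2) <- c("L", "a", "b")
  model <- structure(list(degree = degree, working_space = "Lab", coef = B),
                     class = "correction_model")
  model$diagnostics <- list(
    r2_per_channel = r2,
    residuals = resid,
    chart_error_before = chart_error(lab_to_srgb(L), lab_to_srgb(R)),
    chart_error_after = chart_error(lab_to_srgb(fitted), lab_to_srgb(R))
  )
  model
}

#' Apply a fitted correction model to colours in the working space
#'
#' Maps every value through the per-channel polynomial. Accepts the same
#' shapes as the colour-space converters (triplet, matrix or raster) and
#' returns the corrected values in CIELAB.
#'
#' @param model A [`correction_model`][fit_correction_model].
#' @param x CIELAB colours: length-3 vector, `n x 3` matrix or `H x W x 3`
#'   array.
#' @return Corrected CIELAB values in the shape of `x`.
#' @export
apply_correction <- function(model, x) {
  stopifnot(inherits(model, "correction_model"))
  shape <- .as_triplets(x, "Lab input")
  X <- cbind(1, shape$m)
  if (model$degree == "quadratic") X <- cbind(X, shape$m^2)
  .restore_shape(X %*% model$coef, shape)
}

#' @export
predict.correction_model <- function(object, newdata, ...) {
  apply_correction(object, newdata)
}

#' @export
print.correction_model <- function(x, ...) {
  cat("Colour-correction model (", x$degree, ", working space ",
      x$working_space, ")\n", sep = "")
  cat("  chart error before/after:",
      signif(x$diagnostics$chart_error_before, 4), "/",
      signif(x$diagnostics$chart_error_after, 4), "(sRGB units)\n")
  cat("  R^2 (L*, a*, b*):",
      paste(signif(x$diagnostics$r2_per_channel, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Correct the colours of an image
#'
#' Converts the image to CIELAB, applies the fitted polynomial and converts
#' back to 8-bit sRGB with gamut clipping. By default every pixel is
#' corrected; a mask restricts correction to the region of interest or to
#' plant pixels only, leaving the rest of the raster untouched.
#'
#' @param image `H x W x 3` sRGB raster, channels in `[0, 255]`.
#' @param model A [`correction_model`][fit_correction_model].
#' @param mask Optional `H x W` binary mask; only pixels with `mask > 0` are
#'   corrected.
#' @return The corrected sRGB raster.
#' @export
correct_image <- function(image, model, mask = NULL) {
  if (is.null(mask)) {
    return(lab_to_srgb(apply_correction(model, srgb_to_lab(image))))
  }
  stopifnot(identical(dim(image)[1:2], dim(mask)[1:2]))
  sel <- mask > 0
  px <- matrix(image, ncol = 3)[sel, , drop = FALSE]
  out <- image
  corr <- lab_to_srgb(apply_correction(model, srgb_to_lab(px)))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[sel] <- corr[, ch]
    out[, , ch] <- plane
  }
  out
}

#' Mean Euclidean chart error between paired colour lists
#'
#' The average over tiles of the Euclidean distance between paired sRGB
#' triplets: `E = (1/n) * sum_i sqrt((R'_i-R_i)^2 + (G'_i-G_i)^2 +
#' (B'_i-B_i)^2)`. This is the chart-reproduction error used to quantify how
#' far observed tile colours sit from their reference values before and after
#' correction.
#'
#' @param obs,ref Paired colour lists, `n x 3` matrices (or any shape accepted
#'   by the colour converters) in the same space (normally 8-bit sRGB).
#' @return A single non-negative number; 0 iff the lists are identical.
#' @examples
#' chart_error(rbind(c(0, 0, 0), c(10, 10, 10)),
#'             rbind(c(3, 4, 0), c(10, 10, 10)))  # (5 + 0) / 2 = 2.5
#' @export
chart_error <- function(obs, ref) {
  a <- .as_triplets(obs, "observed colours")$m
  b <- .as_triplets(ref, "reference colours")$m
  if (nrow(a) != nrow(b)) stop("colour lists have different lengths")
  mean(sqrt(rowSums((a - b)^2)))
}

#' Compare linear and quadratic chart fits per RGB channel
#'
#' How well does each polynomial degree explain the observed-versus-reference
#' tile relationship, channel by channel? Both degrees of the polynomial
#' family are fitted per RGB channel directly on the sRGB tile values (the
#' space in which chart-fit quality is conventionally plotted and reported)
#' and the per-channel R^2 is returned. Fitting both degrees on the same
#' design guarantees the quadratic R^2 is never below the linear one.
#'
#' @inheritParams fit_correction_model
#' @return A list with numeric vectors `r2_linear` and `r2_quadratic`
#'   (named R, G, B).
#' @export
compare_fits <- function(obs, ref) {
  obs_rgb <- if (inherits(obs, "chart_observation")) obs$rgb_obs
             else lab_to_srgb(.obs_lab(obs))
  ref_rgb <- lab_to_srgb(.ref_lab(ref))
  if (nrow(obs_rgb) != nrow(ref_rgb)) {
    stop("observed and reference tile counts differ")
  }
  sstot <- colSums(sweep(ref_rgb, 2, colMeans(ref_rgb))^2)
  r2_for <- function(degree) {
    X <- build_design_matrix(obs_rgb, degree)
    B <- .polyfit_ls(X, ref_rgb)
    r2 <- 1 - colSums((ref_rgb - X %*% B)^2) / sstot
    stats::setNames(r2, c("R", "G", "B"))
  }
  list(r2_linear = r2_for("linear"), r2_quadratic = r2_for("quadratic"))
}

#' Serialize a correction model to JSON
#'
#' @param model A [`correction_model`][fit_correction_model].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_correction_model <- function(model, path) {
  stopifnot(inherits(model, "correction_model"))
  obj <- list(
    degree = model$degree,
    working_space = model$working_space,
    coef = model$coef,
    diagnostics = list(
      r2_per_channel = as.list(model$diagnostics$r2_per_channel),
      chart_error_before = model$diagnostics$chart_error_before,
      chart_error_after = model$diagnostics$chart_error_after
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a correction model from JSON
#'
#' @param path File written by [write_correction_model()].
#' @return A `correction_model`.
#' @export
read_correction_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    degree = obj$degree,
    working_space = obj$working_space,
    coef = matrix(as.numeric(obj$coef), ncol = 3),
    diagnostics = list(
      r2_per_channel = unlist(obj$diagnostics$r2_per_channel),
      chart_error_before = obj$diagnostics$chart_error_before,
      chart_error_after = obj$diagnostics$chart_error_after
    )
  ), class = "correction_model")
}
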