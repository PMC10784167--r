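#' Min-max normalization to the unit interval
#'
#' Affine rescaling `(x - min) / (max - min)`: the minimum maps to 0, the
#' maximum to 1, everything else proportionally between. A constant input
#' (max == min) is defined as all zeros, with a warning. Already-normalized
#' data (containing both 0 and 1) is a fixed point.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with values in `[0, 1]`.
#' @examples
#' min_max_normalize(c(10, 15, 20))
#' @export
min_max_normalize <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    warning("constant input to min_max_normalize(); returning zeros")
    x[] <- 0
    return(x)
  }
  (x - lo) / (hi - lo)
}

#' Resize an image to the network input shape
#'
#' Bilinear resize to `target x target`, with the grayscale plane replicated
#' across the requested channel count (e.g. `227 x 227 x 3` for architectures
#' expecting RGB input; `512` is the alternative native resolution used by
#' the tuned network configuration).
#'
#' @param img Numeric matrix (grayscale image).
#' @param target Output side length in pixels (default 227).
#' @param channels Number of replicated channels (default 3). With
#'   `channels = 1` a matrix is returned.
#' @return A `target x target` matrix (`channels = 1`) or a
#'   `target x target x channels` array.
#' @examples
#' dim(resize_to_input(matrix(runif(64), 8, 8), target = 16))
#' @export
resize_to_input <- function(img, target = 227L, channels = 3L) {
  target <- as.integer(target)
  channels <- as.integer(channels)
  if (target < 1L) stop("`target` must be at least 1", call. = FALSE)
  resized <- if (nrow(img) == target && ncol(img) == target) {
    img
  } else {
    as.matrix(EBImage::resize(EBImage::Image(img), w = target, h = target,
                              filter = "bilinear"))
  }
  if (channels == 1L) return(resized)
  array(rep(resized, channels), dim = c(target, target, channels))
}

#' Augmentation configuration
#'
#' Intervals for the five random affine augmentation operators. Defaults are
#' the ranges appropriate for brain-MRI augmentation: small rotations and
#' shears (patient positioning / scanner misalignment), moderate pixel
#' translations, and a wide scale range; axis reflections are off by
#' default.
#'
#' @param rotation_deg Rotation interval in degrees (default `c(-7, 7)`).
#' @param shear_xy Shear interval for both axes (default `c(-0.03, 0.03)`).
#' @param translation_px Translation interval in pixels for both axes
#'   (default `c(-35, 35)`).
#' @param scale_xy Scale interval for both axes (default `c(0.4, 3)`).
#' @param reflect_x,reflect_y Apply an axis reflection (default `FALSE`).
#' @param seed Optional integer seed used by [augment()].
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_deg = c(-7, 7),
                           shear_xy = c(-0.03, 0.03),
                           translation_px = c(-35, 35),
                           scale_xy = c(0.4, 3),
                           reflect_x = FALSE, reflect_y = FALSE,
                           seed = NULL) {
  chk <- function(iv, nm) {
    if (length(iv) != 2L || iv[1] > iv[2]) {
      stop(sprintf("`%s` must be an interval c(lo, hi)", nm), call. = FALSE)
    }
    as.numeric(iv)
  }
  structure(
    list(
      rotation_deg = chk(rotation_deg, "rotation_deg"),
      shear_xy = chk(shear_xy, "shear_xy"),
      translation_px = chk(translation_px, "translation_px"),
      scale_xy = chk(scale_xy, "scale_xy"),
      reflect_x = isTRUE(reflect_x), reflect_y = isTRUE(reflect_y),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "augment_config"
  )
}

# sample one parameter set; fixed draw order: rotation, shear x, shear y,
# translation x, translation y, scale x, scale y
sample_augment_params <- function(cfg) {
  u <- function(iv) stats::runif(1, iv[1], iv[2])
  list(
    rotation = u(cfg$rotation_deg),
    shear_x = u(cfg$shear_xy), shear_y = u(cfg$shear_xy),
    t_x = u(cfg$translation_px), t_y = u(cfg$translation_px),
    s_x = u(cfg$scale_xy), s_y = u(cfg$scale_xy)
  )
}

# 2x2 linear part of the composed transform: scale -> shear -> rotate
augment_linear_part <- function(par) {
  S <- diag(c(par$s_x, par$s_y))
  Sh <- matrix(c(1, par$shear_y, par$shear_x, 1), 2, 2)
  th <- par$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  R %*% Sh %*% S
}

#' Random affine augmentation
#'
#' Samples rotation, shear, translation and scale parameters from the
#' configured intervals, composes them into one affine transform applied
#' about the image center (order: scale, then shear, then rotate, then
#' translate), and warps the image with bilinear resampling and zero fill.
#' Configured reflections are applied first. Output shape equals input
#' shape. Collapsing every interval to the identity values (`0` for
#' rotation/shear/translation, `1` for scale) with reflections off returns
#' the image unchanged.
#'
#' @param img Numeric matrix (grayscale image).
#' @param cfg An [augment_config()].
#' @param seed Optional integer seed; falls back to `cfg$seed`.
#' @return Augmented image matrix of the same shape.
#' @examples
#' img <- matrix(runif(32 * 32), 32, 32)
#' out <- augment(img, augment_config(seed = 1))
#' dim(out)
#' @export
augment <- function(img, cfg = augment_config(), seed = NULL) {
  stopifnot(inherits(cfg, "augment_config"))
  seed <- seed %||% cfg$seed
  with_local_seed(seed, {
    if (cfg$reflect_x) img <- img[nrow(img):1, , drop = FALSE]
    if (cfg$reflect_y) img <- img[, ncol(img):1, drop = FALSE]
    par <- sample_augment_params(cfg)
    A <- augment_linear_part(par)
    ctr <- c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2)
    offset <- ctr + c(par$t_x, par$t_y) - A %*% ctr
    if (max(abs(A - diag(2))) == 0 && max(abs(offset)) == 0) return(img)
    m <- rbind(t(A), as.numeric(offset))  # EBImage: output = m' %*% c(x, 1)
    as.matrix(EBImage::affine(EBImage::Image(img), m,
                              filter = "bilinear", bg.col = 0))
  })
}
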