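#' Specification for the synthetic tumor-image generator
#'
#' Emulates the structure of the public three-class brain-MRI collection the
#' pipeline targets: grayscale images with a bright head-like elliptical
#' background plus a class-conditional tumor-like blob. Class 1
#' (meningioma-like) gets a single round peripheral blob; class 2
#' (pituitary-like) a small central blob; class 3 (glioma-like) a large
#' irregular multi-lobed blob. Defaults mirror the reference collection's
#' per-class counts (708 / 930 / 1426) and 512-pixel images; tests and
#' examples use smaller sizes.
#'
#' @param n_per_class Integer vector of three per-class image counts.
#' @param image_size Side length in pixels (default 512).
#' @param noise_sd Gaussian background noise standard deviation on the 0-255
#'   scale (default 8).
#' @param blob_intensity Added intensity of the tumor-like blob (default 80).
#' @param seed Integer seed making the whole dataset deterministic.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(meningioma = 708L,
                                           pituitary = 930L,
                                           glioma = 1426L),
                           image_size = 512L, noise_sd = 8,
                           blob_intensity = 80, seed = 1L) {
  if (length(n_per_class) != 3L || any(n_per_class < 0)) {
    stop("`n_per_class` must be three non-negative counts", call. = FALSE)
  }
  image_size <- as.integer(image_size)
  if (image_size < 16L) stop("`image_size` must be at least 16", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(
    list(
      n_per_class = as.integer(n_per_class), image_size = image_size,
      noise_sd = noise_sd, blob_intensity = blob_intensity,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# distance-squared field from (cx, cy) with axis scalings
ellipse_field <- function(size, cx, cy, rx, ry) {
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2
}

#' Generate one synthetic tumor image
#'
#' Builds the smooth head-like background (bright ellipse with soft falloff
#' plus Gaussian noise), adds the class-conditional blob, clips to
#' `[0, 255]` and rounds to integer intensities. The returned mask marks the
#' blob pixels; blob pixels are on average brighter than the background.
#'
#' @param class_label Class in `1:3` (meningioma-, pituitary-, glioma-like).
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed for this single image.
#' @return A `dataset_record`: list with integer matrix `image`, integer
#'   `label` and binary matrix `mask`.
#' @examples
#' rec <- generate_image(1, synthetic_spec(image_size = 64), seed = 1)
#' rec$label
#' @export
generate_image <- function(class_label, spec = synthetic_spec(), seed = NULL) {
  class_label <- as.integer(class_label)
  if (!class_label %in% 1:3) stop("`class_label` must be 1, 2 or 3", call. = FALSE)
  with_local_seed(seed, {
    s <- spec$image_size
    ctr <- (s + 1) / 2
    head_r <- 0.42 * s
    d2 <- ellipse_field(s, ctr, ctr, head_r, 0.92 * head_r)
    bg <- 120 * pmax(0, 1 - d2)^0.35
    if (spec$noise_sd > 0) {
      bg <- bg + matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
    }
    mask <- matrix(FALSE, s, s)
    add <- matrix(0, s, s)
    place_blob <- function(cx, cy, rx, ry) {
      f <- ellipse_field(s, cx, cy, rx, ry)
      inside <- f <= 1
      add <<- add + spec$blob_intensity * pmax(0, 1 - f)^0.5
      mask <<- mask | inside
    }
    if (class_label == 1L) {
      # single round peripheral blob
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.22, 0.3) * s
      r <- stats::runif(1, 0.055, 0.08) * s
      place_blob(ctr + rad * cos(ang), ctr + rad * sin(ang), r, r)
    } else if (class_label == 2L) {
      # small central blob
      r <- stats::runif(1, 0.03, 0.045) * s
      jit <- stats::runif(2, -0.02, 0.02) * s
      place_blob(ctr + jit[1], ctr + jit[2], r, r * stats::runif(1, 0.8, 1.1))
    } else {
      # large irregular multi-lobed blob: 2-4 overlapping ellipses
      n_lobes <- sample(2:4, 1)
      base <- ctr + stats::runif(2, -0.12, 0.12) * s
      for (l in seq_len(n_lobes)) {
        off <- stats::runif(2, -0.06, 0.06) * s
        rx <- stats::runif(1, 0.09, 0.14) * s
        ry <- rx * stats::runif(1, 0.6, 1.4)
        place_blob(base[1] + off[1], base[2] + off[2], rx, ry)
      }
    }
    img <- pmin(pmax(bg + add, 0), 255)
    structure(
      list(image = matrix(as.integer(round(img)), s, s),
           label = class_label, mask = mask),
      class = "dataset_record"
    )
  })
}

#' Generate a full synthetic dataset
#'
#' Generates `sum(n_per_class)` records with exact per-class counts and
#' shuffles them with the seeded stream. The whole dataset is deterministic
#' given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of `dataset_record`s.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_per_class = c(3, 3, 3),
#'                                       image_size = 32, seed = 1))
#' table(vapply(ds, `[[`, 0L, "label"))
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    labels <- rep(1:3, times = spec$n_per_class)
    records <- lapply(labels, function(lb) generate_image(lb, spec))
    if (length(records) > 1L) records <- records[sample(length(records))]
    records
  })
}

#' Labels of the reference three-class collection
#'
#' Convenience constructor of the per-class label vector matching the public
#' collection's class sizes (708 meningioma, 930 pituitary, 1426 glioma);
#' used for split bookkeeping without generating images.
#'
#' @param n_per_class Per-class counts (defaults as above).
#' @return Integer label vector of length `sum(n_per_class)`.
#' @export
reference_labels <- function(n_per_class = c(708L, 930L, 1426L)) {
  rep(seq_along(n_per_class), times = n_per_class)
}
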