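#' Hyperparameter search space
#'
#' Continuous box over the four tuned network hyperparameters — depth
#' multiplier, width multiplier, input resolution and dropout rate — with the
#' decode rule that snaps the resolution coordinate to a declared grid.
#' Positions are plain 4-vectors `(depth, width, resolution, dropout)`, so
#' any box optimizer in the package can search the space directly.
#'
#' @param depth,width Intervals for the depth and width multipliers
#'   (defaults `c(0.25, 1)`).
#' @param resolution_grid Allowed input resolutions (default
#'   `c(128, 227, 256, 384, 512)`).
#' @param dropout Interval for the dropout rate (default `c(0, 0.5)`).
#' @return An object of class `search_space` with a `bounds` element.
#' @examples
#' sp <- search_space()
#' sp$bounds$dim
#' @export
search_space <- function(depth = c(0.25, 1), width = c(0.25, 1),
                         resolution_grid = c(128L, 227L, 256L, 384L, 512L),
                         dropout = c(0, 0.5)) {
  resolution_grid <- sort(as.integer(resolution_grid))
  structure(
    list(
      depth = depth, width = width,
      resolution_grid = resolution_grid, dropout = dropout,
      bounds = bounds(
        c(depth[1], width[1], min(resolution_grid), dropout[1]),
        c(depth[2], width[2], max(resolution_grid), dropout[2])
      )
    ),
    class = "search_space"
  )
}

#' Hyperparameter set
#'
#' The four tuned knobs of the scaled-down convolutional classifier. The
#' reference configuration is depth multiplier 0.5, width multiplier 0.75,
#' input resolution 512 and dropout rate 0.2.
#'
#' @param depth_multiplier Channel-count (and block-repeat) shrink factor in
#'   `(0, 1]`.
#' @param width_multiplier Filter-count shrink factor in `(0, 1]`.
#' @param input_resolution Input side length in pixels.
#' @param dropout_rate Fraction of units dropped during training, in `[0, 1)`.
#' @return An object of class `hyperparams`.
#' @examples
#' hyperparams()
#' @export
hyperparams <- function(depth_multiplier = 0.5, width_multiplier = 0.75,
                        input_resolution = 512L, dropout_rate = 0.2) {
  if (depth_multiplier <= 0 || depth_multiplier > 1) {
    stop("`depth_multiplier` must lie in (0, 1]", call. = FALSE)
  }
  if (width_multiplier <= 0 || width_multiplier > 1) {
    stop("`width_multiplier` must lie in (0, 1]", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      depth_multiplier = depth_multiplier,
      width_multiplier = width_multiplier,
      input_resolution = as.integer(input_resolution),
      dropout_rate = dropout_rate
    ),
    class = "hyperparams"
  )
}

#' @export
print.hyperparams <- function(x, ...) {
  cat(sprintf(
    "<hyperparams> depth %.3g | width %.3g | resolution %d | dropout %.3g\n",
    x$depth_multiplier, x$width_multiplier, x$input_resolution, x$dropout_rate))
  invisible(x)
}

#' Encode hyperparameters as an optimizer position
#'
#' @param hp A [hyperparams()] object.
#' @param space A [search_space()].
#' @return Numeric 4-vector `(depth, width, resolution, dropout)`.
#' @export
encode_hyperparams <- function(hp, space = search_space()) {
  stopifnot(inherits(hp, "hyperparams"))
  c(hp$depth_multiplier, hp$width_multiplier,
    hp$input_resolution, hp$dropout_rate)
}

#' Decode an optimizer position into hyperparameters
#'
#' Out-of-box coordinates are clamped (with a warning); the resolution
#' coordinate is snapped to the nearest grid point (ties to the smaller).
#' Decoding is deterministic, and `decode_position(encode_hyperparams(hp))`
#' is the identity for grid-respecting `hp`.
#'
#' @param x Numeric 4-vector.
#' @param space A [search_space()].
#' @return A [hyperparams()] object.
#' @examples
#' decode_position(c(0.5, 0.75, 500, 0.2))$input_resolution  # snaps to 512
#' @export
decode_position <- function(x, space = search_space()) {
  if (length(x) != 4L) stop("position must have 4 coordinates", call. = FALSE)
  clamped <- clamp_to_bounds(x, space$bounds)
  if (any(clamped != x)) {
    warning("position outside the search space; clamped before decoding")
  }
  grid <- space$resolution_grid
  res <- grid[which.min(abs(grid - clamped[3]))]
  hyperparams(
    depth_multiplier = clamped[1],
    width_multiplier = clamped[2],
    input_resolution = res,
    dropout_rate = clamped[4]
  )
}

#' Stratified train/test split
#'
#' Per class, the nearest integer to `train_frac * n_class` samples are
#' chosen uniformly at random for training; the rest are test. This is the
#' per-label split rule that, applied to class sizes 708/930/1426 at 80%,
#' yields 2451 training and 613 test images.
#'
#' @param labels Integer (or factor) class label vector.
#' @param train_frac Training fraction in `(0, 1)` (default 0.8).
#' @param seed Optional integer seed.
#' @return A list with `train_indices`, `test_indices` and
#'   `per_class_train_counts`.
#' @examples
#' sp <- split_dataset(rep(1:3, c(708, 930, 1426)), 0.8, seed = 1)
#' length(sp$train_indices)  # 2451
#' @export
split_dataset <- function(labels, train_frac = 0.8, seed = NULL) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must lie in (0, 1)", call. = FALSE)
  }
  if (is.factor(labels)) labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(labels) == 0L) stop("`labels` must be non-empty", call. = FALSE)
  with_local_seed(seed, {
    train <- integer(0)
    counts <- integer(length(classes))
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      if (length(idx) == 0L) stop("a class has no samples", call. = FALSE)
      n_train <- as.integer(floor(train_frac * length(idx) + 0.5))
      n_train <- min(max(n_train, 0L), length(idx))
      counts[ci] <- n_train
      if (n_train > 0L) {
        train <- c(train, idx[sample.int(length(idx), n_train)])
      }
    }
    train <- sort(train)
    list(
      train_indices = train,
      test_indices = setdiff(seq_along(labels), train),
      per_class_train_counts = counts
    )
  })
}

# ---- toy classifier objective -------------------------------------------

# pooled intensity + edge features for one image at a working resolution:
# an 8x8 grid of block means, a 4x4 edge-energy grid, 6 radial ring means
# (rotation-invariant, so blob position reads out regardless of angle),
# bright-blob area above an adaptive threshold, and 3 global statistics.
toy_features_one <- function(img, work_size) {
  m <- resize_to_input(img, target = work_size, channels = 1L)
  pool <- function(x, g) {
    idx_r <- ceiling(seq_len(nrow(x)) / (nrow(x) / g))
    idx_c <- ceiling(seq_len(ncol(x)) / (ncol(x) / g))
    as.numeric(tapply(as.numeric(x),
                      list(idx_r[row(x)], idx_c[col(x)]), mean))
  }
  gx <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  gy <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  edge <- matrix(0, nrow(m), ncol(m))
  edge[-nrow(m), ] <- abs(gx)
  edge[, -ncol(m)] <- edge[, -ncol(m)] + abs(gy)
  ctr <- (work_size + 1) / 2
  rad <- sqrt((row(m) - ctr)^2 + (col(m) - ctr)^2) / (work_size / 2)
  ring <- findInterval(rad, c(0.15, 0.3, 0.45, 0.6, 0.8)) + 1L
  # hyperintense-lesion mask: an absolute threshold well above the
  # background's peak isolates blob pixels, so its area and radial
  # placement read out the class geometry; fall back to the brightest
  # percentile when nothing clears the threshold
  blob <- m > 0.66 * 255
  if (!any(blob)) blob <- m >= stats::quantile(m, 0.99)
  rings_int <- vapply(1:6, function(k) mean(m[ring == k]), 0)
  rings_blob <- vapply(1:6, function(k) mean(blob[ring == k]), 0)
  c(pool(m, 8L), pool(edge, 4L), rings_int, rings_blob,
    mean(rad[blob]), mean(blob), mean(m), stats::sd(as.numeric(m)))
}

N_TOY_FEATURES <- 8 * 8 + 4 * 4 + 6 + 6 + 4

# feature matrix for a dataset at a resolution; working size capped so the
# toy model stays desk-scale while still responding to the resolution knob
toy_feature_matrix <- function(dataset, input_resolution) {
  work_size <- min(input_resolution, 64L)
  t(vapply(dataset, function(rec) toy_features_one(rec$image, work_size),
           numeric(N_TOY_FEATURES)))
}

#' Toy classifier objective for hyperparameter tuning
#'
#' A deterministic, desk-scale stand-in for full network training that
#' consumes the preprocessing and feature path end to end: images are
#' resampled per the input resolution, pooled intensity/edge/radial features
#' are extracted, the width and depth multipliers rescale the spatial and
#' edge feature blocks against the ridge penalty, the dropout rate enters
#' through its exact marginalized form for linear models (an adaptive ridge
#' penalty `rate/(1-rate) * diag(X'X)`, the expectation of training under
#' unit masking), and a
#' ridge-regularized one-vs-rest linear softmax classifier is fit on a
#' stratified 80/20 split. The returned fitness is
#' `1 - validation accuracy`, in `[0, 1]`, to be minimized.
#'
#' @param dataset List of `dataset_record`s with at least two classes.
#' @param hp A [hyperparams()] object.
#' @param seed Integer seed controlling the split and the dropout mask.
#' @param features Optional precomputed feature matrix (used by [tune()] to
#'   cache per-resolution features).
#' @return Scalar fitness in `[0, 1]`.
#' @export
toy_classifier_objective <- function(dataset, hp = hyperparams(), seed = 1L,
                                     features = NULL) {
  labels <- vapply(dataset, function(r) as.integer(r$label), 0L)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("dataset must contain at least two classes", call. = FALSE)
  }
  X <- features %||% toy_feature_matrix(dataset, hp$input_resolution)

  sp <- split_dataset(labels, 0.8, seed = seed)
  with_local_seed(seed + 1L, {
    Xtr <- X[sp$train_indices, , drop = FALSE]
    Xte <- X[sp$test_indices, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- pmax(apply(Xtr, 2L, stats::sd), 1e-8)
    Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
    Xte <- sweep(sweep(Xte, 2L, mu), 2L, sdv, "/")
    # the multipliers rescale feature blocks against the shared ridge
    # penalty: width governs the spatial intensity grid, depth the edge
    # block; smaller multipliers shrink those blocks' influence
    spatial <- 1:64
    edges <- 65:80
    Xtr[, spatial] <- Xtr[, spatial] * hp$width_multiplier
    Xte[, spatial] <- Xte[, spatial] * hp$width_multiplier
    Xtr[, edges] <- Xtr[, edges] * hp$depth_multiplier
    Xte[, edges] <- Xte[, edges] * hp$depth_multiplier
    Xtr <- cbind(1, Xtr)
    Xte <- cbind(1, Xte)
    Y <- outer(labels[sp$train_indices], classes, `==`) * 1
    # dropout in its marginalized form for linear models: training with
    # units kept with probability 1 - rate is, in expectation, ridge with
    # an adaptive penalty rate/(1 - rate) * diag(X'X) (Wager et al. 2013)
    G <- crossprod(Xtr)
    rate <- hp$dropout_rate
    penalty <- diag(rate / (1 - rate) * diag(G) + 0.1)
    W <- solve(G + penalty, crossprod(Xtr, Y))
    pred <- classes[max.col(Xte %*% W, ties.method = "first")]
    1 - mean(pred == labels[sp$test_indices])
  })
}

#' Tune hyperparameters with the contracted fox optimizer
#'
#' Runs [cfoa_optimize()] over the search space, working internally in the
#' per-dimension normalized unit box so the optimizer's scale-dependent
#' moves treat every hyperparameter uniformly (the raw coordinates span
#' anything from a 0.5-wide dropout interval to a 384-pixel resolution
#' range). The objective is the [toy_classifier_objective()] by default
#' (with per-resolution feature caching so repeated evaluations at the same
#' grid resolution are cheap), or any user function following the plug-in
#' contract `function(hp, seed) -> fitness`.
#'
#' @param dataset List of `dataset_record`s (ignored when `objective` is
#'   supplied and does not need it).
#' @param space A [search_space()].
#' @param config A [cfoa_config()]; the default is the full trial protocol
#'   of 60 agents and 200 iterations.
#' @param objective Optional plug-in objective `function(hp, seed)`.
#' @param seed Integer seed for the tuning run.
#' @return A list with `best_hyperparams` (a [hyperparams()]) and `result`
#'   (the `fox_result` trace, in unit-box coordinates).
#' @examples
#' \donttest{
#' ds <- generate_dataset(synthetic_spec(n_per_class = c(20, 20, 20),
#'                                       image_size = 48, seed = 7))
#' cfg <- cfoa_config(fox = fox_config(n_agents = 10, max_iter = 10),
#'                    elimination = elimination_config(et = 4))
#' fit <- tune(ds, config = cfg, seed = 1)
#' fit$best_hyperparams
#' }
#' @export
tune <- function(dataset = NULL, space = search_space(),
                 config = cfoa_config(), objective = NULL, seed = 1L) {
  if (is.null(objective)) {
    if (is.null(dataset)) stop("`dataset` is required for the toy objective", call. = FALSE)
    cache <- new.env(parent = emptyenv())
    objective <- function(hp, seed) {
      key <- as.character(hp$input_resolution)
      if (is.null(cache[[key]])) {
        cache[[key]] <- toy_feature_matrix(dataset, hp$input_resolution)
      }
      toy_classifier_objective(dataset, hp, seed, features = cache[[key]])
    }
  }
  lo <- space$bounds$lower
  hi <- space$bounds$upper
  from_unit <- function(u) lo + u * (hi - lo)
  wrapped <- function(u) {
    hp <- suppressWarnings(decode_position(from_unit(u), space))
    objective(hp, seed)
  }
  unit_box <- bounds(rep(0, space$bounds$dim), rep(1, space$bounds$dim))
  result <- cfoa_optimize(wrapped, unit_box, config, seed = seed)
  list(
    best_hyperparams = suppressWarnings(
      decode_position(from_unit(result$best_x), space)),
    result = result
  )
}
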