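#' CLAHE configuration
#'
#' Contrast-limited adaptive histogram equalization: the image is partitioned
#' into a grid of tiles, each tile's histogram is clipped at a limit `T`,
#' turned into a cumulative distribution, rescaled to span the intensity
#' levels, and the per-tile mappings are merged back into one image.
#'
#' @param tile_rows,tile_cols Tile grid (default 8 x 8).
#' @param clip_limit The clip limit `T`. With `clip_unit = "count"` it is an
#'   absolute histogram count; with `"fraction"` it is a fraction of the tile
#'   pixel count (converted to a count per tile, floored at 1).
#' @param clip_unit `"count"` or `"fraction"`.
#' @param redistribute If `TRUE`, the clipped excess mass is spread uniformly
#'   over the bins (total conserved); if `FALSE` (default) the literal
#'   clipping rule `H'(k) = min(H(k), T)` discards the excess.
#' @param merge Tile-mapping merge rule: `"bilinear"` (default) interpolates
#'   between the four neighboring tile mappings; `"nearest"` applies each
#'   tile's own mapping.
#' @return An object of class `clahe_config`.
#' @export
clahe_config <- function(tile_rows = 8L, tile_cols = 8L,
                         clip_limit = 0.01, clip_unit = c("fraction", "count"),
                         redistribute = FALSE,
                         merge = c("bilinear", "nearest")) {
  tile_rows <- as.integer(tile_rows)
  tile_cols <- as.integer(tile_cols)
  if (tile_rows < 1L || tile_cols < 1L) {
    stop("tile grid must be at least 1 x 1", call. = FALSE)
  }
  if (clip_limit <= 0) stop("`clip_limit` must be positive", call. = FALSE)
  structure(
    list(
      tile_rows = tile_rows, tile_cols = tile_cols,
      clip_limit = clip_limit, clip_unit = match.arg(clip_unit),
      redistribute = isTRUE(redistribute), merge = match.arg(merge)
    ),
    class = "clahe_config"
  )
}

#' Partition an image into a uniform tile grid
#'
#' The image is reflect-padded on the bottom/right up to a multiple of the
#' tile size, then split into non-overlapping tiles covering every padded
#' pixel exactly once.
#'
#' @param img Integer-valued intensity matrix.
#' @param cfg A [clahe_config()] (only the grid is used).
#' @return A list with `tiles` (row-major list of matrices), `tile_h`,
#'   `tile_w`, `grid` (rows, cols), `padded` (the padded image) and
#'   `orig_dim`.
#' @examples
#' pt <- partition_tiles(matrix(0L, 16, 16), clahe_config(2, 2))
#' length(pt$tiles)
#' @export
partition_tiles <- function(img, cfg = clahe_config()) {
  if (!is.matrix(img) || nrow(img) < 1L || ncol(img) < 1L) {
    stop("`img` must be a non-empty matrix", call. = FALSE)
  }
  th <- as.integer(ceiling(nrow(img) / cfg$tile_rows))
  tw <- as.integer(ceiling(ncol(img) / cfg$tile_cols))
  padded <- reflect_pad(img, th * cfg$tile_rows, tw * cfg$tile_cols)
  tiles <- vector("list", cfg$tile_rows * cfg$tile_cols)
  k <- 1L
  for (i in seq_len(cfg$tile_rows)) {
    for (j in seq_len(cfg$tile_cols)) {
      tiles[[k]] <- padded[((i - 1L) * th + 1L):(i * th),
                           ((j - 1L) * tw + 1L):(j * tw), drop = FALSE]
      k <- k + 1L
    }
  }
  list(
    tiles = tiles, tile_h = th, tile_w = tw,
    grid = c(rows = cfg$tile_rows, cols = cfg$tile_cols),
    padded = padded, orig_dim = dim(img)
  )
}

# reflect-pad img on the bottom/right to target rows x cols
reflect_pad <- function(img, rows, cols) {
  extra_r <- rows - nrow(img)
  extra_c <- cols - ncol(img)
  if (extra_r > 0L) {
    if (extra_r > nrow(img)) stop("padding exceeds image size; use fewer tiles", call. = FALSE)
    img <- rbind(img, img[nrow(img):(nrow(img) - extra_r + 1L), , drop = FALSE])
  }
  if (extra_c > 0L) {
    if (extra_c > ncol(img)) stop("padding exceeds image size; use fewer tiles", call. = FALSE)
    img <- cbind(img, img[, ncol(img):(ncol(img) - extra_c + 1L), drop = FALSE])
  }
  img
}

#' Histogram of an integer tile
#'
#' Counts occurrences of each intensity `k` in `0 .. L-1`.
#'
#' @param tile Integer-valued matrix with entries in `[0, L-1]`.
#' @param L Number of intensity levels (default 256).
#' @return Integer count vector of length `L` summing to the pixel count.
#' @examples
#' tile_histogram(matrix(3L, 2, 2), L = 8)
#' @export
tile_histogram <- function(tile, L = 256L) {
  v <- as.integer(tile)
  if (any(v < 0L) || any(v > L - 1L)) {
    stop(sprintf("tile values must lie in [0, %d]", L - 1L), call. = FALSE)
  }
  tabulate(v + 1L, nbins = L)
}

#' Clip a histogram at the contrast limit
#'
#' Literal mode caps every bin at `T`, discarding the excess. Redistribute
#' mode conserves the total count: the clipped excess is spread uniformly,
#' `floor(excess / L)` to every bin and the remainder round-robin from the
#' first bin.
#'
#' @param H Count vector.
#' @param clip_limit The limit `T` (> 0), in count units.
#' @param redistribute Spread the excess instead of discarding it.
#' @return Clipped count vector.
#' @examples
#' clip_histogram(c(5, 10, 2), 4)                      # c(4, 4, 2)
#' sum(clip_histogram(c(5, 10, 2), 4, TRUE))           # 17, conserved
#' @export
clip_histogram <- function(H, clip_limit, redistribute = FALSE) {
  if (clip_limit <= 0) stop("`clip_limit` must be positive", call. = FALSE)
  clipped <- pmin(H, clip_limit)
  if (!isTRUE(redistribute)) return(clipped)
  excess <- sum(H) - sum(clipped)
  if (excess <= 0) return(clipped)
  L <- length(H)
  clipped <- clipped + excess %/% L
  rem <- excess %% L
  if (rem > 0) clipped[seq_len(rem)] <- clipped[seq_len(rem)] + 1
  clipped
}

#' Cumulative distribution of a histogram
#'
#' @param H Count vector.
#' @return Non-decreasing cumulative vector `C(k) = sum_{j<=k} H(j)`.
#' @examples
#' histogram_cdf(c(1, 2, 3))
#' @export
histogram_cdf <- function(H) cumsum(H)

#' Rescale a cumulative histogram onto the intensity range
#'
#' Maps `C(k)` to `(L-1) * C(k) / n_pixels`, spreading the cumulative mass
#' evenly over the available levels. `n_pixels` is the pixel count underlying
#' the histogram — the tile pixel count in per-tile use.
#'
#' @param C Cumulative vector from [histogram_cdf()].
#' @param L Number of intensity levels.
#' @param n_pixels Pixel count underlying `C` (> 0).
#' @return Mapped vector in `[0, L-1]`, non-decreasing.
#' @examples
#' redistribute_cdf(c(4, 8, 16), L = 8, n_pixels = 16)
#' @export
redistribute_cdf <- function(C, L, n_pixels) {
  if (n_pixels <= 0) stop("`n_pixels` must be positive", call. = FALSE)
  (L - 1) * C / n_pixels
}

# per-tile intensity mapping k -> [0, L-1]
tile_mapping <- function(tile, L, cfg) {
  H <- tile_histogram(tile, L)
  T_count <- if (cfg$clip_unit == "fraction") {
    max(1, cfg$clip_limit * length(tile))
  } else {
    cfg$clip_limit
  }
  Hc <- clip_histogram(H, T_count, cfg$redistribute)
  C <- histogram_cdf(Hc)
  redistribute_cdf(C, L, sum(Hc))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Builds a clipped-equalization mapping per tile and remaps every pixel.
#' With `merge = "bilinear"` a pixel's new value interpolates between the
#' mappings of the four tiles whose centers surround it (edge tiles
#' replicated); with `"nearest"` each tile applies its own mapping
#' independently. Output has the input's shape with values in `[0, L-1]`
#' (not rounded).
#'
#' With a 1 x 1 grid and a clip limit at or above the max bin count, the
#' result is plain global histogram equalization.
#'
#' @param img Integer-valued intensity matrix in `[0, L-1]`.
#' @param cfg A [clahe_config()].
#' @param L Number of intensity levels (default 256).
#' @return Numeric matrix, same shape as `img`, values in `[0, L-1]`.
#' @examples
#' img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
#' out <- clahe(img, clahe_config(4, 4, clip_limit = 0.05))
#' range(out)
#' @export
clahe <- function(img, cfg = clahe_config(), L = 256L) {
  pt <- partition_tiles(img, cfg)
  gr <- cfg$tile_rows
  gc <- cfg$tile_cols
  maps <- array(0, dim = c(L, gr, gc))
  k <- 1L
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      maps[, i, j] <- tile_mapping(pt$tiles[[k]], L, cfg)
      k <- k + 1L
    }
  }
  P <- pt$padded
  nr <- nrow(P)
  nc <- ncol(P)
  pix <- as.integer(P) + 1L  # level index into maps

  if (cfg$merge == "nearest") {
    ti <- pmin((seq_len(nr) - 1L) %/% pt$tile_h + 1L, gr)
    tj <- pmin((seq_len(nc) - 1L) %/% pt$tile_w + 1L, gc)
    I <- matrix(ti, nr, nc)
    J <- matrix(tj, nr, nc, byrow = TRUE)
    out <- matrix(maps[cbind(pix, as.integer(I), as.integer(J))], nr, nc)
  } else {
    # tile centers at (i - 0.5) * tile_h etc.; clamp outside the center
    # lattice to the edge tiles
    rc <- (seq_len(nr) - 0.5) / pt$tile_h + 0.5  # fractional tile row index
    cc <- (seq_len(nc) - 0.5) / pt$tile_w + 0.5
    i0 <- pmin(pmax(floor(rc), 1), gr)
    i1 <- pmin(i0 + 1, gr)
    wi <- pmin(pmax(rc - i0, 0), 1)             # weight on i1
    j0 <- pmin(pmax(floor(cc), 1), gc)
    j1 <- pmin(j0 + 1, gc)
    wj <- pmin(pmax(cc - j0, 0), 1)
    I0 <- matrix(as.integer(i0), nr, nc)
    I1 <- matrix(as.integer(i1), nr, nc)
    WI <- matrix(wi, nr, nc)
    J0 <- matrix(as.integer(j0), nr, nc, byrow = TRUE)
    J1 <- matrix(as.integer(j1), nr, nc, byrow = TRUE)
    WJ <- matrix(wj, nr, nc, byrow = TRUE)
    v00 <- matrix(maps[cbind(pix, as.integer(I0), as.integer(J0))], nr, nc)
    v01 <- matrix(maps[cbind(pix, as.integer(I0), as.integer(J1))], nr, nc)
    v10 <- matrix(maps[cbind(pix, as.integer(I1), as.integer(J0))], nr, nc)
    v11 <- matrix(maps[cbind(pix, as.integer(I1), as.integer(J1))], nr, nc)
    out <- (1 - WI) * ((1 - WJ) * v00 + WJ * v01) +
      WI * ((1 - WJ) * v10 + WJ * v11)
  }
  out[seq_len(pt$orig_dim[1]), seq_len(pt$orig_dim[2]), drop = FALSE]
}
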