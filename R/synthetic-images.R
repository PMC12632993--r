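#' Generate small parametric shape images
#'
#' Renders `n` RGB images each containing one filled parametric shape
#' (circle, square or upward triangle) on a black background, with a factor
#' table recording the ground-truth generative factors (shape, color, scale,
#' position). These are desk-scale stand-ins for object photographs:
#' sufficient to exercise autoencoder training and factor-specific
#' compression. Supplying an explicit `factors` table re-renders exactly
#' those factors, so paired variants that differ in one factor (e.g. color
#' only) can be constructed and differ only inside the shape mask.
#'
#' @param n number of images (>= 1).
#' @param size image side in pixels (>= 8).
#' @param seed integer seed.
#' @param factors optional data frame with columns `shape`
#'   (`"circle"|"square"|"triangle"`), `hue` (in `[0,1]`), `scale`
#'   (fraction of the half-side, in `(0, 1]`), `cx`, `cy` (centers in
#'   `[0,1]`). When given, `n` and the random draws are ignored.
#' @return An object of class `image_set`: list with `images`
#'   (`n x size x size x 3` array, values in `[0,1]`), `ids`, `factors`.
#' @export
gen_shape_images <- function(n, size = 16L, seed = 1L, factors = NULL) {
  size <- check_count(size, "size", min = 8L)
  if (is.null(factors)) {
    n <- check_count(n, "n")
    factors <- with_seed(seed, data.frame(
      shape = sample(c("circle", "square", "triangle"), n, replace = TRUE),
      hue = runif(n),
      scale = runif(n, 0.35, 0.8),
      cx = runif(n, 0.35, 0.65),
      cy = runif(n, 0.35, 0.65),
      stringsAsFactors = FALSE
    ))
  } else {
    n <- nrow(factors)
    if (n < 1L) stop_rdmem("empty factor table", class = "rdmem_empty_set")
  }
  imgs <- array(0, dim = c(n, size, size, 3L))
  gx <- matrix(rep((seq_len(size) - 0.5) / size, each = size), nrow = size)
  gy <- matrix(rep((seq_len(size) - 0.5) / size, times = size), nrow = size)
  for (i in seq_len(n)) {
    f <- factors[i, ]
    r <- f$scale * 0.5
    mask <- switch(as.character(f$shape),
      circle = (gx - f$cx)^2 + (gy - f$cy)^2 <= r^2,
      square = pmax(abs(gx - f$cx), abs(gy - f$cy)) <= r,
      triangle = {
        dy <- gy - (f$cy - r)  # depth below the apex
        dy >= 0 & dy <= 2 * r & abs(gx - f$cx) <= dy / 2
      },
      stop_rdmem("unknown shape: ", f$shape,
                 class = "rdmem_invalid_parameter")
    )
    col <- hue_to_rgb(f$hue)
    for (ch in 1:3) {
      plane <- matrix(0, size, size)
      plane[mask] <- col[ch]
      imgs[i, , , ch] <- plane
    }
  }
  structure(
    list(images = imgs, ids = sprintf("img%04d", seq_len(n)),
         factors = factors),
    class = "image_set"
  )
}

# Minimal hue -> RGB map (full saturation/value), hue in [0,1].
hue_to_rgb <- function(h) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  switch(as.character(i %% 6),
    "0" = c(1, f, 0), "1" = c(1 - f, 1, 0), "2" = c(0, 1, f),
    "3" = c(0, 1 - f, 1), "4" = c(f, 0, 1), "5" = c(1, 0, 1 - f)
  )
}

#' Flatten an image set to an items-by-pixels matrix
#'
#' Rows are images; columns enumerate pixels channel-slowest (all of R, then
#' G, then B, column-major within a channel). Used as network input.
#'
#' @param images an `image_set` or an `n x H x W x 3` array in `[0,1]`.
#' @return numeric matrix `n x (H*W*3)`.
#' @export
flatten_images <- function(images) {
  a <- if (inherits(images, "image_set")) images$images else images
  stopifnot(length(dim(a)) == 4L)
  matrix(a, nrow = dim(a)[1L])
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_set> %d images, %dx%dx%d, values in [%.2f, %.2f]\n",
              d[1], d[2], d[3], d[4], min(x$images), max(x$images)))
  invisible(x)
}
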