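# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are deterministic without side effects.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Coerce EBImage images (or anything matrix-like) back to a plain matrix.
as_img <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

check_image <- function(x, arg = deparse(substitute(x))) {
  if (inherits(x, "Image")) x <- as_img(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a 2-D numeric matrix", arg), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  x
}

# Odd-sized 0/1 disk mask: pixel included iff dx^2 + dy^2 <= r^2.
# The same discretization is used for structuring elements and for the
# synthetic disks drawn in tests, so erosion/survival arguments are exact.
disk_mask <- function(radius_px) {
  r <- as.integer(radius_px)
  stopifnot(r >= 1)
  d <- seq(-r, r)
  outer(d, d, function(dy, dx) as.numeric(dx^2 + dy^2 <= r^2))
}

# Draw a filled disk into a matrix (values added), same discretization as
# disk_mask(); cx, cy in pixel coordinates (column, row).
draw_disk <- function(img, cx, cy, radius, value = 1) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(radius)
  rows <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(img)
  dy <- rows - cy
  dx <- cols - cx
  hit <- outer(dy^2, dx^2, "+") <= radius^2
  img[rows, cols][hit] <- img[rows, cols][hit] + value
  img
}

# Linear pixel indices of a filled disk, same discretization as draw_disk().
disk_window <- function(nr, nc, cx, cy, radius) {
  r <- ceiling(radius)
  rows <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(integer(0))
  hit <- outer((rows - cy)^2, (cols - cx)^2, "+") <= radius^2
  (rep(cols, each = length(rows))[hit] - 1L) * nr + rep(rows, length(cols))[hit]
}

clamp16 <- function(x) {
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pad_matrix <- function(x, r, value) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(value, nr + 2 * r, nc + 2 * r)
  out[(r + 1):(r + nr), (r + 1):(r + nc)] <- x
  out
}

# Flat grayscale erosion/dilation with out-of-frame pixels ignored
# (erosion pads with the image maximum, dilation with the minimum, so the
# padding can never win the min/max inside the frame). EBImage clamps
# grayscale morphology to [0, 1], so intensities are affinely mapped into
# that range and back; min/max filters commute with increasing affine maps.
minmax_filter <- function(image, se, fun, pad_value) {
  r <- se$radius_px
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  p <- (pad_matrix(image, r, pad_value) - lo) / (hi - lo)
  out <- as_img(fun(p, se$mask))[(r + 1):(r + nrow(image)),
                                 (r + 1):(r + ncol(image))]
  out * (hi - lo) + lo
}

erode_flat <- function(image, se)
  minmax_filter(image, se, EBImage::erode, max(image))

dilate_flat <- function(image, se)
  minmax_filter(image, se, EBImage::dilate, min(image))
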