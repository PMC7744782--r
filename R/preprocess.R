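#' Multi-channel image stack
#'
#' Container for a registered set of channel images sharing pixel geometry.
#' Each channel carries a name, a channel class and a 2-D matrix or 3-D
#' z-stack array (rows x cols x slices).
#'
#' @param images named list of numeric matrices or 3-D arrays, all with the
#'   same x-y dimensions.
#' @param classes character vector (recycled by name) giving the channel
#'   class of each image: `"DAPI"`, `"nuclear_antigen"`,
#'   `"cytoplasmic_antigen"` or `"fish_cytoplasmic"`; may be `NA` before
#'   [classify_channels()] is applied.
#' @param pixel_size_um pixel size in micrometers (default 0.325, the
#'   40x acquisition setting the workflow was built around).
#' @param z_step_um z spacing for stacks, if any.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(images, classes = NULL, pixel_size_um = 0.325,
                          z_step_um = NA_real_) {
  if (!is.list(images) || is.null(names(images)) || any(names(images) == ""))
    stop("'images' must be a named list")
  if (anyDuplicated(names(images)))
    stop("channel names must be unique")
  dims <- lapply(images, function(x) dim(x)[1:2])
  if (length(unique(dims)) != 1)
    stop("all channels must share x-y dimensions")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be > 0")
  if (is.null(classes)) classes <- rep(NA_character_, length(images))
  if (is.null(names(classes))) names(classes) <- names(images)
  cls <- classes[names(images)]
  bad <- !is.na(cls) & !cls %in% CHANNEL_CLASSES
  if (any(bad))
    stop("unknown channel class: ", paste(cls[bad], collapse = ", "))
  structure(list(images = images,
                 classes = setNames(as.character(cls), names(images)),
                 pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("channel_stack: %d channel(s), %d x %d px (%.3f um/px)\n",
              length(x$images), d[1], d[2], x$pixel_size_um))
  for (nm in names(x$images)) {
    z <- dim(x$images[[nm]])[3]
    cat(sprintf("  %-10s %-20s %s\n", nm,
                ifelse(is.na(x$classes[nm]), "(unclassified)", x$classes[nm]),
                if (is.na(z) || is.null(z)) "2-D" else sprintf("%d slices", z)))
  }
  invisible(x)
}

#' Project a z-stack onto one all-in-focus plane
#'
#' `"max"` takes the per-pixel maximum across slices. The default
#' `"best_focus_manifold"` selects, for each image tile, the slice with the
#' highest local intensity variance (a focus measure), smooths the resulting
#' slice-index map and samples each pixel from its selected slice. It is a
#' deliberately simple surrogate for full smooth-manifold extraction; the
#' per-cell statistics downstream are robust to the projection method.
#'
#' @param x 3-D array (rows x cols x slices) or a 2-D matrix (returned
#'   unchanged).
#' @param method projection method.
#' @param tile_px tile edge length for the focus measure (default 32).
#' @param smooth_sigma_tiles Gaussian sigma (in tiles) for smoothing the
#'   slice-index map; 0 disables smoothing.
#' @return 2-D numeric matrix with the stack's x-y dimensions.
#' @export
project_stack <- function(x, method = c("best_focus_manifold", "max"),
                          tile_px = 32L, smooth_sigma_tiles = 1) {
  method <- match.arg(method)
  if (is.matrix(x)) return(check_image(x))
  if (!is.array(x) || length(dim(x)) != 3)
    stop("'x' must be a 2-D matrix or 3-D array")
  nz <- dim(x)[3]
  if (nz < 1) stop("empty stack")
  if (nz == 1) return(x[, , 1])
  if (method == "max") return(apply(x, c(1, 2), max))

  nr <- dim(x)[1]; nc <- dim(x)[2]
  tr <- ceiling(nr / tile_px); tc <- ceiling(nc / tile_px)
  row_tile <- pmin((seq_len(nr) - 1L) %/% tile_px + 1L, tr)
  col_tile <- pmin((seq_len(nc) - 1L) %/% tile_px + 1L, tc)
  focus <- array(0, c(tr, tc, nz))
  for (k in seq_len(nz)) {
    sl <- x[, , k]
    sums <- rowsum(t(rowsum(sl, row_tile)), col_tile)          # tc x tr
    sq <- rowsum(t(rowsum(sl^2, row_tile)), col_tile)
    npix <- rowsum(t(rowsum(matrix(1, nr, nc), row_tile)), col_tile)
    focus[, , k] <- t(sq / npix - (sums / npix)^2)
  }
  idx <- apply(focus, c(1, 2), which.max)
  if (smooth_sigma_tiles > 0 && length(idx) > 1) {
    sm <- as_img(EBImage::gblur(pad_matrix(idx, 4, mean(idx)),
                                sigma = smooth_sigma_tiles))
    idx <- round(sm[5:(4 + tr), 5:(4 + tc)])
    idx[idx < 1] <- 1L; idx[idx > nz] <- nz
  }
  sel <- idx[cbind(rep(row_tile, nc), rep(col_tile, each = nr))]
  out <- x[cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr), sel)]
  matrix(out, nr, nc)
}

#' Non-local means denoising
#'
#' Denoises a grayscale image by averaging pixels with similar patch
#' neighbourhoods. When `h` is `NULL` the filtering strength is tied to a
#' robust noise estimate: the noise standard deviation is estimated from
#' the median absolute response to a Laplacian kernel (structure-blind),
#' and `h = 0.8 * sigma_hat`. If the image is noise-free by that estimate
#' it is returned unchanged.
#'
#' @param image 2-D numeric matrix.
#' @param h filtering strength in gray levels (> 0), or `NULL` for the
#'   automatic choice.
#' @param patch_radius patch half-width in px (default 3).
#' @param search_radius search-window half-width in px (default 10).
#' @return Denoised image, same dimensions.
#' @export
denoise_nlm <- function(image, h = NULL, patch_radius = 3L,
                        search_radius = 10L) {
  image <- check_image(image)
  if (is.null(h)) {
    s <- estimate_noise_sd(image)
    if (s <= 0) return(image)
    h <- 0.8 * s
  }
  if (!is.finite(h) || h <= 0) stop("'h' must be > 0")
  .nlm_cpp(image, h, as.integer(patch_radius), as.integer(search_radius))
}

#' Robust image noise estimate
#'
#' Estimates the standard deviation of additive pixel noise from the median
#' absolute response to the 3x3 Laplacian-of-box kernel
#' (1 -2 1 / -2 4 -2 / 1 -2 1), whose response to smooth structure is
#' near zero and whose response variance to white noise of sd sigma is
#' 36 sigma^2.
#'
#' @param image 2-D numeric matrix.
#' @return Estimated noise sd in gray levels.
#' @export
estimate_noise_sd <- function(image) {
  image <- check_image(image)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) return(0)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  lap <- 4 * image[i, j] -
    2 * (image[i - 1, j] + image[i + 1, j] + image[i, j - 1] + image[i, j + 1]) +
    image[i - 1, j - 1] + image[i - 1, j + 1] + image[i + 1, j - 1] + image[i + 1, j + 1]
  1.4826 * median(abs(lap)) / 6
}

#' Tag channels with their channel class
#'
#' Sorts the channels of a stack into the four classes the workflow
#' recognises. Exactly one DAPI channel is required.
#'
#' @param stack a [channel_stack()].
#' @param mapping named character vector, channel name -> channel class.
#' @return The stack with classes assigned.
#' @export
classify_channels <- function(stack, mapping) {
  stopifnot(inherits(stack, "channel_stack"))
  missing <- setdiff(names(stack$images), names(mapping))
  if (length(missing))
    stop("mapping omits channel(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unname(mapping[names(stack$images)]), CHANNEL_CLASSES)
  if (length(bad))
    stop("unknown channel class: ", paste(bad, collapse = ", "))
  cls <- mapping[names(stack$images)]
  dapi <- names(cls)[cls == "DAPI"]
  if (length(dapi) != 1)
    stop("exactly one DAPI channel required; got ",
         if (length(dapi)) paste(dapi, collapse = ", ") else "none")
  stack$classes <- setNames(as.character(cls), names(stack$images))
  stack
}

#' Preprocess a channel stack
#'
#' Applies the fixed projection-then-denoise order to every channel and
#' returns a stack of single-plane denoised images.
#'
#' @param stack a classified [channel_stack()].
#' @param projection projection method, see [project_stack()].
#' @param ... further arguments to [denoise_nlm()].
#' @return A `channel_stack` of 2-D channels.
#' @export
preprocess_stack <- function(stack, projection = "best_focus_manifold", ...) {
  stopifnot(inherits(stack, "channel_stack"))
  stack$images <- lapply(stack$images, function(img) {
    denoise_nlm(project_stack(img, method = projection), ...)
  })
  stack
}
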