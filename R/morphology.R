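#' Disk-shaped structuring element
#'
#' Builds the flat, disk-shaped structuring element (SE) used by all
#' morphological operators in the package. A pixel at offset (dx, dy)
#' belongs to the disk iff dx^2 + dy^2 <= radius_px^2.
#'
#' @param radius_px positive integer radius in pixels.
#' @param pixel_size_um optional pixel size; if given, the physical radius
#'   in micrometers is stored alongside.
#' @return An object of class `svz_se` with elements `shape`, `radius_px`,
#'   `radius_um` (or `NA`) and the 0/1 `mask` matrix.
#' @export
se_disk <- function(radius_px, pixel_size_um = NA_real_) {
  if (length(radius_px) != 1 || !is.finite(radius_px) || radius_px < 1)
    stop("'radius_px' must be a positive integer >= 1")
  radius_px <- as.integer(radius_px)
  structure(list(shape = "disk", radius_px = radius_px,
                 radius_um = radius_px * pixel_size_um,
                 mask = disk_mask(radius_px)),
            class = "svz_se")
}

#' @export
print.svz_se <- function(x, ...) {
  cat(sprintf("disk structuring element, radius %d px%s\n", x$radius_px,
              if (is.finite(x$radius_um)) sprintf(" (%.2f um)", x$radius_um) else ""))
  invisible(x)
}

as_se <- function(se) {
  if (inherits(se, "svz_se")) return(se)
  se_disk(se)
}

check_se <- function(se, image) {
  se <- as_se(se)
  if (nrow(se$mask) > nrow(image) || nrow(se$mask) > ncol(image))
    stop("structuring element is larger than the image")
  se
}

#' Geodesic morphological reconstruction
#'
#' Reconstruction by dilation grows `marker` under `mask` until stability;
#' reconstruction by erosion is its intensity-inversion dual. 8-connectivity.
#'
#' @param marker,mask numeric matrices of equal size. In dilation mode the
#'   marker must lie below the mask pointwise; in erosion mode above it.
#' @param mode `"dilation"` or `"erosion"`.
#' @return The reconstructed image (numeric matrix).
#' @export
reconstruct <- function(marker, mask, mode = c("dilation", "erosion")) {
  mode <- match.arg(mode)
  marker <- check_image(marker); mask <- check_image(mask)
  if (!all(dim(marker) == dim(mask)))
    stop("'marker' and 'mask' must have identical dimensions")
  tol <- 1e-9 * max(1, max(abs(mask)))
  if (mode == "dilation") {
    if (any(marker > mask + tol))
      stop("dilation mode requires marker <= mask pointwise")
    .reconstruct_dilation_cpp(pmin(marker, mask), mask)
  } else {
    if (any(marker < mask - tol))
      stop("erosion mode requires marker >= mask pointwise")
    m <- max(marker)
    m - .reconstruct_dilation_cpp(m - pmax(marker, mask), m - mask)
  }
}

#' Opening and closing by reconstruction
#'
#' `opening_by_reconstruction()` erodes with the SE and reconstructs by
#' dilation under the original image, so surviving structures are restored
#' with their exact shape. `closing_by_reconstruction()` is the dual,
#' implemented by intensity inversion, and fills dark structures narrower
#' than the SE.
#'
#' @param image numeric matrix.
#' @param se an [se_disk()] structuring element (or an integer radius).
#' @return Filtered image, same dimensions.
#' @export
opening_by_reconstruction <- function(image, se) {
  image <- check_image(image)
  se <- check_se(se, image)
  eroded <- erode_flat(image, se)
  .reconstruct_dilation_cpp(pmin(eroded, image), image)
}

#' @rdname opening_by_reconstruction
#' @export
closing_by_reconstruction <- function(image, se) {
  image <- check_image(image)
  se <- check_se(se, image)
  m <- max(image)
  m - opening_by_reconstruction(m - image, se)
}

#' Top-hat by reconstruction with dark-variation suppression
#'
#' Background suppression filter for fluorescence channels. A plain top-hat
#' subtracts an opening-based background estimate from the image; here a
#' closing by reconstruction (same SE) is applied first so that dark
#' blotches narrower than the SE are filled and cannot perturb the
#' background estimate. The filter computes
#' `C = closing_by_reconstruction(image, se)`,
#' `B = opening_by_reconstruction(C, se)` and returns `max(C - B, 0)`:
#' only bright structures standing above the background survive, and the
#' output is invariant to adding a constant to the input.
#'
#' @inheritParams opening_by_reconstruction
#' @return Non-negative filtered image.
#' @export
modified_tophat <- function(image, se) {
  image <- check_image(image)
  se <- check_se(se, image)
  cl <- closing_by_reconstruction(image, se)
  bg <- opening_by_reconstruction(cl, se)
  pmax(cl - bg, 0)
}

#' Granulometry (pattern spectrum) of an image
#'
#' Applies openings by reconstruction at increasing disk radii and records
#' the retained intensity volume. The pattern spectrum is the negative
#' discrete derivative of the retained volume: `spectrum[i]` is the volume
#' lost when the SE grows past `radii[i]`, i.e. the amount of structure at
#' size class `radii[i]`.
#'
#' @param image numeric matrix.
#' @param radii strictly increasing positive integer radii (>= 2 values).
#' @return Object of class `pattern_spectrum` with `radii_px`,
#'   `retained_volume` (one per radius) and `spectrum` (one per size class,
#'   i.e. per radius except the last).
#' @export
granulometry <- function(image, radii) {
  image <- check_image(image)
  if (length(radii) < 2) stop("need at least two radii")
  radii <- as.integer(radii)
  if (any(radii < 1) || any(diff(radii) <= 0))
    stop("'radii' must be strictly increasing integers >= 1")
  vol <- vapply(radii, function(r)
    sum(opening_by_reconstruction(image, se_disk(r))), numeric(1))
  # openings at nested SEs are anti-extensive and ordered; clip float noise
  vol <- rev(cummax(rev(vol)))
  spec <- -diff(vol)
  structure(list(radii_px = radii, retained_volume = vol,
                 spectrum = pmax(spec, 0)),
            class = "pattern_spectrum")
}

#' @export
print.pattern_spectrum <- function(x, ...) {
  cat("pattern spectrum over radii", paste(x$radii_px, collapse = ", "), "px\n")
  print(data.frame(radius_px = x$radii_px[-length(x$radii_px)],
                   spectrum = x$spectrum))
  invisible(x)
}

#' Select a structuring-element radius from a pattern spectrum
#'
#' The SE must retain objects at the modal size class, so the selected
#' radius is the smallest radius strictly greater than the dominant
#' spectrum peak. Ties between equal peaks are broken toward the larger
#' radius. For punctate FISH channels the peak search is restricted to
#' radii at or below `puncta_max_radius`, since large autofluorescent
#' structures must not inflate the SE.
#'
#' With `rule = "support"` the reference size class is instead the largest
#' radius still carrying an appreciable share of the spectrum (at least
#' `support_tail` of the spectral maximum). This is the batch-calibration
#' choice for stains that coalesce across adjacent cells (dense
#' cytoplasmic staining, touching nuclei), where structures larger than
#' the modal single-cell size must still be kept out of the background
#' estimate. On fields of identically sized compact objects both rules
#' select the same radius.
#'
#' @param spectrum a [granulometry()] result.
#' @param channel_class one of `"DAPI"`, `"nuclear_antigen"`,
#'   `"cytoplasmic_antigen"`, `"fish_cytoplasmic"`.
#' @param puncta_max_radius peak-search cap (px) for `fish_cytoplasmic`.
#' @param rule `"modal"` (default) or `"support"`, see Details.
#' @param support_tail spectral-mass fraction defining the support edge.
#' @return An [se_disk()] of the selected radius.
#' @export
select_se_radius <- function(spectrum, channel_class = "cytoplasmic_antigen",
                             puncta_max_radius = 5L,
                             rule = c("modal", "support"),
                             support_tail = 0.02) {
  stopifnot(inherits(spectrum, "pattern_spectrum"))
  rule <- match.arg(rule)
  channel_class <- match.arg(channel_class, CHANNEL_CLASSES)
  size_radii <- spectrum$radii_px[-length(spectrum$radii_px)]
  spec <- spectrum$spectrum
  if (channel_class == "fish_cytoplasmic") {
    keep <- size_radii <= puncta_max_radius
    if (!any(keep)) stop("no size class at or below 'puncta_max_radius'")
    size_radii <- size_radii[keep]
    spec <- spec[keep]
  }
  if (all(spec <= 0))
    stop("pattern spectrum is identically zero; supply an SE radius manually")
  peak <- if (rule == "modal")
    max(size_radii[spec == max(spec)])   # tie-break: larger radius
  else
    max(size_radii[spec >= support_tail * max(spec)])
  larger <- spectrum$radii_px[spectrum$radii_px > peak]
  se_disk(if (length(larger)) min(larger) else peak + 1L)
}

CHANNEL_CLASSES <- c("DAPI", "nuclear_antigen", "cytoplasmic_antigen",
                     "fish_cytoplasmic")
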