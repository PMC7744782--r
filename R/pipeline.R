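#' Granulometry-based SE calibration per channel class
#'
#' Computes, on a calibration stack, the pattern spectrum of each channel
#' and selects one disk SE radius per channel class (not per image), to be
#' reused across all fields of an imaging batch.
#'
#' Because stains of adjacent cells coalesce on tissue (dense cytoplasmic
#' staining, touching nuclei), the SE is sized past the spectrum support
#' (`rule = "support"` of [select_se_radius()]), so that coalesced patches
#' are kept out of the background estimate; FISH channels remain capped at
#' the puncta scale.
#'
#' @param stack a preprocessed, classified [channel_stack()] of 2-D
#'   channels.
#' @param radii radii scanned by the granulometry.
#' @param puncta_max_radius peak-search cap for FISH channels.
#' @return Named integer vector: SE radius per channel class present.
#' @export
calibrate_se_radii <- function(stack, radii = c(2:16, seq(18, 26, 2)),
                               puncta_max_radius = 5L) {
  stopifnot(inherits(stack, "channel_stack"))
  out <- integer(0)
  for (cl in unique(stack$classes)) {
    nm <- names(stack$classes)[stack$classes == cl][1]
    g <- granulometry(stack$images[[nm]], radii)
    out[cl] <- select_se_radius(g, cl, puncta_max_radius,
                                rule = "support")$radius_px
  }
  out
}

#' Full per-cell marker quantification of one field
#'
#' Runs the whole cytometry chain on a classified stack: projection and
#' denoising, per-class top-hat by reconstruction, DAPI segmentation with
#' restricted dilation, two-step Z-score/Li thresholding of every marker
#' channel, per-cell area fractions in the class-appropriate compartment,
#' cutoff application and the co-expression matrix.
#'
#' @param stack a classified [channel_stack()].
#' @param se_radii named vector of SE radii per channel class (from
#'   [calibrate_se_radii()], or set manually).
#' @param cutoffs named per-channel area-fraction cutoffs; if `NULL`,
#'   `calibration` must be given.
#' @param calibration optional data frame of expert labels used to
#'   calibrate cutoffs on this field: columns `cell_id`, `channel_name`,
#'   `label` (logical or "positive"/"negative"), with cell ids referring
#'   to the segmented cells.
#' @param roi_polygon optional RoI polygon applied to the masks.
#' @param max_dilation_um restricted-dilation bound (default 3).
#' @param preprocess run projection + denoising first (default TRUE; set
#'   FALSE if the stack is already preprocessed).
#' @param projection projection method used when preprocessing.
#' @param ... further arguments to [segment_nuclei()].
#' @return List with `masks` (a [cell_mask_set()]), `fractions` (long
#'   per-cell x channel table), `cutoffs`, `calls` (marker call table) and
#'   `coexpression` (the [coexpression_matrix()]).
#' @export
quantify_field <- function(stack, se_radii, cutoffs = NULL,
                           calibration = NULL, roi_polygon = NULL,
                           max_dilation_um = 3, preprocess = TRUE,
                           projection = "best_focus_manifold", ...) {
  stopifnot(inherits(stack, "channel_stack"))
  if (anyNA(stack$classes)) stop("stack must be classified first")
  if (preprocess) stack <- preprocess_stack(stack, projection = projection)
  px <- stack$pixel_size_um
  miss <- setdiff(unique(stack$classes), names(se_radii))
  if (length(miss))
    stop("no SE radius for channel class(es): ", paste(miss, collapse = ", "))

  tophat <- lapply(names(stack$images), function(nm) {
    modified_tophat(stack$images[[nm]],
                    se_disk(se_radii[[stack$classes[[nm]]]], px))
  })
  names(tophat) <- names(stack$images)

  dapi_name <- names(stack$classes)[stack$classes == "DAPI"]
  nuclei <- segment_nuclei(tophat[[dapi_name]], pixel_size_um = px, ...)
  cells <- restricted_dilation(nuclei, px, max_dilation_um)
  masks <- cell_mask_set(nuclei, cells, px)
  if (!is.null(roi_polygon)) masks <- apply_roi(masks, roi_polygon)

  marker_names <- setdiff(names(stack$images), dapi_name)
  fr <- do.call(rbind, lapply(marker_names, function(nm) {
    gated <- zscore_gate(tophat[[nm]])
    binary <- if (any(gated > 0) && length(unique(gated[gated > 0])) >= 2)
      gated >= li_threshold(gated) else gated > 0
    af <- area_fraction(masks, binary,
                        default_compartment(stack$classes[[nm]]))
    af$channel_name <- nm
    af
  }))

  if (is.null(cutoffs)) {
    if (is.null(calibration))
      stop("either 'cutoffs' or a 'calibration' label table is required")
    lab <- merge(fr, calibration, by = c("cell_id", "channel_name"))
    cal <- calibrate_cutoffs(lab)
    cutoffs <- vapply(cal, `[[`, numeric(1), "cutoff")
  }
  calls <- classify_cells(fr, cutoffs)
  list(masks = masks, fractions = fr, cutoffs = cutoffs, calls = calls,
       coexpression = coexpression_matrix(calls))
}

#' Match detected cells to ground-truth cells
#'
#' Nearest-neighbour matching of detected nuclear centroids to true cell
#' centres within `max_dist_px`, used to transfer ground-truth labels onto
#' segmented cells (each truth cell is matched at most once, closest pair
#' first).
#'
#' @param detected data frame with `id`, `centroid_x`, `centroid_y` (e.g.
#'   the `table` of a [cell_mask_set()]).
#' @param truth generator truth table with `id`, `x`, `y`.
#' @param max_dist_px maximum matching distance.
#' @return Data frame with `detected_id`, `truth_id`, `dist_px`.
#' @export
match_cells <- function(detected, truth, max_dist_px = 6) {
  if (!nrow(detected) || !nrow(truth))
    return(data.frame(detected_id = integer(), truth_id = integer(),
                      dist_px = numeric()))
  dx <- outer(detected$centroid_x, truth$x, "-")
  dy <- outer(detected$centroid_y, truth$y, "-")
  dd <- sqrt(dx^2 + dy^2)
  pairs <- which(dd <= max_dist_px, arr.ind = TRUE)
  if (!nrow(pairs))
    return(data.frame(detected_id = integer(), truth_id = integer(),
                      dist_px = numeric()))
  ord <- order(dd[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_d <- logical(nrow(detected)); used_t <- logical(nrow(truth))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    di <- pairs[i, 1]; ti <- pairs[i, 2]
    if (used_d[di] || used_t[ti]) next
    used_d[di] <- TRUE; used_t[ti] <- TRUE
    out[[length(out) + 1]] <- data.frame(detected_id = detected$id[di],
                                         truth_id = truth$id[ti],
                                         dist_px = dd[di, ti])
  }
  do.call(rbind, out)
}
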