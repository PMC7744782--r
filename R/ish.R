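#' Grade a cell's ISH expression level from its precipitate fill fraction
#'
#' Four-level colorimetric grading: level 3 cells are filled with dye
#' precipitate (f >= 0.8), level 2 cells are partially filled
#' (0.3 <= f < 0.8), level 1 cells carry scattered minute particles
#' (0 < f < 0.3) and level 0 cells lack detectable precipitate (f = 0).
#' The interior bin edges are a calibration of this implementation
#' (configurable); the f = 0 and f = 1 anchors follow the level
#' definitions directly.
#'
#' @param f precipitate area fraction(s) in \[0, 1\].
#' @param edges interior bin edges `c(level1_min, level2_min, level3_min)`;
#'   default `c(0, 0.3, 0.8)`.
#' @return Integer level(s) in 0..3.
#' @export
grade_cell <- function(f, edges = c(0, 0.3, 0.8)) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("fill fraction must lie in [0, 1]")
  stopifnot(length(edges) == 3, !is.unsorted(edges))
  ifelse(f >= edges[3], 3L, ifelse(f >= edges[2], 2L,
         ifelse(f > edges[1], 1L, 0L)))
}

#' Detect and grade cells on a colorimetric ISH image
#'
#' Cells appear as pale footprints on a bright background with dark dye
#' precipitate inside expressing cells. Intensities are inverted so cells
#' become bright blobs; footprints are found by a robust threshold above
#' the inverted background mode, split by a distance-transform watershed,
#' and the precipitate is binarised by a global Li threshold over all
#' footprint pixels. The threshold is accepted only if the two intensity
#' classes it separates differ by at least `guard_mads` robust deviations
#' of the image noise; otherwise the field is treated as precipitate-free
#' (all cells level 0).
#'
#' @param image grayscale colorimetric image (dark precipitate on pale
#'   cells, bright background).
#' @param pixel_size_um pixel size (default 0.501, whole-slide scan
#'   resolution).
#' @param min_area_um2 minimum cell footprint retained.
#' @param footprint_mads robust deviations above the inverted background
#'   mode at which footprints are cut (default 6).
#' @param guard_mads minimum separation of the precipitate and pale
#'   intensity classes, in robust deviations of the image noise (default 5).
#' @param edges grading bin edges, see [grade_cell()].
#' @param rois optional named list of RoI polygons (two-column x, y
#'   matrices); cells are assigned to the first polygon containing their
#'   centroid, else `"none"`.
#' @return A graded cell set: data frame with id, centroid, footprint
#'   area, fill_fraction, level and roi.
#' @export
detect_colorimetric_cells <- function(image, pixel_size_um = 0.501,
                                      min_area_um2 = 20,
                                      footprint_mads = 6, guard_mads = 5,
                                      edges = c(0, 0.3, 0.8), rois = NULL) {
  img <- check_image(image)
  inv <- max(img) - img
  bg <- median(inv)
  s <- mad(inv)
  if (s == 0) s <- 1
  fp_thr <- bg + footprint_mads * s
  fg <- inv > fp_thr
  empty <- data.frame(id = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), area_px = numeric(),
                      fill_fraction = numeric(), level = integer(),
                      roi = character())
  if (!any(fg)) return(empty)
  fg <- as_img(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  dm <- as_img(EBImage::distmap(fg * 1))
  dm <- as_img(EBImage::gblur(dm, sigma = 1 / pixel_size_um, boundary = "replicate"))
  dm[!fg] <- 0
  lab <- as_img(EBImage::watershed(dm, tolerance = 1, ext = 1))
  storage.mode(lab) <- "integer"
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area_um2 / pixel_size_um^2)
  if (!length(keep)) return(empty)
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  nz <- lab > 0
  lab[nz] <- relabel[lab[nz]]

  fp_vals <- inv[lab > 0]
  # global precipitate threshold with a guard against precipitate-free
  # fields: the split is accepted only if the two intensity classes it
  # separates differ by clearly more than the noise scale
  prec_thr <- tryCatch(li_threshold(fp_vals, exclude_zeros = FALSE),
                       error = function(e) Inf)
  if (is.finite(prec_thr)) {
    gap <- mean(fp_vals[fp_vals >= prec_thr]) -
      mean(fp_vals[fp_vals < prec_thr])
    if (!is.finite(gap) || gap < guard_mads * s) prec_thr <- Inf
  }

  st <- label_centroids(lab)
  pos <- tabulate(lab[inv >= prec_thr], nbins = max(lab))
  f <- ifelse(st$area > 0, pos[st$id] / st$area, 0)
  roi <- rep("none", nrow(st))
  if (!is.null(rois)) {
    for (nm in names(rois)) {
      hit <- roi == "none" & point_in_polygon(st$cx, st$cy, rois[[nm]])
      roi[hit] <- nm
    }
  }
  data.frame(id = st$id, centroid_x = st$cx, centroid_y = st$cy,
             area_px = st$area, fill_fraction = f,
             level = grade_cell(pmin(f, 1), edges), roi = roi,
             stringsAsFactors = FALSE)
}

#' Rectangular RoI band in physical units
#'
#' Builds the evaluation band used for SEL/CSVZ quantification: a
#' rectangle of `width_um` x `length_um` anchored at `origin` (e.g. the
#' dorsal tip of the lateral ventricle) and extending along `direction`.
#'
#' @param origin numeric (x, y) anchor in pixel coordinates.
#' @param direction numeric (dx, dy) direction of the band's long axis
#'   (any nonzero length).
#' @param width_um,length_um physical size (defaults 100 x 1500).
#' @param pixel_size_um pixel size.
#' @return 4 x 2 matrix of polygon vertices (x, y) in pixels.
#' @export
define_roi_band <- function(origin, direction, width_um = 100,
                            length_um = 1500, pixel_size_um = 0.501) {
  if (length_um <= 0 || width_um <= 0)
    stop("degenerate band: width and length must be > 0")
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("zero direction vector")
  u <- direction / nrm
  v <- c(-u[2], u[1])
  L <- length_um / pixel_size_um
  W <- width_um / pixel_size_um
  rbind(origin - v * W / 2,
        origin - v * W / 2 + u * L,
        origin + v * W / 2 + u * L,
        origin + v * W / 2)
}

#' RoI-level quantification of graded cells
#'
#' The expression score of an RoI is the ratio of level 2 and level 3
#' cells to all detected cells in the RoI.
#'
#' @param cells a graded cell set from [detect_colorimetric_cells()] (or
#'   any data frame with `level` and `roi` columns).
#' @param roi RoI name to quantify (cells with matching `roi`), or `NULL`
#'   to use all cells.
#' @param condition condition label carried through to reports.
#' @return List with `roi_name`, `condition`, `n_cells`, `n_level23`,
#'   `ratio` (`NA` and `defined = FALSE` when the RoI holds no cells).
#' @export
quantify_roi <- function(cells, roi = NULL, condition = NA_character_) {
  d <- if (is.null(roi)) cells else cells[cells$roi == roi, , drop = FALSE]
  n <- nrow(d)
  n23 <- sum(d$level >= 2)
  list(roi_name = roi %||% "all", condition = condition, n_cells = n,
       n_level23 = n23, ratio = if (n > 0) n23 / n else NA_real_,
       defined = n > 0)
}

#' Fold change of RoI expression between conditions
#'
#' @param ischemic,control [quantify_roi()] results.
#' @return List with `fold` (ischemic ratio / control ratio) and a flag;
#'   a zero control ratio is reported as induced-from-zero with `NA` fold.
#' @export
fold_change <- function(ischemic, control) {
  if (!isTRUE(ischemic$defined) || !isTRUE(control$defined))
    stop("both ratios must be defined")
  if (control$ratio == 0)
    return(list(fold = NA_real_, induced_from_zero = TRUE))
  list(fold = ischemic$ratio / control$ratio, induced_from_zero = FALSE)
}

GROUP_SETS <- list(
  `1` = c("EL", "SEL", "CSVZ", "STR"),
  `2` = c("EL", "SEL", "STR"),
  `3` = c("EL", "SEL", "CSVZ"),
  `4` = c("EL", "CSVZ", "STR"),
  `5` = c("EL", "SEL"),
  `6` = c("EL", "STR"),
  `7` = "EL",
  `8` = "STR")

#' Assign a gene to an induction group from its RoI score profile
#'
#' Genes are grouped by which regions of interest show strong postischemic
#' induction. An RoI counts as strongly induced when the ischemic visual
#' score is at least `min_score` and exceeds the control score by at least
#' `min_delta` (both configurable; the grouping itself is qualitative).
#' The strongly-induced RoI set is then matched, in order, against:
#' group 1 all four RoIs; group 2 the striatal side (EL, SEL, STR);
#' group 3 EL, SEL, CSVZ; group 4 EL, CSVZ, STR; group 5 EL, SEL;
#' group 6 EL, STR; group 7 EL only; group 8 STR only; group 9 anything
#' else (including no induction).
#'
#' @param profile list or one-row data frame with integer scores 0..3 in
#'   elements `EL_control`, `EL_ischemic`, `SEL_control`, `SEL_ischemic`,
#'   `CSVZ_control`, `CSVZ_ischemic`, `STR_control`, `STR_ischemic`.
#' @param min_score,min_delta induction thresholds (defaults 2 and 1).
#' @return Integer group in 1..9.
#' @export
assign_group <- function(profile, min_score = 2, min_delta = 1) {
  rois <- c("EL", "SEL", "CSVZ", "STR")
  need <- c(paste0(rois, "_control"), paste0(rois, "_ischemic"))
  if (!all(need %in% names(profile)))
    stop("incomplete profile; need ", paste(need, collapse = ", "))
  sc <- function(nm) {
    v <- as.numeric(profile[[nm]])
    if (!is.finite(v) || v < 0 || v > 3 || v != round(v))
      stop("score '", nm, "' must be an integer in 0..3")
    v
  }
  induced <- rois[vapply(rois, function(r) {
    i <- sc(paste0(r, "_ischemic")); c0 <- sc(paste0(r, "_control"))
    i >= min_score && (i - c0) >= min_delta
  }, logical(1))]
  for (g in names(GROUP_SETS))
    if (setequal(induced, GROUP_SETS[[g]])) return(as.integer(g))
  9L
}

#' @rdname assign_group
#' @param profiles data frame of score profiles, one gene per row, with a
#'   `gene` column plus the eight score columns.
#' @return `assign_groups()`: the data frame with a `group` column added.
#' @export
assign_groups <- function(profiles, min_score = 2, min_delta = 1) {
  profiles$group <- vapply(seq_len(nrow(profiles)), function(i)
    assign_group(profiles[i, ], min_score, min_delta), integer(1))
  profiles
}
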