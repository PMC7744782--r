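#' Specification of a synthetic colorimetric ISH field
#'
#' Cells are rendered as pale footprints on a bright background; each
#' cell's expression level is drawn from `level_proportions` and its
#' precipitate fill fraction from the level's range. Level 2 and 3
#' precipitate is drawn as a concentric fill of the footprint; level 1 as
#' scattered minute particles. The fill-fraction ranges must be ordered
#' and non-overlapping across levels (level 0 is fixed at zero fill).
#'
#' @param n_cells number of cells.
#' @param level_proportions probabilities over levels 0..3 (sum to 1).
#' @param fill_fraction_ranges named list `"1"`, `"2"`, `"3"` of `(lo, hi)`
#'   fill-fraction ranges per expressing level.
#' @param width_px,height_px field size.
#' @param pixel_size_um pixel size (default 0.501, slide-scanner
#'   resolution).
#' @param cell_radius_um mean footprint radius.
#' @param background_level,footprint_depth,precipitate_depth gray-level
#'   geometry of the rendering (16-bit scale).
#' @param noise_sigma additive Gaussian noise sd.
#' @param roi_geometry optional named list of RoI polygons recorded in the
#'   truth (default: one `SEL` band of 100 x 1500 um anchored at the field
#'   origin).
#' @param seed integer seed.
#' @return Object of class `colorimetric_spec`.
#' @export
colorimetric_spec <- function(n_cells = 200L,
                              level_proportions = c(`0` = 0.25, `1` = 0.25,
                                                    `2` = 0.25, `3` = 0.25),
                              fill_fraction_ranges = list(
                                `1` = c(0.06, 0.24), `2` = c(0.36, 0.72),
                                `3` = c(0.88, 1.0)),
                              width_px = 700L, height_px = 700L,
                              pixel_size_um = 0.501, cell_radius_um = 5,
                              background_level = 58000,
                              footprint_depth = 9000,
                              precipitate_depth = 40000,
                              noise_sigma = 250, roi_geometry = NULL,
                              seed = 1L) {
  if (abs(sum(level_proportions) - 1) > 1e-9)
    stop("level_proportions must sum to 1")
  if (!all(c("1", "2", "3") %in% names(fill_fraction_ranges)))
    stop("fill_fraction_ranges must cover levels 1, 2 and 3")
  r <- fill_fraction_ranges
  for (l in c("1", "2", "3"))
    if (length(r[[l]]) != 2 || r[[l]][1] > r[[l]][2] ||
        r[[l]][1] < 0 || r[[l]][2] > 1)
      stop("invalid fill range for level ", l)
  if (r[["1"]][2] >= r[["2"]][1] || r[["2"]][2] >= r[["3"]][1])
    stop("fill ranges must be ordered and non-overlapping across levels")
  if (r[["1"]][1] <= 0)
    stop("level-1 fill range must be strictly positive")
  structure(list(n_cells = as.integer(n_cells),
                 level_proportions = level_proportions,
                 fill_fraction_ranges = r,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 cell_radius_um = cell_radius_um,
                 background_level = background_level,
                 footprint_depth = footprint_depth,
                 precipitate_depth = precipitate_depth,
                 noise_sigma = noise_sigma,
                 roi_geometry = roi_geometry, seed = as.integer(seed)),
            class = "colorimetric_spec")
}

#' Generate a synthetic colorimetric ISH field with ground truth
#'
#' @param spec a [colorimetric_spec()].
#' @return List with `image` (16-bit-range matrix) and `truth` (per cell:
#'   id, centre, radius, level, drawn fill fraction, realized rendered
#'   fill fraction, roi).
#' @export
generate_colorimetric_field <- function(spec) {
  stopifnot(inherits(spec, "colorimetric_spec"))
  px <- spec$pixel_size_um
  with_seed(spec$seed, {
    r_px <- spec$cell_radius_um / px
    n <- spec$n_cells
    radii <- pmin(pmax(rnorm(n, r_px, 0.12 * r_px), 0.7 * r_px), 1.3 * r_px)
    cells <- place_nuclei(n, radii, spec$width_px, spec$height_px,
                          touching_fraction = 0)
    levels <- if (n > 0)
      sample(0:3, n, replace = TRUE, prob = spec$level_proportions)
    else integer(0)
    fill <- numeric(n)
    for (i in seq_len(n)) {
      if (levels[i] > 0) {
        rg <- spec$fill_fraction_ranges[[as.character(levels[i])]]
        fill[i] <- runif(1, rg[1], rg[2])
      }
    }

    img <- matrix(spec$background_level, spec$height_px, spec$width_px)
    realized <- numeric(n)
    for (i in seq_len(n)) {
      foot <- draw_disk(matrix(0, spec$height_px, spec$width_px),
                        cells$x[i], cells$y[i], cells$r[i], 1) > 0
      img[foot] <- spec$background_level - spec$footprint_depth
      area <- sum(foot)
      prec <- matrix(FALSE, spec$height_px, spec$width_px)
      if (levels[i] >= 2) {
        # concentric fill covering the drawn fraction of the footprint
        pr <- cells$r[i] * sqrt(fill[i])
        prec <- draw_disk(matrix(0, spec$height_px, spec$width_px),
                          cells$x[i], cells$y[i], pr, 1) > 0 & foot
      } else if (levels[i] == 1) {
        # scattered minute particles totalling the drawn fraction
        target <- round(fill[i] * area)
        idx <- which(foot)
        while (sum(prec) < target && length(idx)) {
          ctr <- sample(idx, 1)
          cy <- (ctr - 1) %% spec$height_px + 1
          cx <- (ctr - 1) %/% spec$height_px + 1
          p <- draw_disk(matrix(0, spec$height_px, spec$width_px),
                         cx, cy, 1.2, 1) > 0 & foot
          prec <- prec | p
        }
      }
      img[prec] <- spec$background_level - spec$precipitate_depth
      realized[i] <- if (area > 0) sum(prec) / area else 0
    }
    img <- round(clamp16(img + rnorm(length(img), 0, spec$noise_sigma)))

    roi <- rep("none", n)
    if (!is.null(spec$roi_geometry)) {
      for (nm in names(spec$roi_geometry)) {
        hit <- roi == "none" &
          point_in_polygon(cells$x, cells$y, spec$roi_geometry[[nm]])
        roi[hit] <- nm
      }
    }
    list(image = img,
         truth = data.frame(id = cells$id, x = cells$x, y = cells$y,
                            radius_px = cells$r, level = levels,
                            fill_fraction = fill,
                            realized_fill = realized, roi = roi,
                            stringsAsFactors = FALSE))
  })
}
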