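#' Segment nuclei from a top-hat-filtered DAPI image
#'
#' Foreground is taken by Li's minimum cross-entropy threshold on the
#' filtered image, holes are filled, touching nuclei are split by a
#' watershed on the smoothed distance transform, and objects smaller than
#' `min_area_um2` are discarded.
#'
#' @param dapi_tophat top-hat-filtered DAPI image (numeric matrix).
#' @param pixel_size_um pixel size in micrometers.
#' @param min_area_um2 minimum nuclear area retained (default 10, removes
#'   sub-nuclear debris).
#' @param smooth_sigma_um Gaussian sigma applied to the distance map before
#'   the watershed (default 1).
#' @param watershed_tolerance minimum depth (in px of distance) separating
#'   two objects (default 0.2).
#' @param threshold optional manual foreground threshold overriding Li.
#' @return Integer label matrix with consecutive labels from 1; an empty
#'   foreground yields an all-zero map with a warning.
#' @export
segment_nuclei <- function(dapi_tophat, pixel_size_um = 0.325,
                           min_area_um2 = 10, smooth_sigma_um = 1,
                           watershed_tolerance = 0.2, threshold = NULL) {
  img <- check_image(dapi_tophat)
  pos <- img[img > 0]
  if (is.null(threshold)) {
    if (length(unique(pos)) < 2) {
      warning("empty foreground: no nuclei detected")
      return(matrix(0L, nrow(img), ncol(img)))
    }
    threshold <- li_threshold(img)
  }
  fg <- img >= threshold
  if (!any(fg)) {
    warning("empty foreground: no nuclei detected")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  fg <- as_img(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  dm <- as_img(EBImage::distmap(fg * 1))
  sig <- smooth_sigma_um / pixel_size_um
  if (sig > 0) dm <- as_img(EBImage::gblur(dm, sigma = sig, boundary = "replicate"))
  dm[!fg] <- 0
  lab <- as_img(EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1))
  storage.mode(lab) <- "integer"
  min_px <- min_area_um2 / pixel_size_um^2
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_px)
  relabel <- integer(max(lab, 1L))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(img), ncol(img))
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  out
}

#' Grow nuclear labels into disjoint cellular masks (restricted dilation)
#'
#' Each nuclear label is dilated outward by up to `max_dilation_um`;
#' growth halts where two labels would meet, so the frontier between
#' neighbouring cells is their equidistant line and cellular masks are
#' pairwise disjoint by construction. Distances are exact Euclidean;
#' equidistant ties are resolved by the geometric order of the nucleus
#' centroids (top-left first), so the result does not depend on how labels
#' are enumerated.
#'
#' @param nuclei integer label matrix of nuclear masks.
#' @param pixel_size_um pixel size in micrometers.
#' @param max_dilation_um maximal outward growth (default 3).
#' @return Integer label matrix of cellular masks; each nuclear label is
#'   contained in its cellular label.
#' @export
restricted_dilation <- function(nuclei, pixel_size_um = 0.325,
                                max_dilation_um = 3) {
  lab <- nuclei
  if (inherits(lab, "Image")) lab <- as_img(lab)
  storage.mode(lab) <- "integer"
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  maxpx <- max_dilation_um / pixel_size_um
  ext <- ceiling(maxpx) + 1L
  nr <- nrow(lab); nc <- ncol(lab)

  # geometric processing order: centroid (row, col), top-left first
  stats <- label_centroids(lab)
  ord <- ids[order(stats$cy, stats$cx)]

  best_d <- matrix(Inf, nr, nc)
  out <- matrix(0L, nr, nc)
  for (id in ord) {
    w <- which(lab == id, arr.ind = TRUE)
    r0 <- max(1L, min(w[, 1]) - ext); r1 <- min(nr, max(w[, 1]) + ext)
    c0 <- max(1L, min(w[, 2]) - ext); c1 <- min(nc, max(w[, 2]) + ext)
    win <- lab[r0:r1, c0:c1]
    bin <- (win != id) * 1
    d <- as_img(EBImage::distmap(bin))  # distance to nearest pixel of id
    cand <- d <= maxpx
    sub_d <- best_d[r0:r1, c0:c1]
    take <- cand & (d < sub_d - 1e-9)
    sub_d[take] <- d[take]
    best_d[r0:r1, c0:c1] <- sub_d
    sub_o <- out[r0:r1, c0:c1]
    sub_o[take] <- id
    out[r0:r1, c0:c1] <- sub_o
  }
  out[lab > 0] <- lab[lab > 0]   # nuclei always belong to their own cell
  out
}

label_centroids <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  nr <- nrow(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  data.frame(id = ids,
             cy = as.numeric(tapply(rows, l, mean)[as.character(ids)]),
             cx = as.numeric(tapply(cols, l, mean)[as.character(ids)]),
             area = as.numeric(table(factor(l, levels = ids))))
}

#' Cellular mask set
#'
#' Couples a nuclear label map with its restricted-dilation cellular label
#' map and the per-cell geometry table.
#'
#' @param nuclei,cells integer label matrices (cellular labels from
#'   [restricted_dilation()]).
#' @param pixel_size_um pixel size in micrometers.
#' @param roi_polygon optional polygon (matrix of x, y pixel coordinates)
#'   recorded with the masks.
#' @return Object of class `cell_mask_set` with the label maps and a table
#'   of cell id, nuclear centroid, nuclear and cellular areas.
#' @export
cell_mask_set <- function(nuclei, cells, pixel_size_um = 0.325,
                          roi_polygon = NULL) {
  storage.mode(nuclei) <- "integer"
  storage.mode(cells) <- "integer"
  stopifnot(all(dim(nuclei) == dim(cells)))
  tab <- if (any(nuclei > 0)) {
    st <- label_centroids(nuclei)
    ca <- tabulate(cells, nbins = max(st$id))
    data.frame(id = st$id, centroid_x = st$cx, centroid_y = st$cy,
               nuclear_area_px = st$area, cellular_area_px = ca[st$id])
  } else {
    data.frame(id = integer(), centroid_x = numeric(), centroid_y = numeric(),
               nuclear_area_px = numeric(), cellular_area_px = numeric())
  }
  structure(list(nuclei = nuclei, cells = cells,
                 pixel_size_um = pixel_size_um, roi_polygon = roi_polygon,
                 table = tab),
            class = "cell_mask_set")
}

#' @export
print.cell_mask_set <- function(x, ...) {
  cat(sprintf("cell_mask_set: %d cells, %d x %d px\n", nrow(x$table),
              nrow(x$nuclei), ncol(x$nuclei)))
  invisible(x)
}

#' Validate the invariants of a cellular mask set
#'
#' Checks that nuclear labels are contained in the matching cellular
#' labels, that every cellular pixel lies within `max_dilation_um` of its
#' nucleus, and that labels are consecutive from 1. Invoked by tests after
#' every segmentation; errors on violation.
#'
#' @param masks a [cell_mask_set()].
#' @param max_dilation_um the dilation bound the cells were built with.
#' @return `TRUE`, invisibly.
#' @export
validate_cell_mask_set <- function(masks, max_dilation_um = 3) {
  stopifnot(inherits(masks, "cell_mask_set"))
  n <- masks$nuclei; cm <- masks$cells
  ids <- sort(unique(n[n > 0]))
  if (length(ids) && !identical(ids, seq_along(ids)))
    stop("labels are not consecutive from 1")
  nz <- n > 0
  if (any(cm[nz] != n[nz]))
    stop("a nuclear label is not contained in its cellular label")
  maxpx <- max_dilation_um / masks$pixel_size_um
  ext <- ceiling(maxpx) + 2L
  nr <- nrow(n); nc <- ncol(n)
  for (id in ids) {
    w <- which(cm == id, arr.ind = TRUE)
    r0 <- max(1L, min(w[, 1]) - ext); r1 <- min(nr, max(w[, 1]) + ext)
    c0 <- max(1L, min(w[, 2]) - ext); c1 <- min(nc, max(w[, 2]) + ext)
    nwin <- n[r0:r1, c0:c1]; cwin <- cm[r0:r1, c0:c1]
    d <- as_img(EBImage::distmap((nwin != id) * 1))
    if (any(d[cwin == id] > maxpx + 1e-6))
      stop("cellular pixel of label ", id, " farther than max dilation")
  }
  invisible(TRUE)
}

#' Restrict a mask set to a region of interest
#'
#' Removes cells whose nuclear centroid lies outside the polygon and
#' re-compacts the labels.
#'
#' @param masks a [cell_mask_set()].
#' @param roi_polygon matrix or data frame with two columns (x, y) in pixel
#'   coordinates, at least 3 vertices.
#' @return A filtered `cell_mask_set`.
#' @export
apply_roi <- function(masks, roi_polygon) {
  stopifnot(inherits(masks, "cell_mask_set"))
  poly <- as.matrix(roi_polygon)
  if (nrow(poly) < 3) stop("RoI polygon needs at least 3 vertices")
  keep <- masks$table$id[point_in_polygon(masks$table$centroid_x,
                                          masks$table$centroid_y, poly)]
  relabel <- integer(max(masks$table$id, 1L))
  relabel[keep] <- seq_along(keep)
  remap <- function(m) {
    out <- matrix(0L, nrow(m), ncol(m))
    nz <- m > 0 & m %in% keep
    out[nz] <- relabel[m[nz]]
    out
  }
  cell_mask_set(remap(masks$nuclei), remap(masks$cells),
                masks$pixel_size_um, roi_polygon = poly)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised ray-casting test used for RoI membership. Points exactly on
#' an edge may fall on either side, as usual for the even-odd rule.
#'
#' @param x,y point coordinates.
#' @param poly two-column matrix of polygon vertices.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}
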