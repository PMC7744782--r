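#' Z-score gate
#'
#' First thresholding step of the two-step channel thresholding: every
#' pixel's gray value is replaced by its Z-score over the whole frame, and
#' pixels with Z <= 1 (i.e. below the mean plus one standard deviation)
#' are set to 0. Surviving pixels retain their original intensities so the
#' subsequent Li threshold operates in intensity units. A constant frame
#' (sd = 0) gates to all zeros.
#'
#' @param image top-hat-filtered channel image.
#' @return Gated image, same dimensions.
#' @export
zscore_gate <- function(image) {
  image <- check_image(image)
  s <- sd(image)
  if (!is.finite(s) || s == 0) return(matrix(0, nrow(image), ncol(image)))
  z <- (image - mean(image)) / s
  image[z <= 1] <- 0
  image
}

#' Li minimum cross-entropy threshold
#'
#' Finds the global threshold minimising Li's cross-entropy criterion
#' between foreground and background means,
#' eta(t) = -sum(v < t) v log mu_b(t) - sum(v >= t) v log mu_f(t)
#' (up to a term independent of t). The minimiser is found exactly over
#' all candidate gray levels via cumulative sums. Zeros produced by the
#' Z-score gate are excluded from the fit by default, since they would
#' otherwise dominate the histogram.
#'
#' @param x image matrix or numeric vector of gray values (must be
#'   non-negative for the cross-entropy criterion).
#' @param exclude_zeros drop zero-valued pixels before fitting (default
#'   TRUE).
#' @return The threshold t; binarisation is `pixel >= t`.
#' @export
li_threshold <- function(x, exclude_zeros = TRUE) {
  v <- as.numeric(x)
  if (exclude_zeros) v <- v[v > 0]
  v <- v[is.finite(v)]
  if (any(v < 0)) stop("Li threshold requires non-negative gray values")
  u <- sort(unique(v))
  if (length(u) < 2)
    stop("need >= 2 distinct positive gray values; supply a manual threshold")
  cnt <- tabulate(match(v, u))
  s <- u * cnt
  cum_n <- cumsum(cnt); cum_s <- cumsum(s)
  N <- cum_n[length(u)]; S <- cum_s[length(u)]
  # candidate thresholds: each unique value u[k], k >= 2 (background = v < t)
  k <- 2:length(u)
  mb <- cum_s[k - 1] / cum_n[k - 1]
  mf <- (S - cum_s[k - 1]) / (N - cum_n[k - 1])
  eta <- -cum_s[k - 1] * log(mb) - (S - cum_s[k - 1]) * log(mf)
  u[k[which.min(eta)]]
}

#' Per-cell thresholded-signal area fraction
#'
#' For each cell, the fraction of its compartment mask (nuclear or
#' cellular) covered by the binarised channel signal.
#'
#' @param masks a [cell_mask_set()].
#' @param binary_signal logical or 0/1 matrix aligned with the masks.
#' @param compartment `"nuclear_mask"` or `"cellular_mask"`; nuclear
#'   antigens are scored in the nuclear mask, cytoplasmic and FISH signal
#'   in the cellular mask.
#' @return Data frame with cell_id, compartment area, positive pixels and
#'   the area fraction `f`; zero-area compartments yield `NA` and are
#'   flagged in `valid`.
#' @export
area_fraction <- function(masks, binary_signal,
                          compartment = c("cellular_mask", "nuclear_mask")) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(masks, "cell_mask_set"))
  lab <- if (compartment == "nuclear_mask") masks$nuclei else masks$cells
  if (!all(dim(binary_signal) == dim(lab)))
    stop("'binary_signal' is not aligned with the masks")
  b <- binary_signal > 0
  ids <- masks$table$id
  nb <- max(ids, 1L)
  tot <- tabulate(lab, nbins = nb)[ids]
  pos <- tabulate(lab[b], nbins = nb)[ids]
  f <- ifelse(tot > 0, pos / tot, NA_real_)
  data.frame(cell_id = ids, area_px = tot, positive_px = pos, f = f,
             valid = tot > 0)
}

#' ROC calibration of the positivity cutoff
#'
#' Chooses, per channel, the area-fraction cutoff maximising Youden's J
#' (sensitivity + specificity - 1) against expert positive/negative labels,
#' searching all midpoints between consecutive distinct area fractions.
#' Ties are broken toward the smallest cutoff. Cells at exactly the cutoff
#' are called positive (`f >= c`).
#'
#' @param f numeric area fractions of the labelled cells.
#' @param label logical (TRUE = expert-positive) or a vector coercible to
#'   logical via `label == "positive"`.
#' @return List with `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
calibrate_cutoff <- function(f, label) {
  if (!is.logical(label)) label <- label == "positive" | label == TRUE
  ok <- is.finite(f) & !is.na(label)
  f <- f[ok]; label <- label[ok]
  if (length(unique(label)) < 2)
    stop("calibration needs both positive and negative expert labels")
  u <- sort(unique(f))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  cand <- c(min(u), cand)  # allow calling everything positive
  npos <- sum(label); nneg <- sum(!label)
  stats <- vapply(cand, function(c0) {
    call <- f >= c0
    sens <- sum(call & label) / npos
    spec <- sum(!call & !label) / nneg
    c(sens + spec - 1, sens, spec)
  }, numeric(3))
  best <- max(stats[1, ])
  i <- which(stats[1, ] >= best - 1e-12)[1]  # smallest cutoff among ties
  list(cutoff = cand[i], J = stats[1, i], sensitivity = stats[2, i],
       specificity = stats[3, i])
}

#' @rdname calibrate_cutoff
#' @param fractions data frame with columns `channel_name`, `f`, `label`.
#' @return `calibrate_cutoffs()`: named list of per-channel calibrations.
#' @export
calibrate_cutoffs <- function(fractions) {
  stopifnot(all(c("channel_name", "f", "label") %in% names(fractions)))
  out <- lapply(split(fractions, fractions$channel_name),
                function(d) calibrate_cutoff(d$f, d$label))
  out
}

#' Classify cells as marker-positive or negative
#'
#' The decision rule is a single area-fraction cutoff per channel:
#' positive iff `f >= cutoff` (boundary counts positive).
#'
#' @param fractions data frame with columns `cell_id`, `channel_name`, `f`
#'   and optionally `valid` (invalid cells get `NA` calls).
#' @param cutoffs named numeric vector of per-channel cutoffs.
#' @return A marker call table: one row per cell x channel with the area
#'   fraction and the call (`"positive"`/`"negative"`, `NA` if invalid).
#' @export
classify_cells <- function(fractions, cutoffs) {
  stopifnot(all(c("cell_id", "channel_name", "f") %in% names(fractions)))
  miss <- setdiff(unique(fractions$channel_name), names(cutoffs))
  if (length(miss))
    stop("missing cutoff for channel(s): ", paste(miss, collapse = ", "))
  valid <- if ("valid" %in% names(fractions)) fractions$valid else
    !is.na(fractions$f)
  cut <- unlist(cutoffs)[fractions$channel_name]
  call <- ifelse(valid & !is.na(fractions$f),
                 ifelse(fractions$f >= cut, "positive", "negative"),
                 NA_character_)
  data.frame(cell_id = fractions$cell_id,
             channel_name = fractions$channel_name,
             f = fractions$f, cutoff = unname(cut), call = call,
             stringsAsFactors = FALSE)
}

#' Co-expression matrix from marker calls
#'
#' Computes, over all valid cells, the marginal percentage of cells
#' positive for each marker and the conditional matrix M\[a, b\] =
#' percentage of a-positive cells that are b-positive (diagonal 100).
#' Cells with any invalid call are excluded from numerator and
#' denominator. Rows conditioned on a marker with zero positive cells are
#' reported as `NA` (undefined), not 0.
#'
#' @param calls a marker call table from [classify_cells()], or a logical
#'   cell x marker matrix of positivity (the ground-truth pass-through).
#' @return Object of class `coexpression_matrix` with `markers`,
#'   `n_cells`, per-marker `counts`, `marginal_pct` and the conditional
#'   `matrix` in percent.
#' @export
coexpression_matrix <- function(calls) {
  status <- if (is.matrix(calls)) {
    storage.mode(calls) <- "logical"
    calls[complete.cases(calls), , drop = FALSE]
  } else {
    wide <- tapply(calls$call == "positive",
                   list(calls$cell_id, calls$channel_name), identity)
    wide[complete.cases(wide), , drop = FALSE]
  }
  if (nrow(status) < 1) stop("no valid cells")
  markers <- colnames(status)
  n <- nrow(status)
  counts <- colSums(status)
  M <- matrix(NA_real_, length(markers), length(markers),
              dimnames = list(markers, markers))
  for (a in markers) {
    if (counts[a] == 0) next
    for (b in markers)
      M[a, b] <- 100 * sum(status[, a] & status[, b]) / counts[a]
  }
  structure(list(markers = markers, n_cells = n, counts = counts,
                 marginal_pct = 100 * counts / n, matrix = M),
            class = "coexpression_matrix")
}

#' @export
print.coexpression_matrix <- function(x, digits = 1, ...) {
  cat(sprintf("co-expression over %d cells\n", x$n_cells))
  cat("marginal %:\n")
  print(round(x$marginal_pct, digits))
  cat("P(column + | row +) in %:\n")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Default compartment for each channel class
#'
#' Nuclear antigens (and DAPI) are scored in the nuclear mask; cytoplasmic
#' antigens and FISH signal in the full cellular mask.
#'
#' @param channel_class channel class string.
#' @return `"nuclear_mask"` or `"cellular_mask"`.
#' @export
default_compartment <- function(channel_class) {
  ifelse(channel_class %in% c("DAPI", "nuclear_antigen"),
         "nuclear_mask", "cellular_mask")
}
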