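#' Write a channel stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' One TIFF page per channel (z-stacks are flattened page-by-page with the
#' slice count recorded in the sidecar). The sidecar stores channel names,
#' classes, pixel size and any extra metadata (e.g. the generator seed and
#' spec echo).
#'
#' @param stack a [channel_stack()].
#' @param tiff_file,json_file output paths.
#' @param extra named list merged into the sidecar.
#' @export
write_channel_stack <- function(stack, tiff_file,
                                json_file = sub("\\.tiff?$", ".json", tiff_file),
                                extra = list()) {
  stopifnot(inherits(stack, "channel_stack"))
  pages <- list()
  slices <- integer(0)
  for (nm in names(stack$images)) {
    img <- stack$images[[nm]]
    if (length(dim(img)) == 3) {
      slices[nm] <- dim(img)[3]
      for (z in seq_len(dim(img)[3]))
        pages[[length(pages) + 1]] <- clamp16(img[, , z]) / 65535
    } else {
      slices[nm] <- 1L
      pages[[length(pages) + 1]] <- clamp16(img) / 65535
    }
  }
  tiff::writeTIFF(pages, tiff_file, bits.per.sample = 16L)
  meta <- c(list(channels = names(stack$images),
                 classes = unname(stack$classes),
                 n_slices = unname(slices),
                 pixel_size_um = stack$pixel_size_um,
                 z_step_um = stack$z_step_um), extra)
  jsonlite::write_json(meta, json_file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(tiff_file)
}

#' @rdname write_channel_stack
#' @return `read_channel_stack()`: the reconstructed [channel_stack()],
#'   with the sidecar attached as attribute `"sidecar"`.
#' @export
read_channel_stack <- function(tiff_file,
                               json_file = sub("\\.tiff?$", ".json", tiff_file)) {
  meta <- jsonlite::read_json(json_file, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_file, all = TRUE)
  pages <- lapply(pages, function(p) round(p * 65535))
  images <- list()
  at <- 1L
  for (i in seq_along(meta$channels)) {
    ns <- meta$n_slices[i]
    images[[meta$channels[i]]] <- if (ns > 1)
      array(unlist(pages[at:(at + ns - 1)]),
            c(dim(pages[[at]]), ns)) else pages[[at]]
    at <- at + ns
  }
  st <- channel_stack(images, setNames(meta$classes, meta$channels),
                      pixel_size_um = meta$pixel_size_um,
                      z_step_um = meta$z_step_um %||% NA_real_)
  attr(st, "sidecar") <- meta
  st
}

#' Write per-cell ground truth (or any cell table) as CSV and JSON
#'
#' @param truth data frame, one row per cell.
#' @param csv_file,json_file output paths (either may be `NULL`).
#' @export
write_cell_table <- function(truth, csv_file = NULL, json_file = NULL) {
  if (!is.null(csv_file))
    utils::write.csv(truth, csv_file, row.names = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(truth, json_file, digits = NA)
  invisible(truth)
}

#' Write / read per-channel cutoffs as YAML
#'
#' @param cutoffs named list (or vector) of per-channel cutoffs.
#' @param file path to the YAML file.
#' @export
write_cutoffs <- function(cutoffs, file) {
  yaml::write_yaml(as.list(cutoffs), file)
  invisible(file)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(file) {
  unlist(yaml::read_yaml(file))
}

#' Write / read an RoI polygon set as JSON
#'
#' @param rois named list of two-column (x, y) vertex matrices.
#' @param file path to the JSON file.
#' @export
write_rois <- function(rois, file) {
  jsonlite::write_json(lapply(rois, function(p)
    list(x = as.numeric(p[, 1]), y = as.numeric(p[, 2]))),
    file, digits = NA)
  invisible(file)
}

#' @rdname write_rois
#' @export
read_rois <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  lapply(raw, function(p) cbind(x = p$x, y = p$y))
}
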