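#' Specification of a synthetic fluorescence field
#'
#' Describes a simulated microscope field of the subependymal layer:
#' DAPI-stained nuclei (round, optionally touching), per-cell marker status
#' drawn from a co-expression table, marker signal rendered in the
#' compartment appropriate to each channel class, uneven background and
#' additive noise. Defaults emulate a 40x field at 0.325 um/px with a
#' realistic SEL cell density; nucleus size statistics are configuration
#' values, not constants of the workflow.
#'
#' @param width_px,height_px field size in pixels.
#' @param pixel_size_um micrometers per pixel (default 0.325).
#' @param n_cells number of cells.
#' @param mean_nucleus_radius_um,sd_nucleus_radius_um nucleus radius
#'   distribution (truncated normal).
#' @param touching_fraction fraction of nuclei placed adjacent to another
#'   nucleus.
#' @param channel_panel data frame with columns `name` and `class`; exactly
#'   one `DAPI` channel.
#' @param coexpression_table named probabilities over marker combinations;
#'   names are `"+"`-joined subsets of the non-DAPI channel names (`"none"`
#'   for the empty combination); must sum to 1.
#' @param signal_model named list (per non-DAPI channel, plus optionally
#'   `DAPI`) of lists with `amplitude` (gray levels), `blur_sigma_um`, and
#'   `puncta_density` (expected puncta per positive cell, FISH channels).
#' @param background_model list with `gradient_amplitude` (gray levels,
#'   corner-to-corner plane), `dark_blotch_density` and
#'   `bright_blob_density` (count per 100x100 um), `blotch_sigma_um`,
#'   `blotch_amplitude`.
#' @param noise_sigma additive Gaussian noise sd in gray levels.
#' @param texture_contrast relative sd of the within-cell stain texture
#'   (chromatin granularity, cytoskeletal filaments); 0 renders flat
#'   stains.
#' @param texture_scale_um correlation length of the texture.
#' @param baseline constant background offset in gray levels.
#' @param annulus_um cytoplasmic annulus width around the nucleus.
#' @param n_z_slices 1 for direct 2-D generation (default); 3-7 to produce
#'   a thin z-stack with one in-focus slice, for exercising projection.
#' @param seed integer seed; generation is bitwise deterministic given the
#'   spec and seed.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(width_px = 768L, height_px = 768L,
                       pixel_size_um = 0.325, n_cells = 500L,
                       mean_nucleus_radius_um = 3, sd_nucleus_radius_um = 0.35,
                       touching_fraction = 0.1,
                       channel_panel = data.frame(
                         name = c("DAPI", "APLNR", "GFAP"),
                         class = c("DAPI", "fish_cytoplasmic",
                                   "cytoplasmic_antigen")),
                       coexpression_table = c("APLNR+GFAP" = 0.45,
                                              "APLNR" = 0.15, "GFAP" = 0.09,
                                              "none" = 0.31),
                       signal_model = NULL,
                       background_model = list(gradient_amplitude = 600,
                                               dark_blotch_density = 0.4,
                                               bright_blob_density = 0.25,
                                               blotch_sigma_um = 12,
                                               blotch_amplitude = 500),
                       noise_sigma = 120, texture_contrast = 0.45,
                       texture_scale_um = 0.8, baseline = 900,
                       annulus_um = 3, n_z_slices = 1L, seed = 1L) {
  stopifnot(is.data.frame(channel_panel),
            all(c("name", "class") %in% names(channel_panel)))
  panel <- data.frame(name = as.character(channel_panel$name),
                      class = as.character(channel_panel$class),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(panel$name)) stop("every channel_name must be unique")
  if (!all(panel$class %in% CHANNEL_CLASSES))
    stop("unknown channel class in panel")
  if (sum(panel$class == "DAPI") != 1)
    stop("exactly one DAPI channel required")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be > 0")
  if (touching_fraction < 0 || touching_fraction > 1)
    stop("'touching_fraction' must be in [0, 1]")
  if (abs(sum(coexpression_table) - 1) > 1e-9)
    stop("coexpression_table probabilities must sum to 1")
  markers <- setdiff(panel$name, panel$name[panel$class == "DAPI"])
  for (combo in names(coexpression_table)) {
    members <- combo_members(combo)
    if (!all(members %in% markers))
      stop("coexpression_table entry '", combo,
           "' names channels outside the panel")
  }
  if (is.null(signal_model)) {
    signal_model <- lapply(seq_len(nrow(panel)), function(i) {
      switch(panel$class[i],
             DAPI = list(amplitude = 6000, blur_sigma_um = 0.4),
             nuclear_antigen = list(amplitude = 7000, blur_sigma_um = 0.4),
             cytoplasmic_antigen = list(amplitude = 5000, blur_sigma_um = 0.5),
             fish_cytoplasmic = list(amplitude = 12000, blur_sigma_um = 0.35,
                                     puncta_density = 14))
    })
    names(signal_model) <- panel$name
  }
  if (!(n_z_slices == 1 || (n_z_slices >= 3 && n_z_slices <= 7)))
    stop("'n_z_slices' must be 1 or between 3 and 7")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 mean_nucleus_radius_um = mean_nucleus_radius_um,
                 sd_nucleus_radius_um = sd_nucleus_radius_um,
                 touching_fraction = touching_fraction,
                 channel_panel = panel,
                 coexpression_table = coexpression_table,
                 signal_model = signal_model,
                 background_model = background_model,
                 noise_sigma = noise_sigma,
                 texture_contrast = texture_contrast,
                 texture_scale_um = texture_scale_um, baseline = baseline,
                 annulus_um = annulus_um,
                 n_z_slices = as.integer(n_z_slices),
                 seed = as.integer(seed)),
            class = "field_spec")
}

combo_members <- function(combo) {
  if (identical(combo, "none")) character(0) else strsplit(combo, "+", fixed = TRUE)[[1]]
}

#' Field specification for the SEL reference marker panel
#'
#' Convenience constructor of a [field_spec()] carrying the reference
#' co-expression structure of the subependymal layer: the APLNR FISH
#' channel with the GFAP, VIM and GLUT1 immunofluorescence channels, with
#' P(APLNR+) = 0.60 and the conditional positivities P(GFAP+ | APLNR+) =
#' 0.75, P(VIM+ | APLNR+) = 0.41 and P(GLUT1+ | APLNR+) = 0.15; the
#' APLNR-negative conditionals are set so the GFAP marginal is 0.54 and
#' nearly every GLUT1+ (endothelial) cell is APLNR+ (98%). The three
#' antibody markers are conditionally independent given APLNR status.
#'
#' @param n_cells,seed,... passed to [field_spec()].
#' @return A `field_spec`.
#' @export
sel_reference_field_spec <- function(n_cells = 500L, seed = 1L, ...) {
  p_a <- 0.60
  cond_pos <- c(GFAP = 0.75, VIM = 0.41, GLUT1 = 0.15)
  cond_neg <- c(GFAP = (0.54 - p_a * 0.75) / (1 - p_a),
                VIM = 0.10875, GLUT1 = 0.003)
  markers <- names(cond_pos)
  tab <- c()
  for (a in c(TRUE, FALSE)) {
    pc <- if (a) cond_pos else cond_neg
    for (i in 0:(2^3 - 1)) {
      on <- as.logical(bitwAnd(i, 2^(0:2)))
      p <- (if (a) p_a else 1 - p_a) *
        prod(ifelse(on, pc, 1 - pc))
      members <- c(if (a) "APLNR", markers[on])
      nm <- if (length(members)) paste(members, collapse = "+") else "none"
      tab[nm] <- p
    }
  }
  field_spec(n_cells = n_cells, seed = seed,
             channel_panel = data.frame(
               name = c("DAPI", "APLNR", "GFAP", "VIM", "GLUT1"),
               class = c("DAPI", "fish_cytoplasmic", "cytoplasmic_antigen",
                         "cytoplasmic_antigen", "cytoplasmic_antigen")),
             coexpression_table = tab, ...)
}

# Random sequential placement of nuclei. Non-touching nuclei keep an edge
# gap of >= 2 px from every other nucleus; touching nuclei are placed with
# edges adjacent to a randomly chosen earlier nucleus.
place_nuclei <- function(n, radii, width, height, touching_fraction,
                         max_tries = 200L) {
  if (n == 0)
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      r = numeric(), touching = logical()))
  gap <- 2
  x <- y <- numeric(n)
  n_touch <- round(touching_fraction * n)
  touching <- rep(FALSE, n)
  if (n_touch > 0 && n >= 2)
    touching[sample(2:n, min(n_touch, n - 1))] <- TRUE
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (touching[i]) {
        j <- sample.int(i - 1L, 1L)
        ang <- runif(1, 0, 2 * pi)
        d <- radii[i] + radii[j]
        xi <- x[j] + d * cos(ang); yi <- y[j] + d * sin(ang)
        others <- setdiff(seq_len(i - 1L), j)
      } else {
        xi <- runif(1, radii[i] + 1, width - radii[i])
        yi <- runif(1, radii[i] + 1, height - radii[i])
        others <- seq_len(i - 1L)
      }
      if (xi < radii[i] + 1 || xi > width - radii[i] ||
          yi < radii[i] + 1 || yi > height - radii[i]) next
      ok <- TRUE
      if (length(others)) {
        dd <- sqrt((x[others] - xi)^2 + (y[others] - yi)^2)
        ok <- all(dd >= radii[others] + radii[i] + gap)
      }
      if (ok) { x[i] <- xi; y[i] <- yi; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place cell ", i, " of ", n,
           ": 'n_cells' is unachievable at this density within ",
           max_tries, " placement retries; reduce 'n_cells' or enlarge the field")
  }
  data.frame(id = seq_len(n), x = x, y = y, r = radii, touching = touching)
}

render_background <- function(spec) {
  w <- spec$width_px; h <- spec$height_px
  bm <- spec$background_model
  px <- spec$pixel_size_um
  xg <- matrix(rep(seq_len(w) / w, each = h), h, w)
  yg <- matrix(rep(seq_len(h) / h, w), h, w)
  bg <- spec$baseline + bm$gradient_amplitude * (xg + yg) / 2
  area_units <- (w * px / 100) * (h * px / 100)   # in 100x100 um tiles
  sig_px <- bm$blotch_sigma_um / px
  add_bumps <- function(bg, k, sign) {
    for (i in seq_len(k)) {
      cx <- runif(1, 1, w); cy <- runif(1, 1, h)
      amp <- sign * bm$blotch_amplitude * runif(1, 0.5, 1)
      ext <- ceiling(3 * sig_px)
      rows <- max(1, floor(cy - ext)):min(h, ceiling(cy + ext))
      cols <- max(1, floor(cx - ext)):min(w, ceiling(cx + ext))
      g <- exp(-(outer((rows - cy)^2, (cols - cx)^2, "+")) / (2 * sig_px^2))
      bg[rows, cols] <- bg[rows, cols] + amp * g
    }
    bg
  }
  bg <- add_bumps(bg, rpois(1, bm$dark_blotch_density * area_units), -1)
  bg <- add_bumps(bg, rpois(1, bm$bright_blob_density * area_units), +1)
  bg
}

#' Generate a synthetic fluorescence field with ground truth
#'
#' Places nuclei, draws each cell's marker combination from the
#' co-expression table, and renders one image per channel: DAPI in every
#' nucleus, nuclear antigens inside the nuclei of positive cells,
#' cytoplasmic antigens filling the cell's cytoplasmic territory (an
#' annulus of `annulus_um` around the nucleus, clipped against neighbours
#' so cytoplasm does not interpenetrate), and FISH channels as blurred
#' puncta in that territory. Background structure and Gaussian noise are
#' added and images are clipped and rounded to the 16-bit range.
#'
#' @param spec a [field_spec()].
#' @return A list with `stack` (a [channel_stack()]), `truth` (one row per
#'   cell: id, centre, nucleus radius, and one logical column per marker),
#'   `nuclei` (ground-truth nucleus label map) and `territory` (ground-truth
#'   cellular label map).
#' @export
generate_fluorescence_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  px <- spec$pixel_size_um
  panel <- spec$channel_panel
  markers <- setdiff(panel$name, panel$name[panel$class == "DAPI"])
  with_seed(spec$seed, {
    r_mean <- spec$mean_nucleus_radius_um / px
    r_sd <- spec$sd_nucleus_radius_um / px
    radii <- rnorm(spec$n_cells, r_mean, r_sd)
    radii <- pmin(pmax(radii, 0.5 * r_mean), 1.5 * r_mean)
    cells <- place_nuclei(spec$n_cells, radii, spec$width_px, spec$height_px,
                          spec$touching_fraction)
    status <- matrix(FALSE, spec$n_cells, length(markers),
                     dimnames = list(NULL, markers))
    if (spec$n_cells > 0) {
      combos <- sample(names(spec$coexpression_table), spec$n_cells,
                       replace = TRUE, prob = spec$coexpression_table)
      for (m in markers)
        status[, m] <- vapply(combos, function(cb) m %in% combo_members(cb),
                              logical(1))
    }

    nuclei <- matrix(0L, spec$height_px, spec$width_px)
    for (i in seq_len(nrow(cells))) {
      w <- disk_window(spec$height_px, spec$width_px,
                       cells$x[i], cells$y[i], cells$r[i])
      nuclei[w] <- i
    }
    territory <- if (spec$n_cells > 0)
      restricted_dilation(nuclei, px, spec$annulus_um) else nuclei
    # per-cell pixel index lists (fast painting)
    n_lev <- factor(nuclei[nuclei > 0], levels = seq_len(spec$n_cells))
    nuc_idx <- split(which(nuclei > 0), n_lev)
    cyt <- territory > 0 & nuclei == 0
    c_lev <- factor(territory[cyt], levels = seq_len(spec$n_cells))
    cyt_idx <- split(which(cyt), c_lev)

    channels <- list()
    for (k in seq_len(nrow(panel))) {
      nm <- panel$name[k]; cl <- panel$class[k]
      sm <- spec$signal_model[[nm]]
      img <- matrix(0, spec$height_px, spec$width_px)
      if (spec$n_cells > 0) {
        # stained structures are textured (chromatin, filaments), not flat;
        # the texture is spatially correlated so it survives the optical
        # blur instead of averaging out
        tex <- matrix(1, spec$height_px, spec$width_px)
        if (spec$texture_contrast > 0) {
          z <- matrix(rnorm(spec$height_px * spec$width_px),
                      spec$height_px, spec$width_px)
          z <- as_img(EBImage::gblur(z, sigma = spec$texture_scale_um / px, boundary = "replicate"))
          z <- (z - mean(z)) / sd(z)
          tex <- pmax(1 + spec$texture_contrast * z, 0.15)
        }
        if (cl == "DAPI") {
          amp <- sm$amplitude * runif(spec$n_cells, 0.8, 1.2)
          for (i in seq_len(nrow(cells)))
            img[nuc_idx[[i]]] <- amp[i] * tex[nuc_idx[[i]]]
        } else if (cl == "nuclear_antigen") {
          amp <- sm$amplitude * runif(spec$n_cells, 0.8, 1.2)
          for (i in which(status[, nm]))
            img[nuc_idx[[i]]] <- amp[i] * tex[nuc_idx[[i]]]
        } else if (cl == "cytoplasmic_antigen") {
          amp <- sm$amplitude * runif(spec$n_cells, 0.8, 1.2)
          for (i in which(status[, nm]))
            img[cyt_idx[[i]]] <- amp[i] * tex[cyt_idx[[i]]]
        } else { # fish_cytoplasmic
          for (i in which(status[, nm])) {
            zone <- cyt_idx[[i]]
            if (!length(zone)) zone <- nuc_idx[[i]]
            np <- max(3L, rpois(1, sm$puncta_density))
            at <- sample(zone, min(np, length(zone)),
                         replace = np > length(zone))
            img[at] <- img[at] + sm$amplitude
          }
        }
        sig_px <- sm$blur_sigma_um / px
        if (sig_px > 0)
          img <- as_img(EBImage::gblur(img, sigma = sig_px, boundary = "replicate"))
      }
      img <- img + render_background(spec)
      img <- img + rnorm(length(img), 0, spec$noise_sigma)
      img <- round(clamp16(img))
      if (spec$n_z_slices > 1) {
        focus <- sample.int(spec$n_z_slices, 1)
        st <- array(0, c(spec$height_px, spec$width_px, spec$n_z_slices))
        for (z in seq_len(spec$n_z_slices)) {
          defocus <- abs(z - focus)
          sl <- if (defocus == 0) img else
            as_img(EBImage::gblur(img, sigma = 2 * defocus, boundary = "replicate")) +
              rnorm(length(img), 0, spec$noise_sigma / 4)
          st[, , z] <- round(clamp16(sl))
        }
        channels[[nm]] <- st
      } else channels[[nm]] <- img
    }

    truth <- cbind(data.frame(id = cells$id, x = cells$x, y = cells$y,
                              nucleus_radius_px = cells$r,
                              touching = cells$touching),
                   as.data.frame(status))
    list(stack = channel_stack(channels,
                               setNames(panel$class, panel$name),
                               pixel_size_um = px),
         truth = truth, nuclei = nuclei, territory = territory)
  })
}
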