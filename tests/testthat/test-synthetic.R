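test_that("field_spec validates its invariants", {
  expect_error(field_spec(coexpression_table = c(APLNR = 0.5)), "sum to 1")
  expect_error(field_spec(channel_panel = data.frame(
    name = c("DAPI", "DAPI"), class = c("DAPI", "fish_cytoplasmic"))),
    "unique")
  expect_error(field_spec(channel_panel = data.frame(
    name = c("A", "B"), class = c("DAPI", "DAPI"))), "exactly one DAPI")
  expect_error(field_spec(pixel_size_um = -1), "> 0")
  expect_error(field_spec(touching_fraction = 1.2), "touching_fraction")
  expect_error(field_spec(coexpression_table = c(FOO = 1)), "outside the panel")
})

test_that("empty and degenerate fields", {
  sp0 <- field_spec(n_cells = 0, width_px = 96, height_px = 96, seed = 1)
  fl0 <- generate_fluorescence_field(sp0)
  expect_equal(nrow(fl0$truth), 0)
  expect_equal(length(fl0$stack$images), 3)
  expect_true(all(fl0$nuclei == 0))

  sp1 <- field_spec(n_cells = 25, width_px = 192, height_px = 192, seed = 2,
                    coexpression_table = c("APLNR+GFAP" = 1))
  fl1 <- generate_fluorescence_field(sp1)
  expect_true(all(fl1$truth$APLNR) && all(fl1$truth$GFAP))
})

test_that("generation is bitwise deterministic given the seed", {
  sp <- field_spec(n_cells = 40, width_px = 224, height_px = 224, seed = 77)
  expect_identical(generate_fluorescence_field(sp),
                   generate_fluorescence_field(sp))
  sp2 <- field_spec(n_cells = 40, width_px = 224, height_px = 224, seed = 78)
  expect_false(identical(generate_fluorescence_field(sp)$stack,
                         generate_fluorescence_field(sp2)$stack))
})

test_that("realized marker fractions match the co-expression marginals", {
  # ~2000 cells pooled over four fields; binomial 99.9% CI around P = 0.60
  status <- unlist(lapply(1:4, function(s) {
    sp <- field_spec(n_cells = 500, seed = 300 + s)
    generate_fluorescence_field(sp)$truth$APLNR
  }))
  n <- length(status)
  expect_equal(n, 2000)
  p <- mean(status)
  expect_lt(abs(p - 0.60), 3.3 * sqrt(0.6 * 0.4 / n))
})

test_that("marker signal stays within the annulus of positive cells", {
  sp <- field_spec(n_cells = 30, width_px = 224, height_px = 224, seed = 5,
                   noise_sigma = 0, baseline = 100,
                   background_model = list(gradient_amplitude = 0,
                                           dark_blotch_density = 0,
                                           bright_blob_density = 0,
                                           blotch_sigma_um = 10,
                                           blotch_amplitude = 0))
  fl <- generate_fluorescence_field(sp)
  for (m in c("APLNR", "GFAP")) {
    img <- fl$stack$images[[m]]
    pos <- fl$truth$id[fl$truth[[m]]]
    allowed <- matrix(FALSE, 224, 224)
    if (length(pos)) {
      terr <- matrix(fl$territory %in% pos, 224, 224)
      # blur tails extend a few sigma beyond the territory edge
      blur_px <- sp$signal_model[[m]]$blur_sigma_um / sp$pixel_size_um
      d <- svzquant:::as_img(EBImage::distmap(1 - terr * 1))
      allowed <- d <= 4 * blur_px + 1
    }
    expect_true(all(img[!allowed] <= 100 + 2))
  }
})

test_that("placement fails loudly when the density is unachievable", {
  sp <- field_spec(n_cells = 400, width_px = 96, height_px = 96, seed = 1)
  expect_error(generate_fluorescence_field(sp), "n_cells")
})

test_that("colorimetric spec validation and trivial fields", {
  expect_error(colorimetric_spec(level_proportions = c(`0` = 0.5, `1` = 0.2,
                                                       `2` = 0.2, `3` = 0.2)),
               "sum to 1")
  expect_error(colorimetric_spec(fill_fraction_ranges = list(
    `1` = c(0.05, 0.4), `2` = c(0.3, 0.7), `3` = c(0.85, 1))),
    "non-overlapping")
  sp0 <- colorimetric_spec(n_cells = 30, width_px = 256, height_px = 256,
                           level_proportions = c(`0` = 1, `1` = 0, `2` = 0,
                                                 `3` = 0), seed = 4)
  f0 <- generate_colorimetric_field(sp0)
  expect_true(all(f0$truth$level == 0))
  expect_true(all(f0$truth$fill_fraction == 0))
  # no precipitate rendered: darkest pixel is just a footprint
  expect_gt(min(f0$image), sp0$background_level - sp0$footprint_depth - 2000)
})

test_that("colorimetric truth respects the fill ranges and the draw", {
  sp <- colorimetric_spec(n_cells = 120, width_px = 560, height_px = 560,
                          seed = 9)
  fl <- generate_colorimetric_field(sp)
  expect_identical(generate_colorimetric_field(sp)$image, fl$image)
  for (l in 1:3) {
    rg <- sp$fill_fraction_ranges[[as.character(l)]]
    f <- fl$truth$fill_fraction[fl$truth$level == l]
    expect_true(all(f >= rg[1] & f <= rg[2]))
  }
  # the recorded level histogram is the realized multinomial draw
  expect_equal(sort(unique(fl$truth$level)), 0:3)
  expect_equal(nrow(fl$truth), 120)
  # level-3 cells with range (0.95, 1) truly are nearly filled
  sp3 <- colorimetric_spec(n_cells = 10, width_px = 224, height_px = 224,
                           level_proportions = c(`0` = 0, `1` = 0, `2` = 0,
                                                 `3` = 1),
                           fill_fraction_ranges = list(`1` = c(0.05, 0.2),
                                                       `2` = c(0.3, 0.6),
                                                       `3` = c(0.95, 1)),
                           seed = 3)
  f3 <- generate_colorimetric_field(sp3)
  expect_true(all(f3$truth$fill_fraction >= 0.95))
})

test_that("count generator: trivial cases and determinism", {
  expect_error(count_spec(de_fraction = 1.5), "de_fraction")
  expect_error(count_spec(lfc_min = 0.3), "exceed 0.5")
  sp0 <- count_spec(n_genes = 50, de_fraction = 0, seed = 8)
  d0 <- generate_count_matrix(sp0)
  expect_equal(nrow(d0$truth), 0)
  expect_equal(dim(d0$counts), c(50L, 18L))
  expect_identical(generate_count_matrix(sp0)$counts, d0$counts)
  sp1 <- count_spec(n_genes = 50, de_fraction = 0.2, seed = 8)
  d1 <- generate_count_matrix(sp1)
  expect_equal(nrow(d1$truth), 10)
  expect_true(all(abs(d1$truth$log2fc) > 0.5))
  expect_true(all(d1$truth$gene %in% rownames(d1$counts)))
})

test_that("zero dispersion reaches the Poisson limit (variance = mean)", {
  sp <- count_spec(n_genes = 10000, de_fraction = 0, batch_effect_sd = 0,
                   nb_dispersion = 0, library_size_range = c(1e6, 1e6),
                   mean_log2_expr = 7, sd_log2_expr = 0.5, seed = 13)
  d <- generate_count_matrix(sp)
  m <- rowMeans(d$counts)
  v <- apply(d$counts, 1, var)
  keep <- m > 20
  expect_equal(mean(v[keep] / m[keep]), 1, tolerance = 0.02)
})

test_that("count matrices survive the TSV round trip", {
  d <- generate_count_matrix(count_spec(n_genes = 40, seed = 2))
  cf <- tempfile(fileext = ".tsv"); lf <- tempfile(fileext = ".tsv")
  write_count_matrix(d$counts, d$gene_lengths, cf, lf)
  back <- read_count_matrix(cf, lf)
  expect_identical(back$counts, d$counts)
  expect_equal(back$gene_lengths, d$gene_lengths)
  expect_equal(back$meta$condition, d$meta$condition)
  expect_equal(back$meta$fragment, d$meta$fragment)
})
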