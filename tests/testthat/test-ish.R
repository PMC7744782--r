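test_that("grading bins follow the level definitions", {
  expect_equal(grade_cell(0), 0L)
  expect_equal(grade_cell(1), 3L)     # filled with precipitate
  expect_equal(grade_cell(0.5), 2L)   # partially filled
  expect_equal(grade_cell(0.1), 1L)   # scattered particles
  expect_equal(grade_cell(c(0.3, 0.8)), c(2L, 3L))  # bin edges inclusive up
  expect_error(grade_cell(1.2), "\\[0, 1\\]")
  expect_error(grade_cell(-0.1), "\\[0, 1\\]")
  # monotone in f
  f <- seq(0, 1, by = 0.01)
  expect_true(all(diff(grade_cell(f)) >= 0))
})

test_that("detection grades a mixed field against its truth", {
  sp <- colorimetric_spec(n_cells = 80, width_px = 460, height_px = 460,
                          seed = 19)
  fl <- generate_colorimetric_field(sp)
  det <- detect_colorimetric_cells(fl$image)
  expect_gt(nrow(det), 70)
  mm <- match_cells(det, fl$truth, max_dist_px = 8)
  agree <- mean(det$level[match(mm$detected_id, det$id)] ==
                  fl$truth$level[match(mm$truth_id, fl$truth$id)])
  expect_gte(agree, 0.95)
  # blank image -> empty set
  blank <- matrix(58000, 128, 128)
  expect_equal(nrow(detect_colorimetric_cells(blank)), 0)
})

test_that("a fully filled cell grades level 3 through detection", {
  sp <- colorimetric_spec(n_cells = 1, width_px = 96, height_px = 96,
                          level_proportions = c(`0` = 0, `1` = 0, `2` = 0,
                                                `3` = 1),
                          fill_fraction_ranges = list(`1` = c(0.05, 0.2),
                                                      `2` = c(0.3, 0.6),
                                                      `3` = c(0.99, 1)),
                          seed = 23)
  fl <- generate_colorimetric_field(sp)
  det <- detect_colorimetric_cells(fl$image)
  expect_equal(nrow(det), 1)
  expect_equal(det$level, 3L)
})

test_that("RoI band geometry converts physical units", {
  poly <- define_roi_band(c(0, 0), c(1, 0), width_um = 100,
                          length_um = 1500, pixel_size_um = 0.325)
  expect_equal(round(max(poly[, 1]) - min(poly[, 1])), 4615)
  expect_equal(round(max(poly[, 2]) - min(poly[, 2])), 308)
  # axis-aligned vertices for direction (0, 1)
  poly2 <- define_roi_band(c(10, 20), c(0, 1), 100, 1500, 0.5)
  expect_equal(sort(unique(round(poly2[, 1]))), c(-90, 110))
  expect_equal(sort(unique(round(poly2[, 2]))), c(20, 3020))
  expect_error(define_roi_band(c(0, 0), c(0, 0)), "zero direction")
  expect_error(define_roi_band(c(0, 0), c(1, 0), length_um = 0),
               "degenerate")
})

test_that("RoI ratios count level 2+3 cells", {
  cells <- data.frame(level = rep(3L, 12), roi = "SEL")
  expect_equal(quantify_roi(cells, "SEL")$ratio, 1)
  cells2 <- data.frame(level = c(rep(2L, 25), rep(3L, 15), rep(1L, 40),
                                 rep(0L, 20)), roi = "SEL")
  q <- quantify_roi(cells2, "SEL")
  expect_equal(q$n_cells, 100)
  expect_equal(q$n_level23, 40)
  expect_equal(q$ratio, 0.4)
  empty <- quantify_roi(cells2, "CSVZ")
  expect_false(empty$defined)
  expect_true(is.na(empty$ratio))
})

test_that("fold change is the ratio of RoI ratios", {
  qa <- quantify_roi(data.frame(level = c(2, 2, 3, 0, 1), roi = "SEL"), "SEL")
  qb <- quantify_roi(data.frame(level = c(2, 3, 3, 0, 1), roi = "SEL"), "SEL")
  expect_equal(fold_change(qb, qa)$fold, 1)
  isch <- quantify_roi(data.frame(level = rep(c(3, 0), c(6, 4)), roi = "X"), "X")
  ctrl <- quantify_roi(data.frame(level = rep(c(3, 0), c(2, 8)), roi = "X"), "X")
  expect_equal(fold_change(isch, ctrl)$fold, 3)
  zero <- quantify_roi(data.frame(level = rep(0L, 5), roi = "X"), "X")
  fc <- fold_change(isch, zero)
  expect_true(fc$induced_from_zero)
  expect_true(is.na(fc$fold))
  expect_error(fold_change(isch, quantify_roi(data.frame(level = integer(),
                                                         roi = character()),
                                              "X")), "defined")
})

test_that("group assignment covers the caption rules", {
  prof <- function(...) {
    p <- list(EL_control = 0, EL_ischemic = 0, SEL_control = 0,
              SEL_ischemic = 0, CSVZ_control = 0, CSVZ_ischemic = 0,
              STR_control = 0, STR_ischemic = 0)
    modifyList(p, list(...))
  }
  induced_all <- prof(EL_ischemic = 3, SEL_ischemic = 3, CSVZ_ischemic = 2,
                      STR_ischemic = 2)
  expect_equal(assign_group(induced_all), 1L)
  expect_equal(assign_group(prof(EL_ischemic = 2)), 7L)
  expect_equal(assign_group(prof()), 9L)
  expect_equal(assign_group(prof(STR_ischemic = 3)), 8L)
  # ischemic high but control equally high: not induced
  expect_equal(assign_group(prof(EL_control = 3, EL_ischemic = 3)), 9L)
  expect_error(assign_group(list(EL_control = 1)), "incomplete")
  expect_error(assign_group(prof(EL_ischemic = 5)), "0..3")
})

test_that("group assignment is total over all score profiles", {
  set.seed(71)
  for (i in 1:60) {
    p <- as.list(setNames(sample(0:3, 8, TRUE),
                          c("EL_control", "EL_ischemic", "SEL_control",
                            "SEL_ischemic", "CSVZ_control", "CSVZ_ischemic",
                            "STR_control", "STR_ischemic")))
    g <- assign_group(p)
    expect_true(g %in% 1:9)
  }
})
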