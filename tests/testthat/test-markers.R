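test_that("z-score gate conventions", {
  expect_equal(zscore_gate(matrix(9, 20, 20)), matrix(0, 20, 20))
  img <- matrix(0, 100, 100)
  img[5, 5] <- 1000
  gated <- zscore_gate(img)
  expect_equal(sum(gated > 0), 1)
  expect_equal(gated[5, 5], 1000)  # original intensity retained
})

test_that("z-score gate survival matches the normal tail", {
  set.seed(91)
  img <- matrix(rnorm(600 * 600), 600, 600)
  frac <- mean(zscore_gate(img) != 0)
  p <- pnorm(1, lower.tail = FALSE)
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / length(img)) + 1e-3)
})

test_that("z-score gate is invariant to affine intensity rescaling", {
  set.seed(92)
  img <- matrix(runif(400, 10, 200), 20, 20)
  a <- zscore_gate(img) > 0
  b <- zscore_gate(img * 3.7 + 55) > 0
  expect_identical(a, b)
})

test_that("Li threshold equals the exhaustive criterion minimiser", {
  v <- c(rep(10, 900), rep(200, 100))
  t1 <- li_threshold(v)
  expect_gt(t1, 10); expect_lte(t1, 200)
  expect_equal(t1, li_oracle(v))
  set.seed(14)
  for (i in 1:30) {
    img <- rand_img8(12, 12) + 1
    expect_equal(li_threshold(img), li_oracle(c(img)))
  }
  expect_error(li_threshold(matrix(5, 4, 4)), "distinct positive")
  expect_error(li_threshold(c(-1, 3, 5), exclude_zeros = FALSE),
               "non-negative")
})

test_that("Li threshold separates a well-separated bimodal mixture", {
  set.seed(15)
  truth <- runif(20000) < 0.3
  v <- ifelse(truth, rnorm(20000, 180, 12), rnorm(20000, 40, 12))
  v <- pmax(v, 1)
  t <- li_threshold(v)
  expect_lt(mean((v >= t) != truth), 0.01)
})

test_that("area fractions per compartment", {
  nuc <- matrix(0L, 10, 10); nuc[2:6, 2:6] <- 1L
  cells <- matrix(0L, 10, 10); cells[1:8, 1:8] <- 1L
  masks <- cell_mask_set(nuc, cells, 0.325)
  ones <- matrix(TRUE, 10, 10)
  expect_equal(area_fraction(masks, ones, "nuclear_mask")$f, 1)
  expect_equal(area_fraction(masks, !ones, "cellular_mask")$f, 0)
  sig <- matrix(FALSE, 10, 10); sig[2:6, 2:3] <- TRUE  # 10 of 25 nuclear px
  expect_equal(area_fraction(masks, sig, "nuclear_mask")$f, 0.4)
  expect_error(area_fraction(masks, matrix(TRUE, 4, 4), "nuclear_mask"),
               "aligned")
})

test_that("zero-area compartments are flagged, not divided by", {
  nuc <- matrix(0L, 8, 8); nuc[2:3, 2:3] <- 1L
  cells <- nuc
  masks <- cell_mask_set(nuc, cells, 0.325)
  masks$table <- rbind(masks$table,
                       data.frame(id = 2L, centroid_x = 6, centroid_y = 6,
                                  nuclear_area_px = 0, cellular_area_px = 0))
  af <- area_fraction(masks, matrix(TRUE, 8, 8), "nuclear_mask")
  expect_true(is.na(af$f[af$cell_id == 2]))
  expect_false(af$valid[af$cell_id == 2])
})

test_that("ROC calibration maximises Youden's J", {
  f <- c(0.01, 0.05, 0.08, 0.55, 0.7, 0.9)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  cal <- calibrate_cutoff(f, lab)
  expect_equal(cal$J, 1)
  expect_gt(cal$cutoff, 0.08); expect_lt(cal$cutoff, 0.55)

  f2 <- c(0.1, 0.2, 0.3, 0.15)
  l2 <- c(FALSE, FALSE, TRUE, TRUE)
  cal2 <- calibrate_cutoff(f2, l2)
  or2 <- youden_oracle(f2, l2)
  expect_equal(cal2$J, or2$best_J)
  expect_equal(cal2$cutoff, min(or2$cutoffs))  # documented tie rule

  expect_error(calibrate_cutoff(c(0.1, 0.2), c(TRUE, TRUE)), "both")
})

test_that("calibration equals brute force on 300 beta-distributed cells", {
  set.seed(33)
  n <- 300
  lab <- runif(n) < 0.5
  f <- ifelse(lab, rbeta(n, 4, 3), rbeta(n, 1, 8))
  cal <- calibrate_cutoff(f, lab)
  or <- youden_oracle(f, lab)
  expect_equal(cal$J, or$best_J)
  expect_true(cal$cutoff %in% or$cutoffs)
})

test_that("classification applies the f >= cutoff rule", {
  fr <- data.frame(cell_id = 1:10, channel_name = "GFAP",
                   f = c(0, 0.05, 0.1, 0.19, 0.2, 0.21, 0.4, 0.6, 0.9, 1))
  calls <- classify_cells(fr, c(GFAP = 0.2))
  expect_equal(calls$call,
               ifelse(fr$f >= 0.2, "positive", "negative"))
  expect_equal(calls$call[fr$f == 0.2], "positive")  # boundary is positive
  expect_true(all(classify_cells(
    data.frame(cell_id = 1:3, channel_name = "X", f = 0),
    c(X = 0.1))$call == "negative"))
  expect_error(classify_cells(fr, c(OTHER = 0.1)), "missing cutoff")
})

test_that("classification is monotone in f", {
  set.seed(44)
  f <- runif(50)
  base <- classify_cells(data.frame(cell_id = 1:50, channel_name = "m",
                                    f = f), c(m = 0.35))$call
  raised <- classify_cells(data.frame(cell_id = 1:50, channel_name = "m",
                                      f = pmin(f + runif(50, 0, 0.3), 1)),
                           c(m = 0.35))$call
  expect_false(any(base == "positive" & raised == "negative"))
})

test_that("co-expression matrix marginals and conditionals", {
  status <- cbind(A = rep(TRUE, 6), B = rep(TRUE, 6))
  cx <- coexpression_matrix(status)
  expect_true(all(cx$matrix == 100))
  expect_true(all(cx$marginal_pct == 100))

  set.seed(51)
  s2 <- cbind(A = runif(200) < 0.6, B = runif(200) < 0.3)
  cx2 <- coexpression_matrix(s2)
  expect_equal(unname(cx2$marginal_pct["A"]), 100 * mean(s2[, "A"]))
  expect_equal(cx2$matrix["A", "B"],
               100 * sum(s2[, "A"] & s2[, "B"]) / sum(s2[, "A"]))
  expect_equal(diag(cx2$matrix), c(A = 100, B = 100))

  s3 <- cbind(A = c(TRUE, FALSE, TRUE), B = c(FALSE, FALSE, FALSE))
  cx3 <- coexpression_matrix(s3)
  expect_true(all(is.na(cx3$matrix["B", ])))  # undefined, not 0
})

test_that("truth pass-through recovers the realized draw exactly", {
  fl <- generate_fluorescence_field(field_spec(
    n_cells = 300, width_px = 640, height_px = 640, seed = 61))
  cx <- coexpression_matrix(as.matrix(fl$truth[, c("APLNR", "GFAP")]))
  expect_equal(unname(cx$marginal_pct["APLNR"]),
               100 * mean(fl$truth$APLNR))
  expect_equal(cx$matrix["APLNR", "GFAP"],
               100 * sum(fl$truth$APLNR & fl$truth$GFAP) /
                 sum(fl$truth$APLNR))
})

test_that("calls from a marker call table round-trip into the matrix", {
  calls <- data.frame(
    cell_id = rep(1:4, each = 2),
    channel_name = rep(c("A", "B"), 4),
    f = 0.5,
    call = c("positive", "positive",  # cell 1: A+B+
             "positive", "negative",  # cell 2: A+
             "negative", "negative",  # cell 3: none
             NA, "positive"))         # cell 4: invalid -> excluded
  cx <- coexpression_matrix(calls)
  expect_equal(cx$n_cells, 3)
  expect_equal(unname(cx$marginal_pct), c(200 / 3, 100 / 3))
  expect_equal(cx$matrix["A", "B"], 50)
  expect_equal(cx$matrix["B", "A"], 100)
})
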