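# Independent brute-force oracles used against the package implementations.
# These deliberately re-derive every quantity by naive loops so that a bug
# in the fast path cannot hide in its own oracle.

# naive flat erosion/dilation: min/max over the disk support, out-of-frame
# pixels ignored
naive_minmax <- function(img, radius, fun) {
  nr <- nrow(img); nc <- ncol(img)
  off <- which(svzquant:::disk_mask(radius) == 1, arr.ind = TRUE) - radius - 1
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- r + off[, 1]; cc <- c + off[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out[r, c] <- fun(img[cbind(rr[ok], cc[ok])])
  }
  out
}

# elementary 3x3 box min/max (8-connectivity, matching the implementation)
naive_box <- function(img, fun) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- max(1, r - 1):min(nr, r + 1)
    cc <- max(1, c - 1):min(nc, c + 1)
    out[r, c] <- fun(img[rr, cc])
  }
  out
}

# naive geodesic reconstruction by dilation: elementary 8-connected
# dilation and pointwise min with the mask, iterated to stability
naive_reconstruct <- function(marker, mask) {
  J <- pmin(marker, mask)
  repeat {
    Jn <- pmin(naive_box(J, max), mask)
    if (identical(Jn, J)) return(J)
    J <- Jn
  }
}

naive_opening_rec <- function(img, radius)
  naive_reconstruct(naive_minmax(img, radius, min), img)

naive_closing_rec <- function(img, radius) {
  m <- max(img)
  m - naive_opening_rec(m - img, radius)
}

naive_tophat <- function(img, radius) {
  cl <- naive_closing_rec(img, radius)
  pmax(cl - naive_opening_rec(cl, radius), 0)
}

# Li cross-entropy criterion minimised by exhaustive search over all
# candidate gray levels (background strictly below the candidate)
li_oracle <- function(v) {
  v <- v[v > 0]
  u <- sort(unique(v))
  best <- Inf; best_t <- NA
  for (t in u[-1]) {
    b <- v[v < t]; f <- v[v >= t]
    eta <- -sum(b) * log(mean(b)) - sum(f) * log(mean(f))
    if (eta < best - 1e-12) { best <- eta; best_t <- t }
  }
  best_t
}

# brute-force Youden calibration: all candidate cutoffs, loop evaluation;
# returns the full argmax set
youden_oracle <- function(f, label) {
  u <- sort(unique(f))
  cand <- c(min(u), if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)
  J <- sapply(cand, function(c0) {
    call <- f >= c0
    sum(call & label) / sum(label) + sum(!call & !label) / sum(!label) - 1
  })
  list(best_J = max(J), cutoffs = cand[J >= max(J) - 1e-12])
}

# two-sided Fisher p by exhaustive hypergeometric tail summation
hyper_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  kk <- max(0, k - n):min(k, m)
  pr <- dhyper(kk, m, n, k)
  sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

rand_img8 <- function(nr = 16, nc = 16) {
  matrix(as.numeric(sample(0:255, nr * nc, TRUE)), nr, nc)
}

# field of non-overlapping disks of one or more radii on a flat background
disk_field <- function(radii_counts, size = 200, value = 200, bg = 10,
                       seed = 1) {
  set.seed(seed)
  img <- matrix(bg, size, size)
  placed <- data.frame(x = numeric(), y = numeric(), r = numeric())
  for (r in names(radii_counts)) {
    ri <- as.numeric(r)
    for (i in seq_len(radii_counts[[r]])) {
      for (try in 1:500) {
        # integer centres so erosion/survival arguments are exact
        x <- round(runif(1, ri + 2, size - ri - 1))
        y <- round(runif(1, ri + 2, size - ri - 1))
        if (!nrow(placed) ||
            all(sqrt((placed$x - x)^2 + (placed$y - y)^2) >
                placed$r + ri + 3)) {
          img <- svzquant:::draw_disk(img, x, y, ri, value)
          placed <- rbind(placed, data.frame(x = x, y = y, r = ri))
          break
        }
      }
    }
  }
  img
}

# small DAPI-only field spec for segmentation tests
dapi_field_spec <- function(n_cells, seed, touching_fraction = 0.1, ...) {
  field_spec(n_cells = n_cells, seed = seed,
             touching_fraction = touching_fraction,
             channel_panel = data.frame(name = "DAPI", class = "DAPI"),
             coexpression_table = c(none = 1), ...)
}

# truth-label calibration table for the first n matched cells
truth_calibration <- function(matches, truth, markers, n = 300) {
  m <- matches[seq_len(min(n, nrow(matches))), ]
  do.call(rbind, lapply(markers, function(mk)
    data.frame(cell_id = m$detected_id, channel_name = mk,
               label = truth[[mk]][match(m$truth_id, truth$id)])))
}
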