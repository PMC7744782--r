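#' RPKM normalization
#'
#' RPKM\[g, s\] = counts\[g, s\] * 1e9 / (length_bp\[g\] * total\[s\]),
#' where total\[s\] is the per-sample sum of reads mapped to annotated
#' genes (the column sum of the count matrix).
#'
#' @param counts genes x samples matrix of non-negative integers.
#' @param gene_lengths per-gene transcript lengths in bp (named or in row
#'   order), all > 0.
#' @return Matrix of RPKM values, same dimensions.
#' @export
rpkm_normalize <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts))
    stop("one gene length per gene required")
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene lengths must be > 0")
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("zero mapped reads in sample(s): ",
         paste(colnames(counts)[tot <= 0], collapse = ", "))
  sweep(counts * 1e9 / gene_lengths, 2, tot, "/")
}

check_paired_meta <- function(counts, meta) {
  stopifnot(all(c("condition", "subject", "fragment") %in% names(meta)),
            nrow(meta) == ncol(counts))
  if (!setequal(meta$condition, c("sham", "ischemic")))
    stop("conditions must be 'sham' and 'ischemic'")
  key <- paste(meta$subject, meta$fragment)
  sham <- which(meta$condition == "sham")
  isch <- which(meta$condition == "ischemic")
  if (length(sham) != length(isch))
    stop("conditions must have equally many samples")
  m <- match(key[sham], key[isch])
  if (anyNA(m) || anyDuplicated(m))
    stop("samples are not fully paired by (subject, fragment)")
  list(sham = sham, ischemic = isch[m])
}

#' Paired t-test per gene
#'
#' Two-sided paired t-test on per-pair differences of RPKM values, pairs
#' defined by (subject, fragment). Genes whose paired differences have
#' zero variance get p = 1 (conservative convention; this includes genes
#' identical across conditions).
#'
#' @param rpkm genes x samples RPKM matrix.
#' @param meta sample metadata with condition, subject, fragment.
#' @return Per-gene two-sided p-values.
#' @export
paired_t_test <- function(rpkm, meta) {
  pr <- check_paired_meta(rpkm, meta)
  d <- rpkm[, pr$ischemic, drop = FALSE] - rpkm[, pr$sham, drop = FALSE]
  n <- ncol(d)
  if (n < 2) stop("need at least 2 pairs")
  mean_d <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - mean_d)^2) / (n - 1))
  t <- mean_d / (sd_d / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  p[!is.finite(t)] <- 1   # zero-variance differences
  p[sd_d == 0] <- 1
  unname(p)
}

#' Median-of-ratios size factors
#'
#' Per-sample size factor: the median across genes of the ratio between
#' the sample's counts and the geometric-mean reference, computed over
#' genes expressed in every sample.
#'
#' @param counts genes x samples matrix.
#' @return Per-sample size factors.
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg)
  use <- is.finite(ref)
  if (!any(use)) stop("no gene is expressed in every sample")
  sf <- apply(lg[use, , drop = FALSE], 2, function(col)
    exp(median(col - ref[use], na.rm = TRUE)))
  sf
}

# Method-of-moments dispersion per gene (replicate groups = condition x
# subject, so batch differences do not inflate the estimate) with a
# parametric mean-dispersion trend; the working dispersion is the
# log-space average of the gene-wise estimate and the fitted trend.
estimate_dispersions <- function(norm_counts, group) {
  G <- nrow(norm_counts)
  groups <- split(seq_along(group), group)
  mu <- rowMeans(norm_counts)
  ss <- matrix(0, G, length(groups))
  dfree <- 0
  v <- rep(0, G)
  for (g in groups) {
    m <- rowMeans(norm_counts[, g, drop = FALSE])
    v <- v + rowSums((norm_counts[, g, drop = FALSE] - m)^2)
    dfree <- dfree + length(g) - 1
  }
  v <- v / dfree
  raw <- (v - mu) / mu^2
  raw[!is.finite(raw)] <- 0
  raw <- pmin(pmax(raw, 1e-8), 20)
  # robust trend a0 + a1/mu: least squares through per-bin medians, so a
  # minority of genes with genuinely high dispersion (or true effects when
  # labels are permuted) cannot drag the trend
  fit_ok <- which(mu > 0 & raw > 1e-7)
  trend <- rep(max(median(raw[fit_ok]), 1e-4), G)
  if (length(fit_ok) >= 50) {
    qs <- quantile(mu[fit_ok], seq(0, 1, length.out = 21))
    bin <- cut(mu[fit_ok], unique(qs), include.lowest = TRUE)
    med <- tapply(raw[fit_ok], bin, median)
    mid <- tapply(mu[fit_ok], bin, median)
    ok <- is.finite(med) & is.finite(mid)
    if (sum(ok) >= 3) {
      co <- tryCatch(stats::coef(stats::lm(med[ok] ~ I(1 / mid[ok]))),
                     error = function(e) NULL)
      if (!is.null(co) && all(is.finite(co)))
        trend <- pmax(co[1] + pmax(co[2], 0) / pmax(mu, 1e-8), 1e-4)
    }
  }
  shrunk <- exp((log(pmax(trend, 1e-8)) + log(pmax(raw, 1e-8))) / 2)
  pmax(pmin(shrunk, 20), 1e-8)
}

#' Negative-binomial differential test with batch adjustment
#'
#' A DESeq-style (but independent) negative-binomial test: counts are
#' normalised by median-of-ratios size factors; per-gene dispersions are
#' estimated by method-of-moments on normalised counts within
#' condition-by-subject replicate groups and shrunk toward a parametric
#' mean-dispersion trend (log-space average of gene-wise and trend
#' values); the condition effect is then tested by a Wald test in an NB
#' log-linear model with condition and subject (batch) terms. It does not
#' aim for numerical agreement with any historical package.
#'
#' @param counts genes x samples integer matrix.
#' @param meta sample metadata with condition, subject, fragment.
#' @param condition optional factor overriding `meta$condition` (used by
#'   the permutation engine).
#' @return List with per-gene `p` (all-zero genes get p = 1), `log2fc_mle`
#'   (model-based log2 fold change), `dispersion` and `size_factors`.
#' @export
nb_test <- function(counts, meta, condition = NULL) {
  counts <- as.matrix(counts)
  cond <- factor(condition %||% meta$condition, levels = c("sham", "ischemic"))
  if (nlevels(droplevels(cond)) < 2 || min(table(cond)) < 2)
    stop("need at least 2 samples per condition")
  subj <- factor(meta$subject)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  disp <- estimate_dispersions(norm, interaction(cond, subj))
  X <- stats::model.matrix(~ cond + subj)
  ci <- which(colnames(X) == "condischemic") - 1L
  fit <- .nb_wald_cpp(counts, X, log(sf), disp, ci)
  z <- fit[, 1] / fit[, 2]
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(p)] <- 1
  allzero <- rowSums(counts) == 0
  p[allzero] <- 1
  list(p = unname(p), log2fc_mle = unname(fit[, 1] / log(2)),
       dispersion = disp, size_factors = sf)
}

#' Combined UP/DOWN/NS call
#'
#' A gene is called UP when the paired-t and NB p-values are both below
#' their thresholds and the log2 fold change exceeds `lfc`; DOWN
#' symmetrically with log2FC below `-lfc`; otherwise NS. The fold-change
#' criterion is applied signed-symmetrically.
#'
#' @param log2fc per-gene log2 fold change (ischemic vs sham).
#' @param p_t,p_nb per-gene p-values.
#' @param alpha_t,alpha_nb,lfc thresholds (defaults 0.05, 0.05, 0.5).
#' @return Character vector of calls in `{"UP", "DOWN", "NS"}`.
#' @export
call_de <- function(log2fc, p_t, p_nb, alpha_t = 0.05, alpha_nb = 0.05,
                    lfc = 0.5) {
  sig <- p_t < alpha_t & p_nb < alpha_nb
  out <- rep("NS", length(log2fc))
  out[sig & log2fc > lfc] <- "UP"
  out[sig & log2fc < -lfc] <- "DOWN"
  out[is.na(sig) | is.na(log2fc)] <- "NS"
  out
}

#' Full paired differential-expression analysis
#'
#' Runs RPKM normalization, the paired t-test, the batch-aware NB test and
#' the combined call on a paired count matrix. The log2 fold change used
#' by the call criterion is computed from condition means of
#' size-factor-normalised counts with a pseudocount of 1 (the same
#' normalisation the NB test uses), so it is robust to composition shifts
#' that total-count scaling cannot remove; the per-condition mean RPKM is
#' reported alongside.
#'
#' @param counts genes x samples integer matrix.
#' @param gene_lengths per-gene lengths in bp.
#' @param meta sample metadata (see [paired_design()]).
#' @param alpha_t,alpha_nb,lfc call thresholds.
#' @param pseudocount added to condition-mean RPKM before the log ratio.
#' @param condition optional permuted condition labels.
#' @return Object of class `svz_de`: per-gene table (mean RPKM per
#'   condition, log2FC, p_t, p_nb, call) plus settings and counts of UP
#'   and DOWN genes.
#' @export
de_analysis <- function(counts, gene_lengths, meta, alpha_t = 0.05,
                        alpha_nb = 0.05, lfc = 0.5, pseudocount = 1,
                        condition = NULL) {
  counts <- as.matrix(counts)
  cond <- condition %||% meta$condition
  rpkm <- rpkm_normalize(counts, gene_lengths)
  meta2 <- meta
  meta2$condition <- cond
  p_t <- paired_t_test(rpkm, meta2)
  nb <- nb_test(counts, meta, condition = cond)
  mean_sham <- rowMeans(rpkm[, cond == "sham", drop = FALSE])
  mean_isch <- rowMeans(rpkm[, cond == "ischemic", drop = FALSE])
  norm <- sweep(counts, 2, nb$size_factors, "/")
  log2fc <- log2(
    (rowMeans(norm[, cond == "ischemic", drop = FALSE]) + pseudocount) /
      (rowMeans(norm[, cond == "sham", drop = FALSE]) + pseudocount))
  call <- call_de(log2fc, p_t, nb$p, alpha_t, alpha_nb, lfc)
  tab <- data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
                    mean_rpkm_sham = mean_sham,
                    mean_rpkm_ischemic = mean_isch,
                    log2fc = log2fc, p_t = p_t, p_nb = nb$p, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n_up = sum(call == "UP"),
                 n_down = sum(call == "DOWN"),
                 settings = list(alpha_t = alpha_t, alpha_nb = alpha_nb,
                                 lfc = lfc, pseudocount = pseudocount),
                 size_factors = nb$size_factors),
            class = "svz_de")
}

#' @export
print.svz_de <- function(x, ...) {
  cat(sprintf("paired DE analysis: %d genes, %d UP, %d DOWN\n",
              nrow(x$table), x$n_up, x$n_down))
  cat(sprintf("criteria: paired-t p < %g, NB p < %g, |log2FC| > %g\n",
              x$settings$alpha_t, x$settings$alpha_nb, x$settings$lfc))
  invisible(x)
}

#' Permutation estimate of the false discovery rate
#'
#' Re-runs the full combined criterion under permuted condition labels and
#' estimates the FDR as the median number of significant genes across
#' permutations divided by the significant count on the real labels.
#' Because the design is paired, labels are permuted by independent
#' condition swaps within each of the 9 pairs; the 2^9 = 512 distinct
#' swap patterns are sampled uniformly with replacement.
#'
#' @param counts,gene_lengths,meta as in [de_analysis()].
#' @param n_permutations number of permutations (>= 1; the study-scale
#'   setting is 1000).
#' @param seed integer seed for the permutation draws.
#' @param ... call thresholds passed to [de_analysis()].
#' @return Object of class `svz_perm_fdr`: `fdr_estimate` (NA with a flag
#'   if the real data yield zero significant genes), `n_significant_real`,
#'   the per-permutation counts, `n_permutations` and `seed`.
#' @export
permutation_fdr <- function(counts, gene_lengths, meta,
                            n_permutations = 1000, seed = 1, ...) {
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  counts <- as.matrix(counts)
  pr <- check_paired_meta(counts, meta)
  real <- de_analysis(counts, gene_lengths, meta, ...)
  n_real <- real$n_up + real$n_down
  perm_counts <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      swap <- runif(length(pr$sham)) < 0.5
      cond <- meta$condition
      cond[pr$sham[swap]] <- "ischemic"
      cond[pr$ischemic[swap]] <- "sham"
      d <- de_analysis(counts, gene_lengths, meta, condition = cond, ...)
      d$n_up + d$n_down
    }, numeric(1))
  })
  structure(list(fdr_estimate = if (n_real > 0)
                   median(perm_counts) / n_real else NA_real_,
                 undefined = n_real == 0,
                 n_significant_real = n_real,
                 perm_significant = perm_counts,
                 n_permutations = n_permutations, seed = seed),
            class = "svz_perm_fdr")
}

#' @export
print.svz_perm_fdr <- function(x, ...) {
  cat(sprintf("permutation FDR: %s (real significant: %d, median over %d permutations: %g)\n",
              if (x$undefined) "undefined (no significant genes)" else
                sprintf("%.3f", x$fdr_estimate),
              x$n_significant_real, x$n_permutations,
              median(x$perm_significant)))
  invisible(x)
}

#' Fisher's exact enrichment of a gene set
#'
#' Two-sided Fisher's exact test of the overlap between a DE gene set and
#' a reference set (e.g. a cell-type expression profile) within a gene
#' universe.
#'
#' @param de_set,reference_set character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return List with the 2 x 2 `table`, `odds_ratio` (conditional MLE)
#'   and two-sided `p`.
#' @export
fisher_enrichment <- function(de_set, reference_set, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  de_set <- intersect(unique(de_set), universe)
  reference_set <- intersect(unique(reference_set), universe)
  a <- length(intersect(de_set, reference_set))
  b <- length(setdiff(de_set, reference_set))
  c <- length(setdiff(reference_set, de_set))
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), 2, 2,
                dimnames = list(c("in_ref", "not_ref"),
                                c("in_de", "not_de")))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}
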