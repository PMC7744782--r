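test_that("RPKM follows the formula and its invariances", {
  counts <- rbind(g1 = c(s1 = 10, s2 = 0),
                  g2 = c(s1 = 999990, s2 = 1000))  # totals: s1 = 1e6
  rp <- rpkm_normalize(counts, c(g1 = 1000, g2 = 5000))
  expect_equal(rp["g1", "s1"], 10)     # 10 reads / 1 kb / 1 M reads
  expect_equal(rp["g1", "s2"], 0)

  d <- generate_count_matrix(count_spec(n_genes = 30, seed = 3))
  rp1 <- rpkm_normalize(d$counts, d$gene_lengths)
  doubled <- d$counts; doubled[, 1] <- doubled[, 1] * 2L
  rp2 <- rpkm_normalize(doubled, d$gene_lengths)
  expect_equal(rp1[, 1], rp2[, 1])   # depth-scaling invariance
  halved <- d$gene_lengths; halved[1] <- halved[1] / 2
  rp3 <- rpkm_normalize(d$counts, halved)
  expect_equal(rp3[1, ], 2 * rp1[1, ])  # length equivariance
  bad <- d$counts; bad[, 2] <- 0L
  expect_error(rpkm_normalize(bad, d$gene_lengths), "sham_s1_f2")
})

test_that("paired t-test matches the closed form", {
  meta <- paired_design()
  rpkm <- matrix(5, 3, 18, dimnames = list(NULL, meta$sample))
  expect_equal(paired_t_test(rpkm, meta), rep(1, 3))

  set.seed(7)
  d9 <- 1 + rnorm(9, 0, 0.01)
  x <- matrix(10, 1, 18, dimnames = list("g", meta$sample))
  x[1, meta$condition == "ischemic"] <- 10 + d9
  p <- paired_t_test(x, meta)
  tstat <- mean(d9) / (sd(d9) / 3)
  expect_equal(p, 2 * pt(-abs(tstat), 8))
  expect_lt(p, 1e-6)

  # one discordant pair
  y <- matrix(10, 1, 18, dimnames = list("g", meta$sample))
  y[1, meta$condition == "ischemic" & meta$subject == 1 &
      meta$fragment == 1] <- 13
  dif <- c(3, rep(0, 8))
  expect_equal(paired_t_test(y, meta),
               2 * pt(-abs(mean(dif) / (sd(dif) / 3)), 8))
  expect_error(paired_t_test(rpkm[, -1, drop = FALSE], meta[-1, ]),
               "equally many|paired")
})

test_that("size factors undo depth differences", {
  d <- generate_count_matrix(count_spec(n_genes = 400, de_fraction = 0,
                                        seed = 5))
  sf <- size_factors(d$counts)
  scaled <- d$counts
  scaled[, 3] <- as.integer(round(scaled[, 3] * 3))
  sf2 <- size_factors(scaled)
  # relative to an unscaled sample (the reference itself shifts slightly)
  expect_equal(unname((sf2[3] / sf2[1]) / (sf[3] / sf[1])), 3,
               tolerance = 0.02)
})

test_that("NB Wald fit agrees with R's IRLS at fixed dispersion", {
  d <- generate_count_matrix(count_spec(n_genes = 25, de_fraction = 0.2,
                                        seed = 6))
  meta <- d$meta
  cond <- factor(meta$condition, levels = c("sham", "ischemic"))
  subj <- factor(meta$subject)
  X <- model.matrix(~ cond + subj)
  sf <- size_factors(d$counts)
  alpha <- rep(0.08, 25)
  fit <- svzquant:::.nb_wald_cpp(d$counts, X, log(sf), alpha, 1L)
  for (g in c(1, 7, 19)) {
    rf <- suppressWarnings(glm.fit(X, d$counts[g, ],
                                   family = MASS::negative.binomial(1 / 0.08),
                                   offset = log(sf)))
    expect_equal(fit[g, 1], unname(coef(rf)["condischemic"]),
                 tolerance = 1e-4)
    # standard error from the weighted least-squares information
    w <- rf$weights
    cov <- solve(t(X) %*% (X * w))
    expect_equal(fit[g, 2], sqrt(cov[2, 2]), tolerance = 1e-4)
  }
})

test_that("NB test p-values are near-uniform under the null", {
  d <- generate_count_matrix(count_spec(n_genes = 2000, de_fraction = 0,
                                        seed = 9))
  nb <- nb_test(d$counts, d$meta)
  expect_equal(length(nb$p), 2000)
  ks <- suppressWarnings(ks.test(nb$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(nb$p < 0.05), 0.08)
})

test_that("NB test detects a strong fold change and handles zeros", {
  d <- generate_count_matrix(count_spec(n_genes = 300, de_fraction = 0.1,
                                        lfc_min = 2, seed = 10))
  nb <- nb_test(d$counts, d$meta)
  de <- rownames(d$counts) %in% d$truth$gene
  expect_gt(mean(nb$p[de] < 0.01), 0.9)
  z <- d$counts; z[5, ] <- 0L
  expect_equal(nb_test(z, d$meta)$p[5], 1)
})

test_that("depth confounding alone does not inflate the NB test", {
  d <- generate_count_matrix(count_spec(n_genes = 1500, de_fraction = 0,
                                        seed = 12))
  cf <- d$counts
  cf[, d$meta$condition == "ischemic"] <-
    cf[, d$meta$condition == "ischemic"] * 2L
  nb <- nb_test(cf, d$meta)
  expect_lt(mean(nb$p < 0.05), 0.08)
})

test_that("combined call applies the three criteria", {
  expect_equal(call_de(0.7, 0.01, 0.02), "UP")
  expect_equal(call_de(0.4, 0.001, 0.001), "NS")
  expect_equal(call_de(-0.9, 0.06, 0.01), "NS")
  expect_equal(call_de(-0.9, 0.01, 0.01), "DOWN")
  res <- de_analysis(generate_count_matrix(count_spec(200, seed = 2))$counts,
                     generate_count_matrix(count_spec(200, seed = 2))$gene_lengths,
                     paired_design())
  with(res$table, {
    expect_true(all((call == "UP") ==
                      (p_t < 0.05 & p_nb < 0.05 & log2fc > 0.5)))
    expect_true(all((call == "DOWN") ==
                      (p_t < 0.05 & p_nb < 0.05 & log2fc < -0.5)))
  })
})

test_that("permutation FDR is reproducible and validated", {
  d <- generate_count_matrix(count_spec(n_genes = 400, de_fraction = 0.15,
                                        seed = 14))
  p1 <- permutation_fdr(d$counts, d$gene_lengths, d$meta,
                        n_permutations = 15, seed = 5)
  p2 <- permutation_fdr(d$counts, d$gene_lengths, d$meta,
                        n_permutations = 15, seed = 5)
  expect_identical(p1$perm_significant, p2$perm_significant)
  expect_equal(p1$fdr_estimate, p2$fdr_estimate)
  p3 <- permutation_fdr(d$counts, d$gene_lengths, d$meta,
                        n_permutations = 15, seed = 6)
  expect_false(identical(p1$perm_significant, p3$perm_significant))
  expect_error(permutation_fdr(d$counts, d$gene_lengths, d$meta,
                               n_permutations = 0), ">= 1")
  expect_gte(p1$fdr_estimate, 0)
})

test_that("Fisher enrichment equals the hypergeometric oracle", {
  uni <- sprintf("g%04d", 1:1000)
  expect_error(fisher_enrichment(uni[1:5], uni[1:5], character(0)), "empty")
  degen <- fisher_enrichment(uni, uni, uni)
  expect_equal(degen$p, 1)

  de <- uni[1:20]; ref <- uni[11:30]
  fe <- fisher_enrichment(de, ref, uni)
  expect_equal(unname(fe$table["in_ref", "in_de"]), 10)
  expect_equal(fe$p, hyper_oracle(10, 10, 10, 970), tolerance = 1e-9)

  disj <- fisher_enrichment(uni[1:50], uni[51:100], uni[1:100])
  expect_equal(disj$p, hyper_oracle(0, 50, 50, 0), tolerance = 1e-9)
})

test_that("NB stage ranks genes like an established NB pipeline", {
  d <- generate_count_matrix(count_spec(n_genes = 150, de_fraction = 0.2,
                                        lfc_min = 1.5, seed = 16))
  nb <- nb_test(d$counts, d$meta)
  suppressMessages({
    library(DESeq2)
    colda <- data.frame(condition = factor(d$meta$condition,
                                           levels = c("sham", "ischemic")),
                        subject = factor(d$meta$subject))
    dds <- DESeqDataSetFromMatrix(d$counts, colda, ~ subject + condition)
    dds <- suppressWarnings(DESeq(dds, quiet = TRUE, fitType = "mean"))
    pref <- results(dds)$pvalue
  })
  ok <- is.finite(pref) & is.finite(nb$p)
  expect_gt(cor(rank(nb$p[ok]), rank(pref[ok])), 0.85)
  de <- rownames(d$counts) %in% d$truth$gene
  expect_gt(mean((nb$p < 0.01) == (pref < 0.01), na.rm = TRUE), 0.85)
})
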