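#' Specification of a synthetic paired RNA-seq count matrix
#'
#' Emulates the study design the differential-expression stage assumes:
#' 2 conditions (sham, ischemic) x 3 subjects x 3 adjacent tissue
#' fragments, 9 samples per condition, fragments paired across conditions
#' by index. Counts are negative-binomially distributed around
#' condition x subject means; a per-gene, per-subject batch effect (shared
#' by both members of each pair) models between-animal variation, which
#' the paired analysis is designed to remove.
#'
#' @param n_genes number of genes.
#' @param gene_length_bp optional per-gene transcript lengths; sampled
#'   log-uniformly in 400..8000 bp when `NULL`.
#' @param de_fraction fraction of genes truly differentially expressed.
#' @param lfc_min minimum absolute true log2 fold change (all true DE
#'   effects exceed 0.5; default 1).
#' @param lfc_exp_mean mean of the exponential excess above `lfc_min`.
#' @param prop_up proportion of true-DE genes that are upregulated.
#' @param batch_effect_sd sd of the per-gene subject effect on the log2
#'   scale.
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   a scalar for a common value, a vector for per-gene values, 0 for the
#'   Poisson limit.
#' @param library_size_range range the per-sample library sizes are drawn
#'   from.
#' @param mean_log2_expr,sd_log2_expr distribution of baseline gene
#'   abundance (log2 scale, arbitrary units renormalised to the library
#'   size).
#' @param seed integer seed.
#' @return Object of class `count_spec`.
#' @export
count_spec <- function(n_genes = 2000L, gene_length_bp = NULL,
                       de_fraction = 0.1, lfc_min = 1, lfc_exp_mean = 0.5,
                       prop_up = 0.5, batch_effect_sd = 0.25,
                       nb_dispersion = 0.05,
                       library_size_range = c(8e5, 1.6e6),
                       mean_log2_expr = 5, sd_log2_expr = 2, seed = 1L) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("'de_fraction' must lie in [0, 1]")
  if (lfc_min <= 0.5)
    stop("'lfc_min' must exceed 0.5 so every true effect clears the call threshold")
  if (any(library_size_range <= 0)) stop("library sizes must be > 0")
  if (any(nb_dispersion < 0)) stop("'nb_dispersion' must be >= 0")
  if (!length(nb_dispersion) %in% c(1L, n_genes))
    stop("'nb_dispersion' must be a scalar or one value per gene")
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_bp = gene_length_bp,
                 de_fraction = de_fraction, lfc_min = lfc_min,
                 lfc_exp_mean = lfc_exp_mean, prop_up = prop_up,
                 batch_effect_sd = batch_effect_sd,
                 nb_dispersion = nb_dispersion,
                 library_size_range = library_size_range,
                 mean_log2_expr = mean_log2_expr,
                 sd_log2_expr = sd_log2_expr, seed = as.integer(seed)),
            class = "count_spec")
}

#' Sample metadata for the paired 9 vs 9 design
#'
#' @return Data frame with sample id, condition, subject and fragment for
#'   the 18 samples; the pairing key is (subject, fragment).
#' @export
paired_design <- function() {
  d <- expand.grid(fragment = 1:3, subject = 1:3,
                   condition = c("sham", "ischemic"),
                   stringsAsFactors = FALSE)
  d$sample <- sprintf("%s_s%d_f%d", d$condition, d$subject, d$fragment)
  d[, c("sample", "condition", "subject", "fragment")]
}

#' Generate a paired synthetic count matrix with known DE genes
#'
#' @param spec a [count_spec()].
#' @return List with `counts` (genes x 18 samples integer matrix),
#'   `gene_lengths`, `meta` (the [paired_design()] table) and `truth`
#'   (gene, sign and true log2FC of every truly DE gene).
#' @export
generate_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "count_spec"))
  meta <- paired_design()
  G <- spec$n_genes
  with_seed(spec$seed, {
    lens <- spec$gene_length_bp %||%
      round(exp(runif(G, log(400), log(8000))))
    genes <- sprintf("gene%05d", seq_len(G))
    base <- 2^rnorm(G, spec$mean_log2_expr, spec$sd_log2_expr)
    n_de <- round(spec$de_fraction * G)
    de_idx <- if (n_de > 0) sort(sample.int(G, n_de)) else integer(0)
    sign <- ifelse(runif(n_de) < spec$prop_up, 1, -1)
    lfc <- numeric(G)
    lfc[de_idx] <- sign * (spec$lfc_min + rexp(n_de, 1 / spec$lfc_exp_mean))
    batch <- matrix(rnorm(G * 3, 0, spec$batch_effect_sd), G, 3)
    libs <- runif(18, spec$library_size_range[1], spec$library_size_range[2])
    alpha <- rep(spec$nb_dispersion, length.out = G)

    rel <- base / sum(base)
    counts <- matrix(0L, G, 18, dimnames = list(genes, meta$sample))
    for (j in seq_len(18)) {
      cond_lfc <- if (meta$condition[j] == "ischemic") lfc else 0
      mu <- rel * 2^(cond_lfc + batch[, meta$subject[j]]) * libs[j]
      y <- ifelse(alpha > 0,
                  rnbinom(G, mu = mu, size = 1 / pmax(alpha, 1e-12)),
                  rpois(G, mu))
      counts[, j] <- as.integer(y)
    }
    truth <- data.frame(gene = genes[de_idx],
                        sign = ifelse(lfc[de_idx] > 0, "UP", "DOWN"),
                        log2fc = lfc[de_idx], stringsAsFactors = FALSE)
    list(counts = counts, gene_lengths = setNames(lens, genes),
         meta = meta, truth = truth)
  })
}

#' Write / read a count matrix as TSV
#'
#' Sample ids in the header encode condition, subject and fragment
#' (`condition_sN_fM`); gene lengths go to a two-column TSV.
#'
#' @param counts genes x samples integer matrix.
#' @param gene_lengths named per-gene lengths (bp).
#' @param counts_file,lengths_file output paths.
#' @export
write_count_matrix <- function(counts, gene_lengths, counts_file,
                               lengths_file) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = names(gene_lengths),
                         length_bp = unname(gene_lengths)),
              lengths_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_file)
}

#' @rdname write_count_matrix
#' @return `read_count_matrix()`: list with `counts`, `gene_lengths` and
#'   `meta` decoded from the sample ids.
#' @export
read_count_matrix <- function(counts_file, lengths_file) {
  df <- read.delim(counts_file, check.names = FALSE)
  counts <- as.matrix(df[, -1])
  rownames(counts) <- df$gene
  storage.mode(counts) <- "integer"
  ld <- read.delim(lengths_file)
  m <- regmatches(colnames(counts),
                  regexec("^(sham|ischemic)_s(\\d+)_f(\\d+)$", colnames(counts)))
  if (any(lengths(m) != 4))
    stop("sample ids must have the form condition_sN_fM")
  meta <- data.frame(sample = colnames(counts),
                     condition = vapply(m, `[`, "", 2),
                     subject = as.integer(vapply(m, `[`, "", 3)),
                     fragment = as.integer(vapply(m, `[`, "", 4)))
  list(counts = counts,
       gene_lengths = setNames(ld$length_bp, ld$gene), meta = meta)
}
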