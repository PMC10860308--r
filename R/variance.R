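#' Bartlett's test of homogeneity of variances
#'
#' Direct evaluation of Bartlett's corrected likelihood-ratio statistic
#' K^2 = [(N-k) ln S_p^2 - sum (n_i-1) ln S_i^2] /
#'       [1 + (sum 1/(n_i-1) - 1/(N-k)) / (3(k-1))]
#' referred to a chi-squared distribution with k-1 degrees of freedom. A
#' group with zero variance makes the statistic undefined; the result is
#' then flagged not-computable rather than thrown, so per-gene scans can
#' record and move on.
#'
#' @param groups List of numeric vectors, one per group (k >= 2 groups,
#'   each with at least 2 observations).
#' @return List with `K2`, `df` (= k-1), `p` (upper tail) and `computable`;
#'   `K2` and `p` are `NA` when any group variance is zero.
#' @export
bartlett_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  n <- lengths(groups)
  if (any(n < 2)) stop("each group needs at least 2 observations",
                       call. = FALSE)
  k <- length(groups)
  v <- vapply(groups, stats::var, 0)
  if (any(v <= 0)) {
    return(list(K2 = NA_real_, df = k - 1L, p = NA_real_,
                computable = FALSE))
  }
  N <- sum(n)
  sp2 <- sum((n - 1) * v) / (N - k)
  num <- (N - k) * log(sp2) - sum((n - 1) * log(v))
  den <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  K2 <- num / den
  list(K2 = K2, df = k - 1L,
       p = stats::pchisq(K2, k - 1, lower.tail = FALSE), computable = TRUE)
}

# vectorized Bartlett over the rows of a value matrix, with groups given by
# a factor over columns; returns K2/p per row, NA where not computable
bartlett_rows <- function(x, f) {
  f <- droplevels(as.factor(f))
  k <- nlevels(f)
  if (k < 2) stop("factor has fewer than 2 levels", call. = FALSE)
  n <- as.vector(table(f))
  if (any(n < 2)) stop("each group needs at least 2 eggs", call. = FALSE)
  G <- nrow(x)
  v <- matrix(NA_real_, G, k)
  for (j in seq_len(k)) {
    xa <- x[, f == levels(f)[j], drop = FALSE]
    m <- rowMeans(xa)
    v[, j] <- rowSums((xa - m)^2) / (n[j] - 1)
  }
  computable <- rowSums(v <= 0) == 0
  N <- sum(n)
  sp2 <- as.vector(v %*% (n - 1)) / (N - k)
  num <- (N - k) * log(sp2) - as.vector(log(v) %*% (n - 1))
  den <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  K2 <- ifelse(computable, num / den, NA_real_)
  list(K2 = K2, df = k - 1L,
       p = stats::pchisq(K2, k - 1, lower.tail = FALSE),
       computable = computable)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Per-gene Bartlett variance tests for genotype, stress and interaction
#'
#' For every gene, tests homogeneity of TPM variance across (i) maternal
#' genotype levels, (ii) maternal stress conditions (C vs H) and (iii) the
#' genotype-by-stress cells (the individual clutches of a full design) —
#' the per-gene machinery behind the gene-panel variance reports. A factor
#' with fewer than 2 levels skips its column with a warning. Significance
#' flags use the Bonferroni threshold `alpha / n_tests`, where `n_tests`
#' defaults to the number of genes with all requested tests computable
#' (recorded in the attributes).
#'
#' @param em TPM matrix.
#' @param meta Per-egg metadata with `genotype` and `stress` columns.
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Override for the Bonferroni family size, e.g. the gene
#'   count of a larger family the table belongs to.
#' @param log_transform Test log-transformed values (`log(TPM + 1)`)
#'   instead of raw TPM. Off by default: the heterogeneity analysis works
#'   on the TPM scale.
#' @return data.frame with per-gene `p_genotype`, `p_interaction`,
#'   `p_stress` and `sig_*` flags; attributes `threshold` and `n_tests`.
#' @export
per_gene_variance_tests <- function(em, meta, alpha = 0.05, n_tests = NULL,
                                    log_transform = FALSE) {
  meta <- align_meta(sample_meta(meta), colnames(em))
  x <- if (log_transform) log(em + 1) else em
  out <- data.frame(gene_id = rownames(em), row.names = NULL,
                    stringsAsFactors = FALSE)
  factors <- list(
    genotype = meta$genotype,
    interaction = interaction(meta$genotype, meta$stress, drop = TRUE),
    stress = meta$stress
  )
  computable_all <- rep(TRUE, nrow(em))
  for (nm in names(factors)) {
    f <- droplevels(as.factor(factors[[nm]]))
    col <- paste0("p_", nm)
    if (nlevels(f) < 2) {
      warning("factor '", nm, "' has fewer than 2 levels; test skipped")
      out[[col]] <- NA_real_
      next
    }
    bt <- bartlett_rows(x, f)
    out[[col]] <- bt$p
    computable_all <- computable_all & bt$computable
  }
  if (is.null(n_tests)) n_tests <- sum(computable_all)
  thr <- bonferroni_threshold(alpha, n_tests)
  for (nm in names(factors)) {
    p <- out[[paste0("p_", nm)]]
    if (!is.null(p)) out[[paste0("sig_", nm)]] <- !is.na(p) & p < thr
  }
  attr(out, "threshold") <- thr
  attr(out, "n_tests") <- n_tests
  attr(out, "n_computable") <- sum(computable_all)
  out
}

#' Global Bartlett test of variance homogeneity across a design factor
#'
#' Pools the TPM values of all genes after standardizing each gene by its
#' grand mean (so genes with different abundance contribute on a common
#' scale), groups the pooled values by the levels of one design factor
#' (e.g. stress or genotype) and applies Bartlett's test. Genes with grand
#' mean zero cannot be standardized and are excluded. The pooling
#' construction is one of several possible readings of a "global"
#' variance-homogeneity test and is documented in the methods vignette.
#'
#' @param em TPM matrix.
#' @param meta Per-egg metadata.
#' @param factor_name Metadata column to group by (`"stress"`,
#'   `"genotype"`, ...).
#' @return As [bartlett_test()], plus `n_genes_used`.
#' @export
global_homogeneity_test <- function(em, meta, factor_name) {
  meta <- align_meta(sample_meta(meta), colnames(em))
  if (!factor_name %in% names(meta)) {
    stop("metadata has no column '", factor_name, "'", call. = FALSE)
  }
  f <- droplevels(as.factor(meta[[factor_name]]))
  if (nlevels(f) < 2) {
    stop("factor '", factor_name, "' has fewer than 2 levels", call. = FALSE)
  }
  gm <- rowMeans(em)
  keep <- gm > 0
  z <- em[keep, , drop = FALSE] / gm[keep]
  groups <- lapply(levels(f), function(l) {
    as.vector(z[, f == l, drop = FALSE])
  })
  res <- bartlett_test(groups)
  res$n_genes_used <- sum(keep)
  res
}

#' Gene-by-environment interaction test on variance structure
#'
#' Asks whether the between-egg variance structure of the transcriptome
#' depends on the environmental factor beyond a gene-wise baseline: the
#' Bartlett statistic for grouping values by gene-by-factor cell is
#' compared with the statistic for grouping by gene alone; under the null
#' of no interaction the difference is referred to a chi-squared
#' distribution with the difference of the degrees of freedom. Genes with a
#' zero-variance cell are excluded (tallied in the result). This nested-
#' grouping construction is the package's reading of an "interaction"
#' variance test and is discussed in the methods vignette.
#'
#' @param em TPM matrix.
#' @param meta Per-egg metadata.
#' @param factor_name Environmental factor column (default `"stress"`).
#' @return List with `K2` (statistic difference), `df`, `p`,
#'   `n_genes_used`, `n_genes_excluded`.
#' @export
gene_environment_interaction_test <- function(em, meta,
                                              factor_name = "stress") {
  meta <- align_meta(sample_meta(meta), colnames(em))
  f <- droplevels(as.factor(meta[[factor_name]]))
  if (nlevels(f) < 2) {
    stop("factor '", factor_name, "' has fewer than 2 levels", call. = FALSE)
  }
  cell <- bartlett_rows(em, f)
  n <- as.vector(table(f))
  keep <- cell$computable & apply(em, 1, stats::var) > 0
  if (!any(keep)) stop("no gene usable for the interaction test",
                       call. = FALSE)
  x <- em[keep, , drop = FALSE]
  G <- nrow(x)
  k <- nlevels(f)
  # grouping by gene alone: one group per gene, values = that gene's eggs
  by_gene <- bartlett_test(split(as.vector(t(x)),
                                 rep(seq_len(G), each = ncol(x))))
  # grouping by gene x factor cell
  cells <- vector("list", G * k)
  idx <- 1L
  for (j in seq_len(k)) {
    xa <- x[, f == levels(f)[j], drop = FALSE]
    for (g in seq_len(G)) {
      cells[[(j - 1L) * G + g]] <- xa[g, ]
    }
  }
  by_cell <- bartlett_test(cells)
  K2 <- by_cell$K2 - by_gene$K2
  df <- by_cell$df - by_gene$df
  list(K2 = K2, df = df,
       p = stats::pchisq(K2, df, lower.tail = FALSE),
       n_genes_used = G, n_genes_excluded = sum(!keep))
}
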