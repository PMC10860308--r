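#' Per-gene moments and CV-squared within one clutch
#'
#' For every gene, the mean, unbiased (n-1) variance and squared coefficient
#' of variation CV^2 = variance / mean^2 of TPM across the eggs of one
#' clutch — the heterogeneity statistic of the analysis. Genes with mean 0
#' in the clutch have no defined CV^2 and are flagged.
#'
#' @param em TPM matrix (genes x eggs).
#' @param meta Per-egg metadata containing a `clutch` column.
#' @param clutch Clutch label to summarize.
#' @return data.frame with columns `gene_id`, `n`, `mean`, `var`, `cv2`,
#'   `defined` (mean > 0).
#' @export
clutch_moments <- function(em, meta, clutch) {
  meta <- align_meta(sample_meta(meta), colnames(em))
  eggs <- meta$egg_id[meta$clutch == clutch]
  if (!length(eggs)) {
    stop("clutch not present in metadata: ", clutch, call. = FALSE)
  }
  if (length(eggs) < 2) {
    stop("clutch ", clutch, " has fewer than 2 eggs", call. = FALSE)
  }
  x <- em[, eggs, drop = FALSE]
  n <- ncol(x)
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (n - 1)
  cv2 <- ifelse(m > 0, v / m^2, NA_real_)
  data.frame(gene_id = rownames(em), n = n, mean = m, var = v, cv2 = cv2,
             defined = m > 0, row.names = NULL, stringsAsFactors = FALSE)
}

#' Log10 CV-squared ratio between a stressed and a control clutch
#'
#' Joins the moment tables of an H (maternal heat stress) and a C (control)
#' clutch over their common gene universe and computes
#' log10(CV^2_H / CV^2_C) per gene. The ratio is defined only where both
#' CV^2 are strictly positive; other genes are kept in the table with
#' `defined = FALSE` and excluded from all summaries. Exclusion reasons are
#' tallied in the `exclusions` attribute.
#'
#' @param momH,momC Moment tables from [clutch_moments()] sharing one gene
#'   universe.
#' @return data.frame (`ratio_table`) with columns `gene_id`, `avg_C`,
#'   `avg_H`, `var_C`, `var_H`, `cv2_C`, `cv2_H`, `log10_ratio`, `defined`,
#'   `P5`, `M5` (outlier flags, all zero until [call_fold_outliers()]).
#' @export
cv2_log_ratio <- function(momH, momC) {
  if (!setequal(momH$gene_id, momC$gene_id)) {
    stop("moment tables do not share a gene universe", call. = FALSE)
  }
  momC <- momC[match(momH$gene_id, momC$gene_id), ]
  ok <- !is.na(momH$cv2) & !is.na(momC$cv2) & momH$cv2 > 0 & momC$cv2 > 0
  if (!any(ok)) {
    stop("no gene with positive CV^2 in both clutches", call. = FALSE)
  }
  rt <- data.frame(gene_id = momH$gene_id,
                   avg_C = momC$mean, avg_H = momH$mean,
                   var_C = momC$var, var_H = momH$var,
                   cv2_C = momC$cv2, cv2_H = momH$cv2,
                   log10_ratio = ifelse(ok, log10(momH$cv2 / momC$cv2),
                                        NA_real_),
                   defined = ok, P5 = 0L, M5 = 0L,
                   row.names = NULL, stringsAsFactors = FALSE)
  attr(rt, "exclusions") <- c(
    undefined_H = sum(is.na(momH$cv2) | momH$cv2 == 0),
    undefined_C = sum(is.na(momC$cv2) | momC$cv2 == 0),
    excluded_total = sum(!ok)
  )
  rt
}

#' Summarize a ratio table
#'
#' @param rt Ratio table from [cv2_log_ratio()].
#' @return List with `mean_log10_ratio`, `n_decreasing` (log10 ratio < 0),
#'   `n_defined`, `pct_decreasing` (100 * n_decreasing / n_defined).
#' @export
summarize_ratios <- function(rt) {
  r <- rt$log10_ratio[rt$defined]
  if (!length(r)) stop("no defined ratios to summarize", call. = FALSE)
  n_dec <- sum(r < 0)
  list(mean_log10_ratio = mean(r),
       n_decreasing = n_dec,
       n_defined = length(r),
       pct_decreasing = 100 * n_dec / length(r))
}

#' Flag genes with a fold-change in CV-squared
#'
#' Marks genes whose CV^2 ratio H/C reaches `fold` (`P5` = variance-inflated
#' under stress) or 1/`fold` (`M5` = variance-suppressed). Thresholds are
#' inclusive; undefined genes are never flagged.
#'
#' @param rt Ratio table from [cv2_log_ratio()].
#' @param fold Fold threshold (> 1); default 5.
#' @return The ratio table with `P5`/`M5` columns set to 0/1.
#' @export
call_fold_outliers <- function(rt, fold = 5) {
  if (!is.finite(fold) || fold <= 1) {
    stop("fold threshold must exceed 1", call. = FALSE)
  }
  ratio <- rt$cv2_H / rt$cv2_C
  rt$P5 <- as.integer(rt$defined & ratio >= fold)
  rt$M5 <- as.integer(rt$defined & ratio <= 1 / fold)
  rt
}

#' Intersect two outlier gene sets
#'
#' @param setA,setB Character vectors of gene IDs.
#' @return Sorted character vector of the exact intersection.
#' @export
overlap_outliers <- function(setA, setB) {
  sort(intersect(setA, setB))
}

# gene IDs carrying a given flag in a ratio table
flagged_genes <- function(rt, flag = c("P5", "M5")) {
  flag <- match.arg(flag)
  rt$gene_id[rt[[flag]] == 1L]
}
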