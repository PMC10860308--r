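#' Drop low-quality eggs
#'
#' Removes egg columns in which fewer than `min_detected_genes` genes have a
#' nonzero count — the single-egg libraries that yielded almost no usable
#' signal. Removed egg IDs are reported via `message()`.
#'
#' @param cm A [count_matrix].
#' @param min_detected_genes Minimum number of genes with count > 0 for an
#'   egg to be retained. The default of 200 operationalizes "almost no gene
#'   showing any expression"; tune to the depth of the protocol at hand.
#' @return The filtered [count_matrix].
#' @export
filter_low_quality_eggs <- function(cm, min_detected_genes = 200L) {
  stopifnot(inherits(cm, "count_matrix"), min_detected_genes >= 0)
  detected <- colSums(cm$counts > 0)
  keep <- detected >= min_detected_genes
  if (!any(keep)) {
    stop("all eggs fall below the detection threshold (",
         min_detected_genes, " genes)", call. = FALSE)
  }
  if (any(!keep)) {
    message("removing ", sum(!keep), " low-quality egg(s): ",
            paste(colnames(cm$counts)[!keep], collapse = ", "))
  }
  subset_cm(cm, eggs = which(keep))
}

#' Keep genes expressed in a majority of eggs
#'
#' Retains gene models with a nonzero count in strictly more than `fraction`
#' of all egg columns ("expression in over 50% of samples"). Spike-in genes
#' are always dropped at this step: they are controls, not gene models.
#'
#' @param cm A [count_matrix].
#' @param fraction Required expressed fraction, in `[0, 1)`; the comparison
#'   is strict, so a gene seen in exactly half the eggs is dropped at the
#'   default 0.5.
#' @return The filtered [count_matrix].
#' @export
filter_genes_expressed_majority <- function(cm, fraction = 0.5) {
  stopifnot(inherits(cm, "count_matrix"), fraction >= 0, fraction < 1)
  frac_nz <- rowMeans(cm$counts > 0)
  keep <- frac_nz > fraction & !cm$spikein
  if (!any(keep)) {
    stop("no gene expressed in more than ", 100 * fraction, "% of eggs",
         call. = FALSE)
  }
  subset_cm(cm, genes = which(keep))
}

#' TPM-normalize a count matrix
#'
#' Transcripts per million over the retained genes: per egg, each count is
#' divided by the gene length in kilobases and the resulting rates are
#' scaled to sum to 10^6. Run after gene filtering; columns are not
#' re-scaled by any later filter.
#'
#' @param cm A [count_matrix] whose eggs all have at least one nonzero
#'   count over the retained genes.
#' @return Numeric matrix of TPM values (genes x eggs); every column sums
#'   to 10^6.
#' @export
tpm_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  zero_eggs <- colSums(cm$counts) == 0
  if (any(zero_eggs)) {
    stop("egg(s) with all-zero counts over retained genes: ",
         paste(colnames(cm$counts)[zero_eggs], collapse = ", "),
         "; run filter_low_quality_eggs() first", call. = FALSE)
  }
  rate <- cm$counts / (cm$lengths / 1000)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Keep genes detected in a minimum fraction of eggs (TPM scale)
#'
#' Retains genes with TPM > 0 in strictly more than `fraction` of all eggs
#' pooled across clutches ("values above zero for over 20% of all the
#' single-egg transcriptome samples"). TPM values are deliberately left
#' unchanged: normalization happens once, before this filter.
#'
#' @param em TPM matrix from [tpm_normalize()].
#' @param fraction Required nonzero fraction, in `[0, 1)`; strict
#'   comparison.
#' @return The row-subset TPM matrix.
#' @export
filter_genes_min_nonzero <- function(em, fraction = 0.2) {
  stopifnot(is.matrix(em), fraction >= 0, fraction < 1)
  keep <- rowMeans(em > 0) > fraction
  if (!any(keep)) {
    stop("no gene with TPM > 0 in more than ", 100 * fraction, "% of eggs",
         call. = FALSE)
  }
  em[keep, , drop = FALSE]
}

#' Run the full filtering and normalization chain
#'
#' Fixed order: egg quality control, majority-expression gene filter, TPM
#' normalization, minimum-detection gene filter. Gene and egg tallies after
#' every stage are recorded so a run can be audited.
#'
#' @param cm A [count_matrix].
#' @param meta Per-egg metadata; returned subset to the retained eggs.
#' @param min_detected_genes Egg QC threshold (see
#'   [filter_low_quality_eggs()]).
#' @param majority_fraction Gene filter on raw counts (default 0.5).
#' @param nonzero_fraction Gene filter on TPM (default 0.2).
#' @return List with `tpm` (filtered TPM matrix), `meta` (aligned metadata)
#'   and `log` (data.frame of gene/egg counts after each stage).
#' @export
prepare_expression <- function(cm, meta, min_detected_genes = 200L,
                               majority_fraction = 0.5,
                               nonzero_fraction = 0.2) {
  meta <- sample_meta(meta)
  stages <- list(input = c(nrow(cm$counts), ncol(cm$counts)))
  cm <- filter_low_quality_eggs(cm, min_detected_genes)
  stages$egg_qc <- dim(cm$counts)
  cm <- filter_genes_expressed_majority(cm, majority_fraction)
  stages$majority_filter <- dim(cm$counts)
  em <- tpm_normalize(cm)
  stages$tpm <- dim(em)
  em <- filter_genes_min_nonzero(em, nonzero_fraction)
  stages$nonzero_filter <- dim(em)
  log <- data.frame(stage = names(stages),
                    n_genes = vapply(stages, `[`, 0, 1L),
                    n_eggs = vapply(stages, `[`, 0, 2L),
                    row.names = NULL)
  list(tpm = em, meta = align_meta(meta, colnames(em)), log = log)
}
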