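#' Single-egg count matrix
#'
#' Container for a gene-by-egg matrix of raw read counts together with the
#' per-gene annotation needed downstream: transcript length (for TPM) and a
#' spike-in flag (spike-ins are carried along but excluded from all
#' gene-model statistics).
#'
#' @param counts Integer matrix, genes in rows and eggs in columns, with
#'   unique rownames (gene IDs) and colnames (egg IDs).
#' @param lengths Positive integer vector of per-gene transcript lengths in
#'   bases, one per row of `counts`.
#' @param spikein Logical vector marking spike-in genes; defaults to all
#'   `FALSE`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `lengths` and `spikein`, all aligned to the gene IDs in
#'   `rownames(counts)`.
#' @export
count_matrix <- function(counts, lengths, spikein = NULL) {
  if (!is.matrix(counts)) {
    stop("`counts` must be a matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene IDs as rownames and egg IDs as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop("duplicate gene ID: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate egg IDs in count matrix", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1L, , drop = TRUE]
    stop("counts must be non-negative integers; offending gene ",
         rownames(counts)[bad[["row"]]], call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (length(lengths) != nrow(counts)) {
    stop("`lengths` must have one entry per gene", call. = FALSE)
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  if (is.null(spikein)) spikein <- rep(FALSE, nrow(counts))
  if (length(spikein) != nrow(counts) || !is.logical(spikein)) {
    stop("`spikein` must be a logical vector with one entry per gene",
         call. = FALSE)
  }
  lengths <- as.integer(round(lengths))
  names(lengths) <- rownames(counts)
  names(spikein) <- rownames(counts)
  structure(list(counts = counts, lengths = lengths, spikein = spikein),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d eggs (%d spike-ins)\n",
              nrow(x$counts), ncol(x$counts), sum(x$spikein)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# subset a count_matrix by gene and/or egg index, keeping annotation aligned
subset_cm <- function(cm, genes = NULL, eggs = NULL) {
  if (is.null(genes)) genes <- seq_len(nrow(cm$counts))
  if (is.null(eggs)) eggs <- seq_len(ncol(cm$counts))
  count_matrix(cm$counts[genes, eggs, drop = FALSE],
               cm$lengths[genes], cm$spikein[genes])
}

#' Per-egg sample metadata
#'
#' Validates and normalizes the egg-level design table: one row per egg with
#' its clutch label, the maternal genotype (cross lineage), the maternal
#' stress condition and a generation tag.
#'
#' @param meta A data.frame with columns `egg_id`, `clutch`, `genotype`,
#'   `stress` and optionally `generation` (defaulted to `"F1"`).
#'
#' @return The validated data.frame with character columns; `stress` must be
#'   `"C"` (control) or `"H"` (maternal heat stress).
#' @export
sample_meta <- function(meta) {
  need <- c("egg_id", "clutch", "genotype", "stress")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"generation" %in% names(meta)) meta$generation <- "F1"
  for (col in c("egg_id", "clutch", "genotype", "stress", "generation")) {
    meta[[col]] <- as.character(meta[[col]])
  }
  if (anyDuplicated(meta$egg_id)) {
    stop("duplicate egg_id in metadata", call. = FALSE)
  }
  bad <- setdiff(unique(meta$stress), c("C", "H"))
  if (length(bad)) {
    stop("stress must be 'C' or 'H'; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  meta
}

# metadata rows for the eggs present in a matrix, in column order
align_meta <- function(meta, egg_ids) {
  missing_eggs <- setdiff(egg_ids, meta$egg_id)
  if (length(missing_eggs)) {
    stop("eggs absent from metadata: ",
         paste(utils::head(missing_eggs, 5L), collapse = ", "), call. = FALSE)
  }
  meta[match(egg_ids, meta$egg_id), , drop = FALSE]
}
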