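#' Read a featureCounts-style count table
#'
#' Parses a tab-separated count table with a `Geneid` column, an optional
#' `Length` column, optional `Chr`/`Start`/`End`/`Strand` annotation columns
#' (skipped), and one numeric column per egg. Lines starting with `#`
#' (featureCounts writes its command line there) are ignored. An optional
#' `Spikein` column (0/1) marks spike-in genes.
#'
#' @param path Path to the TSV file.
#' @return A [count_matrix].
#' @export
read_counts <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"Geneid" %in% names(raw)) {
    stop("count table has no Geneid column: ", path, call. = FALSE)
  }
  gene_ids <- as.character(raw$Geneid)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ID in ", path, ": ",
         gene_ids[duplicated(gene_ids)][1L], call. = FALSE)
  }
  drop_cols <- intersect(c("Geneid", "Chr", "Start", "End", "Strand",
                           "Length", "Spikein"), names(raw))
  count_cols <- setdiff(names(raw), drop_cols)
  if (!length(count_cols)) {
    stop("count table has no egg columns: ", path, call. = FALSE)
  }
  counts <- as.matrix(raw[, count_cols, drop = FALSE])
  if (!is.numeric(counts)) {
    stop("non-numeric count cells in ", path, call. = FALSE)
  }
  bad <- which(counts != round(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count in ", path, ", gene ",
         gene_ids[bad[1L, "row"]], call. = FALSE)
  }
  rownames(counts) <- gene_ids
  if ("Length" %in% names(raw)) {
    lengths <- raw$Length
  } else {
    stop("count table has no Length column (required for TPM): ", path,
         call. = FALSE)
  }
  spikein <- if ("Spikein" %in% names(raw)) as.logical(raw$Spikein) else NULL
  count_matrix(counts, lengths, spikein)
}

#' Write a count matrix as a featureCounts-style TSV
#'
#' Inverse of [read_counts()]: columns `Geneid`, `Length`, `Spikein` and one
#' column per egg.
#'
#' @param cm A [count_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  out <- data.frame(Geneid = rownames(cm$counts),
                    Length = cm$lengths,
                    Spikein = as.integer(cm$spikein),
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(cm$counts, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-egg sample metadata from TSV
#'
#' @param path TSV with columns `egg_id`, `clutch`, `genotype`, `stress`
#'   and optionally `generation`.
#' @return A validated metadata data.frame (see [sample_meta()]).
#' @export
read_sample_meta <- function(path) {
  sample_meta(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write per-egg sample metadata to TSV
#'
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(sample_meta(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
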