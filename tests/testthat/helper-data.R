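# small fixtures built in code

# count_matrix from a plain matrix, defaulting lengths to 1 kb
make_cm <- function(m, lengths = rep(1000L, nrow(m)), spikein = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("egg", seq_len(ncol(m)))
  count_matrix(m, lengths, spikein)
}

# metadata for a two-clutch H/C design over the columns of a matrix
make_meta <- function(egg_ids, clutch) {
  stress <- ifelse(grepl("H", clutch), "H", "C")
  sample_meta(data.frame(egg_id = egg_ids, clutch = clutch,
                         genotype = "BB", stress = stress,
                         generation = "F1"))
}

# compact two-clutch scenario used across tests
two_clutch_config <- function(...) {
  sim_config(clutches = data.frame(
    label = c("BBC", "BBH"), genotype = "BB", stress = c("C", "H"),
    n_eggs = c(14L, 16L), generation = "F1"), ...)
}
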