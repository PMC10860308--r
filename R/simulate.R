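#' Configuration for the single-egg count simulator
#'
#' Defines a Gamma--Poisson generative model for single-egg RNA-seq counts.
#' Each gene g has a baseline relative abundance mu_g drawn log-normally and
#' a baseline biological squared coefficient of variation (overdispersion)
#' phi_g, also log-normal. In clutches listed in `inflated_clutches`, a
#' fraction `inflated_fraction` of genes has phi multiplied by
#' `inflation_factor` -- the known heterogeneity shift the analysis is asked
#' to recover. Per-egg expression is x_ge ~ Gamma(shape 1/phi_gc, mean mu_g);
#' counts are Poisson with rate L_e * x_ge / sum_g(x_ge), where the library
#' size L_e is log-normal with the stated mean and coefficient of variation.
#' Spike-in genes have phi = 0 (Poisson noise only) and are flagged.
#'
#' @param n_genes Number of gene models to simulate.
#' @param clutches data.frame with columns `label`, `genotype`, `stress`,
#'   `n_eggs` and optionally `generation`; defaults to the six-clutch design
#'   of [default_clutches()].
#' @param mu_log_mean,mu_log_sd Natural-log mean and sd of the baseline
#'   abundance distribution (TPM-like scale).
#' @param phi_log_mean,phi_log_sd Natural-log mean and sd of the baseline
#'   biological CV^2 distribution.
#' @param inflation_factor Multiplier applied to phi_g for inflated genes in
#'   inflated clutches (> 0; 1 disables any shift).
#' @param inflated_fraction Fraction of genes receiving the inflation.
#' @param inflated_clutches Character vector of clutch labels in which the
#'   inflation acts (typically the stressed clutches).
#' @param library_size_mean,library_size_cv Mean and coefficient of
#'   variation of the per-egg sequencing depth.
#' @param n_spikein Number of spike-in genes (fixed biological abundance).
#' @param dropout_rate Probability that an expressed gene yields zero counts
#'   in an egg, independently per cell of the matrix.
#' @param seed Master seed; all randomness derives from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       clutches = default_clutches(),
                       mu_log_mean = 3, mu_log_sd = 1.5,
                       phi_log_mean = log(0.1), phi_log_sd = 0.6,
                       inflation_factor = 1,
                       inflated_fraction = 0,
                       inflated_clutches = character(0),
                       library_size_mean = 1e6, library_size_cv = 0.3,
                       n_spikein = 0L,
                       dropout_rate = 0,
                       seed = 1L) {
  clutches <- as.data.frame(clutches, stringsAsFactors = FALSE)
  need <- c("label", "genotype", "stress", "n_eggs")
  if (!all(need %in% names(clutches))) {
    stop("clutches needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"generation" %in% names(clutches)) clutches$generation <- "F1"
  if (any(clutches$n_eggs < 2)) {
    stop("each clutch needs at least 2 eggs", call. = FALSE)
  }
  if (anyDuplicated(clutches$label)) {
    stop("clutch labels must be unique", call. = FALSE)
  }
  stopifnot(n_genes >= 1,
            is.finite(inflation_factor), inflation_factor > 0,
            inflated_fraction >= 0, inflated_fraction <= 1,
            dropout_rate >= 0, dropout_rate < 1,
            is.finite(mu_log_mean), mu_log_sd >= 0,
            is.finite(phi_log_mean), phi_log_sd >= 0,
            library_size_mean > 0, library_size_cv >= 0,
            n_spikein >= 0)
  unknown <- setdiff(inflated_clutches, clutches$label)
  if (length(unknown)) {
    stop("inflated_clutches not in design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), clutches = clutches,
                 mu_log_mean = mu_log_mean, mu_log_sd = mu_log_sd,
                 phi_log_mean = phi_log_mean, phi_log_sd = phi_log_sd,
                 inflation_factor = inflation_factor,
                 inflated_fraction = inflated_fraction,
                 inflated_clutches = inflated_clutches,
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 n_spikein = as.integer(n_spikein),
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' The six-clutch study design
#'
#' Clutch labels, maternal genotypes, stress conditions, generations and the
#' exact egg counts of the study design this package emulates: a type-B
#' conspecific cross (BBC n=14, BBH n=16 eggs), an AB hybrid cross (ABC
#' n=37, ABH n=36) and its unstressed F2 generation (ABCB n=32, ABHB n=43).
#'
#' @return A data.frame with one row per clutch.
#' @export
default_clutches <- function() {
  data.frame(
    label = c("BBC", "BBH", "ABC", "ABH", "ABCB", "ABHB"),
    genotype = c("BB", "BB", "AB", "AB", "ABB", "ABB"),
    stress = c("C", "H", "C", "H", "C", "H"),
    n_eggs = c(14L, 16L, 37L, 36L, 32L, 43L),
    generation = c("F1", "F1", "F1", "F1", "F2", "F2"),
    stringsAsFactors = FALSE
  )
}

# deterministic per-clutch substream seed: adding a clutch to the design
# must not perturb the counts drawn for earlier clutches
clutch_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 69621) %% 2147483587) + 1L
}

#' Simulate single-egg count matrices with known ground truth
#'
#' Draws gene-level parameters once from the master seed, then each clutch
#' from its own deterministic substream, so the counts of a clutch depend
#' only on the master seed, the gene panel and the clutch's position in the
#' design. See [sim_config()] for the generative model.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix] including any
#'   spike-in rows), `meta` (per-egg metadata) and `truth` (per-gene
#'   data.frame: `mu`, `phi`, `inflated`, one `phi_<label>` column with the
#'   effective overdispersion and one `exp_cv2_<label>` column with the
#'   expected total CV^2 `phi_gc + 1/E[count]` per clutch).
#' @export
simulate_clutches <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$clutches
  G <- config$n_genes

  set.seed(config$seed)
  mu <- stats::rlnorm(G, config$mu_log_mean, config$mu_log_sd)
  phi <- stats::rlnorm(G, config$phi_log_mean, config$phi_log_sd)
  n_inf <- round(config$inflated_fraction * G)
  inflated <- rep(FALSE, G)
  if (n_inf > 0) inflated[sample.int(G, n_inf)] <- TRUE
  lengths <- pmax(200L, as.integer(round(stats::rlnorm(G, log(1500), 0.7))))
  gene_ids <- sprintf("SIM.Chr%d.%d", 1L + (seq_len(G) - 1L) %% 14L,
                      seq_len(G))
  spike_mu <- spike_len <- numeric(0)
  if (config$n_spikein > 0) {
    spike_mu <- stats::rlnorm(config$n_spikein, config$mu_log_mean,
                              config$mu_log_sd)
    spike_len <- pmax(200L, as.integer(round(
      stats::rlnorm(config$n_spikein, log(1000), 0.3))))
  }
  spike_ids <- sprintf("SPIKE-%04d", seq_len(config$n_spikein))

  mu_all <- c(mu, spike_mu)
  n_all <- G + config$n_spikein
  ls_sdlog <- sqrt(log(1 + config$library_size_cv^2))
  ls_meanlog <- log(config$library_size_mean) - ls_sdlog^2 / 2

  mats <- vector("list", nrow(cl))
  meta <- vector("list", nrow(cl))
  truth <- data.frame(gene_id = gene_ids, mu = mu, phi = phi,
                      inflated = inflated, stringsAsFactors = FALSE)

  for (i in seq_len(nrow(cl))) {
    lab <- cl$label[i]
    n_eggs <- cl$n_eggs[i]
    phi_c <- phi
    if (lab %in% config$inflated_clutches) {
      phi_c[inflated] <- phi[inflated] * config$inflation_factor
    }
    set.seed(clutch_seed(config$seed, i))
    lib <- stats::rlnorm(n_eggs, ls_meanlog, ls_sdlog)
    shape <- 1 / phi_c
    k <- matrix(0L, n_all, n_eggs)
    for (e in seq_len(n_eggs)) {
      x <- mu
      pos <- phi_c > 0
      x[pos] <- stats::rgamma(sum(pos), shape = shape[pos],
                              scale = mu[pos] * phi_c[pos])
      x_all <- c(x, spike_mu)
      cnt <- stats::rpois(n_all, lib[e] * x_all / sum(x_all))
      if (config$dropout_rate > 0) {
        cnt[stats::runif(n_all) < config$dropout_rate] <- 0L
      }
      k[, e] <- cnt
    }
    colnames(k) <- sprintf("%s_%02d", lab, seq_len(n_eggs))
    mats[[i]] <- k
    meta[[i]] <- data.frame(egg_id = colnames(k), clutch = lab,
                            genotype = cl$genotype[i], stress = cl$stress[i],
                            generation = cl$generation[i],
                            stringsAsFactors = FALSE)
    truth[[paste0("phi_", lab)]] <- phi_c
    exp_count <- config$library_size_mean * mu / sum(mu_all)
    truth[[paste0("exp_cv2_", lab)]] <- phi_c + 1 / exp_count
  }

  counts <- do.call(cbind, mats)
  rownames(counts) <- c(gene_ids, spike_ids)
  cm <- count_matrix(counts, c(lengths, spike_len),
                     c(rep(FALSE, G), rep(TRUE, config$n_spikein)))
  list(counts = cm, meta = sample_meta(do.call(rbind, meta)), truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the three TSVs a simulation scenario produces: a featureCounts-style
#' count table, the per-egg metadata and the per-gene truth table.
#'
#' @param sim Result of [simulate_clutches()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(sim$counts, paths[["counts"]])
  write_sample_meta(sim$meta, paths[["meta"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
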