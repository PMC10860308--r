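#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: either paths to a count TSV
#' and a metadata TSV, or a simulation scenario; the filter parameters; the
#' list of H-vs-C clutch comparisons; optional gene panels of interest; and
#' the output directory.
#'
#' @param counts,meta Paths to a featureCounts-style count TSV and a
#'   metadata TSV (mutually exclusive with `scenario`).
#' @param scenario A [sim_config()] to simulate inputs instead of reading
#'   them.
#' @param out_dir Output directory for reports.
#' @param comparisons List of named pairs `c(H = "<stressed clutch>",
#'   C = "<control clutch>")`; `NULL` derives one comparison per
#'   genotype-generation lineage that has exactly one H and one C clutch.
#' @param min_detected_genes,majority_fraction,nonzero_fraction Filter
#'   parameters (see [prepare_expression()]).
#' @param fold CV^2 fold threshold for outlier calling (default 5).
#' @param alpha Family-wise error rate for Bonferroni control.
#' @param panels Named list of gene-ID vectors to report as panels.
#' @param exclude_genes Gene IDs removed before any analysis (e.g. rRNA
#'   models counted separately upstream).
#' @param ancova_response `"cv2"` or `"log10cv2"`.
#' @param seed Seed fixed at the start of the run for reproducibility.
#' @return List of class `run_config`.
#' @export
run_config <- function(counts = NULL, meta = NULL, scenario = NULL,
                       out_dir = tempfile("clutchvar_run_"),
                       comparisons = NULL,
                       min_detected_genes = 200L,
                       majority_fraction = 0.5, nonzero_fraction = 0.2,
                       fold = 5, alpha = 0.05,
                       panels = list(), exclude_genes = character(0),
                       ancova_response = "cv2", seed = 1L) {
  have_files <- !is.null(counts) && !is.null(meta)
  if (!have_files && is.null(scenario)) {
    stop("give either counts+meta paths or a simulation scenario",
         call. = FALSE)
  }
  if (have_files && !is.null(scenario)) {
    stop("counts/meta and scenario are mutually exclusive", call. = FALSE)
  }
  if (!is.null(scenario) && !inherits(scenario, "sim_config")) {
    stop("scenario must be a sim_config", call. = FALSE)
  }
  if (!is.null(comparisons)) {
    if (!length(comparisons)) {
      stop("comparison list must not be empty", call. = FALSE)
    }
    for (cmp in comparisons) {
      if (!all(c("H", "C") %in% names(cmp))) {
        stop("each comparison needs named elements H and C", call. = FALSE)
      }
    }
  }
  structure(list(counts = counts, meta = meta, scenario = scenario,
                 out_dir = out_dir, comparisons = comparisons,
                 min_detected_genes = min_detected_genes,
                 majority_fraction = majority_fraction,
                 nonzero_fraction = nonzero_fraction,
                 fold = fold, alpha = alpha, panels = panels,
                 exclude_genes = exclude_genes,
                 ancova_response = ancova_response,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `scenario`
#' section holds [sim_config()] arguments (with `clutches` as a list of
#' records); `comparisons` is a list of `{H: ..., C: ...}` records.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) {
    sc <- y$scenario
    if (!is.null(sc$clutches)) {
      sc$clutches <- do.call(rbind, lapply(sc$clutches, as.data.frame))
    }
    y$scenario <- do.call(sim_config, sc)
  }
  if (!is.null(y$comparisons)) {
    y$comparisons <- lapply(y$comparisons, unlist)
  }
  if (!is.null(y$panels)) y$panels <- lapply(y$panels, as.character)
  do.call(run_config, y)
}

# one H-vs-C comparison per genotype+generation lineage, when unambiguous
derive_comparisons <- function(meta) {
  key <- paste(meta$genotype, meta$generation)
  cmps <- list()
  for (k in unique(key)) {
    sub <- unique(meta[key == k, c("clutch", "stress")])
    if (sum(sub$stress == "H") == 1 && sum(sub$stress == "C") == 1) {
      cmps[[length(cmps) + 1L]] <- c(H = sub$clutch[sub$stress == "H"],
                                     C = sub$clutch[sub$stress == "C"])
    }
  }
  if (!length(cmps)) stop("no H-vs-C clutch pair derivable from metadata",
                          call. = FALSE)
  cmps
}

#' Run the full heterogeneity pipeline
#'
#' Loads (or simulates) counts and metadata, applies the filter chain,
#' computes per-comparison CV^2 ratio tables with five-fold outlier flags,
#' runs the per-gene and global variance tests over all clutches jointly,
#' fits the ANCOVA-style stress trend per comparison, and writes
#' per-comparison TSVs, panel reports, histogram/scatter data and a JSON
#' run summary to `cfg$out_dir`. All outputs are deterministic given the
#' seed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `tpm`, `meta`, `filter_log`,
#'   `comparisons` (per comparison: ratio table, summary, trend fit),
#'   `variance_tests`, `global_tests`, `interaction_test`, `overlaps`,
#'   `panels` and `summary` (the JSON content).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  if (!is.null(cfg$scenario)) {
    sim <- simulate_clutches(cfg$scenario)
    cm <- sim$counts
    meta <- sim$meta
  } else {
    cm <- read_counts(cfg$counts)
    meta <- read_sample_meta(cfg$meta)
  }
  if (length(cfg$exclude_genes)) {
    keep <- !(rownames(cm$counts) %in% cfg$exclude_genes)
    cm <- subset_cm(cm, genes = which(keep))
  }

  prep <- prepare_expression(cm, meta, cfg$min_detected_genes,
                             cfg$majority_fraction, cfg$nonzero_fraction)
  em <- prep$tpm
  meta <- prep$meta
  comparisons <- if (is.null(cfg$comparisons)) derive_comparisons(meta) else
    cfg$comparisons

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  cmp_results <- list()
  for (cmp in comparisons) {
    name <- paste0(cmp[["H"]], "_vs_", cmp[["C"]])
    momH <- clutch_moments(em, meta, cmp[["H"]])
    momC <- clutch_moments(em, meta, cmp[["C"]])
    rt <- call_fold_outliers(cv2_log_ratio(momH, momC), cfg$fold)
    smry <- summarize_ratios(rt)
    fit <- ancova_stress_trend(momH, momC, cfg$ancova_response)
    write_ratio_table(rt, file.path(cfg$out_dir,
                                    paste0(name, "_ratios.tsv")))
    write_hist_data(rt, file.path(cfg$out_dir, paste0(name, "_hist.tsv")))
    write_scatter_data(rt, file.path(cfg$out_dir,
                                     paste0(name, "_outlier_scatter.tsv")))
    cmp_results[[name]] <- list(comparison = cmp, ratios = rt,
                                summary = smry, trend = fit)
  }

  # outlier overlaps between every pair of comparisons, per flag direction
  overlaps <- list()
  nms <- names(cmp_results)
  if (length(nms) > 1) {
    for (i in seq_len(length(nms) - 1)) {
      for (j in seq((i + 1), length(nms))) {
        for (flag in c("P5", "M5")) {
          key <- paste(nms[i], nms[j], flag, sep = ".")
          overlaps[[key]] <- overlap_outliers(
            flagged_genes(cmp_results[[nms[i]]]$ratios, flag),
            flagged_genes(cmp_results[[nms[j]]]$ratios, flag))
        }
      }
    }
  }

  vt <- per_gene_variance_tests(em, meta, cfg$alpha)
  utils::write.table(vt, file.path(cfg$out_dir, "variance_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  global_tests <- list()
  for (fac in c("stress", "genotype")) {
    if (length(unique(meta[[fac]])) >= 2) {
      global_tests[[fac]] <- global_homogeneity_test(em, meta, fac)
    }
  }
  interaction_test <- gene_environment_interaction_test(em, meta, "stress")

  panel_reports <- list()
  for (nm in names(cfg$panels)) {
    panel_reports[[nm]] <- summarize_panels(vt, em, meta, cfg$panels[[nm]])
    utils::write.table(panel_reports[[nm]],
                       file.path(cfg$out_dir, paste0("panel_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = cfg$seed,
    filter_log = prep$log,
    bonferroni = list(alpha = cfg$alpha,
                      n_tests = attr(vt, "n_tests"),
                      threshold = attr(vt, "threshold")),
    comparisons = lapply(cmp_results, function(r) {
      c(r$summary,
        list(n_P5 = sum(r$ratios$P5), n_M5 = sum(r$ratios$M5),
             exclusions = as.list(attr(r$ratios, "exclusions")),
             ancova = r$trend$coefficients[
               r$trend$coefficients$term == "condition", c("estimate", "t",
                                                           "p")]))
    }),
    outlier_overlaps = lapply(overlaps, as.list),
    global_tests = global_tests,
    interaction_test = interaction_test
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(tpm = em, meta = meta, filter_log = prep$log,
                 comparisons = cmp_results, variance_tests = vt,
                 global_tests = global_tests,
                 interaction_test = interaction_test,
                 overlaps = overlaps, panels = panel_reports,
                 summary = summary))
}

#' Report the variance tests for a panel of genes of interest
#'
#' Subsets the per-gene variance-test table to a named gene panel (e.g. the
#' Hsp70/Hsp90 chaperones or a curated buffering-gene set) and appends
#' per-clutch mean TPM. Significance is judged at the Bonferroni threshold
#' of the full gene family, never of the panel alone. Panel IDs absent from
#' the filtered matrix are reported in the `not_tested` attribute with a
#' warning.
#'
#' @param vt Result of [per_gene_variance_tests()].
#' @param em TPM matrix.
#' @param meta Per-egg metadata.
#' @param panel Character vector of gene IDs.
#' @return data.frame with the panel's p-values, significance flags and
#'   per-clutch means; attribute `not_tested` lists missing IDs.
#' @export
summarize_panels <- function(vt, em, meta, panel) {
  if (!length(panel)) stop("panel must be nonempty", call. = FALSE)
  meta <- align_meta(sample_meta(meta), colnames(em))
  missing_ids <- setdiff(panel, vt$gene_id)
  if (length(missing_ids)) {
    warning("panel gene(s) not tested (absent after filtering): ",
            paste(missing_ids, collapse = ", "))
  }
  out <- vt[match(intersect(panel, vt$gene_id), vt$gene_id), , drop = FALSE]
  for (cl in unique(meta$clutch)) {
    eggs <- meta$egg_id[meta$clutch == cl]
    out[[paste0("mean_", cl)]] <-
      rowMeans(em[out$gene_id, eggs, drop = FALSE])
  }
  rownames(out) <- NULL
  attr(out, "not_tested") <- missing_ids
  attr(out, "threshold") <- attr(vt, "threshold")
  out
}

# Table-S3-style per-comparison output: averages, variances, CV^2 per
# condition, the log10 ratio, and '_P5'/'_M5' indicator columns
write_ratio_table <- function(rt, path) {
  out <- data.frame(gene_id = rt$gene_id, avg_C = rt$avg_C,
                    avg_H = rt$avg_H, var_C = rt$var_C, var_H = rt$var_H,
                    CV2_C = rt$cv2_C, CV2_H = rt$cv2_H,
                    log10_ratio = rt$log10_ratio,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out[["_P5"]] <- rt$P5
  out[["_M5"]] <- rt$M5
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# binned frequencies of the log10 CV^2 ratios (histogram source data)
write_hist_data <- function(rt, path, binwidth = 0.1) {
  r <- rt$log10_ratio[rt$defined]
  breaks <- seq(floor(min(r) / binwidth) * binwidth,
                ceiling(max(r) / binwidth) * binwidth, by = binwidth)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  utils::write.table(data.frame(bin_mid = h$mids, count = h$counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# H-vs-C mean expression of flagged genes (scatter source data)
write_scatter_data <- function(rt, path) {
  flagged <- rt$P5 == 1L | rt$M5 == 1L
  out <- data.frame(gene_id = rt$gene_id[flagged],
                    avg_C = rt$avg_C[flagged], avg_H = rt$avg_H[flagged],
                    flag = ifelse(rt$P5[flagged] == 1L, "P5", "M5"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
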