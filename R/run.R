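# High-level entry points backing the command-line interface.

#' Estimate normalization factors from read files
#'
#' Loads BED6/tagAlign reads for a ChIP and a control sample, shifts them
#' to fragment midpoints, runs the requested estimators and (optionally)
#' writes a TSV summary plus one JSON record per method.
#'
#' @param chip_path,control_path Paths to BED6/tagAlign read files.
#' @param chrom_sizes_path Path to a chrom.sizes file.
#' @param methods Estimators to run (default all five).
#' @param l Average fragment length in bp (default 200).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param format Input format passed to [load_reads()].
#' @return The [estimate_all()] result, invisibly when writing.
#' @export
run_estimate <- function(chip_path, control_path, chrom_sizes_path,
                         methods = c("ncis", "cisgenome", "spp", "ccat", "peakseq"),
                         l = 200, out_dir = NULL, format = "bed") {
  layout <- read_chrom_sizes(chrom_sizes_path)
  chip <- shift_reads(load_reads(chip_path, format, layout), l, layout)
  control <- shift_reads(load_reads(control_path, format, layout), l, layout)
  res <- estimate_all(chip, control, layout, methods = methods)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(res$summary, file.path(out_dir, "estimates.tsv"), sep = "\t")
    for (m in names(res$results)) {
      r <- res$results[[m]]
      if (is.null(r)) next
      rec <- r[c("method", "r_hat", "pi0_hat", "w_star", "t_star",
                 "n_background_bins", "depth_ratio", "flags")]
      rec$trace <- r$trace
      jsonlite::write_json(rec, file.path(out_dir, paste0(m, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    return(invisible(res))
  }
  res
}

#' Call sites with sample-swap FDR control from read files
#'
#' @inheritParams run_estimate
#' @param method Normalization method used for the caller's `r_hat`
#'   (one estimator name, or `"depth"` for the sequencing depth ratio).
#' @param config A [caller_config()].
#' @param truth_path Optional BED file of true sites for classification.
#' @return A list with the `swap_fdr_result`, the `normalization_result`
#'   used, and (when truth is given) the `eval_result`.
#' @export
run_evaluate <- function(chip_path, control_path, chrom_sizes_path,
                         method = "ncis", config = caller_config(), l = 200,
                         truth_path = NULL, out_dir = NULL, format = "bed") {
  layout <- read_chrom_sizes(chrom_sizes_path)
  chip <- shift_reads(load_reads(chip_path, format, layout), l, layout)
  control <- shift_reads(load_reads(control_path, format, layout), l, layout)
  if (method == "depth") {
    r_hat <- nrow(chip) / nrow(control)
    norm <- NULL
  } else {
    norm <- estimate_all(chip, control, layout, methods = method)$results[[method]]
    if (is.null(norm)) stop("normalization method '", method, "' failed on these samples")
    r_hat <- norm$r_hat
  }
  swap <- swap_fdr_call(chip, control, layout, r_hat, config)
  ev <- NULL
  if (!is.null(truth_path)) {
    tr <- data.table::fread(truth_path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1), data.table = FALSE)
    truth <- data.frame(chrom = tr[[1L]], pos = (tr[[2L]] + tr[[3L]]) / 2,
                        stringsAsFactors = FALSE)
    ev <- evaluate_calls(swap$declared, truth, config$match_dist)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sites(swap$declared, file.path(out_dir, "declared.bed"),
                file.path(out_dir, "declared.tsv"))
    rec <- list(method = method, r_hat = r_hat, threshold = swap$threshold,
                R_C = swap$R_C, R_I = swap$R_I,
                empirical_fdr = swap$empirical_fdr, flags = swap$flags,
                evaluation = if (!is.null(ev)) unclass(ev))
    jsonlite::write_json(rec, file.path(out_dir, "swap_fdr.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(swap = swap, normalization = norm, evaluation = ev)
}

#' Replicated simulation benchmark of the estimators
#'
#' For every combination of setting, signal proportion `c`, subsampling
#' divisor `d` and replicate, simulates a paired dataset, runs the selected
#' estimators and records their estimates; per-cell bias, variance and MSE
#' are summarized with [estimator_mse()]. Deterministic given the master
#' seed (replicate seeds are derived from it).
#'
#' @param layout A [genome_layout()].
#' @param settings Simulation settings to run (subset of `c(1, 2, 3)`).
#' @param c_values Signal proportions (default 1).
#' @param d_values Subsampling divisors (default `c(1, 5, 20)`).
#' @param n_reps Replicates per cell (default 10).
#' @param methods Estimators to run.
#' @param background_depth Background depth before subsampling.
#' @param seed Master seed.
#' @param ... Further arguments to [simulate_dataset()].
#' @return A list with `estimates` (one row per setting/c/d/replicate/
#'   method) and `summary` (per-cell bias, variance, MSE per method).
#' @export
run_benchmark <- function(layout, settings = 1, c_values = 1,
                          d_values = c(1, 5, 20), n_reps = 10,
                          methods = c("ncis", "cisgenome", "spp", "ccat", "peakseq"),
                          background_depth = 200000, seed = 1, ...) {
  grid <- expand.grid(setting = settings, c_signal = c_values, d = d_values,
                      rep = seq_len(n_reps), stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell_seed <- (seed * 10007L + g * 7919L) %% .Machine$integer.max
    sim <- simulate_dataset(layout, setting = grid$setting[g],
                            background_depth = background_depth,
                            c_signal = grid$c_signal[g], d = grid$d[g],
                            seed = cell_seed, ...)
    est <- estimate_all(sim$chip, sim$control, layout, methods = methods)
    s <- est$summary
    rows[[g]] <- cbind(setting = grid$setting[g], c_signal = grid$c_signal[g],
                       d = grid$d[g], rep = grid$rep[g], true_r = sim$true_r,
                       seed = cell_seed, s)
  }
  estimates <- do.call(rbind, rows)
  cells <- unique(estimates[c("setting", "c_signal", "d", "method")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- estimates$setting == cells$setting[i] &
      estimates$c_signal == cells$c_signal[i] & estimates$d == cells$d[i] &
      estimates$method == cells$method[i]
    r <- estimates$r_hat[sel]
    tr <- mean(estimates$true_r[sel])
    if (sum(is.finite(r)) >= 2L) {
      m <- estimator_mse(r, tr)
      cbind(cells[i, ], true_r = tr, mean_r = mean(r[is.finite(r)]),
            bias = m$bias, variance = m$variance, mse = m$mse,
            n = m$n, n_failed = sum(!is.finite(r)))
    } else {
      cbind(cells[i, ], true_r = tr, mean_r = NA_real_, bias = NA_real_,
            variance = NA_real_, mse = NA_real_, n = sum(is.finite(r)),
            n_failed = sum(!is.finite(r)))
    }
  }))
  rownames(estimates) <- rownames(summ) <- NULL
  list(estimates = estimates, summary = summ)
}
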