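# Two-stage binomial peak calling and sample-swap empirical FDR.

#' Binomial enrichment p-value
#'
#' Conditional on the total count of a region, the ChIP count under the
#' background model is Binomial(n1 + n2, r / (1 + r)) where `r` is the
#' normalization factor: background ChIP counts are `r` times control
#' counts in expectation. The enrichment statistic is the upper tail
#' `P(X >= n1)`; an empty region (total 0) scores 1.
#'
#' @param n1,n2 ChIP and control counts (vectorized).
#' @param r_hat Normalization factor (> 0).
#' @return Upper-tail binomial probabilities in `[0, 1]`.
#' @export
binomial_pvalue <- function(n1, n2, r_hat) {
  if (!is.finite(r_hat) || r_hat <= 0) stop("'r_hat' must be positive")
  if (any(n1 < 0) || any(n2 < 0)) stop("counts must be non-negative")
  stats::pbinom(n1 - 1, n1 + n2, r_hat / (1 + r_hat), lower.tail = FALSE)
}

#' Caller configuration
#'
#' @param stage1_bin Coarse scan bin width in bp (default 100).
#' @param stage1_alpha Liberal stage-1 retention threshold (default 0.05).
#' @param fine_bin Fine localization bin width in bp (default 20).
#' @param extend Half-width of the site window in bp (default 110; the
#'   window is `[pos - extend, pos + extend)`).
#' @param nominal_fdr Sample-swap nominal FDR level (default 0.05).
#' @param match_dist Distance within which a prediction matches a true site
#'   (default 100 bp).
#' @param merge_gap Maximum gap in bp between retained stage-1 bins merged
#'   into one region (default 0 = adjacent only).
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(stage1_bin = 100, stage1_alpha = 0.05, fine_bin = 20,
                          extend = 110, nominal_fdr = 0.05, match_dist = 100,
                          merge_gap = 0) {
  stopifnot(fine_bin <= stage1_bin, extend > 0, nominal_fdr > 0,
            nominal_fdr < 1, stage1_alpha > 0, match_dist > 0, merge_gap >= 0)
  structure(list(stage1_bin = stage1_bin, stage1_alpha = stage1_alpha,
                 fine_bin = fine_bin, extend = extend,
                 nominal_fdr = nominal_fdr, match_dist = match_dist,
                 merge_gap = merge_gap), class = "caller_config")
}

# count of sorted positions in [lo, hi); lo/hi vectorized
.count_in <- function(sorted_pos, lo, hi) {
  findInterval(hi - 0.5, sorted_pos) - findInterval(lo - 0.5, sorted_pos)
}

#' Two-stage binomial site caller
#'
#' Stage 1 partitions the genome into coarse bins and retains bins whose
#' binomial p-value (ChIP vs control at probability `r / (1 + r)`) is at
#' most a liberal threshold; retained bins within `merge_gap` bp are merged
#' into putative regions. Stage 2 locates, within each region, the fine bin
#' with the highest ChIP count (leftmost on ties) and takes its center as
#' the predicted site. Each site gets a window of `+/- extend` bp and a
#' binomial p-value from the window counts.
#'
#' @param chip,control `shifted_tags` data.frames.
#' @param layout A [genome_layout()].
#' @param r_hat Normalization factor for the ChIP-vs-control comparison.
#' @param config A [caller_config()].
#' @return A data.frame of class `predicted_sites`, sorted by p-value:
#'   `chrom`, `pos`, `window_start`, `window_end`, `n1`, `n2`, `pvalue`.
#' @export
call_sites <- function(chip, control, layout, r_hat, config = caller_config()) {
  chip <- .as_tags(chip); control <- .as_tags(control)
  stopifnot(inherits(config, "caller_config"))
  if (!is.finite(r_hat) || r_hat <= 0) stop("'r_hat' must be positive")
  w1 <- config$stage1_bin; wf <- config$fine_bin
  gap_bins <- floor(config$merge_gap / w1)
  out <- list()
  for (ci in seq_len(nrow(layout))) {
    chrom <- layout$chrom[ci]; len <- layout$length[ci]
    cpos <- sort(chip$pos[chip$chrom == chrom])
    kpos <- sort(control$pos[control$chrom == chrom])
    if (length(cpos) == 0L) next
    nb <- ceiling(len / w1)
    c1 <- tabulate(cpos %/% w1 + 1L, nbins = nb)
    c2 <- tabulate(kpos %/% w1 + 1L, nbins = nb)
    p1 <- binomial_pvalue(c1, c2, r_hat)
    idx <- which(p1 <= config$stage1_alpha & c1 + c2 > 0L)
    if (length(idx) == 0L) next
    # merge retained bins into regions
    brk <- c(0L, which(diff(idx) > 1L + gap_bins), length(idx))
    nf <- ceiling(len / wf)
    fine <- tabulate(cpos %/% wf + 1L, nbins = nf)
    nreg <- length(brk) - 1L
    pos <- numeric(nreg)
    for (ri in seq_len(nreg)) {
      bins <- idx[(brk[ri] + 1L):brk[ri + 1L]]
      reg_start <- (bins[1L] - 1L) * w1
      reg_end <- min(bins[length(bins)] * w1, len)
      fs <- reg_start %/% wf + 1L
      fe <- min((reg_end - 1L) %/% wf + 1L, nf)
      k <- which.max(fine[fs:fe])   # leftmost max
      pos[ri] <- (fs + k - 2L) * wf + wf / 2
    }
    lo <- pos - config$extend; hi <- pos + config$extend
    n1 <- .count_in(cpos, lo, hi)
    n2 <- .count_in(kpos, lo, hi)
    out[[length(out) + 1L]] <- data.frame(chrom = chrom, pos = pos,
                                          window_start = lo, window_end = hi,
                                          n1 = n1, n2 = n2,
                                          pvalue = binomial_pvalue(n1, n2, r_hat),
                                          stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(), pos = numeric(), window_start = numeric(),
               window_end = numeric(), n1 = integer(), n2 = integer(),
               pvalue = numeric(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$pvalue), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("predicted_sites", "data.frame")
  res
}

#' Sample-swap FDR-controlled calling
#'
#' Runs the caller twice — ChIP vs control with `r_hat`, and with the
#' samples' roles swapped using `1 / r_hat` — and finds the largest
#' p-value threshold `s` among the ChIP-side site p-values such that the
#' empirical FDR, the ratio of control-side to ChIP-side calls at `s`
#' (`R_I(s) / R_C(s)`), does not exceed the nominal level. The ChIP-side
#' sites at that threshold are declared.
#'
#' @inheritParams call_sites
#' @return A list of class `swap_fdr_result`: `threshold`, `R_C`, `R_I`,
#'   `empirical_fdr`, `declared` (a `predicted_sites` data.frame),
#'   `chip_sites`, `control_sites` and `flags`.
#' @export
swap_fdr_call <- function(chip, control, layout, r_hat,
                          config = caller_config()) {
  chip_sites <- call_sites(chip, control, layout, r_hat, config)
  ctrl_sites <- call_sites(control, chip, layout, 1 / r_hat, config)
  s_cand <- sort(unique(chip_sites$pvalue))
  flags <- character()
  if (length(s_cand)) {
    pc <- sort(chip_sites$pvalue)
    pi_ <- sort(ctrl_sites$pvalue)
    R_C <- findInterval(s_cand, pc)
    R_I <- findInterval(s_cand, pi_)
    ok <- which(R_I / R_C <= config$nominal_fdr)
  } else ok <- integer()
  if (length(ok)) {
    i <- ok[length(ok)]
    s <- s_cand[i]
    declared <- chip_sites[chip_sites$pvalue <= s, , drop = FALSE]
    res <- list(threshold = s, R_C = R_C[i], R_I = R_I[i],
                empirical_fdr = R_I[i] / R_C[i], declared = declared,
                chip_sites = chip_sites, control_sites = ctrl_sites,
                flags = flags)
  } else {
    res <- list(threshold = NA_real_, R_C = 0L, R_I = 0L, empirical_fdr = 0,
                declared = chip_sites[0, , drop = FALSE],
                chip_sites = chip_sites, control_sites = ctrl_sites,
                flags = "no_qualifying_threshold")
  }
  class(res) <- "swap_fdr_result"
  res
}

#' @export
print.swap_fdr_result <- function(x, ...) {
  cat(sprintf("<swap_fdr_result> declared %d site(s); R_C = %d, R_I = %d, empirical FDR = %.4g\n",
              nrow(x$declared), x$R_C, x$R_I, x$empirical_fdr))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Classify declared sites against ground truth
#'
#' A declared site is a true positive when the distance from its predicted
#' position to the closest true site (same chromosome) is at most
#' `match_dist`; otherwise it is a false positive. `power` counts the
#' distinct true sites recovered, so several predictions of the same true
#' site count once towards power (each still counts as a site-level true
#' positive, never as a false positive).
#'
#' @param declared A `predicted_sites` data.frame (or any data.frame with
#'   `chrom` and `pos`).
#' @param true_sites A data.frame with `chrom` and `pos` of true sites.
#' @param match_dist Matching distance in bp (default 100).
#' @return A list of class `eval_result`: `n_declared`, `n_true_positive`,
#'   `n_false_positive`, `realized_fdr`, `power`.
#' @export
evaluate_calls <- function(declared, true_sites, match_dist = 100) {
  if (match_dist <= 0) stop("'match_dist' must be positive")
  n_decl <- nrow(declared)
  if (n_decl == 0L) {
    return(structure(list(n_declared = 0L, n_true_positive = 0L,
                          n_false_positive = 0L, realized_fdr = 0, power = 0L),
                     class = "eval_result"))
  }
  nearest <- rep(NA_integer_, n_decl)
  dist <- rep(Inf, n_decl)
  for (chrom in unique(declared$chrom)) {
    di <- which(declared$chrom == chrom)
    ti <- which(true_sites$chrom == chrom)
    if (length(ti) == 0L) next
    tp <- sort(true_sites$pos[ti])
    ord <- order(true_sites$pos[ti])
    lo <- pmin(pmax(findInterval(declared$pos[di], tp), 1L), length(tp))
    hi <- pmin(lo + 1L, length(tp))
    d_lo <- abs(declared$pos[di] - tp[lo])
    d_hi <- abs(declared$pos[di] - tp[hi])
    use_hi <- d_hi < d_lo
    dist[di] <- ifelse(use_hi, d_hi, d_lo)
    nearest[di] <- ti[ord][ifelse(use_hi, hi, lo)]
  }
  tp_mask <- dist <= match_dist
  n_tp <- sum(tp_mask)
  structure(list(n_declared = n_decl, n_true_positive = n_tp,
                 n_false_positive = n_decl - n_tp,
                 realized_fdr = (n_decl - n_tp) / max(n_decl, 1L),
                 power = length(unique(nearest[tp_mask]))),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> declared %d: TP %d, FP %d, realized FDR %.4g, power %d\n",
              x$n_declared, x$n_true_positive, x$n_false_positive,
              x$realized_fdr, x$power))
  invisible(x)
}

#' Bias / variance / MSE of replicate estimates
#'
#' Mean squared error around the true normalization factor, with its
#' decomposition into squared bias plus (population) variance.
#'
#' @param estimates Numeric vector of per-replicate estimates (>= 2).
#' @param true_r True normalization factor.
#' @return A list with `bias`, `variance`, `mse` and `n`.
#' @export
estimator_mse <- function(estimates, true_r) {
  estimates <- estimates[is.finite(estimates)]
  if (length(estimates) < 2L) stop("need at least 2 finite estimates")
  bias <- mean(estimates) - true_r
  variance <- mean((estimates - mean(estimates))^2)
  list(bias = bias, variance = variance,
       mse = mean((estimates - true_r)^2), n = length(estimates))
}

#' Export declared sites as BED and TSV
#'
#' @param sites A `predicted_sites` data.frame.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_sites <- function(sites, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(sites$chrom, as.integer(pmax(sites$window_start, 0)),
                      as.integer(sites$window_end),
                      sprintf("site_%d", seq_len(nrow(sites))),
                      round(-log10(pmax(sites$pvalue, 1e-300)), 3), ".")
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    data.table::fwrite(as.data.frame(sites), tsv_path, sep = "\t")
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}
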