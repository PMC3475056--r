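# Normalization-factor estimators.
#
# The normalization factor r is the ratio by which control bin counts must
# be scaled to match the background component of ChIP bin counts:
# r = pi0 * N1 / N2, where pi0 is the proportion of ChIP reads arising from
# background. Every estimator below reduces to choosing a background bin
# set B and applying the plug-in ratio sum(n1[B]) / sum(n2[B]) (or, for the
# regression estimator, a slope).

#' Background-set ratio estimator
#'
#' The plug-in estimate of the normalization factor given a set of bins
#' assumed to be signal-free: the summed ChIP count over `B` divided by the
#' summed control count over `B`.
#'
#' @param table A `bin_table`.
#' @param B Integer vector of row indices into `table` (the background set).
#' @return The ratio, a positive number.
#' @export
background_ratio <- function(table, B) {
  if (length(B) == 0L) stop("degenerate background: empty bin set")
  s1 <- sum(table$n1[B]); s2 <- sum(table$n2[B])
  if (s2 <= 0) stop("degenerate background: control count sum over B is zero")
  s1 / s2
}

# Container for an estimator's output.
.norm_result <- function(method, r_hat, N1, N2, w_star = NA_real_,
                         t_star = NA_real_, n_background_bins = NA_integer_,
                         trace = NULL, flags = character(), converged = NA) {
  depth_ratio <- N1 / N2
  pi0 <- pi0_from_r(r_hat, N1, N2)
  structure(list(method = method, r_hat = r_hat, pi0_hat = as.vector(pi0),
                 w_star = w_star, t_star = t_star,
                 n_background_bins = n_background_bins,
                 depth_ratio = depth_ratio, N1 = N1, N2 = N2,
                 trace = trace, converged = converged,
                 flags = union(flags, attr(pi0, "flags"))),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("<normalization_result> method = %s\n", x$method))
  cat(sprintf("  r_hat = %.6g   pi0_hat = %.6g   depth ratio N1/N2 = %.6g\n",
              x$r_hat, x$pi0_hat, x$depth_ratio))
  if (!is.na(x$w_star)) cat(sprintf("  selected bin width = %g bp\n", x$w_star))
  if (!is.na(x$t_star)) cat(sprintf("  selected total-count threshold = %g\n", x$t_star))
  if (!is.na(x$n_background_bins)) {
    cat(sprintf("  background bins |B| = %d\n", x$n_background_bins))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Background proportion from a normalization factor
#'
#' Inverts r = pi0 * N1 / N2: the estimated fraction of ChIP reads that are
#' background is `r_hat * N2 / N1`. Values above 1 are logically impossible
#' (more background than reads) but occur for estimators whose `r_hat`
#' exceeds the sequencing depth ratio; they are returned as-is with a
#' warning flag.
#'
#' @param r_hat Normalization factor estimate (> 0).
#' @param N1,N2 Total ChIP and control read counts (> 0).
#' @return The estimated background proportion; attribute `flags` contains
#'   `"pi0_above_1"` when it exceeds 1.
#' @export
pi0_from_r <- function(r_hat, N1, N2) {
  if (!is.finite(r_hat) || r_hat <= 0) stop("'r_hat' must be positive")
  if (!is.finite(N1) || N1 <= 0 || !is.finite(N2) || N2 <= 0) {
    stop("'N1' and 'N2' must be positive")
  }
  pi0 <- r_hat * N2 / N1
  flags <- character()
  if (pi0 > 1) {
    warning(sprintf("estimated background proportion %.4g exceeds 1 (r_hat above the depth ratio)", pi0))
    flags <- "pi0_above_1"
  }
  structure(pi0, flags = flags)
}

#' Fixed-width data-adaptive threshold search
#'
#' For a fixed bin width, scans total-count thresholds `t` over the
#' ascending distinct observed totals. The candidate background set at `t`
#' is `B_w(t) = {i : n_i <= t}`. Small `t` gives low bias (low-total bins
#' are most likely background) but high variance; the scan therefore starts
#' at the upper quartile of the retained bins (`|B_w(t)| >= quartile_floor *
#' m_w`, default three quarters) and stops at the first threshold whose
#' ratio estimate is larger than or equal to the estimate at the previous
#' distinct total — the point where the background plateau ends and signal
#' infusion begins. If no threshold qualifies, the estimate falls back to
#' the ratio over all retained bins (flagged).
#'
#' @param table A zero-filtered `bin_table`.
#' @param quartile_floor Minimum fraction of retained bins that the
#'   background set must contain (default 0.75).
#' @return A list with `r_hat`, `t_star`, `n_background_bins` and `flags`.
#' @export
ncis_fixed_w <- function(table, quartile_floor = 0.75) {
  stopifnot(inherits(table, "bin_table"))
  if (!isTRUE(attr(table, "zero_filtered"))) {
    stop("ncis_fixed_w expects a zero-filtered bin table")
  }
  if (quartile_floor <= 0 || quartile_floor >= 1) {
    stop("'quartile_floor' must be in (0, 1)")
  }
  m <- nrow(table)
  if (m == 0L) stop("degenerate background: no non-empty bins")
  ord <- order(table$n)
  n_sorted <- table$n[ord]
  cs1 <- cumsum(table$n1[ord])
  cs2 <- cumsum(table$n2[ord])
  # index of the last bin at each distinct total
  last <- which(diff(c(n_sorted, Inf)) > 0)
  t_vals <- n_sorted[last]
  S1 <- cs1[last]; S2 <- cs2[last]
  r_t <- ifelse(S2 > 0, S1 / S2, NA_real_)
  size_B <- last
  k <- length(t_vals)

  flags <- character()
  if (k >= 2L) {
    eligible <- size_B >= quartile_floor * m
    ok <- seq_len(k) >= 2L & eligible & !is.na(r_t) & !is.na(c(NA, r_t[-k])) &
      r_t >= c(NA, r_t[-k])
    hit <- which(ok)
    if (length(hit)) {
      i <- hit[1L]
      return(list(r_hat = r_t[i], t_star = t_vals[i],
                  n_background_bins = size_B[i], flags = flags))
    }
    flags <- "threshold_fallback_all_bins"
  } else {
    flags <- "single_total_fallback"
  }
  if (is.na(r_t[k])) stop("degenerate background: zero control counts at every threshold")
  list(r_hat = r_t[k], t_star = t_vals[k], n_background_bins = size_B[k],
       flags = flags)
}

#' Data-adaptive normalization factor estimate (bin-width grid search)
#'
#' Runs the fixed-width threshold search of [ncis_fixed_w()] along an
#' ascending grid of bin widths and stops at the first width whose
#' successor's estimate is larger than or equal to its own; that width's
#' estimate is the final normalization factor. The per-width estimates are
#' bound to rise eventually — at bin width equal to the genome size the
#' ratio is the sequencing depth ratio, the upper limit of the
#' normalization factor — so the stop rule picks the width where the
#' estimate bottoms out. A strictly decreasing profile across the whole
#' grid falls back to the last width (flagged).
#'
#' @param chip,control `shifted_tags` data.frames.
#' @param layout A [genome_layout()].
#' @param grid Ascending bin widths in bp (default
#'   `c(100, 200, 500, 1000, 2000, 5000, 10000)`).
#' @param quartile_floor Passed to [ncis_fixed_w()].
#' @return A `normalization_result`; `$trace` holds the visited
#'   `(w, r_hat)` pairs.
#' @export
ncis_estimate <- function(chip, control, layout,
                          grid = c(100, 200, 500, 1000, 2000, 5000, 10000),
                          quartile_floor = 0.75) {
  chip <- .as_tags(chip); control <- .as_tags(control)
  if (nrow(chip) == 0L || nrow(control) == 0L) stop("both samples must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("'grid' must be strictly ascending")
  N1 <- nrow(chip); N2 <- nrow(control)
  fits <- vector("list", length(grid))
  r_w <- rep(NA_real_, length(grid))
  pick <- NA_integer_
  flags <- character()
  for (i in seq_along(grid)) {
    tab <- bin_counts(chip, control, layout, grid[i], drop_zero = TRUE)
    fits[[i]] <- ncis_fixed_w(tab, quartile_floor)
    r_w[i] <- fits[[i]]$r_hat
    if (i >= 2L && r_w[i] >= r_w[i - 1L]) {
      pick <- i - 1L
      break
    }
  }
  if (is.na(pick)) {
    pick <- length(grid)
    flags <- "grid_fallback_last_width"
  }
  visited <- !is.na(r_w)
  sel <- fits[[pick]]
  .norm_result("ncis", sel$r_hat, N1, N2, w_star = grid[pick],
               t_star = sel$t_star, n_background_bins = sel$n_background_bins,
               trace = data.frame(w = grid[visited], r_hat = r_w[visited]),
               flags = c(flags, sel$flags))
}

#' Low-total-count background estimator
#'
#' Uses the bins with total count at most `t` (default 1, the smallest
#' possible non-zero total) as the background set at a fixed 100 bp bin
#' width. Nearly unbiased but increasingly variable with sequencing depth:
#' deeply sequenced genomes may contain few or no total-count-1 bins, in
#' which case the estimator is degenerate and errors.
#'
#' @param table A zero-filtered `bin_table` (conventionally at w = 100 bp).
#' @param t Total-count threshold (default 1).
#' @return A `normalization_result`.
#' @export
cisgenome_estimate <- function(table, t = 1) {
  stopifnot(inherits(table, "bin_table"))
  B <- which(table$n <= t)
  if (length(B) == 0L) {
    stop(sprintf("degenerate background: no bins with total count <= %g (deeply sequenced data?)", t))
  }
  r <- background_ratio(table, B)
  .norm_result("cisgenome", r, attr(table, "N1"), attr(table, "N2"),
               w_star = attr(table, "w"), t_star = t,
               n_background_bins = length(B))
}

#' Poisson-tail exclusion background estimator
#'
#' Excludes bins that look enriched in either sample under a uniform-reads
#' null: bin `i` is excluded when `min(p1i, p2i) <= c`, where `p1i` is the
#' upper-tail Poisson probability `P(X >= n1i)` at rate `N1 * w / G` (and
#' likewise for the control). The ratio over the surviving bins is the
#' estimate. Conventionally w = 1000 bp and c = 1e-5.
#'
#' @param table A zero-filtered `bin_table`.
#' @param layout A [genome_layout()] providing the total genome length `G`.
#' @param c_threshold Exclusion p-value threshold (default `1e-5`).
#' @return A `normalization_result`.
#' @export
spp_estimate <- function(table, layout, c_threshold = 1e-5) {
  stopifnot(inherits(table, "bin_table"))
  if (c_threshold <= 0 || c_threshold >= 1) stop("'c_threshold' must be in (0, 1)")
  G <- genome_size(layout)
  w <- attr(table, "w")
  rate1 <- attr(table, "N1") * w / G
  rate2 <- attr(table, "N2") * w / G
  # P(X >= n) = P(X > n - 1)
  p1 <- stats::ppois(table$n1 - 1, rate1, lower.tail = FALSE)
  p2 <- stats::ppois(table$n2 - 1, rate2, lower.tail = FALSE)
  B <- which(pmin(p1, p2) > c_threshold)
  if (length(B) == 0L) stop("degenerate background: every bin excluded by the Poisson-tail filter")
  r <- background_ratio(table, B)
  .norm_result("spp", r, attr(table, "N1"), attr(table, "N2"),
               w_star = w, n_background_bins = length(B))
}

#' Iterative strand-split background estimator
#'
#' Alternates between selecting background bins from positive-strand counts
#' and re-estimating the ratio from negative-strand counts: starting at the
#' sequencing depth ratio, iteration `j` takes
#' `B = {i : n1i+ < r_j * n2i+}` (strict inequality) and updates
#' `r_{j+1} = sum(n1i- over B) / sum(n2i- over B)` until the change drops
#' below `tolerance`. Using opposite strands for selection and estimation
#' decouples the two steps. If the selection set becomes empty (e.g. when
#' ChIP and control are identical, so no bin lies strictly below the line)
#' the current estimate is returned as the fixed point, flagged.
#'
#' @param table A zero-filtered `bin_table` with per-strand counts
#'   (conventionally at w = 1000 bp).
#' @param tolerance Convergence tolerance on successive estimates
#'   (default `1e-6`).
#' @param max_iter Maximum iterations (default 100).
#' @return A `normalization_result`; `$converged` reports convergence and
#'   `$trace` the per-iteration estimates.
#' @export
ccat_estimate <- function(table, tolerance = 1e-6, max_iter = 100) {
  stopifnot(inherits(table, "bin_table"))
  if (tolerance <= 0) stop("'tolerance' must be positive")
  N1 <- attr(table, "N1"); N2 <- attr(table, "N2")
  if (N2 <= 0) stop("control sample is empty")
  r <- N1 / N2
  trace <- r
  converged <- FALSE
  flags <- character()
  n_B <- nrow(table)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    B <- which(table$n1_plus < r * table$n2_plus)
    if (length(B) == 0L) {
      flags <- "empty_background_set"
      converged <- TRUE
      n_B <- 0L
      break
    }
    s2 <- sum(table$n2_minus[B])
    if (s2 <= 0) {
      stop(sprintf("degenerate background at iteration %d: negative-strand control sum over B is zero", iter))
    }
    r_new <- sum(table$n1_minus[B]) / s2
    trace <- c(trace, r_new)
    n_B <- length(B)
    done <- abs(r_new - r) < tolerance
    r <- r_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) flags <- c(flags, "not_converged")
  .norm_result("ccat", r, N1, N2, w_star = attr(table, "w"),
               n_background_bins = max(n_B, 0L),
               trace = data.frame(iteration = seq_along(trace) - 1L, r_hat = trace),
               flags = flags, converged = converged)
}

#' Regression-slope estimator
#'
#' The ordinary least-squares slope of ChIP bin counts regressed on control
#' bin counts (with intercept) at a coarse bin width, conventionally
#' w = 10 Kbp. The full variant excludes a fraction `Pf` of bins
#' overlapping putative enriched regions before regressing; only `Pf = 0`
#' (no exclusion, all bins including zero-total bins) is supported.
#'
#' @param table A `bin_table` built with `drop_zero = FALSE`.
#' @param Pf Exclusion fraction; only 0 is supported.
#' @return A `normalization_result`.
#' @export
peakseq_estimate <- function(table, Pf = 0) {
  stopifnot(inherits(table, "bin_table"))
  if (Pf != 0) stop("only Pf = 0 (no enriched-region exclusion) is supported")
  x <- table$n2; y <- table$n1
  if (nrow(table) < 2L || stats::var(x) == 0) {
    stop("regression slope undefined: control bin counts are constant")
  }
  slope <- stats::cov(x, y) / stats::var(x)
  if (slope <= 0) {
    stop("regression slope is non-positive; no usable normalization factor")
  }
  .norm_result("peakseq", slope, attr(table, "N1"), attr(table, "N2"),
               w_star = attr(table, "w"), n_background_bins = nrow(table))
}

#' Run some or all normalization estimators on a sample pair
#'
#' Convenience wrapper that bins the tag pair at each method's conventional
#' width and runs the requested estimators. Estimator-specific degeneracies
#' (e.g. the low-count estimator on deeply sequenced data) are caught and
#' reported in the `error` column rather than aborting the remaining
#' methods.
#'
#' @param chip,control `shifted_tags` data.frames.
#' @param layout A [genome_layout()].
#' @param methods Subset of
#'   `c("ncis", "cisgenome", "spp", "ccat", "peakseq")`.
#' @param grid,quartile_floor Passed to [ncis_estimate()].
#' @return A list with `results` (named list of `normalization_result` or
#'   `NULL` where a method failed) and `summary` (one data.frame row per
#'   method: `method`, `r_hat`, `pi0_hat`, `w_star`, `t_star`,
#'   `n_background_bins`, `depth_ratio`, `flags`, `error`).
#' @export
estimate_all <- function(chip, control, layout,
                         methods = c("ncis", "cisgenome", "spp", "ccat", "peakseq"),
                         grid = c(100, 200, 500, 1000, 2000, 5000, 10000),
                         quartile_floor = 0.75) {
  methods <- match.arg(methods, several.ok = TRUE)
  chip <- .as_tags(chip); control <- .as_tags(control)
  tables <- list()
  tab_at <- function(w, drop_zero = TRUE) {
    key <- paste0(w, "/", drop_zero)
    if (is.null(tables[[key]])) {
      tables[[key]] <<- bin_counts(chip, control, layout, w, drop_zero = drop_zero)
    }
    tables[[key]]
  }
  runner <- list(
    ncis = function() ncis_estimate(chip, control, layout, grid, quartile_floor),
    cisgenome = function() cisgenome_estimate(tab_at(100)),
    spp = function() spp_estimate(tab_at(1000), layout),
    ccat = function() ccat_estimate(tab_at(1000)),
    peakseq = function() peakseq_estimate(tab_at(10000, drop_zero = FALSE))
  )
  results <- stats::setNames(vector("list", length(methods)), methods)
  rows <- vector("list", length(methods))
  for (i in seq_along(methods)) {
    m <- methods[i]
    res <- tryCatch(withCallingHandlers(runner[[m]](),
                                        warning = function(w) invokeRestart("muffleWarning")),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(method = m, r_hat = NA_real_, pi0_hat = NA_real_,
                              w_star = NA_real_, t_star = NA_real_,
                              n_background_bins = NA_integer_,
                              depth_ratio = nrow(chip) / nrow(control),
                              flags = "", error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      results[[m]] <- res
      rows[[i]] <- data.frame(method = m, r_hat = res$r_hat, pi0_hat = res$pi0_hat,
                              w_star = res$w_star, t_star = res$t_star,
                              n_background_bins = res$n_background_bins,
                              depth_ratio = res$depth_ratio,
                              flags = paste(res$flags, collapse = ";"),
                              error = "", stringsAsFactors = FALSE)
    }
  }
  list(results = results, summary = do.call(rbind, rows))
}
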