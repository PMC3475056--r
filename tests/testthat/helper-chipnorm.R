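# Shared test helpers: tiny fixtures built in code and independent oracles.

mk_tags <- function(pos, chrom = "chrA", strand = "+") {
  df <- data.frame(chrom = rep_len(chrom, length(pos)), pos = as.numeric(pos),
                   strand = rep_len(strand, length(pos)), stringsAsFactors = FALSE)
  class(df) <- c("shifted_tags", "data.frame")
  df
}

# hand-built bin table (zero-total bins removed), bypassing read counting
fake_bin_table <- function(n1, n2, n1p = floor(n1 / 2), n2p = floor(n2 / 2),
                           w = 100) {
  df <- data.frame(chrom = "chrA", bin_start = (seq_along(n1) - 1) * w,
                   bin_end = seq_along(n1) * w, n1 = n1, n2 = n2,
                   n1_plus = n1p, n1_minus = n1 - n1p,
                   n2_plus = n2p, n2_minus = n2 - n2p, n = n1 + n2,
                   stringsAsFactors = FALSE)
  df <- df[df$n > 0, , drop = FALSE]
  structure(df, w = w, N1 = sum(n1), N2 = sum(n2), m_w = nrow(df),
            zero_filtered = TRUE, class = c("bin_table", "data.frame"))
}

# independent brute-force oracle for the fixed-width threshold search:
# materializes B(t) for every distinct total and applies the ratio formula
brute_fixed_w <- function(n1, n2, floor_frac = 0.75) {
  n <- n1 + n2
  m <- length(n)
  ts <- sort(unique(n))
  r_of <- function(t) {
    B <- n <= t
    s2 <- sum(n2[B])
    if (s2 == 0) NA_real_ else sum(n1[B]) / s2
  }
  if (length(ts) >= 2) {
    for (i in 2:length(ts)) {
      if (sum(n <= ts[i]) >= floor_frac * m) {
        r_now <- r_of(ts[i]); r_prev <- r_of(ts[i - 1])
        if (!is.na(r_now) && !is.na(r_prev) && r_now >= r_prev) {
          return(list(r_hat = r_now, t_star = ts[i],
                      n_background_bins = sum(n <= ts[i])))
        }
      }
    }
  }
  list(r_hat = r_of(max(ts)), t_star = max(ts), n_background_bins = m)
}

# random small count table with occasional enriched bins
rand_count_table <- function(max_bins = 200) {
  repeat {
    m <- sample(5:max_bins, 1)
    n1 <- rpois(m, runif(1, 0.2, 3))
    n2 <- rpois(m, runif(1, 0.2, 3))
    if (runif(1) < 0.5) {
      k <- sample(1:3, 1)
      i <- sample(m, k)
      n1[i] <- n1[i] + rpois(k, 20)
    }
    keep <- n1 + n2 > 0
    if (sum(keep) >= 2 && sum(n2[keep]) > 0) {
      return(list(n1 = n1[keep], n2 = n2[keep]))
    }
  }
}

write_bed6 <- function(chrom, start, end, strand, path) {
  write.table(data.frame(chrom, start, end, "N", 0L, strand),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# 12 Mbp four-chromosome layout used by the simulation studies
study_layout <- function() genome_layout(paste0("chr", 1:4), rep(3e6, 4))

# memoised replicate batches shared across acceptance blocks
.batch_cache <- new.env(parent = emptyenv())

estimator_batch <- function(setting, seeds, methods, background_depth = 2e5,
                            c_signal = 1) {
  key <- paste(setting, paste(range(seeds), collapse = "-"),
               paste(methods, collapse = ","), background_depth, c_signal,
               sep = "|")
  if (!is.null(.batch_cache[[key]])) return(.batch_cache[[key]])
  gl <- study_layout()
  rows <- lapply(seeds, function(s) {
    sim <- simulate_dataset(gl, setting = setting,
                            background_depth = background_depth,
                            c_signal = c_signal, seed = s)
    est <- suppressWarnings(estimate_all(sim$chip, sim$control, gl,
                                         methods = methods))
    cbind(seed = s, true_r = sim$true_r, est$summary)
  })
  out <- do.call(rbind, rows)
  .batch_cache[[key]] <- out
  out
}

power_fdr_batch <- function(seeds, background_depth = 1e5, c_signal = 0.5) {
  key <- paste("power", paste(range(seeds), collapse = "-"),
               background_depth, c_signal, sep = "|")
  if (!is.null(.batch_cache[[key]])) return(.batch_cache[[key]])
  gl <- study_layout()
  cfg <- caller_config()
  rows <- lapply(seeds, function(s) {
    sim <- simulate_dataset(gl, setting = "power",
                            background_depth = background_depth,
                            c_signal = c_signal, seed = s)
    r_ncis <- ncis_estimate(sim$chip, sim$control, gl)$r_hat
    fdr_of <- function(r) {
      sw <- swap_fdr_call(sim$chip, sim$control, gl, r, cfg)
      ev <- evaluate_calls(sw$declared, sim$true_sites, cfg$match_dist)
      c(fdr = ev$realized_fdr, power = ev$power, declared = ev$n_declared)
    }
    c(seed = s, r_ncis = r_ncis, true_r = sim$true_r,
      ncis = fdr_of(r_ncis), oracle = fdr_of(sim$true_r))
  })
  out <- as.data.frame(do.call(rbind, rows))
  .batch_cache[[key]] <- out
  out
}
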