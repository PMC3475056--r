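# Genome binning and bin-count tables.
#
# Bin i on a chromosome covers [i*w, (i+1)*w) in 0-based coordinates; the
# last bin of a chromosome is truncated at the chromosome end.

# per-chromosome bin counts and global 0-based bin offsets for width w
.bin_scheme <- function(layout, w) {
  nbins <- ceiling(layout$length / w)
  list(nbins = nbins, offset = c(0, cumsum(nbins))[seq_along(nbins)],
       total = sum(nbins))
}

# 1-based global bin id for each tag
.tag_gid <- function(tags, layout, w, scheme = .bin_scheme(layout, w)) {
  idx <- match(tags$chrom, layout$chrom)
  if (anyNA(idx)) {
    bad <- unique(tags$chrom[is.na(idx)])
    stop("chromosome(s) not in genome layout: ", paste(bad, collapse = ", "))
  }
  scheme$offset[idx] + tags$pos %/% w + 1L
}

#' Bin-count table for a ChIP/control pair
#'
#' Partitions the genome into non-overlapping bins of width `w` and counts
#' the ChIP and control tags (and their per-strand components) falling in
#' each bin. Bins with zero total count carry no information for ratio
#' estimation and are dropped by default.
#'
#' @param chip,control `shifted_tags` data.frames (see [shift_reads()]).
#' @param layout A [genome_layout()].
#' @param w Bin width in bp.
#' @param drop_zero Drop bins whose ChIP + control total is zero
#'   (default `TRUE`).
#'
#' @return A data.frame of class `bin_table` with columns `chrom`,
#'   `bin_start`, `bin_end`, `n1`, `n2` (ChIP and control counts), `n1_plus`,
#'   `n1_minus`, `n2_plus`, `n2_minus` and `n` (= `n1 + n2`), and attributes
#'   `w`, `N1`, `N2` (sample totals over all tags), `m_w` (number of retained
#'   bins) and `zero_filtered`.
#' @export
bin_counts <- function(chip, control, layout, w, drop_zero = TRUE) {
  chip <- .as_tags(chip); control <- .as_tags(control)
  if (!is.numeric(w) || length(w) != 1L || w <= 0) stop("bin width 'w' must be positive")
  if (nrow(chip) + nrow(control) == 0L) stop("no tags in either sample")
  scheme <- .bin_scheme(layout, w)
  cnt <- function(tags, keep = TRUE) {
    gid <- .tag_gid(tags, layout, w, scheme)[keep]
    tabulate(gid, nbins = scheme$total)
  }
  chip_plus <- chip$strand == "+"
  ctrl_plus <- control$strand == "+"
  n1p <- cnt(chip, chip_plus);   n1m <- cnt(chip, !chip_plus)
  n2p <- cnt(control, ctrl_plus); n2m <- cnt(control, !ctrl_plus)
  n1 <- n1p + n1m; n2 <- n2p + n2m; n <- n1 + n2

  chrom <- rep(layout$chrom, scheme$nbins)
  bin <- unlist(lapply(scheme$nbins, function(k) seq_len(k) - 1L), use.names = FALSE)
  bin_start <- bin * w
  bin_end <- pmin(bin_start + w, rep(layout$length, scheme$nbins))

  keep <- if (drop_zero) n > 0L else rep(TRUE, scheme$total)
  out <- data.frame(chrom = chrom[keep], bin_start = bin_start[keep],
                    bin_end = bin_end[keep],
                    n1 = n1[keep], n2 = n2[keep],
                    n1_plus = n1p[keep], n1_minus = n1m[keep],
                    n2_plus = n2p[keep], n2_minus = n2m[keep],
                    n = n[keep], stringsAsFactors = FALSE)
  structure(out, w = w, N1 = nrow(chip), N2 = nrow(control),
            m_w = nrow(out), zero_filtered = drop_zero,
            class = c("bin_table", "data.frame"))
}

#' Marginal ChIP/control ratio profile
#'
#' For each distinct observed total count `t`, the marginal ratio is the sum
#' of ChIP counts over bins with total exactly `t` divided by the matching
#' sum of control counts. Plotted against `t`, background bins produce a
#' flat left limb while signal infusion bends the right limb upward; the
#' profile is the main diagnostic behind threshold selection.
#'
#' @param table A zero-filtered `bin_table`.
#' @return A data.frame with one row per distinct total, ascending:
#'   `t`, `chip_sum`, `control_sum`, `bins_at_t`, `ratio` (NA where the
#'   control sum is zero) and `defined`.
#' @export
marginal_ratio_profile <- function(table) {
  stopifnot(inherits(table, "bin_table"))
  if (!isTRUE(attr(table, "zero_filtered"))) {
    stop("marginal_ratio_profile expects a zero-filtered bin table")
  }
  agg <- rowsum(cbind(n1 = table$n1, n2 = table$n2, one = rep(1L, nrow(table))),
                group = table$n, reorder = TRUE)
  t_vals <- as.numeric(rownames(agg))
  ratio <- ifelse(agg[, "n2"] > 0, agg[, "n1"] / agg[, "n2"], NA_real_)
  data.frame(t = t_vals, chip_sum = agg[, "n1"], control_sum = agg[, "n2"],
             bins_at_t = agg[, "one"], ratio = ratio,
             defined = agg[, "n2"] > 0, row.names = NULL)
}

#' Export a bin table as TSV
#'
#' @param table A `bin_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_table <- function(table, path) {
  stopifnot(inherits(table, "bin_table"))
  out <- data.frame(chrom = table$chrom, bin_start = table$bin_start,
                    bin_end = table$bin_end, n1 = table$n1, n2 = table$n2,
                    n1_plus = table$n1_plus, n1_minus = table$n1_minus,
                    n2_plus = table$n2_plus, n2_minus = table$n2_minus)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("<bin_table> w = %d bp, %d bin(s)%s; N1 = %d, N2 = %d\n",
              as.integer(attr(x, "w")), nrow(x),
              if (isTRUE(attr(x, "zero_filtered"))) " (zero-filtered)" else "",
              attr(x, "N1"), attr(x, "N2")))
  print(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
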