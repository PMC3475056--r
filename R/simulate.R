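# Synthetic paired ChIP/control samples with known ground truth.
#
# The generator emulates the structure of a matched ChIP/control pair:
# a shared non-uniform background (the same latent intensity drives both
# samples, so their background parts are linearly related in expectation),
# point-source signal spiked only into ChIP, control-only artifact piles,
# and diffuse kilobase-scale enriched domains.

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# uniform random genome positions; returns data.frame(chrom, pos)
.random_positions <- function(n, layout) {
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(), stringsAsFactors = FALSE))
  }
  ci <- sample.int(nrow(layout), n, replace = TRUE, prob = layout$length)
  data.frame(chrom = layout$chrom[ci],
             pos = floor(stats::runif(n) * layout$length[ci]),
             stringsAsFactors = FALSE)
}

.random_strands <- function(n) sample(c("+", "-"), n, replace = TRUE)

.make_tags <- function(chrom, pos, strand) {
  out <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    strand = as.character(strand), stringsAsFactors = FALSE)
  class(out) <- c("shifted_tags", "data.frame")
  out
}

#' Shared-intensity background pair
#'
#' Draws one latent per-window intensity profile (gamma distributed with
#' unit mean; `roughness` is its variance) and places the background reads
#' of both samples by sampling windows proportionally to the same profile,
#' then uniformly within the window. The two samples are conditionally
#' independent given the intensity, so their expected per-bin ratio is the
#' depth ratio at every bin — the linear-background premise that all
#' normalization estimators rely on. `roughness = 0` reduces exactly to
#' uniform sampling.
#'
#' @param layout A [genome_layout()].
#' @param depth1,depth2 Background read counts for ChIP and control.
#' @param roughness Variance of the unit-mean per-window intensity
#'   (default 0.25; 0 = uniform background).
#' @param window Intensity window width in bp (default 1000).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A list with `chip` and `control` `shifted_tags`.
#' @export
synth_background <- function(layout, depth1, depth2, roughness = 0.25,
                             window = 1000, seed = NULL) {
  stopifnot(depth1 > 0, depth2 > 0, roughness >= 0, window > 0)
  .with_seed(seed, {
    nwin <- ceiling(layout$length / window)
    win_chrom_idx <- rep(seq_len(nrow(layout)), nwin)
    win_start <- unlist(lapply(nwin, function(k) (seq_len(k) - 1) * window),
                        use.names = FALSE)
    win_len <- pmin(win_start + window, layout$length[win_chrom_idx]) - win_start
    lambda <- if (roughness > 0) {
      shp <- 1 / roughness
      stats::rgamma(length(win_start), shape = shp, rate = shp)
    } else rep(1, length(win_start))
    wgt <- lambda * win_len
    draw <- function(depth) {
      wi <- sample.int(length(wgt), depth, replace = TRUE, prob = wgt)
      pos <- win_start[wi] + floor(stats::runif(depth) * win_len[wi])
      .make_tags(layout$chrom[win_chrom_idx[wi]], pos, .random_strands(depth))
    }
    list(chip = draw(depth1), control = draw(depth2))
  })
}

#' Split a read set into two halves and subsample
#'
#' Randomly partitions the reads into two disjoint halves (sizes differing
#' by at most one), then thins each half to a fraction `1/d`. The default
#' thinning keeps each read independently with probability `1/d` (binomial
#' thinning, matching sequencing-depth semantics); `exact = TRUE` instead
#' keeps exactly `floor(size/d)` reads per half.
#'
#' @param reads A data.frame of reads or tags.
#' @param d Subsampling divisor (>= 1).
#' @param exact Use exact-count subsampling instead of binomial thinning.
#' @param seed Optional integer seed.
#' @return A list with `half_a` and `half_b`.
#' @export
split_subsample <- function(reads, d = 1, exact = FALSE, seed = NULL) {
  if (nrow(reads) == 0L) stop("cannot split an empty read set")
  if (d < 1) stop("'d' must be >= 1")
  .with_seed(seed, {
    n <- nrow(reads)
    idx <- sample.int(n)
    a <- idx[seq_len(ceiling(n / 2))]
    b <- idx[-seq_len(ceiling(n / 2))]
    thin <- function(i) {
      if (d == 1) return(i)
      if (exact) sample(i, floor(length(i) / d))
      else i[stats::runif(length(i)) < 1 / d]
    }
    list(half_a = reads[thin(a), , drop = FALSE],
         half_b = reads[thin(b), , drop = FALSE])
  })
}

#' Spike point-source signal into a ChIP background
#'
#' Places `p` transcription-factor-like sites uniformly along the genome.
#' Per-site read counts are exponential with mean `c * N2 / p` (rounded),
#' so on average `c` times the control depth is spiked in; read positions
#' are normal around the site with variance `sigma2`, rounded and clamped
#' to the chromosome, with uniform random strands.
#'
#' @param background_chip `shifted_tags` background for the ChIP sample.
#' @param layout A [genome_layout()].
#' @param p Number of sites.
#' @param c_signal Signal/background proportion (expected spiked reads =
#'   `c_signal * N2`).
#' @param N2 Control sample depth that `c_signal` is relative to.
#' @param sigma2 Positional variance in bp^2 (default 900).
#' @param seed Optional integer seed.
#' @return A list with `chip` (background plus signal tags) and
#'   `true_sites` (data.frame `chrom`, `pos`, `count`).
#' @export
spike_point_sources <- function(background_chip, layout, p, c_signal, N2,
                                sigma2 = 900, seed = NULL) {
  stopifnot(p >= 1, c_signal > 0, N2 > 0, sigma2 >= 0)
  .with_seed(seed, {
    sites <- .random_positions(p, layout)
    counts <- round(stats::rexp(p, rate = p / (c_signal * N2)))
    tags <- .place_site_reads(sites, counts, layout, sigma2)
    list(chip = rbind(background_chip, tags),
         true_sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                                 count = counts, stringsAsFactors = FALSE))
  })
}

# normal(mu, sigma2) read placement around point sites, clamped to chromosome
.place_site_reads <- function(sites, counts, layout, sigma2) {
  total <- sum(counts)
  if (total == 0L) {
    return(.make_tags(character(), numeric(), character()))
  }
  site_of <- rep.int(seq_len(nrow(sites)), counts)
  pos <- round(stats::rnorm(total, mean = sites$pos[site_of], sd = sqrt(sigma2)))
  len <- .chrom_lengths(layout, sites$chrom[site_of])
  pos <- pmin(pmax(pos, 0), len - 1)
  .make_tags(sites$chrom[site_of], pos, .random_strands(total))
}

#' Add control-only artifact piles
#'
#' Emulates localized control-sample artifacts such as PCR
#' over-amplification: `k` locations are chosen uniformly along the genome
#' and `floor(frac * N2)` artifact reads are split evenly across them
#' (remainder to the first), each read jittered uniformly within
#' `+/- jitter` bp of its location. Artifact reads are appended to the
#' control only, so they violate the shared-background model by design.
#'
#' @param control `shifted_tags` control sample.
#' @param layout A [genome_layout()].
#' @param k Number of artifact locations (default 20).
#' @param frac Artifact reads as a fraction of the control depth
#'   (default 0.005).
#' @param jitter Half-width of the artifact pile in bp (default 50).
#' @param seed Optional integer seed.
#' @return A list with `control` (augmented) and `artifact_sites`.
#' @export
add_control_artifacts <- function(control, layout, k = 20, frac = 0.005,
                                  jitter = 50, seed = NULL) {
  stopifnot(k >= 1, frac > 0, frac < 1, jitter >= 0)
  .with_seed(seed, {
    N2 <- nrow(control)
    n_art <- floor(frac * N2)
    per <- rep(n_art %/% k, k)
    per[1L] <- per[1L] + n_art %% k
    locs <- .random_positions(k, layout)
    loc_of <- rep.int(seq_len(k), per)
    pos <- locs$pos[loc_of] + round(stats::runif(n_art, -jitter, jitter))
    len <- .chrom_lengths(layout, locs$chrom[loc_of])
    pos <- pmin(pmax(pos, 0), len - 1)
    art <- .make_tags(locs$chrom[loc_of], pos, .random_strands(n_art))
    list(control = rbind(control, art),
         artifact_sites = data.frame(chrom = locs$chrom, pos = locs$pos,
                                     count = per, stringsAsFactors = FALSE))
  })
}

#' Spike diffuse enriched domains into a ChIP background
#'
#' Histone-modification-like signal: `p` regions with lengths uniform in
#' `len_range` are placed uniformly (rejecting placements that do not fit
#' on a chromosome), per-region read counts are exponential with mean
#' `c_signal * N2 / p`, and reads are uniform within their region.
#'
#' @param background_chip `shifted_tags` background for the ChIP sample.
#' @param layout A [genome_layout()].
#' @param p Number of regions (default 50).
#' @param c_signal Signal/background proportion.
#' @param N2 Control depth that `c_signal` is relative to.
#' @param len_range Region length range in bp (default `c(5000, 15000)`).
#' @param max_tries Placement retries per region before erroring.
#' @param seed Optional integer seed.
#' @return A list with `chip` and `true_regions` (data.frame `chrom`,
#'   `start`, `end`, `count`).
#' @export
spike_diffuse_regions <- function(background_chip, layout, p = 50, c_signal = 1,
                                  N2, len_range = c(5000, 15000),
                                  max_tries = 1000, seed = NULL) {
  stopifnot(p >= 1, c_signal > 0, N2 > 0, len_range[1] <= len_range[2])
  .with_seed(seed, {
    regions <- data.frame(chrom = character(p), start = numeric(p),
                          end = numeric(p), stringsAsFactors = FALSE)
    for (i in seq_len(p)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        len <- round(stats::runif(1, len_range[1], len_range[2]))
        ci <- sample.int(nrow(layout), 1L, prob = layout$length)
        if (layout$length[ci] >= len) {
          start <- floor(stats::runif(1) * (layout$length[ci] - len + 1))
          regions$chrom[i] <- layout$chrom[ci]
          regions$start[i] <- start
          regions$end[i] <- start + len
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place an enriched region; are the chromosomes shorter than 'len_range'?")
    }
    counts <- round(stats::rexp(p, rate = p / (c_signal * N2)))
    total <- sum(counts)
    reg_of <- rep.int(seq_len(p), counts)
    pos <- regions$start[reg_of] +
      floor(stats::runif(total) * (regions$end[reg_of] - regions$start[reg_of]))
    tags <- .make_tags(regions$chrom[reg_of], pos, .random_strands(total))
    list(chip = rbind(background_chip, tags),
         true_regions = cbind(regions, count = counts))
  })
}

#' Binding-site pool with Poisson read strengths
#'
#' Builds a pool of `site_pool_size` candidate sites with exponential
#' strengths scaled so that `n_sites` sampled sites carry `c_signal * N2`
#' signal reads in expectation (a synthetic stand-in for a pool of
#' peak-caller-derived real site strengths), samples `n_sites` of them
#' without replacement, draws per-site read counts Poisson(strength) and
#' places reads normally around each site as in the point-source setting.
#'
#' @param background_chip `shifted_tags` background for the ChIP sample.
#' @param layout A [genome_layout()].
#' @param n_sites Sites sampled per dataset (default 1000).
#' @param site_pool_size Pool size (default 1572).
#' @param c_signal,N2 Scale of the strength distribution.
#' @param sigma2 Positional variance (default 900).
#' @param seed Optional integer seed.
#' @return A list with `chip` and `true_sites` (data.frame `chrom`, `pos`,
#'   `strength`, `count`).
#' @export
make_power_truth <- function(background_chip, layout, n_sites = 1000,
                             site_pool_size = 1572, c_signal = 0.5, N2,
                             sigma2 = 900, seed = NULL) {
  stopifnot(n_sites >= 1, n_sites <= site_pool_size, c_signal > 0, N2 > 0)
  .with_seed(seed, {
    pool <- .random_positions(site_pool_size, layout)
    pool$strength <- stats::rexp(site_pool_size, rate = n_sites / (c_signal * N2))
    pick <- sort(sample.int(site_pool_size, n_sites))
    sites <- pool[pick, , drop = FALSE]
    counts <- stats::rpois(n_sites, sites$strength)
    tags <- .place_site_reads(sites, counts, layout, sigma2)
    list(chip = rbind(background_chip, tags),
         true_sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                                 strength = sites$strength, count = counts,
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate a full paired dataset with ground truth
#'
#' Orchestrates the generators into the standard study conditions:
#' * setting 1 — shared background plus point-source signal in ChIP;
#' * setting 2 — setting 1 plus control-only artifact piles;
#' * setting 3 — shared background plus diffuse enriched domains in ChIP;
#' * `"power"` — Poisson-strength site pool plus artifacts (for
#'   FDR/power evaluation).
#'
#' The subsampling divisor `d` emulates shallower sequencing by dividing
#' both background depths. Ground truth is exact by construction:
#' `true_pi0` is the fraction of ChIP reads that are background, and
#' `true_r` is the ratio of background ChIP to background control reads —
#' equal to `true_pi0 * N1 / N2` in settings without artifacts, while
#' control-side artifact reads are model violations that leave the true
#' factor untouched.
#'
#' @param layout A [genome_layout()].
#' @param setting One of `1`, `2`, `3`, `"power"`.
#' @param background_depth Background reads per sample before subsampling
#'   (default 200000).
#' @param c_signal Signal/background proportion (default 1).
#' @param d Subsampling divisor (default 1).
#' @param p Number of sites/regions (defaults: 1000 for point-source
#'   settings, 50 for diffuse).
#' @param sigma2 Positional variance for point sources (default 900).
#' @param artifact_k,artifact_frac Artifact parameters for settings 2 and
#'   power (defaults 20 loci, 0.005 of control depth).
#' @param region_len_range Diffuse region length range (default 5-15 Kbp).
#' @param roughness,window Background intensity parameters
#'   (see [synth_background()]).
#' @param n_sites,site_pool_size Power-setting site pool parameters.
#' @param seed Optional integer seed.
#' @return An object of class `simulated_dataset`: a list with `chip`,
#'   `control` (`shifted_tags`), `true_r`, `true_pi0`, `true_sites`
#'   (positions or regions), `setting`, `seed` and the resolved `config`.
#' @export
simulate_dataset <- function(layout, setting = 1, background_depth = 200000,
                             c_signal = 1, d = 1, p = NULL, sigma2 = 900,
                             artifact_k = 20, artifact_frac = 0.005,
                             region_len_range = c(5000, 15000),
                             roughness = 0.25, window = 1000,
                             n_sites = 1000, site_pool_size = 1572,
                             seed = NULL) {
  setting <- as.character(setting)
  setting <- match.arg(setting, c("1", "2", "3", "power"))
  if (is.null(p)) p <- if (setting == "3") 50 else 1000
  .with_seed(seed, {
    depth <- max(1L, round(background_depth / d))
    bg <- synth_background(layout, depth, depth, roughness, window)
    control <- bg$control
    n2_bg <- nrow(control)
    artifact_sites <- NULL
    if (setting %in% c("2", "power")) {
      art <- add_control_artifacts(control, layout, k = artifact_k,
                                   frac = artifact_frac)
      control <- art$control
      artifact_sites <- art$artifact_sites
    }
    if (setting %in% c("1", "2")) {
      sig <- spike_point_sources(bg$chip, layout, p = p, c_signal = c_signal,
                                 N2 = n2_bg, sigma2 = sigma2)
      chip <- sig$chip; truth <- sig$true_sites
    } else if (setting == "3") {
      sig <- spike_diffuse_regions(bg$chip, layout, p = p, c_signal = c_signal,
                                   N2 = n2_bg, len_range = region_len_range)
      chip <- sig$chip; truth <- sig$true_regions
    } else {
      sig <- make_power_truth(bg$chip, layout, n_sites = n_sites,
                              site_pool_size = site_pool_size,
                              c_signal = c_signal, N2 = n2_bg, sigma2 = sigma2)
      chip <- sig$chip; truth <- sig$true_sites
    }
    N1 <- nrow(chip); N2 <- nrow(control)
    true_pi0 <- depth / N1
    # the true normalization factor aligns the background components:
    # background ChIP over background control reads. Artifact reads are
    # model violations and do not enter it (with equal background depths
    # the true factor is exactly 1 in every setting).
    structure(list(chip = chip, control = control,
                   true_r = depth / n2_bg, true_pi0 = true_pi0,
                   n_background_chip = depth, n_background_control = n2_bg,
                   true_sites = truth, artifact_sites = artifact_sites,
                   setting = setting, seed = seed,
                   config = list(background_depth = background_depth,
                                 c_signal = c_signal, d = d, p = p,
                                 sigma2 = sigma2, artifact_k = artifact_k,
                                 artifact_frac = artifact_frac,
                                 region_len_range = region_len_range,
                                 roughness = roughness, window = window,
                                 n_sites = n_sites,
                                 site_pool_size = site_pool_size)),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> setting %s: N1 = %d, N2 = %d, true r = %.4f, true pi0 = %.4f\n",
              x$setting, nrow(x$chip), nrow(x$control), x$true_r, x$true_pi0))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes `chip.tagAlign` and `control.tagAlign`, the truth as BED
#' (`truth.bed`: point sites as 1 bp intervals, diffuse regions as their
#' intervals) and a JSON manifest with the ground truth and resolved
#' configuration.
#'
#' @param sim A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tagalign(sim$chip, file.path(dir, "chip.tagAlign"))
  write_tagalign(sim$control, file.path(dir, "control.tagAlign"))
  tr <- sim$true_sites
  bed <- if (!is.null(tr$pos)) {
    data.frame(tr$chrom, as.integer(tr$pos), as.integer(tr$pos) + 1L,
               sprintf("site_%d", seq_len(nrow(tr))), tr$count, ".")
  } else {
    data.frame(tr$chrom, as.integer(tr$start), as.integer(tr$end),
               sprintf("region_%d", seq_len(nrow(tr))), tr$count, ".")
  }
  data.table::fwrite(bed, file.path(dir, "truth.bed"), sep = "\t",
                     col.names = FALSE)
  manifest <- list(setting = sim$setting, true_r = sim$true_r,
                   true_pi0 = sim$true_pi0, N1 = nrow(sim$chip),
                   N2 = nrow(sim$control), seed = sim$seed,
                   config = sim$config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
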