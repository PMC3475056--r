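test_that("shared-intensity background conserves depths and is seed-deterministic", {
  gl <- genome_layout(c("chrA", "chrB"), c(2e5, 1e5))
  bg1 <- synth_background(gl, 5000, 4000, seed = 1)
  expect_equal(nrow(bg1$chip), 5000L)
  expect_equal(nrow(bg1$control), 4000L)
  expect_true(all(bg1$chip$pos >= 0))
  expect_true(all(bg1$chip$pos < 2e5))
  bg2 <- synth_background(gl, 5000, 4000, seed = 1)
  expect_identical(bg1, bg2)
  bg3 <- synth_background(gl, 5000, 4000, seed = 2)
  expect_false(identical(bg1$chip$pos, bg3$chip$pos))
})

test_that("zero roughness is indistinguishable from uniform placement", {
  gl <- genome_layout("chrA", 2e5)
  # chi-square goodness of fit against the uniform multinomial over 20 cells
  for (s in 1:4) {
    bg <- synth_background(gl, 20000, 100, roughness = 0, seed = 40 + s)
    counts <- tabulate(bg$chip$pos %/% 10000 + 1, nbins = 20)
    expect_gt(chisq.test(counts)$p.value, 0.01)
  }
})

test_that("split-subsample partitions and thins as requested", {
  set.seed(3)
  reads <- mk_tags(sample(0:99999, 10001, replace = TRUE))
  sp <- split_subsample(reads, d = 1, seed = 10)
  expect_equal(nrow(sp$half_a), 5001L)
  expect_equal(nrow(sp$half_b), 5000L)
  both <- sort(c(as.numeric(rownames(sp$half_a)), as.numeric(rownames(sp$half_b))))
  expect_equal(both, seq_len(10001))  # disjoint union of the input rows
  sp2 <- split_subsample(reads, d = 2, seed = 11)
  expect_lt(abs(nrow(sp2$half_a) - 2500), 4 * sqrt(2500))
  spx <- split_subsample(reads, d = 2, exact = TRUE, seed = 11)
  expect_equal(nrow(spx$half_a), 2500L)
  expect_identical(split_subsample(reads, d = 5, seed = 7),
                   split_subsample(reads, d = 5, seed = 7))
  expect_error(split_subsample(reads[0, ], d = 1), "empty")
})

test_that("point-source spikes have the stated count and positional spread", {
  gl <- genome_layout("chrA", 5e6)
  bg <- mk_tags(numeric())
  # expected spiked total is c * N2; site scatter has sd = sqrt(900) = 30 bp
  sp <- spike_point_sources(bg, gl, p = 400, c_signal = 0.5, N2 = 40000,
                            sigma2 = 900, seed = 8)
  total <- nrow(sp$chip)
  expect_equal(sum(sp$true_sites$count), total)
  # total ~ sum of 400 exponentials with mean 50: sd = 50*20 = 1000
  expect_lt(abs(total - 20000), 4000)
  site_of <- rep.int(seq_len(400), sp$true_sites$count)
  dev <- sp$chip$pos - sp$true_sites$pos[site_of]
  expect_lt(abs(sd(dev) - 30), 2)
  expect_true(all(sp$chip$chrom == sp$true_sites$chrom[site_of]))
})

test_that("control artifacts split the stated read budget across loci", {
  gl <- genome_layout("chrA", 1e6)
  ctrl <- synth_background(gl, 1000, 100000, seed = 2)$control
  art <- add_control_artifacts(ctrl, gl, k = 20, frac = 0.005, seed = 3)
  expect_equal(nrow(art$control), 100000L + 500L)
  expect_equal(art$artifact_sites$count, rep(25L, 20))
  # fewer artifact reads than loci: conservation still holds
  small <- add_control_artifacts(mk_tags(rep(1, 2000)), gl, k = 20,
                                 frac = 0.005, seed = 4)
  expect_equal(sum(small$artifact_sites$count), 10L)
  expect_equal(nrow(small$control), 2010L)
  # artifact reads pile tightly around their locus
  pos <- art$control$pos[100001:100500]
  loc <- rep.int(art$artifact_sites$pos, art$artifact_sites$count)
  expect_true(all(abs(pos - loc) <= 50))
})

test_that("diffuse regions contain their reads and respect placement bounds", {
  gl <- genome_layout(c("chrA", "chrB"), c(1e5, 6e4))
  sp <- spike_diffuse_regions(mk_tags(numeric()), gl, p = 10, c_signal = 1,
                              N2 = 5000, len_range = c(5000, 15000), seed = 6)
  expect_equal(nrow(sp$true_regions), 10L)
  lens <- sp$true_regions$end - sp$true_regions$start
  expect_true(all(lens >= 5000 & lens <= 15000))
  reg_of <- rep.int(seq_len(10), sp$true_regions$count)
  expect_true(all(sp$chip$pos >= sp$true_regions$start[reg_of] &
                    sp$chip$pos < sp$true_regions$end[reg_of]))
  tiny <- genome_layout("chrA", 1000)
  expect_error(spike_diffuse_regions(mk_tags(numeric()), tiny, p = 1,
                                     c_signal = 1, N2 = 100,
                                     len_range = c(5000, 15000), seed = 1),
               "region")
})

test_that("power-simulation sites carry Poisson counts around sampled strengths", {
  gl <- genome_layout("chrA", 5e6)
  pt <- make_power_truth(mk_tags(numeric()), gl, n_sites = 200,
                         site_pool_size = 300, c_signal = 0.5, N2 = 20000,
                         seed = 12)
  expect_equal(nrow(pt$true_sites), 200L)
  expect_equal(nrow(pt$chip), sum(pt$true_sites$count))
  # Poisson counts scatter around strengths: standardized residuals are O(1)
  z <- (pt$true_sites$count - pt$true_sites$strength) /
    sqrt(pmax(pt$true_sites$strength, 1e-9))
  expect_lt(abs(mean(z)), 0.5)
  expect_identical(pt$true_sites,
                   make_power_truth(mk_tags(numeric()), gl, n_sites = 200,
                                    site_pool_size = 300, c_signal = 0.5,
                                    N2 = 20000, seed = 12)$true_sites)
})

test_that("simulated datasets carry exact ground truth by construction", {
  gl <- genome_layout(c("chrA", "chrB"), c(1e6, 5e5))
  for (st in list(1, 2, 3, "power")) {
    sim <- simulate_dataset(gl, setting = st, background_depth = 20000,
                            c_signal = 0.5, p = if (identical(st, 3)) 20 else 200,
                            n_sites = 150, site_pool_size = 200, seed = 50)
    N1 <- nrow(sim$chip); N2 <- nrow(sim$control)
    # the first n_background_chip rows are the background component
    expect_equal(sim$true_pi0, sim$n_background_chip / N1)
    # true factor aligns the background components of the two samples
    expect_equal(sim$true_r, sim$n_background_chip / sim$n_background_control)
    n_signal <- N1 - sim$n_background_chip
    expect_equal(n_signal, sum(sim$true_sites$count))
    if (identical(st, 2) || identical(st, "power")) {
      expect_equal(N2, 20000L + floor(0.005 * 20000))
    } else {
      # without artifacts the control is pure background, so the identity
      # true_r = true_pi0 * N1 / N2 holds exactly
      expect_equal(sim$true_r, sim$true_pi0 * N1 / N2)
      expect_null(sim$artifact_sites)
    }
  }
  expect_identical(simulate_dataset(gl, 1, 5000, seed = 3)$chip,
                   simulate_dataset(gl, 1, 5000, seed = 3)$chip)
})

test_that("subsampling divisor shrinks both background depths", {
  gl <- genome_layout("chrA", 1e6)
  sim <- simulate_dataset(gl, setting = 1, background_depth = 20000, d = 10,
                          c_signal = 0.2, p = 50, seed = 77)
  expect_equal(sim$n_background_chip, 2000L)
  expect_equal(nrow(sim$control), 2000L)
})

test_that("background-only pairs satisfy the linear-relationship premise", {
  # both samples' bin counts follow the same latent intensity, so they are
  # strongly correlated and every ratio-type estimator recovers the depth
  # ratio. (The raw OLS slope of one noisy count on the other is attenuated
  # by regression dilution and is deliberately not the yardstick here.)
  gl <- genome_layout("chrA", 2e6)
  r <- sapply(1:8, function(s) {
    bg <- synth_background(gl, 60000, 40000, seed = 600 + s)
    tab <- bin_counts(bg$chip, bg$control, gl, 10000, drop_zero = FALSE)
    expect_gt(cor(tab$n1, tab$n2), 0.4)
    # background-only estimates can land a hair above the depth ratio,
    # triggering the pi0 > 1 advisory
    suppressWarnings(ncis_estimate(bg$chip, bg$control, gl)$r_hat)
  })
  # recovered to ~1% relative error (the adaptive stop rule carries a small
  # depth-dependent downward selection bias, so an SE-only band is too strict)
  expect_lt(abs(mean(r) - 1.5) / 1.5, 0.01)
})

test_that("datasets round-trip to tagAlign/BED/JSON on disk", {
  gl <- genome_layout("chrA", 1e5)
  sim <- simulate_dataset(gl, setting = 1, background_depth = 2000,
                          c_signal = 0.5, p = 20, seed = 9)
  dir <- withr::local_tempdir()
  write_simulated_dataset(sim, dir)
  chip_back <- shift_reads(load_reads(file.path(dir, "chip.tagAlign"),
                                      "tagalign", gl), l = 1)
  expect_equal(sort(chip_back$pos), sort(sim$chip$pos))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$true_r, sim$true_r)
  truth <- read.delim(file.path(dir, "truth.bed"), header = FALSE)
  expect_equal(nrow(truth), 20L)
})
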