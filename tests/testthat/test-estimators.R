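test_that("background-set ratio is the plain count ratio over B", {
  tab <- fake_bin_table(n1 = c(3, 1), n2 = c(2, 2))
  expect_equal(background_ratio(tab, 1:2), 1)
  expect_equal(background_ratio(tab, 1L), 1.5)
  expect_error(background_ratio(tab, integer()), "empty")
  tab0 <- fake_bin_table(n1 = c(2, 5), n2 = c(0, 0))
  expect_error(background_ratio(tab0, 1:2), "zero")
})

test_that("threshold search picks the first non-decreasing eligible total", {
  # 6x(1,1), 2x(2,1), 1x(1,2), 1x(10,1): eligible from t=3 (9 of 10 bins),
  # r(3) = 11/10 >= r(2) = 1
  tab <- fake_bin_table(n1 = c(rep(1, 6), 2, 2, 1, 10),
                        n2 = c(rep(1, 6), 1, 1, 2, 1))
  fx <- ncis_fixed_w(tab)
  expect_equal(fx$r_hat, 1.1)
  expect_equal(fx$t_star, 3)
  expect_equal(fx$n_background_bins, 9L)
  expect_length(fx$flags, 0)
})

test_that("threshold search degenerate inputs fall back as documented", {
  # symmetric counts: unit ratio wherever the search stops
  sym <- ncis_fixed_w(fake_bin_table(rep(1, 8), rep(1, 8)))
  expect_equal(sym$r_hat, 1)
  # a single distinct total: ratio over all bins, flagged
  one <- ncis_fixed_w(fake_bin_table(c(2, 1, 2), c(1, 2, 1)))
  expect_equal(one$r_hat, 5 / 4)
  expect_true("single_total_fallback" %in% one$flags)
})

test_that("threshold search agrees with the brute-force oracle on random tables", {
  set.seed(202)
  for (i in 1:250) {
    ct <- rand_count_table(120)
    ours <- ncis_fixed_w(fake_bin_table(ct$n1, ct$n2))
    ref <- brute_fixed_w(ct$n1, ct$n2)
    expect_equal(ours$r_hat, ref$r_hat)
    expect_equal(ours$t_star, ref$t_star)
    expect_equal(ours$n_background_bins, ref$n_background_bins)
  }
})

test_that("grid search stops at the first non-decreasing width", {
  gl <- genome_layout("chrA", 2e5)
  set.seed(77)
  chip <- mk_tags(sample(0:199999, 4000, replace = TRUE))
  ctrl <- mk_tags(sample(0:199999, 4000, replace = TRUE))
  res <- ncis_estimate(chip, ctrl, gl, grid = c(100, 200, 500, 1000))
  # trace must stop right after the selected width
  w_sel <- res$w_star
  tr <- res$trace
  i <- match(w_sel, tr$w)
  expect_true(i == nrow(tr) - 1L || "grid_fallback_last_width" %in% res$flags)
  if (i < nrow(tr)) expect_gte(tr$r_hat[i + 1], tr$r_hat[i])
  if (i > 1) expect_true(all(diff(tr$r_hat[1:i]) < 0))
  expect_equal(res$pi0_hat, res$r_hat / res$depth_ratio)
})

test_that("identical ChIP and control give unit normalization where defined", {
  gl <- genome_layout(c("chrA", "chrB"), c(5e4, 5e4))
  set.seed(5)
  tags <- mk_tags(sample(0:49999, 3000, replace = TRUE),
                  chrom = sample(c("chrA", "chrB"), 3000, replace = TRUE),
                  strand = sample(c("+", "-"), 3000, replace = TRUE))
  nc <- ncis_estimate(tags, tags, gl)
  expect_equal(nc$r_hat, 1)
  expect_equal(nc$pi0_hat, 1)
  expect_equal(nc$w_star, 100)  # first grid width: estimates never decrease
  t1000 <- bin_counts(tags, tags, gl, 1000)
  expect_equal(spp_estimate(t1000, gl)$r_hat, 1)
  cc <- ccat_estimate(t1000)
  expect_equal(cc$r_hat, 1)
  expect_true("empty_background_set" %in% cc$flags)
  t10k <- bin_counts(tags, tags, gl, 10000, drop_zero = FALSE)
  expect_equal(peakseq_estimate(t10k)$r_hat, 1)
  # identical samples make every bin total even: the low-count estimator's
  # background set (total <= 1) is empty, its documented deep-data degeneracy
  expect_error(cisgenome_estimate(bin_counts(tags, tags, gl, 100)),
               "degenerate")
})

test_that("low-count background estimator uses total-count-1 bins", {
  tab <- fake_bin_table(n1 = c(1, 1, 1, 0, 0, 9), n2 = c(0, 0, 0, 1, 1, 9))
  res <- suppressWarnings(cisgenome_estimate(tab))  # r above the depth ratio
  expect_equal(res$r_hat, 1.5)
  expect_equal(res$n_background_bins, 5L)
  expect_equal(res$t_star, 1)
  expect_error(cisgenome_estimate(fake_bin_table(c(1, 5), c(0, 5))), "zero")
  expect_error(cisgenome_estimate(fake_bin_table(c(2, 5), c(2, 5))),
               "degenerate")
})

test_that("Poisson-tail exclusion drops enriched bins at the exact tail", {
  # G chosen so each sample's rate is its depth * w / G
  gl <- genome_layout("chrA", 51 * 1000)
  n1 <- c(rep(1, 50), 60); n2 <- rep(1, 51)
  tab <- fake_bin_table(n1, n2, w = 1000)
  rate1 <- sum(n1) * 1000 / genome_size(gl)
  # independent oracle: exact tail mass P(X >= 60)
  p_spike <- 1 - sum(dpois(0:59, rate1))
  expect_lt(p_spike, 1e-5)
  res <- spp_estimate(tab, gl)
  expect_equal(res$n_background_bins, 50L)
  expect_equal(res$r_hat, 1)
  # a zero count can never be excluded: P(X >= 0) = 1
  tab0 <- fake_bin_table(c(0, rep(1, 50)), rep(1, 51), w = 1000)
  expect_equal(spp_estimate(tab0, gl)$n_background_bins, 51L)
})

test_that("strand-split iteration follows the hand-computed trajectory", {
  # bin A: (+: chip 1, ctrl 2; -: chip 2, ctrl 2); bin B: (+: 5, 1; -: 5, 1)
  tab <- fake_bin_table(n1 = c(3, 10), n2 = c(4, 2),
                        n1p = c(1, 5), n2p = c(2, 1), w = 1000)
  res <- ccat_estimate(tab)
  expect_equal(res$r_hat, 1)
  expect_true(res$converged)
  expect_equal(res$trace$r_hat[1], 13 / 6)  # starts at the depth ratio
  expect_equal(res$trace$r_hat[2], 1)
  none <- ccat_estimate(tab, max_iter = 0)
  expect_equal(none$r_hat, 13 / 6)
  expect_false(none$converged)
  expect_true("not_converged" %in% none$flags)
})

test_that("regression estimator returns the OLS slope of ChIP on control", {
  expect_equal(peakseq_estimate(fake_bin_table(c(2, 4, 6, 8), c(1, 2, 3, 4),
                                               w = 10000))$r_hat, 2)
  expect_equal(peakseq_estimate(fake_bin_table(c(3, 7, 5), c(3, 7, 5),
                                               w = 10000))$r_hat, 1)
  expect_error(peakseq_estimate(fake_bin_table(c(1, 5, 9), c(2, 2, 2),
                                               w = 10000)), "constant")
  expect_error(peakseq_estimate(fake_bin_table(c(2, 4), c(1, 2), w = 10000),
                                Pf = 0.1), "Pf = 0")
  # matches lm() on noisy data
  set.seed(9)
  n2 <- rpois(200, 5); n1 <- rpois(200, 5) + n2
  fit <- unname(coef(lm(n1 ~ n2))[2])
  expect_equal(peakseq_estimate(fake_bin_table(n1, n2, w = 10000))$r_hat, fit)
})

test_that("background proportion arithmetic inverts r = pi0 * N1/N2", {
  expect_equal(round(as.numeric(pi0_from_r(1.265, 1.658e6, 1e6)), 3), 0.763)
  expect_equal(round(as.numeric(pi0_from_r(1.370, 1.658e6, 1e6)), 3), 0.826)
  expect_equal(as.numeric(pi0_from_r(1.658, 1.658e6, 1e6)), 1)
  expect_warning(p <- pi0_from_r(2, 1e6, 1e6), "exceeds 1")
  expect_equal(as.numeric(p), 2)
  expect_true("pi0_above_1" %in% attr(p, "flags"))
  expect_error(pi0_from_r(-1, 10, 10), "positive")
  expect_error(pi0_from_r(1, 0, 10), "positive")
})

test_that("with ChIP-only signal the adaptive estimate stays below the depth ratio", {
  gl <- genome_layout("chrA", 1e6)
  for (s in 1:5) {
    sim <- simulate_dataset(gl, setting = 1, background_depth = 2e4,
                            c_signal = 1, p = 100, seed = 900 + s)
    res <- ncis_estimate(sim$chip, sim$control, gl)
    expect_lte(res$r_hat, res$depth_ratio)
  }
})

test_that("estimate_all reports per-method failures without aborting", {
  gl <- genome_layout("chrA", 5e4)
  set.seed(12)
  tags <- mk_tags(sample(0:49999, 2000, replace = TRUE),
                  strand = sample(c("+", "-"), 2000, replace = TRUE))
  res <- estimate_all(tags, tags, gl)
  expect_equal(nrow(res$summary), 5L)
  ok <- res$summary$method != "cisgenome"
  expect_equal(res$summary$r_hat[ok], rep(1, 4))
  expect_match(res$summary$error[!ok], "degenerate")
  expect_null(res$results$cisgenome)
})
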