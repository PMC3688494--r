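test_that("the mixture log-likelihood collapses correctly at theta 0 and 1", {
  rates <- uniform_mismatch_rates(1e-3, read_length = 10, pairs = "all")
  col <- make_pileup("t", 1, "C", c(2, 5, 7), c("C", "T", "C"),
                     c(400, 30, 500))
  llC <- sum(col$n * log(rate_lookup(rates, col$read_pos, "C", col$obs)))
  llT <- sum(col$n * log(rate_lookup(rates, col$read_pos, "T", col$obs)))
  expect_equal(site_log_likelihood(col, rates, 0), llC)
  expect_equal(site_log_likelihood(col, rates, 1), llT)

  # empty column: 0 by convention
  expect_equal(site_log_likelihood(col[0], rates, 0.3), 0)
})

test_that("position-uniform rates reduce to the binomial-mixture closed form", {
  rates <- uniform_mismatch_rates(1e-3, read_length = 20, pairs = "ct_only")
  col <- make_pileup("t", 1, "C", c(3, 11), c("C", "T"), c(900, 100))
  pCC <- rate_lookup(rates, 1L, "C", "C"); pCT <- rate_lookup(rates, 1L, "C", "T")
  pTC <- rate_lookup(rates, 1L, "T", "C"); pTT <- rate_lookup(rates, 1L, "T", "T")
  th <- 0.1
  closed <- 900 * log((1 - th) * pCC + th * pTC) +
            100 * log((1 - th) * pCT + th * pTT)
  expect_equal(site_log_likelihood(col, rates, th), closed)
})

test_that("no T observations yield the null call", {
  rates <- uniform_mismatch_rates(1e-3, read_length = 10)
  col <- make_pileup("t", 1, "C", 4, "C", 1000)
  call <- call_editing_site(col, rates)
  expect_equal(call$theta_hat, 0)
  expect_equal(call$lrt, 0)
  expect_equal(call$pvalue, 1)
  # depth 0: flagged uncovered with the same null statistics
  call0 <- call_editing_site(col[0], rates)
  expect_equal(call0$depth, 0L)
  expect_equal(call0$pvalue, 1)
})

test_that("in the error-free limit theta_hat equals the count fraction", {
  rates <- uniform_mismatch_rates(0, read_length = 10, pairs = "ct_only")
  col <- make_pileup("t", 1, "C", c(1, 2), c("C", "T"), c(900, 100))
  call <- call_editing_site(col, rates)
  expect_equal(call$theta_hat, 0.1, tolerance = 1e-6)
  expect_equal(call$t_fraction, 0.1)
})

test_that("MLE and LRT match closed-form and grid-search oracles", {
  eps <- 1e-3
  rates <- uniform_mismatch_rates(eps, read_length = 97, pairs = "ct_only")
  col <- make_pileup("t", 1, "C", c(10, 40), c("C", "T"), c(9900, 100))
  call <- call_editing_site(col, rates)
  # closed form for the symmetric C/T-only channel
  expect_equal(call$theta_hat, (0.01 - eps) / (1 - 2 * eps), tolerance = 1e-6)
  # grid-search oracle over theta
  grid <- c(0, 10^seq(-6, 0, length.out = 20000))
  grid <- grid[grid <= 1]
  ll <- site_log_likelihood(col, rates, grid)
  expect_equal(call$theta_hat, grid[which.max(ll)], tolerance = 1e-3)
  lrt_grid <- 2 * (max(ll) - ll[1])
  expect_equal(call$lrt, lrt_grid, tolerance = 1e-4 * lrt_grid)
  expect_equal(call$pvalue, pchisq(call$lrt, 1, lower.tail = FALSE))
})

test_that("lrt is non-negative and the p-value is monotone in it", {
  set.seed(31)
  rates <- calibration_rates(1e-3, n_c = 1e6, n_t = 1e5)
  sim <- simulate_pileup(200, 2000, runif(200, 0, 0.05), error_rate = 1e-3)
  calls <- call_columns(sim$pileup, rates)
  expect_true(all(calls$lrt >= 0))
  ord <- order(calls$lrt)
  expect_true(all(diff(calls$pvalue[ord]) <= 1e-12))
  expect_true(all(calls$theta_hat >= 0 & calls$theta_hat <= 1))
})

test_that("editing fractions are recovered accurately at study depth", {
  set.seed(37)
  rates <- calibration_rates(1e-3, n_c = 2e6, n_t = 2e5)
  thetas <- c(0.05, 0.1, 0.5, 0.9)
  sim <- simulate_pileup(200, 5500, rep(thetas, each = 50), error_rate = 1e-3)
  calls <- call_columns(sim$pileup, rates)
  joined <- merge(calls, sim$truth, by = c("template_id", "position"))
  err <- joined[, .(mean_abs = mean(abs(theta_hat - theta))), by = theta]
  expect_true(all(err$mean_abs < 0.01))
})

test_that("detection power is non-decreasing in depth at fixed theta", {
  set.seed(41)
  rates <- calibration_rates(1e-3, n_c = 2e6, n_t = 2e5)
  depths <- c(100, 500, 2000, 8000)
  power <- vapply(depths, function(d) {
    sim <- simulate_pileup(150, d, 0.03, error_rate = 1e-3)
    calls <- call_columns(sim$pileup, rates)
    mean(calls$pvalue < 1e-6)
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[4], power[1])
})

test_that("per-library significance marking is strictly below alpha", {
  templates <- template_set(c(t1 = "ACCA"))
  rates <- uniform_mismatch_rates(1e-3, read_length = 5)
  pu <- rbind(make_pileup("t1", 2, "C", 1, c("C", "T"), c(100, 50)),
              make_pileup("t1", 3, "C", 1, "C", 100))
  calls <- call_sites(pu, rates, templates, library_id = "L1",
                      alpha_site = 1e-6)
  expect_equal(nrow(calls), 2L) # the template's two C positions
  expect_true(calls[position == 2]$significant)
  expect_false(calls[position == 3]$significant)
  # boundary: a p-value exactly at alpha is not significant
  fake <- copy(calls)[position == 2, pvalue := 1e-6]
  expect_false(fake[position == 2, pvalue < 1e-6])
})

test_that("candidate selection applies the three filters with strict inequalities", {
  mk <- function(site, lib, pval, tfrac, depth)
    data.table(template_id = "t", position = site, library_id = lib,
               c_count = 0L, t_count = 0L, other_count = 0L,
               depth = depth, t_fraction = tfrac, theta_hat = tfrac,
               lrt = 0, pvalue = pval, significant = pval < 1e-6)
  calls <- rbind(
    mk(1L, "a", 1e-8, 0.20, 500), mk(1L, "b", 0.5, 0.01, 500),   # passes all
    mk(2L, "a", 1e-8, 0.04, 500), mk(2L, "b", 0.9, 0.04, 500),   # fraction fails
    mk(3L, "a", 1e-8, 0.30, 100), mk(3L, "b", 0.9, 0.30, 100),   # depth == 100 fails
    mk(4L, "a", 1e-3, 0.30, 500), mk(4L, "b", 0.9, 0.30, 500))   # union fails
  cand <- select_candidates(calls)
  expect_true(cand[position == 1]$selected)
  expect_false(cand[position == 2]$selected)
  expect_false(cand[position == 3]$selected)  # mean depth exactly 100: strict
  expect_false(cand[position == 4]$selected)
  # fraction exactly at the threshold is excluded too
  calls5 <- rbind(mk(5L, "a", 1e-8, 0.05, 500), mk(5L, "b", 0.5, 0.05, 500))
  expect_false(select_candidates(calls5)$selected)
})

test_that("candidate selection recovers a seeded truth set exactly", {
  set.seed(43)
  rates <- calibration_rates(1e-3, n_c = 2e6, n_t = 2e5)
  n_null <- 5000L; n_edit <- 50L
  theta <- c(rep(0, n_null), rep(c(0.1, 0.5, 0.9), length.out = n_edit))
  sim <- simulate_pileup(n_null + n_edit, 2000, theta, error_rate = 1e-3)
  calls <- call_columns(sim$pileup, rates)
  calls[, library_id := "sim"]
  cand <- select_candidates(calls, n_libraries = 1L)
  picked <- cand[selected == TRUE]
  truth_edited <- sim$truth[theta > 0]
  expect_equal(nrow(picked), n_edit)                      # no false positives
  expect_equal(nrow(picked[truth_edited, on = c("template_id", "position"),
                           nomatch = NULL]), n_edit)      # full recall
})

test_that("editing extent is the T fraction of covered reads", {
  expect_equal(editing_extent(12290 - 117, 117), 117 / 12290)
  expect_equal(round(editing_extent(12290 - 117, 117), 6), 0.009520)
  expect_equal(editing_extent(0, 25), 1)
  expect_equal(editing_extent(25, 0), 0)
  expect_error(editing_extent(0, 0), "undefined")
})

test_that("silent/non-silent annotation follows the genetic code", {
  # geneA CDS: ATG CCT CTT GGA CGT ACC GTA GCT AGC TAA
  templates <- toy_templates()
  # codon 2 CCT: editing its position-2 C -> CTT changes Pro to Leu
  expect_equal(annotate_silent(templates, "tmplA", 5L), "non_silent")
  # codon 2 position 3? position 6 is T; use codon 6 ACC -> position 18 C at
  # codon position 3: ACC(Thr) -> ACT(Thr) silent
  expect_equal(annotate_silent(templates, "tmplA", 18L), "silent")
  # outside the CDS -> non-coding; non-coding template -> non-coding
  expect_equal(annotate_silent(templates, "tmplA", 33L), "non_coding")
  expect_equal(annotate_silent(templates, "tmplB", 9L), "non_coding")
  # inconsistent frame annotation errors
  bad <- template_set(c(x = "ATGCC"), cds_start = 1L, cds_end = 5L)
  expect_error(annotate_silent(bad, "x", 4L), "inconsistent")
})
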