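test_that("binomial tails match exact pmf summation", {
  # worked value: equal libraries, 15 vs 5
  r <- binomial_window_test(15, 5, 1e6, 1e6)
  expect_equal(r$p_inc, 21700 / 1048576, tolerance = 1e-12)
  for (p0 in c(0.3, 0.5, 0.7)) {
    n_a <- round(1e6 * p0); n_b <- 1e6 - n_a
    for (n in c(1, 2, 7, 13)) {
      for (k_a in 0:n) {
        got <- binomial_window_test(k_a, n - k_a, n_a, n_b)
        want <- oracle_binom_tails(k_a, n, p0)
        expect_equal(got$p_inc, want$p_inc, tolerance = 1e-12)
        expect_equal(got$p_dec, want$p_dec, tolerance = 1e-12)
      }
    }
  }
})

test_that("degenerate and symmetric windows behave", {
  r <- binomial_window_test(0, 0, 10, 10)
  expect_equal(r$p_inc, 1)
  expect_equal(r$p_dec, 1)
  expect_equal(r$direction, "none")
  r2 <- binomial_window_test(8, 8, 1e5, 1e5)
  expect_gte(r2$p_inc, 0.5)
  expect_gte(r2$p_dec, 0.5)
})

test_that("p_inc is non-increasing in k_a at fixed n", {
  for (p0n in list(c(3, 7), c(5, 5))) {
    n_a <- p0n[1] * 1e5; n_b <- p0n[2] * 1e5
    for (n in c(6, 19)) {
      p <- binomial_window_test(0:n, n:0, n_a, n_b)$p_inc
      expect_true(all(diff(p) <= 1e-14))
    }
  }
})

test_that("window tiling covers chromosomes deterministically", {
  lib <- make_lib(c(10, 5000), chrom_sizes = c(chr1 = 10000))
  w <- scan_windows(lib, lib, window = 2000, step = 500)
  expect_equal(nrow(w), 17)            # floor((L - w)/s) + 1, no remainder
  expect_equal(w$start, seq(0, 8000, 500))
  expect_false(any(w$truncated))
  # a 3' remainder adds one flagged partial window
  lib2 <- make_lib(10, chrom_sizes = c(chr1 = 10300))
  w2 <- scan_windows(lib2, lib2)
  expect_equal(sum(w2$truncated), 1)
  expect_equal(w2$end[w2$truncated], 10300)
  # chromosome shorter than the window: one truncated window
  lib3 <- make_lib(10, chrom_sizes = c(chr1 = 900))
  w3 <- scan_windows(lib3, lib3)
  expect_equal(nrow(w3), 1)
  expect_true(w3$truncated)
})

test_that("empty libraries give all-none windows", {
  lib <- make_lib(integer(0), chrom_sizes = c(chr1 = 10000))
  w <- scan_windows(lib, lib)
  expect_true(all(w$direction == "none"))
  expect_true(all(w$p_inc == 1 & w$p_dec == 1))
})

test_that("swapping libraries swaps tails and flips directions", {
  sim <- sim_tag_libraries(c(chr1 = 4e5),
                           spikes = tibble::tibble(chrom = "chr1",
                                                   start = c(5e4, 2e5),
                                                   end = c(5.2e4, 2.02e5),
                                                   ratio = c(4, 4)),
                           seed = 41)
  ab <- scan_windows(sim$lib_a, sim$lib_b)
  ba <- scan_windows(sim$lib_b, sim$lib_a)
  expect_equal(ab$p_inc, ba$p_dec, tolerance = 1e-12)
  expect_equal(ab$p_dec, ba$p_inc, tolerance = 1e-12)
  r_ab <- merge_significant(ab)
  r_ba <- merge_significant(ba)
  flip <- c(increase = "decrease", decrease = "increase")
  expect_equal(r_ab[, c("chrom", "start", "end")],
               r_ba[, c("chrom", "start", "end")])
  expect_equal(unname(flip[r_ab$direction]), r_ba$direction)
})

test_that("significant windows merge into homogeneous regions", {
  w <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 500L, 1000L, 8000L, 10000L),
    end = start + 2000L,
    truncated = FALSE,
    p_inc = c(1e-5, 1e-4, 1e-6, 1, 1e-5),
    p_dec = c(1, 1, 1, 1e-4, 1),
    mlog10_inc = -log10(p_inc), mlog10_dec = -log10(p_dec),
    n = 20L, p0 = 0.5
  )
  r <- merge_significant(w, alpha = 1e-3)
  expect_equal(nrow(r), 3)
  inc1 <- r[r$start == 0, ]
  expect_equal(inc1$end, 3000L)          # union of starts 0/500/1000
  expect_equal(inc1$width, 3000L)
  expect_equal(inc1$peak_score, 6)
  expect_equal(inc1$n_windows, 3L)
  # adjacent opposite-direction windows stay separate
  expect_setequal(r$direction[r$start >= 8000], c("decrease", "increase"))
  # a lone significant window gives a region of exactly one window width
  lone <- merge_significant(w[5, ], alpha = 1e-3)
  expect_equal(lone$width, 2000L)
})

test_that("FDR estimate behaves on null and spiked data", {
  # null: nearly all discoveries are false, estimate caps at ~1
  null <- sim_tag_libraries(c(chr1 = 2e6), seed = 23)
  wn <- scan_windows(null$lib_a, null$lib_b)
  fdr_null <- estimate_fdr(wn, alpha = 1e-3)
  expect_gte(fdr_null, 0.9)
  expect_lte(fdr_null, 1)
  # strong spikes dominate discoveries: FDR well below 1
  sp <- tibble::tibble(chrom = "chr1", start = seq(1e5, 9e5, 5e4),
                       end = start + 2000, ratio = 5)
  spk <- sim_tag_libraries(c(chr1 = 2e6), spikes = sp, seed = 29)
  ws <- scan_windows(spk$lib_a, spk$lib_b)
  expect_lt(estimate_fdr(ws, alpha = 1e-3), 0.3)
  # nothing called: NA with a reason
  tiny <- make_lib(c(10, 20), chrom_sizes = c(chr1 = 4000))
  wt <- scan_windows(tiny, tiny)
  expect_true(is.na(estimate_fdr(wt, alpha = 1e-3)))
  expect_match(attr(estimate_fdr(wt, alpha = 1e-3), "reason"), "no window")
})
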