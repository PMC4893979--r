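test_that("window pairing applies the 10% eligibility and 15% penalty rules", {
  layout <- toy_layout(1e5)
  d1 <- disp_from_drci(c(10L, 20L, 30L, 40L), c(2, 4, 12, 9), layout)
  d2 <- disp_from_drci(c(10L, 25L, 30L, 40L), c(3, 8, 11, 9.5), layout)
  pairs <- pair_windows(d1, d2)
  # windows 10, 40: eligible in both; 20 in rep1 only; 25 in rep2 only;
  # 30 eligible in neither (dRCI >= 10 on both sides) and never enters
  expect_equal(sort(pairs$bin), c(10L, 20L, 25L, 40L))
  w <- function(b) pairs[pairs$bin == b, ]
  expect_equal(w(10L)$abs_diff, 1)
  expect_false(w(10L)$penalty_rep1 || w(10L)$penalty_rep2)
  expect_equal(w(20L)$drci_rep2, 15)
  expect_true(w(20L)$penalty_rep2)
  expect_equal(w(20L)$abs_diff, 11)
  expect_equal(w(25L)$drci_rep1, 15)
  expect_true(w(25L)$penalty_rep1)
  expect_equal(w(40L)$abs_diff, 0.5)
  # ranking: ascending abs_diff
  expect_false(is.unsorted(pairs$abs_diff))
})

test_that("pairing is symmetric and exact on self-comparison", {
  layout <- toy_layout(1e6)
  reads <- uniform_reads(3e4, layout, seed = 51)
  d <- run_qc(reads, layout, subsample_plan(seed = 52))$dispersion
  self <- pair_windows(d, d)
  expect_equal(sum(self$penalty_rep1 | self$penalty_rep2), 0L)
  expect_true(all(self$abs_diff == 0))

  d2 <- run_qc(uniform_reads(3e4, layout, seed = 53), layout,
               subsample_plan(seed = 54))$dispersion
  ab <- pair_windows(d, d2)
  ba <- pair_windows(d2, d)
  expect_equal(ab$bin, ba$bin)
  expect_equal(ab$abs_diff, ba$abs_diff)
  expect_equal(idr_curve(ab)$groups$local_idr, idr_curve(ba)$groups$local_idr)

  mism <- run_qc(uniform_reads(1e3, toy_layout(5e4), seed = 1),
                 toy_layout(5e4), subsample_plan(seed = 1))$dispersion
  expect_error(pair_windows(d, mism), "layout")
})

test_that("sliding groups compute the local penalty fraction", {
  layout <- genome_layout("chr1", 5e6)
  # 4500 concordant windows + 500 present only in rep1: one full group
  d1 <- disp_from_drci(1:5000, rep(1, 5000), layout)
  d2 <- disp_from_drci(1:4500, rep(1, 4500), layout)
  pairs <- pair_windows(d1, d2)
  curve <- idr_curve(pairs)
  expect_equal(nrow(curve$groups), 1L)
  expect_equal(curve$groups$local_idr, 0.1)       # 500 / 5,000
  expect_equal(curve$penalty_fraction, 0.1)
  expect_false(curve$single_group)
  # penalty-free pairing: local IDR identically zero
  clean <- idr_curve(pair_windows(d1, d1))
  expect_true(all(clean$groups$local_idr == 0))
  expect_equal(clean$n_windows_below_threshold, 5000L)
})

test_that("group spans follow the sliding scheme and pool the tail", {
  layout <- genome_layout("chr1", 1e7)
  d1 <- disp_from_drci(1:6200, rep(1, 6200), layout)
  d2 <- disp_from_drci(1:6200, rep(1, 6200), layout)
  curve <- idr_curve(pair_windows(d1, d2))
  expect_equal(curve$groups$rank_start, c(1L, 501L, 1001L))
  expect_equal(curve$groups$rank_end, c(5000L, 5500L, 6000L))
  # fewer windows than one group: single flagged group over everything
  small <- idr_curve(pair_windows(disp_from_drci(1:300, rep(1, 300), layout),
                                  disp_from_drci(1:300, rep(1, 300), layout)))
  expect_true(small$single_group)
  expect_equal(nrow(small$groups), 1L)
  expect_equal(small$groups$rank_end, 300L)
})

test_that("windows below the IDR threshold are counted over group cover", {
  layout <- genome_layout("chr1", 1e7)
  # ranking: 5400 real pairs (abs_diff 0) then 800 penalty pairs (15)
  d1 <- disp_from_drci(1:6200, rep(2, 6200), layout)
  d2 <- disp_from_drci(1:5400, rep(2, 5400), layout)
  curve <- idr_curve(pair_windows(d1, d2))
  # groups: [1,5000] idr 0; [501,5500] idr 100/5000 = 0.02;
  # [1001,6000] idr 600/5000 = 0.12 (> 0.1, excluded)
  expect_equal(curve$groups$local_idr, c(0, 0.02, 0.12))
  expect_equal(curve$n_windows_below_threshold, 5500L)
  expect_equal(curve$threshold, 0.1)
})

test_that("degrading one replicate monotonically raises the local IDR", {
  layout <- toy_layout(2e6)
  reads <- uniform_reads(1e5, layout, seed = 61)
  d <- run_qc(reads, layout, subsample_plan(seed = 62))$dispersion
  mean_idr <- function(q) {
    el <- d$drci < 10
    set.seed(100 + round(100 * q))
    drop <- sample(which(el), round(q * sum(el)))
    keep <- setdiff(seq_along(d$bins), drop)
    d2 <- disp_from_drci(d$bins[keep], d$drci[keep], layout)
    mean(idr_curve(pair_windows(d, d2))$groups$local_idr)
  }
  idrs <- vapply(c(0, 0.1, 0.3, 0.5), mean_idr, 0)
  expect_equal(idrs[1], 0)
  expect_true(all(diff(idrs) > 0))
})
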