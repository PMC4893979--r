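test_that("landscape placement is disjoint, in-bounds and seeded", {
  g <- genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
  cfg <- sim_config(g, "sharp", n_regions = 200, total_reads = 1e4, seed = 9)
  land <- plan_landscape(cfg)
  expect_equal(nrow(land), 200L)
  expect_true(all(land$end - land$start == 1000))
  for (cc in unique(land$chrom)) {
    li <- land[land$chrom == cc, ]
    expect_true(all(li$end <= g$length[match(cc, g$chrom)]))
    expect_true(all(li$start >= 0))
    o <- order(li$start)
    if (nrow(li) > 1) expect_true(all(li$start[o][-1] >= li$end[o][-nrow(li)]))
  }
  expect_identical(plan_landscape(cfg), land)
  expect_false(identical(plan_landscape(sim_config(g, "sharp", n_regions = 200,
                                                   total_reads = 1e4, seed = 10)),
                         land))
  # empty landscape and impossible footprints
  expect_equal(nrow(plan_landscape(sim_config(g, "sharp", n_regions = 0,
                                              total_reads = 1e4))), 0L)
  expect_error(sim_config(g, "broad", n_regions = 100, total_reads = 1e4),
               "footprint")
})

test_that("simulated read sets have the configured size and bounds", {
  g <- genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
  cfg <- sim_config(g, "sharp", n_regions = 100, enrichment_fraction = 0.5,
                    total_reads = 25000, seed = 3)
  reads <- simulate_reads(cfg)
  expect_equal(tmr(reads), 25000L)
  expect_true(all(reads$end - reads$start == 50))
  len <- g$length[match(as.character(reads$chrom), g$chrom)]
  expect_true(all(reads$start >= 0 & reads$end <= len))
  expect_true(all(as.character(reads$strand) %in% c("+", "-")))
  # seeded determinism of the full dataset
  expect_equal(simulate_reads(cfg)$start, reads$start)
})

test_that("the empirical enrichment matches the configured share", {
  g <- genome_layout("chr1", 1e7)
  enr <- 0.6
  cfg <- sim_config(g, "sharp", n_regions = 500, enrichment_fraction = enr,
                    total_reads = 5e4, seed = 5)
  reads <- simulate_reads(cfg)
  land <- attr(reads, "landscape")
  # read starts are uniform within regions by construction; background
  # starts land in a region with probability ~ footprint
  pos <- reads$start
  in_region <- rep(FALSE, tmr(reads))
  o <- order(land$start)
  idx <- findInterval(pos, land$start[o])
  hit <- idx >= 1
  in_region[hit] <- pos[hit] < land$end[o][idx[hit]]
  footprint <- sum(land$end - land$start) / sum(g$length)
  p_expected <- enr + (1 - enr) * footprint
  se <- sqrt(p_expected * (1 - p_expected) / tmr(reads))
  expect_lt(abs(mean(in_region) - p_expected), 3 * se)
})

test_that("pure background reads are uniform over the bin grid", {
  g <- genome_layout("chr1", 1e6)
  cfg <- sim_config(g, "sharp", n_regions = 0, enrichment_fraction = 0,
                    total_reads = 5e4, seed = 6)
  counts <- bin_reads(simulate_reads(cfg), g)$counts
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 1e-4)
})

test_that("broad domains dilute the per-enriched-bin coverage", {
  g <- genome_layout("chr1", 5e7)
  common <- list(n_regions = 300, enrichment_fraction = 0.6,
                 total_reads = 2e5, seed = 8)
  per_bin <- function(mark) {
    cfg <- do.call(sim_config, c(list(g, mark), common))
    reads <- simulate_reads(cfg)
    land <- attr(reads, "landscape")
    counts <- bin_reads(reads, g)$counts
    bins <- unlist(lapply(seq_len(nrow(land)), function(i) {
      lo <- floor(land$start[i] / 500) + 1
      hi <- floor((land$end[i] - 1) / 500) + 1
      lo:hi
    }))
    mean(counts[unique(bins)])
  }
  expect_gt(per_bin("sharp"), 5 * per_bin("broad"))
})
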