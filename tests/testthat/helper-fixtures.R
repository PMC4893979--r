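# shared fixture builders and independent brute-force oracles

toy_layout <- function(len = 1e5, bin_width = 500, chroms = "chr1") {
  genome_layout(chroms, rep(len, length(chroms)), bin_width = bin_width)
}

# binned_profile from explicit counts (bypasses read binning)
profile_from_counts <- function(counts, layout) {
  stopifnot(length(counts) == layout$total_bins)
  structure(list(counts = as.integer(counts), assigned_total = sum(counts),
                 layout = layout),
            class = "binned_profile")
}

# dispersion_profile from explicit per-window dRCI values
disp_from_drci <- function(bins, drci, layout, fraction = 0.5) {
  chipgrade:::new_dispersion_profile(fraction, bins, drci, layout)
}

# independent brute-force reimplementation of binning: one explicit loop
# per read, no vectorisation shared with the package
oracle_bin_counts <- function(reads, layout) {
  counts <- integer(layout$total_bins)
  for (i in seq_len(nrow(reads))) {
    ci <- which(layout$chrom == as.character(reads$chrom[i]))
    mid <- floor((reads$start[i] + reads$end[i]) / 2)
    b <- layout$bin_offset[ci] + mid %/% layout$bin_width + 1
    counts[b] <- counts[b] + 1L
  }
  counts
}

# brute-force dRCI + scores on toy profiles
oracle_dispersion <- function(orig, sub, s) {
  bins <- c(); drci <- c()
  for (b in seq_along(orig)) {
    if (orig[b] > 0) {
      expected <- s * orig[b]
      bins <- c(bins, b)
      drci <- c(drci, 100 * abs(sub[b] - expected) / expected)
    }
  }
  list(bins = bins, drci = drci)
}

oracle_scores <- function(drci, thresholds = c(2.5, 5, 10)) {
  out <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    n_ok <- 0L
    for (d in drci) if (d <= thresholds[i]) n_ok <- n_ok + 1L
    out[i] <- 100 * n_ok / length(drci)
  }
  out
}

# uniform reads placed directly (independent of the simulator) for tests
# that need a null dataset without trusting simulate_reads
uniform_reads <- function(n, layout, read_length = 50, seed = 1) {
  set.seed(seed)
  ci <- sample.int(length(layout$chrom), n, replace = TRUE,
                   prob = layout$length / sum(layout$length))
  start <- floor(runif(n) * (layout$length[ci] - read_length))
  mapped_reads(layout$chrom[ci], start, start + read_length, layout = layout)
}

test_boundaries <- function(q25 = c(10, 25, 50), q5 = q25, q10 = q25) {
  grade_boundaries(rbind("2.5" = q25, "5" = q5, "10" = q10),
                   provenance = "test fixture")
}

# depth_curve object from explicit (tmr, score_2_5) points
synthetic_depth_curve <- function(tmrs, scores) {
  structure(list(
    points = data.frame(outer_fraction = tmrs / max(tmrs), tmr = tmrs,
                        score_2_5 = scores, score_5 = scores,
                        score_10 = scores, grade = NA_character_,
                        flagged = FALSE, stringsAsFactors = FALSE),
    results = NULL, total_tmr = max(tmrs)),
    class = "depth_curve")
}

write_bed_lines <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}
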