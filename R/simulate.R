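#' Configuration of a synthetic ChIP-seq read simulation
#'
#' Describes a synthetic enrichment landscape: a uniform background over
#' the whole genome plus `n_regions` enriched intervals that are either
#' narrow peaks (`"sharp"`, H3K4me3-like, 1 kb by default) or wide
#' domains (`"broad"`, H3K27me3-like, 50 kb by default). Each simulated
#' read is drawn from the enriched regions with probability
#' `enrichment_fraction`, otherwise uniformly from the genome.
#'
#' @param genome a [genome_layout()].
#' @param mark_type `"sharp"` or `"broad"`.
#' @param n_regions number of enriched regions.
#' @param region_width region width in bp; defaults to 1,000 (sharp) or
#'   50,000 (broad).
#' @param enrichment_fraction share of reads drawn from enriched regions,
#'   in \[0, 1\].
#' @param total_reads number of reads to simulate.
#' @param read_length read length in bp (default 50).
#' @param seed master seed; landscape placement and read placement use
#'   independent derived substreams.
#' @return a `sim_config` object.
#' @export
sim_config <- function(genome, mark_type = c("sharp", "broad"),
                       n_regions = 1000L, region_width = NULL,
                       enrichment_fraction = 0.5, total_reads = 1e6,
                       read_length = 50L, seed = 1L) {
  stopifnot(inherits(genome, "genome_layout"))
  mark_type <- match.arg(mark_type)
  region_width <- region_width %||% switch(mark_type, sharp = 1000L, broad = 50000L)
  if (enrichment_fraction < 0 || enrichment_fraction > 1) {
    stop_chipgrade("enrichment_fraction must be in [0, 1]")
  }
  if (n_regions < 0) stop_chipgrade("n_regions must be >= 0")
  if (n_regions * region_width >= sum(genome$length)) {
    stop_chipgrade("total region footprint (%.0f bp) must be smaller than the genome (%.0f bp)",
                   n_regions * region_width, sum(genome$length))
  }
  if (read_length <= 0) stop_chipgrade("read_length must be positive")
  if (any(genome$length < read_length)) {
    stop_chipgrade("every chromosome must be at least one read long")
  }
  structure(
    list(genome = genome, mark_type = mark_type,
         n_regions = as.integer(n_regions),
         region_width = as.numeric(region_width),
         enrichment_fraction = enrichment_fraction,
         total_reads = as.numeric(total_reads),
         read_length = as.numeric(read_length), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s: %d x %.0f bp regions, enrichment %.2f, %.3g reads, seed %d\n",
              x$mark_type, x$n_regions, x$region_width,
              x$enrichment_fraction, x$total_reads, x$seed))
  invisible(x)
}

#' Place the enriched-region landscape
#'
#' Draws `n_regions` non-overlapping intervals of `region_width`,
#' uniformly over the genome, deterministically per seed. Placement
#' resamples colliding candidates for a bounded number of rounds and
#' errors out if the genome is too crowded to finish.
#'
#' @param config a [sim_config()].
#' @return a `data.table` with columns `chrom`, `start`, `end`
#'   (0-based half-open), sorted by coordinate.
#' @export
plan_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genome
  w <- config$region_width
  n <- config$n_regions
  empty <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric())
  if (n == 0L) return(empty)
  # candidate slots per chromosome: starts in [0, L - w]
  slots <- pmax(g$length - w + 1, 0)
  if (sum(slots) < 1) stop_chipgrade("no chromosome can hold a %.0f bp region", w)
  with_seed(derive_seed(config$seed, "landscape"), {
    placed_chrom <- integer(0)
    placed_start <- numeric(0)
    need <- n
    for (round in seq_len(200L)) {
      ci <- sample.int(length(slots), need, replace = TRUE,
                       prob = slots / sum(slots))
      st <- floor(stats::runif(need) * slots[ci])
      cand_c <- c(placed_chrom, ci)
      cand_s <- c(placed_start, st)
      o <- order(cand_c, cand_s)
      cand_c <- cand_c[o]; cand_s <- cand_s[o]
      # drop any candidate starting within w of its predecessor on the
      # same chromosome (keeps the earlier one)
      keep <- c(TRUE, !(cand_c[-1] == cand_c[-length(cand_c)] &
                          cand_s[-1] < cand_s[-length(cand_s)] + w))
      # iterate: a dropped interval can unmask a new collision
      while (!all(keep)) {
        cand_c <- cand_c[keep]; cand_s <- cand_s[keep]
        keep <- c(TRUE, !(cand_c[-1] == cand_c[-length(cand_c)] &
                            cand_s[-1] < cand_s[-length(cand_s)] + w))
      }
      placed_chrom <- cand_c
      placed_start <- cand_s
      need <- n - length(placed_chrom)
      if (need == 0L) break
    }
    if (need > 0L) {
      stop_chipgrade("could not place %d regions of %.0f bp without overlap; reduce n_regions",
                     n, w)
    }
    data.table::data.table(chrom = g$chrom[placed_chrom],
                           start = placed_start,
                           end = placed_start + w)
  })
}

#' Simulate genome-aligned ChIP-seq reads
#'
#' Draws `total_reads` reads independently: with probability
#' `enrichment_fraction` a read starts uniformly within a randomly chosen
#' enriched interval, otherwise uniformly on the genome; each read
#' occupies `read_length` bp (clamped to stay within its chromosome) on a
#' uniformly chosen strand. Reads are i.i.d. — no duplicate-structure or
#' mappability model — so count behaviour under subsampling follows the
#' exact hypergeometric law the quality statistic assumes.
#'
#' @param config a [sim_config()].
#' @param landscape enriched intervals from [plan_landscape()]; computed
#'   from `config` when omitted.
#' @return a [mapped_reads()] object with exactly `total_reads` records;
#'   the landscape is attached as attribute `"landscape"`.
#' @export
simulate_reads <- function(config, landscape = NULL) {
  stopifnot(inherits(config, "sim_config"))
  landscape <- landscape %||% plan_landscape(config)
  g <- config$genome
  n <- config$total_reads
  rl <- config$read_length
  with_seed(derive_seed(config$seed, "reads"), {
    enriched <- stats::runif(n) < config$enrichment_fraction &
      nrow(landscape) > 0L
    ne <- sum(enriched)
    ci <- integer(n)
    start <- numeric(n)
    if (ne > 0L) {
      reg <- sample.int(nrow(landscape), ne, replace = TRUE)
      ci[enriched] <- match(landscape$chrom[reg], g$chrom)
      start[enriched] <- landscape$start[reg] +
        floor(stats::runif(ne) * config$region_width)
    }
    nb <- n - ne
    if (nb > 0L) {
      cb <- sample.int(length(g$chrom), nb, replace = TRUE,
                       prob = g$length / sum(g$length))
      ci[!enriched] <- cb
      start[!enriched] <- floor(stats::runif(nb) * (g$length[cb] - rl + 1))
    }
    start <- pmin(start, g$length[ci] - rl)  # enriched reads near a chromosome end
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads <- mapped_reads(g$chrom[ci], start, start + rl, strand = strand,
                          layout = g)
    data.table::setattr(reads, "landscape", landscape)
    reads
  })
}

#' Simulate a complete dataset in one call
#'
#' Convenience wrapper building the configuration, landscape and reads.
#'
#' @inheritParams sim_config
#' @return a [mapped_reads()] object with the landscape attached.
#' @export
simulate_chip <- function(genome, mark_type = "sharp", n_regions = 1000L,
                          region_width = NULL, enrichment_fraction = 0.5,
                          total_reads = 1e6, read_length = 50L, seed = 1L) {
  cfg <- sim_config(genome, mark_type = mark_type, n_regions = n_regions,
                    region_width = region_width,
                    enrichment_fraction = enrichment_fraction,
                    total_reads = total_reads, read_length = read_length,
                    seed = seed)
  simulate_reads(cfg)
}
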