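#' Genome layout: chromosomes and the fixed binning grid
#'
#' A `genome_layout` holds the chromosome names and lengths of the
#' reference assembly together with the fixed bin width (500 nt by
#' default). Bins are half-open intervals `[k*w, (k+1)*w)` laid out
#' per chromosome; the last bin of each chromosome is truncated at the
#' chromosome end. All coordinates in the package are 0-based and
#' half-open (BED convention).
#'
#' @param chrom character vector of unique chromosome names.
#' @param length numeric vector of chromosome lengths in bp (all > 0).
#' @param bin_width bin width in bp (default 500).
#' @return an object of class `genome_layout` with elements `chrom`,
#'   `length`, `bin_width`, `n_bins` (per chromosome), `bin_offset`
#'   (0-based global index of each chromosome's first bin) and
#'   `total_bins`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, length, bin_width = 500L) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) {
    stop_chipgrade("duplicate chromosome name: %s",
                   paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (base::length(chrom) != base::length(length)) {
    stop_chipgrade("chrom and length differ in length")
  }
  if (base::length(chrom) == 0L) stop_chipgrade("layout needs at least one chromosome")
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length))) {
    stop_chipgrade("chromosome lengths must be positive integers")
  }
  bin_width <- as.numeric(bin_width)
  if (!is.finite(bin_width) || bin_width <= 0 || bin_width != floor(bin_width)) {
    stop_chipgrade("bin_width must be a positive integer")
  }
  n_bins <- ceiling(length / bin_width)
  structure(
    list(
      chrom = chrom,
      length = length,
      bin_width = bin_width,
      n_bins = n_bins,
      bin_offset = cumsum(c(0, n_bins[-base::length(n_bins)])),
      total_bins = sum(n_bins)
    ),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %.0f bp, %d bins of %d nt\n",
              length(x$chrom), sum(x$length), x$total_bins, as.integer(x$bin_width)))
  invisible(x)
}

#' @export
format.genome_layout <- function(x, ...) {
  sprintf("%d chromosomes / %.0f bp / bin %d", length(x$chrom), sum(x$length),
          as.integer(x$bin_width))
}

#' Read a two-column chromosome-sizes table
#'
#' Parses the standard `chrom.sizes` format (name, length; tab-separated)
#' into a [genome_layout()].
#'
#' @param path path to the chrom.sizes file.
#' @param bin_width bin width in bp for the layout (default 500).
#' @return a `genome_layout`.
#' @export
read_chrom_sizes <- function(path, bin_width = 500L) {
  if (!file.exists(path)) stop_chipgrade("chrom.sizes file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1), data.table = TRUE)
  if (ncol(dt) < 2L) stop_chipgrade("chrom.sizes must have two columns (name, length)")
  len <- suppressWarnings(as.numeric(dt[[2L]]))
  if (anyNA(len)) {
    stop_chipgrade("non-numeric chromosome length at line %d", which(is.na(len))[1L])
  }
  genome_layout(dt[[1L]], len, bin_width = bin_width)
}

#' Write a genome layout as a chrom.sizes file
#'
#' @param layout a `genome_layout`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  data.table::fwrite(
    data.table::data.table(chrom = layout$chrom, length = layout$length),
    path, sep = "\t", col.names = FALSE
  )
  invisible(path)
}

# 0-based start coordinates of every bin of one chromosome
bin_starts <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (is.na(i)) stop_chipgrade("unknown chromosome: %s", chrom)
  seq(0, by = layout$bin_width, length.out = layout$n_bins[i])
}

# map (chrom index, 0-based position) to 1-based global bin index
global_bin <- function(layout, chrom_idx, pos) {
  layout$bin_offset[chrom_idx] + floor(pos / layout$bin_width) + 1
}

# inverse: for 1-based global bin indices, return chrom index and bin start/end
bin_interval <- function(layout, bins) {
  b0 <- bins - 1                       # 0-based global bin
  ci <- findInterval(b0, layout$bin_offset)
  local <- b0 - layout$bin_offset[ci]
  start <- local * layout$bin_width
  end <- pmin(start + layout$bin_width, layout$length[ci])
  list(chrom_idx = ci, start = start, end = end)
}

same_layout <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$length, b$length) &&
    identical(a$bin_width, b$bin_width)
}
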