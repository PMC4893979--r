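#' Construct a set of genome-aligned reads
#'
#' A `mapped_reads` object is a validated table of aligned reads with
#' columns `chrom`, `start`, `end` (0-based half-open) and `strand`
#' (`+`, `-` or `*`). Its row count is the total-mapped-reads (TMR)
#' count used throughout the quality computations.
#'
#' @param chrom character or factor vector of chromosome names.
#' @param start,end numeric 0-based half-open coordinates, `start < end`.
#' @param strand strand per read; defaults to `*`.
#' @param layout optional [genome_layout()]; when given, every read must
#'   lie on a declared chromosome and within its bounds (reads spanning a
#'   chromosome end are rejected, not clipped).
#' @return a `mapped_reads` object (a `data.table` subclass).
#' @export
mapped_reads <- function(chrom, start, end, strand = NULL, layout = NULL) {
  n <- length(start)
  strand <- strand %||% rep("*", n)
  dt <- data.table::data.table(
    chrom = factor(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = factor(as.character(strand), levels = c("+", "-", "*"))
  )
  bad <- which(!(dt$start >= 0 & dt$start < dt$end))
  if (length(bad)) {
    stop_chipgrade("invalid read interval at record %d: start=%.0f end=%.0f",
                   bad[1L], dt$start[bad[1L]], dt$end[bad[1L]])
  }
  if (anyNA(dt$strand)) stop_chipgrade("strand must be one of +, -, *")
  if (!is.null(layout)) {
    ci <- match(levels(dt$chrom), layout$chrom)
    if (anyNA(ci)) {
      stop_chipgrade("read(s) on chromosome(s) absent from layout: %s",
                     paste(levels(dt$chrom)[is.na(ci)], collapse = ", "))
    }
    chrom_len <- layout$length[ci][as.integer(dt$chrom)]
    over <- which(dt$end > chrom_len)
    if (length(over)) {
      stop_chipgrade(
        "read at record %d ends at %.0f, beyond its chromosome end (%.0f); layout/reads mismatch",
        over[1L], dt$end[over[1L]], chrom_len[over[1L]])
    }
  }
  data.table::setattr(dt, "class", c("mapped_reads", class(dt)))
  dt
}

#' Total mapped reads of a read set
#' @param reads a `mapped_reads` object.
#' @return integer read count.
#' @export
tmr <- function(reads) nrow(reads)

#' @export
print.mapped_reads <- function(x, ...) {
  cat(sprintf("<mapped_reads> %d reads on %d chromosome(s)\n",
              nrow(x), length(unique(as.character(x$chrom)))))
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' Read genome-aligned reads from a BED file
#'
#' Accepts BED3+ (tab-separated, at least chrom/start/end; strand taken
#' from column 6 when present). Records on chromosomes not declared in
#' the layout are an error with `strict = TRUE` (the default); with
#' `strict = FALSE` they are excluded and their number is reported via a
#' warning and the `"skipped"` attribute, never silently dropped.
#'
#' @param path path to the BED file.
#' @param layout a [genome_layout()] the reads must be consistent with.
#' @param strict error (`TRUE`) or skip-and-report (`FALSE`) on records
#'   whose chromosome is absent from the layout.
#' @param remove_duplicates drop duplicated (chrom, start, end, strand)
#'   records before returning. Off by default.
#' @return a [mapped_reads()] object; attribute `"skipped"` holds the
#'   number of excluded unknown-chromosome records.
#' @export
read_bed <- function(path, layout, strict = TRUE, remove_duplicates = FALSE) {
  if (!file.exists(path)) stop_chipgrade("BED file not found: %s", path)
  head_lines <- readLines(path, n = 5L, warn = FALSE)
  skip <- sum(cumprod(grepl("^(track|browser|#)", head_lines)))
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t", skip = skip,
                        fill = TRUE, colClasses = list(character = 1))),
    error = function(e) stop_chipgrade("cannot parse BED file %s: %s",
                                       path, conditionMessage(e))
  )
  if (nrow(dt) == 0L) {
    warning(sprintf("empty BED file: %s", path))
    out <- mapped_reads(character(), numeric(), numeric())
    attr(out, "skipped") <- 0L
    return(out)
  }
  if (ncol(dt) < 3L) stop_chipgrade("BED file needs at least 3 columns: %s", path)
  start <- suppressWarnings(as.numeric(dt[[2L]]))
  end <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop_chipgrade("non-integer coordinates at line %d of %s", bad[1L] + skip, path)
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop_chipgrade("start >= end at line %d of %s (start=%.0f end=%.0f)",
                   bad[1L] + skip, path, start[bad[1L]], end[bad[1L]])
  }
  strand <- if (ncol(dt) >= 6L) {
    s <- as.character(dt[[6L]])
    s[!s %in% c("+", "-")] <- "*"
    s
  } else rep("*", nrow(dt))
  known <- dt[[1L]] %in% layout$chrom
  n_skip <- sum(!known)
  if (n_skip > 0L) {
    unknown <- unique(dt[[1L]][!known])
    if (strict) {
      stop_chipgrade("%d record(s) on undeclared chromosome(s): %s",
                     n_skip, paste(utils::head(unknown, 5L), collapse = ", "))
    }
    warning(sprintf("skipped %d record(s) on undeclared chromosome(s): %s",
                    n_skip, paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  out <- mapped_reads(dt[[1L]][known], start[known], end[known],
                      strand = strand[known], layout = layout)
  if (remove_duplicates) {
    out <- unique(out, by = c("chrom", "start", "end", "strand"))
    data.table::setattr(out, "class", c("mapped_reads", "data.table", "data.frame"))
  }
  attr(out, "skipped") <- n_skip
  out
}

#' Write a read set to a BED6 file
#'
#' @param reads a [mapped_reads()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(reads, path) {
  stopifnot(inherits(reads, "mapped_reads"))
  dt <- data.table::data.table(
    chrom = as.character(reads$chrom),
    start = sprintf("%.0f", reads$start),
    end = sprintf("%.0f", reads$end),
    name = ".",
    score = 0L,
    strand = as.character(reads$strand)
  )
  dt[dt$strand == "*", "strand"] <- "."
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Randomly subsample a read set without replacement
#'
#' Draws exactly `round(fraction * tmr)` reads without replacement, the
#' fixed-size subset the quality indicator compares against the original
#' profile. Deterministic for a given `(seed, fraction)` and input.
#'
#' @param reads a [mapped_reads()] object.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return a `mapped_reads` object with `round(fraction * tmr(reads))` rows.
#' @export
subsample_reads <- function(reads, fraction, seed) {
  stopifnot(inherits(reads, "mapped_reads"))
  check_fraction(fraction)
  if (fraction == 1) return(reads)
  idx <- subsample_index(tmr(reads), fraction, seed)
  out <- reads[idx]
  data.table::setattr(out, "class", c("mapped_reads", "data.table", "data.frame"))
  out
}

# shared index draw so read-level and bin-level subsampling are identical
subsample_index <- function(n, fraction, seed) {
  m <- round(fraction * n)
  with_seed(seed, sample.int(n, m))
}

check_fraction <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop_chipgrade("fraction must be a single value in (0, 1], got %s",
                   paste(fraction, collapse = ","))
  }
  invisible(fraction)
}
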