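#' Write a per-bin numeric track as bedGraph
#'
#' Serialises one value per bin (or a sparse subset of bins) of the fixed
#' grid into standard bedGraph: 0-based, half-open intervals. Used for
#' read-count profiles and for the per-bin dRCI robustness track that
#' accompanies a certificate.
#'
#' @param values numeric vector, one value per entry of `bins`.
#' @param layout a [genome_layout()].
#' @param path output path.
#' @param bins 1-based global bin indices the values belong to; defaults
#'   to all bins of the layout.
#' @param merge merge runs of adjacent equal-valued bins into one record.
#' @param track_name name written in the track header line.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(values, layout, path, bins = NULL,
                           merge = FALSE, track_name = "chipgrade") {
  stopifnot(inherits(layout, "genome_layout"))
  bins <- bins %||% seq_len(layout$total_bins)
  if (length(values) != length(bins)) {
    stop_chipgrade("values (%d) and bins (%d) differ in length",
                   length(values), length(bins))
  }
  if (length(bins) && (min(bins) < 1 || max(bins) > layout$total_bins)) {
    stop_chipgrade("bin index outside layout (total %d bins)", layout$total_bins)
  }
  header <- sprintf("track type=bedGraph name=\"%s\"", track_name)
  if (!length(bins)) {
    writeLines(header, path)
    return(invisible(path))
  }
  o <- order(bins)
  bins <- bins[o]
  values <- values[o]
  iv <- bin_interval(layout, bins)
  dt <- data.table::data.table(
    chrom = layout$chrom[iv$chrom_idx],
    start = iv$start, end = iv$end, value = values
  )
  if (merge && nrow(dt) > 1L) {
    run <- cumsum(c(TRUE, dt$value[-1] != dt$value[-nrow(dt)] |
                      dt$chrom[-1] != dt$chrom[-nrow(dt)] |
                      dt$start[-1] != dt$end[-nrow(dt)]))
    dt <- data.table::data.table(
      chrom = dt$chrom[!duplicated(run)],
      start = dt$start[!duplicated(run)],
      end = dt$end[cumsum(tabulate(run))],
      value = dt$value[!duplicated(run)]
    )
  }
  writeLines(header, path)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a bedGraph file back into per-bin values
#'
#' Inverse of [write_bedgraph()] for unmerged tracks: every record must
#' align with the layout's bin grid.
#'
#' @param path bedGraph path.
#' @param layout a [genome_layout()].
#' @return list with `bins` (1-based global indices) and `values`.
#' @export
read_bedgraph <- function(path, layout) {
  if (!file.exists(path)) stop_chipgrade("bedGraph file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  skip <- as.integer(grepl("^track", first))
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines <= skip) return(list(bins = integer(), values = numeric()))
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = skip,
                          colClasses = list(character = 1))
  ci <- match(dt[[1L]], layout$chrom)
  if (anyNA(ci)) stop_chipgrade("bedGraph chromosome absent from layout: %s",
                                dt[[1L]][which(is.na(ci))[1L]])
  if (any(dt[[2L]] %% layout$bin_width != 0)) {
    stop_chipgrade("bedGraph record not aligned with the %d nt grid",
                   as.integer(layout$bin_width))
  }
  list(bins = as.integer(global_bin(layout, ci, dt[[2L]])), values = dt[[4L]])
}
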