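#' Pair robust windows of two biological replicates
#'
#' A genomic window (one 500 nt bin) is eligible when its dRCI is below
#' 10 percent in a replicate. Windows eligible in both replicates form a
#' real pair carrying their two dRCI values; windows eligible in exactly
#' one replicate are kept and paired with a penalty window to which a
#' dRCI of exactly 15 percent is allocated on the missing side. Windows
#' eligible in neither replicate never enter the table.
#'
#' @param disp1,disp2 [compute_dispersion()] profiles of the two
#'   replicates, on the same layout and subsampling fraction.
#' @param eligibility dRCI eligibility threshold in percent (strict
#'   `<`); default 10.
#' @param penalty dRCI assigned to the missing side of a one-sided
#'   window; default 15.
#' @return an `idr_pairs` table (`data.table`) with columns `bin`,
#'   `drci_rep1`, `drci_rep2`, `penalty_rep1`, `penalty_rep2` and
#'   `abs_diff`, sorted by ascending `abs_diff` (ties by genomic
#'   coordinate, i.e. bin index, for determinism).
#' @export
pair_windows <- function(disp1, disp2, eligibility = 10, penalty = 15) {
  stopifnot(inherits(disp1, "dispersion_profile"),
            inherits(disp2, "dispersion_profile"))
  if (!same_layout(disp1$layout, disp2$layout)) {
    stop_chipgrade("replicate profiles are on different layouts")
  }
  if (abs(disp1$fraction - disp2$fraction) > 1e-12) {
    stop_chipgrade("replicate profiles use different subsampling fractions (%g vs %g)",
                   disp1$fraction, disp2$fraction)
  }
  el1 <- disp1$bins[disp1$drci < eligibility]
  dr1 <- disp1$drci[disp1$drci < eligibility]
  el2 <- disp2$bins[disp2$drci < eligibility]
  dr2 <- disp2$drci[disp2$drci < eligibility]
  universe <- sort(unique(c(el1, el2)))
  i1 <- match(universe, el1)
  i2 <- match(universe, el2)
  drci_rep1 <- ifelse(is.na(i1), penalty, dr1[i1])
  drci_rep2 <- ifelse(is.na(i2), penalty, dr2[i2])
  dt <- data.table::data.table(
    bin = universe,
    drci_rep1 = drci_rep1,
    drci_rep2 = drci_rep2,
    penalty_rep1 = is.na(i1),
    penalty_rep2 = is.na(i2),
    abs_diff = abs(drci_rep1 - drci_rep2)
  )
  data.table::setorderv(dt, c("abs_diff", "bin"))
  data.table::setattr(dt, "class", c("idr_pairs", class(dt)))
  data.table::setattr(dt, "layout", disp1$layout)
  dt
}

#' @export
print.idr_pairs <- function(x, ...) {
  cat(sprintf("<idr_pairs> %d windows, %d penalty-paired (%.2f%%)\n",
              nrow(x), sum(x$penalty_rep1 | x$penalty_rep2),
              if (nrow(x)) 100 * mean(x$penalty_rep1 | x$penalty_rep2) else NA_real_))
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' Local QC-IDR curve over ranked window groups
#'
#' Ranks the paired windows by ascending absolute dRCI difference and
#' slides a group of 5,000 windows in steps of 500 along the ranking. The
#' local QC-IDR of a group is the fraction of its windows that are
#' penalty-paired, i.e. irreproducible between the replicates. Windows
#' belonging to at least one group at or below the IDR threshold (0.1 by
#' default) are counted as sub-threshold. A cumulative variant (fraction
#' of penalty pairs among the top `rank_start + group_size - 1` windows)
#' is reported alongside.
#'
#' @param pairs an [pair_windows()] table.
#' @param group_size windows per group; default 5000.
#' @param step slide of the group start along the ranking; default 500.
#' @param threshold local IDR threshold; default 0.1.
#' @return an `idr_curve`: list with `groups` (data.frame of
#'   `rank_start`, `rank_end`, `local_idr`, `cumulative_idr`),
#'   `n_windows_below_threshold`, `threshold`, `n_pairs`,
#'   `penalty_fraction` and `single_group` (set when fewer windows than
#'   `group_size` forced a single all-window group).
#' @export
idr_curve <- function(pairs, group_size = 5000L, step = 500L, threshold = 0.1) {
  stopifnot(inherits(pairs, "idr_pairs"))
  n <- nrow(pairs)
  if (n == 0L) stop_chipgrade("pair table is empty")
  pen <- pairs$penalty_rep1 | pairs$penalty_rep2
  cpen <- cumsum(pen)
  single_group <- n < group_size
  if (single_group) {
    starts <- 1L
    ends <- n
  } else {
    starts <- seq.int(1L, n - group_size + 1L, by = step)
    ends <- starts + group_size - 1L
  }
  local_idr <- (cpen[ends] - c(0, cpen)[starts]) / (ends - starts + 1L)
  groups <- data.frame(rank_start = starts, rank_end = ends,
                       local_idr = local_idr,
                       cumulative_idr = cpen[ends] / ends)
  below <- logical(n)
  for (g in which(local_idr <= threshold)) {
    below[starts[g]:ends[g]] <- TRUE
  }
  structure(
    list(groups = groups,
         n_windows_below_threshold = sum(below),
         threshold = threshold, n_pairs = n,
         penalty_fraction = mean(pen),
         single_group = single_group,
         group_size = group_size, step = step),
    class = "idr_curve"
  )
}

#' @export
print.idr_curve <- function(x, ...) {
  cat(sprintf(paste0("<idr_curve> %d windows, %d groups of %d (step %d)%s\n",
                     "  penalty fraction %.4f | %d windows in groups with ",
                     "local IDR <= %.2f\n"),
              x$n_pairs, nrow(x$groups), x$group_size, x$step,
              if (x$single_group) " [single undersized group]" else "",
              x$penalty_fraction, x$n_windows_below_threshold, x$threshold))
  invisible(x)
}
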