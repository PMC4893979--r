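#' Quality as a function of sequencing depth
#'
#' Recomputes the full quality-indicator procedure on outer random
#' subsets of the dataset (20-100 percent of total mapped reads by
#' default) and assembles the score-versus-depth curve from which the
#' optimal sequencing depth is interpolated. Outer subsampling and the
#' inner quality subsampling use independent seeded substreams, so depth
#' points are mutually independent given the seed, and the 100 percent
#' point is identical to a direct [run_qc()] with the same plan.
#'
#' @param reads a [mapped_reads()] object.
#' @param layout a [genome_layout()].
#' @param plan a [subsample_plan()] used within every depth point.
#' @param boundaries a [grade_boundaries()]; `NULL` leaves points
#'   ungraded and the optimal depth unevaluated.
#' @param outer_fractions ascending outer fractions in (0, 1]; must
#'   contain 1.
#' @param seed seed for the outer subsampling stream (defaults to the
#'   plan seed).
#' @param thresholds dRCI thresholds in percent.
#' @return a `depth_curve`: list with `points` (data.frame of
#'   outer_fraction, tmr, the three scores and grade), `results` (the
#'   per-point `qc_result`s) and `optimal` (see [optimal_depth()]).
#' @export
depth_profile <- function(reads, layout, plan = subsample_plan(),
                          boundaries = NULL,
                          outer_fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                          seed = NULL, thresholds = c(2.5, 5, 10)) {
  stopifnot(inherits(reads, "mapped_reads"))
  for (f in outer_fractions) check_fraction(f)
  if (is.unsorted(outer_fractions, strictly = TRUE)) {
    stop_chipgrade("outer_fractions must be strictly ascending")
  }
  if (max(outer_fractions) != 1) {
    stop_chipgrade("outer_fractions must contain 1.0 (the full dataset)")
  }
  seed <- seed %||% plan$seed
  n <- tmr(reads)
  results <- vector("list", length(outer_fractions))
  rows <- vector("list", length(outer_fractions))
  for (i in seq_along(outer_fractions)) {
    f <- outer_fractions[i]
    sub <- if (f == 1) reads else {
      subsample_reads(reads, f, derive_seed(seed, "outer", i))
    }
    res <- tryCatch(
      run_qc(sub, layout, plan = plan, boundaries = boundaries,
             thresholds = thresholds),
      chipgrade_error = function(e) e
    )
    flagged <- inherits(res, "condition")
    results[[i]] <- if (flagged) NULL else res
    rows[[i]] <- data.frame(
      outer_fraction = f,
      tmr = round(f * n),
      score_2_5 = if (flagged) NA_real_ else res$score$scores[[1L]],
      score_5 = if (flagged) NA_real_ else res$score$scores[[2L]],
      score_10 = if (flagged) NA_real_ else res$score$scores[[3L]],
      grade = if (flagged || is.null(res$grade)) NA_character_
              else unclass(res$grade),
      flagged = flagged,
      stringsAsFactors = FALSE
    )
    if (f != 1) rm(sub)
  }
  curve <- structure(
    list(points = do.call(rbind, rows), results = results,
         plan = plan, seed = seed, total_tmr = n),
    class = "depth_curve"
  )
  curve$optimal <- if (!is.null(boundaries)) optimal_depth(curve, boundaries)
  curve
}

#' @export
print.depth_curve <- function(x, ...) {
  cat(sprintf("<depth_curve> %d points, TMR=%s\n", nrow(x$points),
              format(x$total_tmr, big.mark = ",")))
  print(x$points, row.names = FALSE)
  if (!is.null(x$optimal)) {
    cat(sprintf("optimal depth: %s\n", format_optimal(x$optimal)))
  }
  invisible(x)
}

format_optimal <- function(opt) {
  switch(opt$status,
         ok = sprintf("%s reads (A/B transition)%s",
                      format(round(opt$reads), big.mark = ","),
                      if (isTRUE(opt$noisy)) " [noisy curve]" else ""),
         below_minimum = sprintf("below minimum tested (%s reads)",
                                 format(opt$min_tmr, big.mark = ",")),
         not_reached = "not reached (no point grades A)")
}

#' Optimal sequencing depth: the interpolated A/B grade transition
#'
#' Locates, on the depth curve's most stringent score (dRCI 2.5 percent),
#' the read count at which the score crosses the A/B boundary (the Q3 cut
#' point of that level), by linear interpolation of score versus mapped
#' reads between the two adjacent curve points straddling the boundary.
#' If every point already grades A the dataset is saturated below the
#' tested range; if no point reaches A the transition is not reached.
#' With several crossings (a noisy curve) the lowest-depth crossing is
#' used and the curve is flagged.
#'
#' @param curve a [depth_profile()] result (>= 2 usable points).
#' @param boundaries a [grade_boundaries()].
#' @return list with `status` (`"ok"`, `"below_minimum"` or
#'   `"not_reached"`), `reads` (interpolated depth, `NA` for sentinels),
#'   `boundary` (the Q3 score used), `noisy` and `min_tmr`.
#' @export
optimal_depth <- function(curve, boundaries) {
  stopifnot(inherits(curve, "depth_curve"), inherits(boundaries, "grade_boundaries"))
  pts <- curve$points[!curve$points$flagged & !is.na(curve$points$score_2_5), ]
  if (nrow(pts) < 2L) stop_chipgrade("depth curve needs at least two usable points")
  pts <- pts[order(pts$tmr), ]
  q3 <- boundaries$q[1L, "Q3"]
  above <- pts$score_2_5 > q3
  out <- list(status = "ok", reads = NA_real_, boundary = unname(q3),
              noisy = FALSE, min_tmr = min(pts$tmr))
  if (all(above)) {
    out$status <- "below_minimum"
    return(out)
  }
  if (!any(above)) {
    out$status <- "not_reached"
    return(out)
  }
  k <- nrow(pts)
  straddle <- which(!above[-k] & above[-1L])
  if (length(straddle) == 0L) {
    # the curve starts A and later falls below: treat the first drop as
    # the transition read count, flagged as noisy
    drop <- which(above[-k] & !above[-1L])[1L]
    i <- drop
    out$noisy <- TRUE
  } else {
    i <- straddle[1L]
    out$noisy <- length(straddle) > 1L || any(above[-k] & !above[-1L])
  }
  s0 <- pts$score_2_5[i]; s1 <- pts$score_2_5[i + 1L]
  t0 <- pts$tmr[i]; t1 <- pts$tmr[i + 1L]
  out$reads <- t0 + (q3 - s0) / (s1 - s0) * (t1 - t0)
  out
}
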