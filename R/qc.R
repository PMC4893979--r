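#' Subsampling plan for the quality-indicator computation
#'
#' @param fractions distinct subsampling fractions in (0, 1]; the
#'   canonical plan draws 90, 70 and 50 percent subsets of the total
#'   mapped reads.
#' @param seed integer master seed; every random draw of the procedure is
#'   derived from it.
#' @param draws_per_fraction independent subsample draws per fraction
#'   (>= 1). With more than one draw the per-bin dRCI is the mean across
#'   draws, a variance-reduced variant of the single-draw statistic.
#' @param grading_fraction fraction whose score feeds the letter grade;
#'   must be among `fractions`. The 50 percent subset — the most
#'   stringent of the three — is the default.
#' @return a `subsample_plan` object.
#' @export
subsample_plan <- function(fractions = c(0.9, 0.7, 0.5), seed = 1L,
                           draws_per_fraction = 1L, grading_fraction = 0.5) {
  for (f in fractions) check_fraction(f)
  if (anyDuplicated(fractions)) stop_chipgrade("fractions must be distinct")
  if (draws_per_fraction < 1L) stop_chipgrade("draws_per_fraction must be >= 1")
  if (!any(abs(fractions - grading_fraction) < 1e-12)) {
    stop_chipgrade("grading_fraction (%g) must be one of the plan fractions",
                   grading_fraction)
  }
  structure(
    list(fractions = as.numeric(fractions), seed = as.integer(seed),
         draws_per_fraction = as.integer(draws_per_fraction),
         grading_fraction = as.numeric(grading_fraction)),
    class = "subsample_plan"
  )
}

#' Per-bin dispersion of a subsampled profile (dRCI)
#'
#' Under random subsampling at fraction `s`, every bin's count is
#' expected to shrink proportionally to `s * c_b`. The dRCI of a bin is
#' the percentage deviation from that expectation,
#' `100 * |c_sub - s * c_b| / (s * c_b)`, defined only on bins populated
#' in the original profile (`c_b > 0`); empty bins enter neither the
#' numerator nor the denominator of any downstream score.
#'
#' @param original `binned_profile` of the full read set.
#' @param subsampled `binned_profile` of the subsample, same layout.
#' @param fraction the sampling fraction `s` in (0, 1).
#' @return a `dispersion_profile`: list with `fraction`, `bins` (1-based
#'   global indices of eligible bins), `drci` (percent), `eligible_bins`
#'   and `layout`.
#' @export
compute_dispersion <- function(original, subsampled, fraction) {
  stopifnot(inherits(original, "binned_profile"),
            inherits(subsampled, "binned_profile"))
  if (!same_layout(original$layout, subsampled$layout)) {
    stop_chipgrade("profiles are on different layouts")
  }
  check_fraction(fraction)
  if (fraction == 1) stop_chipgrade("dispersion is undefined at fraction 1")
  eligible <- which(original$counts > 0L)
  expected <- fraction * original$counts[eligible]
  drci <- 100 * abs(subsampled$counts[eligible] - expected) / expected
  new_dispersion_profile(fraction, eligible, drci, original$layout)
}

new_dispersion_profile <- function(fraction, bins, drci, layout) {
  structure(
    list(fraction = fraction, bins = as.integer(bins), drci = as.numeric(drci),
         eligible_bins = length(bins), layout = layout),
    class = "dispersion_profile"
  )
}

#' @export
print.dispersion_profile <- function(x, ...) {
  cat(sprintf("<dispersion_profile> s=%.2f, %d eligible bins, median dRCI %.2f%%\n",
              x$fraction, x$eligible_bins,
              if (x$eligible_bins) stats::median(x$drci) else NA_real_))
  invisible(x)
}

#' Quality score: fraction of robust bins per dRCI threshold
#'
#' For each dispersion threshold (2.5, 5 and 10 percent by default) the
#' quality indicator is the percentage of eligible bins whose dRCI does
#' not exceed it. Thresholds are nested, so the three scores are
#' non-decreasing by construction.
#'
#' @param disp a [compute_dispersion()] profile.
#' @param thresholds ascending dRCI thresholds in percent.
#' @param tmr total mapped reads of the source dataset (recorded in the
#'   score for depth bookkeeping).
#' @return a `qc_score` with elements `thresholds`, `scores` (percent,
#'   named by threshold), `score_2_5`/`score_5`/`score_10` (positional
#'   aliases for the canonical three), `fraction_used` and `tmr`.
#' @export
qc_score <- function(disp, thresholds = c(2.5, 5, 10), tmr = NA_integer_) {
  stopifnot(inherits(disp, "dispersion_profile"))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_chipgrade("thresholds must be sorted strictly ascending")
  }
  if (disp$eligible_bins == 0L) stop_chipgrade("profile has no populated bins")
  scores <- vapply(thresholds, function(th) 100 * mean(disp$drci <= th), 0)
  names(scores) <- format(thresholds, trim = TRUE)
  out <- list(thresholds = thresholds, scores = scores,
              fraction_used = disp$fraction, tmr = tmr,
              eligible_bins = disp$eligible_bins)
  if (length(thresholds) == 3L) {
    out$score_2_5 <- scores[[1L]]
    out$score_5 <- scores[[2L]]
    out$score_10 <- scores[[3L]]
  }
  structure(out, class = "qc_score")
}

#' @export
print.qc_score <- function(x, ...) {
  cat(sprintf("<qc_score> s=%.2f TMR=%s | %s\n", x$fraction_used,
              format(x$tmr, big.mark = ","),
              paste(sprintf("%s%%: %.2f", names(x$scores), x$scores),
                    collapse = "  ")))
  invisible(x)
}

#' Grade boundaries: quartile cut points per dRCI threshold
#'
#' Scores are discretised into letters A-D against the quartiles
#' (Q1 < Q2 < Q3) of a reference score distribution, one triple per dRCI
#' threshold. The boundaries shipped with the package come from a
#' documented calibration run of the simulator ([calibrate_boundaries()]);
#' boundaries derived from any other score collection can be supplied as
#' a JSON table via [read_boundaries()].
#'
#' @param q matrix with one row per threshold level and columns Q1, Q2,
#'   Q3 (row names are the threshold labels, e.g. `"2.5"`).
#' @param provenance free-text origin of the boundaries.
#' @return a `grade_boundaries` object.
#' @export
grade_boundaries <- function(q, provenance = "user-supplied") {
  q <- as.matrix(q)
  if (ncol(q) != 3L) stop_chipgrade("boundaries need three columns (Q1, Q2, Q3)")
  colnames(q) <- c("Q1", "Q2", "Q3")
  bad <- which(!(q[, 1L] < q[, 2L] & q[, 2L] < q[, 3L]))
  if (length(bad)) {
    stop_chipgrade("boundaries must satisfy Q1 < Q2 < Q3 (violated at level %s)",
                   rownames(q)[bad[1L]] %||% bad[1L])
  }
  structure(list(q = q, provenance = provenance), class = "grade_boundaries")
}

#' @export
print.grade_boundaries <- function(x, ...) {
  cat(sprintf("<grade_boundaries> (%s)\n", x$provenance))
  print(round(x$q, 3))
  invisible(x)
}

#' Discretise a quality score into a three-letter grade
#'
#' Per threshold level the letter is `A` if the score exceeds Q3, `B` in
#' (Q2, Q3], `C` in (Q1, Q2] and `D` otherwise. A score sitting exactly
#' on a boundary takes the lower-quality letter (conservative grading).
#' Letters are ordered by ascending threshold (2.5, 5, 10 percent), most
#' stringent first.
#'
#' @param score a [qc_score()] with the three canonical thresholds.
#' @param boundaries a [grade_boundaries()] with one row per threshold.
#' @return a `qc_grade`: single string such as `"AAB"`, with the letter
#'   vector in attribute `"letters"`.
#' @export
assign_grade <- function(score, boundaries) {
  stopifnot(inherits(score, "qc_score"), inherits(boundaries, "grade_boundaries"))
  if (nrow(boundaries$q) != length(score$thresholds)) {
    stop_chipgrade("boundaries have %d levels but score has %d thresholds",
                   nrow(boundaries$q), length(score$thresholds))
  }
  letters <- vapply(seq_along(score$thresholds), function(i) {
    s <- score$scores[[i]]
    q <- boundaries$q[i, ]
    if (s > q[[3L]]) "A" else if (s > q[[2L]]) "B" else if (s > q[[1L]]) "C" else "D"
  }, "")
  structure(paste(letters, collapse = ""), letters = letters, class = "qc_grade")
}

#' @export
print.qc_grade <- function(x, ...) {
  cat(sprintf("<qc_grade> %s\n", unclass(x)))
  invisible(x)
}

#' Run the full quality-indicator procedure on one read set
#'
#' Orchestrates binning, seeded random subsampling at every plan
#' fraction, per-bin dRCI computation, threshold scores and the letter
#' grade. The headline score and grade come from the plan's grading
#' fraction (50 percent by default); the remaining fractions' scores are
#' computed and retained alongside.
#'
#' @param reads a [mapped_reads()] object.
#' @param layout a [genome_layout()].
#' @param plan a [subsample_plan()].
#' @param boundaries a [grade_boundaries()]; `NULL` skips grading.
#' @param thresholds dRCI thresholds in percent.
#' @param extend fragment extension passed to [bin_reads()].
#' @return a `qc_result`: list with `score` and `grade` (grading
#'   fraction), `scores` (list of `qc_score`, one per fraction),
#'   `dispersion` (the grading fraction's `dispersion_profile`), `tmr`,
#'   `plan` and `profile` (the original `binned_profile`).
#' @export
run_qc <- function(reads, layout, plan = subsample_plan(),
                   boundaries = NULL, thresholds = c(2.5, 5, 10), extend = 0) {
  stopifnot(inherits(reads, "mapped_reads"), inherits(plan, "subsample_plan"))
  profile <- bin_reads(reads, layout, extend = extend)
  idx <- read_bin_index(reads, layout, extend = extend)
  n <- length(idx)
  if (n == 0L) stop_chipgrade("read set is empty")

  scores <- vector("list", length(plan$fractions))
  names(scores) <- format(plan$fractions, trim = TRUE)
  grading_disp <- NULL
  eligible <- which(profile$counts > 0L)
  for (k in seq_along(plan$fractions)) {
    f <- plan$fractions[k]
    drci_sum <- numeric(length(eligible))
    for (d in seq_len(plan$draws_per_fraction)) {
      sub_counts <- subsample_bin_counts(idx, n, f, layout,
                                         derive_seed(plan$seed, "subsample",
                                                     k * 1000L + d))
      expected <- f * profile$counts[eligible]
      drci_sum <- drci_sum + 100 * abs(sub_counts[eligible] - expected) / expected
    }
    disp <- new_dispersion_profile(f, eligible,
                                   drci_sum / plan$draws_per_fraction, layout)
    scores[[k]] <- qc_score(disp, thresholds = thresholds, tmr = n)
    if (abs(f - plan$grading_fraction) < 1e-12) grading_disp <- disp
  }
  gi <- which(abs(plan$fractions - plan$grading_fraction) < 1e-12)[1L]
  grade <- if (!is.null(boundaries)) assign_grade(scores[[gi]], boundaries) else NULL
  structure(
    list(score = scores[[gi]], grade = grade, scores = scores,
         dispersion = grading_disp, tmr = n, plan = plan, profile = profile),
    class = "qc_result"
  )
}

# per-bin counts of a without-replacement subsample, drawn on the read
# index vector; identical in law (and, given the seed contract, in value)
# to subsample_reads() followed by bin_reads()
subsample_bin_counts <- function(idx, n, fraction, layout, seed) {
  tabulate(idx[subsample_index(n, fraction, seed)], nbins = layout$total_bins)
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> TMR=%s grade=%s\n", format(x$tmr, big.mark = ","),
              if (is.null(x$grade)) "(ungraded)" else unclass(x$grade)))
  for (s in x$scores) print(s)
  invisible(x)
}
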