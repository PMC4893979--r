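#' Certify an antibody from two biological replicate ChIP-seq assays
#'
#' Runs the complete certification: the quality-indicator procedure and
#' the depth curve on each replicate, and the local QC-IDR concordance
#' across the two. The certification grade takes, at every threshold
#' position, the worse of the two replicates' letters — a certificate is
#' never better than its weaker replicate.
#'
#' @param rep1,rep2 [mapped_reads()] of the two biological replicates.
#' @param layout a [genome_layout()].
#' @param plan a [subsample_plan()]; both replicates use the same inner
#'   subsampling seed, so a dataset certified against itself is exactly
#'   self-consistent (zero penalty pairs, all-zero local QC-IDR).
#' @param boundaries a [grade_boundaries()].
#' @param outer_fractions depth-curve fractions (see [depth_profile()]).
#' @param idr_group_size,idr_step,idr_threshold local QC-IDR parameters
#'   (see [idr_curve()]).
#' @param reference optional public score table for
#'   [compare_with_reference()]: data.frame with columns `tmr`, `score`.
#' @return a `certificate`: list with `replicates` (per-replicate scores,
#'   grades, optimal depths, TMRs), `certification_grade`, `idr`
#'   (pair table summary and curve), `comparison` (optional) and
#'   `provenance` (seeds, parameters, package version).
#' @export
certify <- function(rep1, rep2, layout, plan = subsample_plan(),
                    boundaries = default_boundaries(),
                    outer_fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                    idr_group_size = 5000L, idr_step = 500L,
                    idr_threshold = 0.1, reference = NULL) {
  stopifnot(inherits(rep1, "mapped_reads"), inherits(rep2, "mapped_reads"))
  if (tmr(rep1) == 0L || tmr(rep2) == 0L) {
    stop_chipgrade("both replicates must be non-empty")
  }
  reps <- list(rep1 = rep1, rep2 = rep2)
  per_rep <- vector("list", 2L)
  names(per_rep) <- names(reps)
  for (i in 1:2) {
    curve <- withCallingHandlers(
      depth_profile(reps[[i]], layout, plan = plan, boundaries = boundaries,
                    outer_fractions = outer_fractions,
                    seed = derive_seed(plan$seed, "outer-replicate", i)),
      error = function(e) {
        stop_chipgrade("replicate %d: %s", i, conditionMessage(e))
      }
    )
    full <- curve$results[[length(curve$results)]]
    per_rep[[i]] <- list(qc = full, depth = curve, plan = plan)
  }
  g1 <- attr(per_rep[[1L]]$qc$grade, "letters")
  g2 <- attr(per_rep[[2L]]$qc$grade, "letters")
  cert_letters <- worse_letters(g1, g2)

  pairs <- pair_windows(per_rep[[1L]]$qc$dispersion, per_rep[[2L]]$qc$dispersion)
  curve <- idr_curve(pairs, group_size = idr_group_size, step = idr_step,
                     threshold = idr_threshold)

  comparison <- if (!is.null(reference)) {
    compare_with_reference(lapply(per_rep, function(r) r$qc$score), reference)
  }
  structure(
    list(
      replicates = lapply(per_rep, function(r) {
        list(tmr = r$qc$tmr,
             scores = lapply(r$qc$scores, function(s) as.list(s$scores)),
             grade = as.character(r$qc$grade),
             grading_fraction = r$plan$grading_fraction,
             optimal_depth = r$depth$optimal,
             depth_points = r$depth$points[, c("outer_fraction", "tmr",
                                               "score_2_5", "score_5",
                                               "score_10", "grade")])
      }),
      certification_grade = paste(cert_letters, collapse = ""),
      idr = list(
        n_pairs = curve$n_pairs,
        penalty_fraction = curve$penalty_fraction,
        n_windows_below_threshold = curve$n_windows_below_threshold,
        threshold = curve$threshold,
        single_group = curve$single_group,
        curve = curve,
        pairs = pairs
      ),
      comparison = comparison,
      provenance = list(
        seed = plan$seed,
        fractions = plan$fractions,
        grading_fraction = plan$grading_fraction,
        draws_per_fraction = plan$draws_per_fraction,
        outer_fractions = outer_fractions,
        bin_width = layout$bin_width,
        boundaries = list(provenance = boundaries$provenance,
                          q = apply(boundaries$q, 1L, unname, simplify = FALSE)),
        tmr = list(rep1 = tmr(rep1), rep2 = tmr(rep2)),
        package_version = as.character(utils::packageVersion("chipgrade"))
      )
    ),
    class = "certificate"
  )
}

# per-position worse of two letter vectors (A best ... D worst)
worse_letters <- function(a, b) {
  ord <- c(A = 1L, B = 2L, C = 3L, D = 4L)
  names(ord)[pmax(ord[a], ord[b])]
}

#' @export
print.certificate <- function(x, ...) {
  cat("== chipgrade certificate ==\n")
  for (nm in names(x$replicates)) {
    r <- x$replicates[[nm]]
    cat(sprintf("%s: TMR=%s grade=%s optimal depth: %s\n", nm,
                format(r$tmr, big.mark = ","), r$grade,
                format_optimal(r$optimal_depth)))
  }
  cat(sprintf("certification grade: %s\n", x$certification_grade))
  cat(sprintf("local QC-IDR: %d paired windows, penalty fraction %.4f, %d windows below IDR %.2f\n",
              x$idr$n_pairs, x$idr$penalty_fraction,
              x$idr$n_windows_below_threshold, x$idr$threshold))
  invisible(x)
}

#' Write a certificate as JSON
#'
#' Serialises everything except the full pair table and depth results
#' (kept as separate TSV/bedGraph outputs by the command-line tool) into
#' a deterministic JSON document: fixed key order, no timestamps, so
#' re-running with identical inputs and seeds yields a byte-identical
#' file.
#'
#' @param cert a [certify()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_certificate <- function(cert, path) {
  stopifnot(inherits(cert, "certificate"))
  js <- list(
    format = "chipgrade-certificate/1",
    certification_grade = cert$certification_grade,
    replicates = lapply(cert$replicates, function(r) {
      list(tmr = r$tmr, grade = r$grade,
           grading_fraction = r$grading_fraction,
           scores = r$scores,
           optimal_depth = r$optimal_depth[c("status", "reads", "boundary",
                                             "noisy")],
           depth_points = r$depth_points)
    }),
    idr = cert$idr[c("n_pairs", "penalty_fraction",
                     "n_windows_below_threshold", "threshold",
                     "single_group")],
    provenance = cert$provenance
  )
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "columns")
  invisible(path)
}

#' Merge certified scores with a public reference score table
#'
#' Builds the table behind the score-versus-depth comparison scatter: the
#' certified datasets' scores tagged `"certified"` concatenated with the
#' reference collection tagged `"reference"`, plus a locally weighted
#' trend of the reference cloud (the two-point limit degenerates to the
#' connecting line). A certified score above every reference score at
#' comparable depth (within a factor of two in reads) is flagged.
#'
#' @param scores list of [qc_score()] objects (the certified datasets).
#' @param reference data.frame with columns `tmr` and `score` (>= 2 rows).
#' @param trend_span LOWESS smoother span for the trend curve.
#' @return list with `table` (source, tmr, score), `trend` (data.frame
#'   tmr/score along the reference trend) and `flags` (per certified
#'   score: `above_reference_cloud`).
#' @export
compare_with_reference <- function(scores, reference, trend_span = 2 / 3) {
  if (inherits(scores, "qc_score")) scores <- list(scores)
  if (is.null(reference) || nrow(reference) < 2L) {
    stop_chipgrade("reference table needs at least 2 rows")
  }
  if (!all(c("tmr", "score") %in% names(reference))) {
    stop_chipgrade("reference table needs columns 'tmr' and 'score'")
  }
  cert <- data.frame(
    source = "certified",
    tmr = vapply(scores, function(s) as.numeric(s$tmr), 0),
    score = vapply(scores, function(s) s$scores[[1L]], 0)
  )
  ref <- data.frame(source = "reference", tmr = as.numeric(reference$tmr),
                    score = as.numeric(reference$score))
  tab <- rbind(cert, ref)
  trend <- if (nrow(ref) == 2L) {
    ref[order(ref$tmr), c("tmr", "score")]
  } else {
    lw <- stats::lowess(ref$tmr, ref$score, f = trend_span)
    data.frame(tmr = lw$x, score = lw$y)
  }
  flags <- vapply(seq_len(nrow(cert)), function(i) {
    comparable <- ref$tmr >= cert$tmr[i] / 2 & ref$tmr <= cert$tmr[i] * 2
    if (!any(comparable)) comparable <- rep(TRUE, nrow(ref))
    cert$score[i] > max(ref$score[comparable])
  }, NA)
  list(table = tab, trend = trend,
       flags = data.frame(tmr = cert$tmr, score = cert$score,
                          above_reference_cloud = flags))
}
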