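#' Grade boundaries shipped with the package
#'
#' Loads the default quartile cut points, derived from a documented
#' calibration run of the bundled simulator over a grid of mark types
#' (sharp, broad), sequencing depths (1, 5 and 20 million reads) and
#' enrichment fractions (0.1-0.8), three seeds each; the quartiles of the
#' resulting score distribution per dRCI threshold are the cut points.
#' Grades against these defaults are comparable only within this tool;
#' supply boundaries from an external score collection via
#' [read_boundaries()] to grade against it.
#'
#' @return a [grade_boundaries()] object.
#' @export
default_boundaries <- function() {
  path <- system.file("extdata", "default_boundaries.json", package = "chipgrade")
  if (path == "") stop_chipgrade("shipped boundary file is missing")
  read_boundaries(path)
}

#' Read grade boundaries from a JSON or TSV table
#'
#' JSON files carry `provenance` and a `levels` object mapping each dRCI
#' threshold to its `[Q1, Q2, Q3]` triple. TSV files have columns
#' `level`, `Q1`, `Q2`, `Q3`.
#'
#' @param path file path.
#' @return a [grade_boundaries()] object.
#' @export
read_boundaries <- function(path) {
  if (!file.exists(path)) stop_chipgrade("boundary file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    q <- do.call(rbind, js$levels)
    grade_boundaries(q, provenance = js$provenance %||% path)
  } else {
    dt <- data.table::fread(path, header = TRUE)
    q <- as.matrix(dt[, c("Q1", "Q2", "Q3")])
    rownames(q) <- as.character(dt$level)
    grade_boundaries(q, provenance = path)
  }
}

#' Write grade boundaries as JSON
#'
#' @param boundaries a [grade_boundaries()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_boundaries <- function(boundaries, path) {
  stopifnot(inherits(boundaries, "grade_boundaries"))
  levels <- lapply(seq_len(nrow(boundaries$q)), function(i) unname(boundaries$q[i, ]))
  names(levels) <- rownames(boundaries$q)
  jsonlite::write_json(list(provenance = boundaries$provenance, levels = levels),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Calibrate grade boundaries from a simulated score collection
#'
#' Runs the quality-indicator procedure over a grid of simulated datasets
#' and returns the quartiles of the resulting score distribution per dRCI
#' threshold, mirroring the quartile-of-collection construction used for
#' public score databases, at a scale a desk calibration can afford.
#'
#' @param layout genome to simulate on; default a single 100 Mb
#'   chromosome.
#' @param depths total-read grid.
#' @param enrichments enrichment-fraction grid.
#' @param seeds one simulation per (mark, depth, enrichment, seed) cell.
#' @param n_regions named list with the region count per mark type.
#' @param plan a [subsample_plan()] template; its seed is re-derived per
#'   cell.
#' @param thresholds dRCI thresholds in percent.
#' @param verbose print one line per cell.
#' @return a [grade_boundaries()] object; the full score table is
#'   attached as attribute `"scores"`.
#' @export
calibrate_boundaries <- function(layout = genome_layout("chr1", 1e8),
                                 depths = c(1e6, 5e6, 2e7),
                                 enrichments = c(0.1, 0.3, 0.5, 0.8),
                                 seeds = 1:3,
                                 n_regions = list(sharp = 20000L, broad = 400L),
                                 plan = subsample_plan(),
                                 thresholds = c(2.5, 5, 10),
                                 verbose = FALSE) {
  grid <- expand.grid(mark = c("sharp", "broad"), depth = depths,
                      enrichment = enrichments, seed = seeds,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- sim_config(layout, mark_type = g$mark,
                      n_regions = n_regions[[g$mark]],
                      enrichment_fraction = g$enrichment,
                      total_reads = g$depth,
                      seed = derive_seed(g$seed, paste0("cal-", g$mark), i))
    reads <- simulate_reads(cfg)
    cell_plan <- subsample_plan(plan$fractions,
                                seed = derive_seed(g$seed, "cal-qc", i),
                                draws_per_fraction = plan$draws_per_fraction,
                                grading_fraction = plan$grading_fraction)
    res <- run_qc(reads, layout, plan = cell_plan, thresholds = thresholds)
    rows[[i]] <- data.frame(g, t(res$score$scores), check.names = FALSE)
    if (verbose) {
      message(sprintf("[%d/%d] %s depth=%g enr=%.1f seed=%d -> %s",
                      i, nrow(grid), g$mark, g$depth, g$enrichment, g$seed,
                      paste(round(res$score$scores, 2), collapse = "/")))
    }
    rm(reads); gc(FALSE)
  }
  scores <- do.call(rbind, rows)
  score_cols <- format(thresholds, trim = TRUE)
  q <- t(vapply(score_cols,
                function(cn) stats::quantile(scores[[cn]], c(0.25, 0.5, 0.75),
                                             names = FALSE),
                numeric(3)))
  colnames(q) <- c("Q1", "Q2", "Q3")
  out <- grade_boundaries(q, provenance = sprintf(
    "simulator calibration: %d datasets, depths %s, enrichments %s, marks sharp/broad",
    nrow(scores), paste(format(depths, trim = TRUE), collapse = "/"),
    paste(enrichments, collapse = "/")))
  attr(out, "scores") <- scores
  out
}
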