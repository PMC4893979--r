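#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the Mersenne-Twister generator seeded at `seed` and
#' restores the caller's RNG state afterwards, so seeded operations never
#' disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

#' Derive a named substream seed from a master seed
#'
#' Each stochastic stage (outer subsampling, inner subsampling, landscape
#' placement, read placement, ...) draws from its own deterministic
#' substream so stages can be re-run independently yet reproducibly.
#' The derivation is a fixed linear-congruential mix kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @param index optional integer index within the stage (e.g. draw number).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, stage, index = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # all arithmetic in doubles; magnitudes stay < 2^53 so this is exact
  x <- (as.numeric(seed) %% 2147483647) * 48271
  x <- (x + stage_code * 69621 + as.numeric(index) * 16807) %% 2147483647
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_chipgrade <- function(fmt, ..., class = "chipgrade_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
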