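# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library functions never perturb user randomness.
#' @keywords internal
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic per-stage substream of a user seed, so each generation stage
# can be re-drawn independently; kept within 32-bit integer range.
#' @keywords internal
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 1000003 * stage) %% .Machine$integer.max)
}

#' @keywords internal
test_result <- function(name, statistic, df, p_value, n_perm = NA_integer_,
                        r_squared = NULL) {
  stopifnot(p_value > 0, p_value <= 1)
  out <- list(name = name, statistic = statistic, df = df, p_value = p_value,
              n_perm = n_perm)
  if (!is.null(r_squared)) out$r_squared <- r_squared
  class(out) <- "test_result"
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %.4g", x$name, x$statistic))
  if (!is.null(x$r_squared)) cat(sprintf(", R2 = %.3f", x$r_squared))
  if (!all(is.na(x$df))) cat(", df =", paste(x$df, collapse = ","))
  cat(sprintf(", p = %.3g", x$p_value))
  if (!is.na(x$n_perm)) cat(sprintf(" (%d permutations)", x$n_perm))
  cat("\n")
  invisible(x)
}
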