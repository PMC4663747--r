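#' @keywords internal
"_PACKAGE"

## shared small helpers -------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Format numbers for diff-stable TSV output
#'
#' All floating-point values exchanged through TSV files are written with 12
#' significant digits so that repeated runs produce byte-identical tables.
#' @noRd
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%d", as.integer64safe(v)))
    sprintf("%.12g", v)
  }, character(1))
  out
}

## integers beyond .Machine$integer.max are formatted through %.15g
as.integer64safe <- function(v) {
  if (abs(v) <= .Machine$integer.max) as.integer(v) else v
}

#' Write a data.frame as a TSV with stable number formatting
#' @noRd
write_tsv_stable <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Error helpers carrying condition classes used by the command-line wrapper
#' to distinguish validation failures (exit 1) from runtime errors (exit 2).
#' @noRd
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("microrep_validation_error", "error")))
}

stop_runtime <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("microrep_runtime_error", "error")))
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores (or removes) the global \code{.Random.seed} afterwards so that
#' generators are pure functions of their configuration.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
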