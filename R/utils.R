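#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed; double arithmetic (exact below
# 2^53) keeps the result inside the 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 7) %% 2147483629)
}

#' Percentage of a count within a total
#'
#' Convenience used in cohort summaries (e.g. severity-band prevalence),
#' rounded to whole percent by default to match questionnaire reporting.
#'
#' @param k count of interest.
#' @param n total count, must be positive.
#' @param digits decimal places to keep.
#' @return numeric percentage.
#' @examples
#' percent_of(19, 38) # 50
#' @export
percent_of <- function(k, n, digits = 0) {
  stopifnot(n > 0, k >= 0)
  round(100 * k / n, digits)
}

# maximal runs of TRUE in a logical vector; returns data.frame(start, end)
# with 1-based indices (callers convert to 0-based frames).
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

msg_log <- function(level = "info", ...) {
  lv <- getOption("ocufatigue.log_level", "info")
  rank <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (rank[[level]] >= rank[[lv]])
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...)))
  invisible(NULL)
}
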