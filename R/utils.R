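# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

# Merge half-open integer-day intervals [start, end) into disjoint sorted pieces.
# `df` needs columns start, end (end > start); returns the same columns.
merge_interval_df <- function(df) {
  if (nrow(df) == 0L) return(df[, c("start", "end")])
  o <- order(df$start, df$end)
  s <- df$start[o]
  e <- df$end[o]
  run_end <- cummax(e)
  # a new block starts where the next interval begins strictly after the
  # running maximum end ([0,30) and [30,60) stay separate blocks: day 30 gap? no,
  # [0,30) U [30,60) is contiguous coverage, so ">" (not ">=") merges them)
  new_block <- c(TRUE, s[-1L] > run_end[-length(run_end)])
  grp <- cumsum(new_block)
  data.frame(
    start = tapply(s, grp, min)[],
    end   = tapply(e, grp, max)[],
    row.names = NULL
  )
}

# Length of (union of intervals) intersected with [lo, hi). Assumes merged input.
interval_coverage <- function(intervals, lo, hi) {
  if (nrow(intervals) == 0L) return(0)
  a <- pmax(intervals$start, lo)
  b <- pmin(intervals$end, hi)
  sum(pmax(b - a, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
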