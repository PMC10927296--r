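# Internal helpers shared across modules.

#' Count spikes in half-open windows
#'
#' Counts, for each window `[starts[i], ends[i])`, the number of elements of
#' the sorted vector `times` it contains. Exact half-open semantics: a spike
#' exactly at a window start is counted, one exactly at the end is not.
#'
#' @param times sorted numeric vector (seconds).
#' @param starts,ends window edges (seconds), recycled to a common length.
#' @return integer vector of counts.
#' @keywords internal
#' @noRd
count_in_windows <- function(times, starts, ends) {
  # findInterval(x, v, left.open = TRUE) = number of v strictly below x
  findInterval(ends, times, left.open = TRUE) -
    findInterval(starts, times, left.open = TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps simulations reproducible without
# clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# One derived seed per unit: deterministic in (master seed, index), kept
# inside 32-bit integer range.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 7919 + 104729 * as.double(index)) %%
               .Machine$integer.max)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
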