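#' Detect an evoked excitatory response
#'
#' Scans the post-stimulus PSTH bins within `search_window` for the first
#' bin whose trial-summed count reaches `bin_mean + threshold_sd * bin_sd`
#' of the baseline. The excitatory response latency is the time, after
#' stimulus onset, at which the firing rate reaches 3 baseline SDs.
#'
#' The crossing is resolved to one bin; `point` selects how the bin is
#' reported as a latency. `"midpoint"` (default) reports the bin centre —
#' the unbiased location of an event known only to lie in a half-open bin —
#' while `"leading"` reports the bin's leading edge, which reads off the
#' definition literally but is biased early by half a bin width. Cohort
#' latency summaries with sub-bin precision (means like 2.39 ms from 2-ms
#' bins) require either narrow bins or the midpoint convention.
#'
#' With a silent baseline (`bin_mean` and `bin_sd` both 0) any threshold is
#' degenerate; the first non-empty post-stimulus bin is then returned with
#' flag `"degenerate-baseline"`.
#'
#' @param x a [psth()].
#' @param baseline a [baseline_stats()] for `x`.
#' @param search_window post-stimulus search extent, s (default 0.030,
#'   matching the extra-spikes window).
#' @param threshold_sd threshold multiplier (default 3).
#' @param point `"midpoint"` or `"leading"`: how the crossing bin is
#'   reported.
#' @return list with `latency` (s, or `NA` if no crossing), `threshold`
#'   (counts, trial-summed scale), `bin_start` of the crossing bin, and
#'   `flags` (character vector).
#' @export
detect_excitation <- function(x, baseline, search_window = 0.030,
                              threshold_sd = 3,
                              point = c("midpoint", "leading")) {
  stopifnot(inherits(x, "psth"), inherits(baseline, "baseline_stats"))
  point <- match.arg(point)
  sel <- which(x$bin_start >= -1e-12 &
                 x$bin_start < search_window - 1e-12)
  if (!length(sel)) stop("search window contains no PSTH bins", call. = FALSE)
  flags <- character()
  threshold <- baseline$bin_mean + threshold_sd * baseline$bin_sd
  if (baseline$bin_sd == 0 && baseline$bin_mean == 0) {
    flags <- "degenerate-baseline"
    hit <- sel[x$counts[sel] > 0][1L]
  } else {
    # a crossing must also exceed the baseline mean itself, which matters
    # only when the baseline is variance-free
    hit <- sel[x$counts[sel] >= threshold &
                 x$counts[sel] > baseline$bin_mean][1L]
  }
  if (is.na(hit)) {
    return(list(latency = NA_real_, threshold = threshold,
                bin_start = NA_real_, flags = flags))
  }
  lat <- x$bin_start[hit] + if (point == "midpoint") x$bin_width / 2 else 0
  list(latency = lat, threshold = threshold,
       bin_start = x$bin_start[hit], flags = flags)
}

#' Detect an evoked inhibitory response
#'
#' Scans the post-stimulus bins within `search_window` for the first run of
#' `run_length` consecutive bins whose trial-summed counts fall below the
#' low threshold, and reports the onset from the first bin of the run. An
#' inhibition response is a stretch of three consecutive bins with counts
#' below one baseline SD of the mean baseline count.
#'
#' That criterion admits two readings, kept behind `criterion`:
#' `"mean-minus-sd"` (default) uses `bin_mean - threshold_sd * bin_sd` as
#' the threshold — the only reading that yields a usable suppression test
#' for tonically active cells — while `"sd-value"` uses
#' `threshold_sd * bin_sd` itself.
#'
#' Under the default reading, a unit whose `bin_mean - bin_sd` is not
#' positive cannot exhibit the signature (counts are non-negative); the
#' result is then absent with flag `"floor-limited"`. Silent or low-rate
#' cells are floor-limited by construction.
#'
#' @param x a [psth()].
#' @param baseline a [baseline_stats()] for `x`.
#' @param search_window post-stimulus search extent, s (default 0.100:
#'   suppression typically outlasts the brief excitation).
#' @param threshold_sd SD multiplier (default 1).
#' @param run_length required number of consecutive sub-threshold bins
#'   (default 3).
#' @param criterion `"mean-minus-sd"` or `"sd-value"` (see above).
#' @param point as in [detect_excitation()].
#' @return list with `onset` (s or `NA`), `threshold`, `bin_start`, `flags`.
#' @export
detect_inhibition <- function(x, baseline, search_window = 0.100,
                              threshold_sd = 1, run_length = 3L,
                              criterion = c("mean-minus-sd", "sd-value"),
                              point = c("midpoint", "leading")) {
  stopifnot(inherits(x, "psth"), inherits(baseline, "baseline_stats"))
  criterion <- match.arg(criterion)
  point <- match.arg(point)
  run_length <- as.integer(run_length)
  sel <- which(x$bin_start >= -1e-12 &
                 x$bin_start < search_window - 1e-12)
  if (length(sel) < run_length) {
    stop("search window holds fewer bins than run_length", call. = FALSE)
  }
  threshold <- switch(criterion,
    "mean-minus-sd" = baseline$bin_mean - threshold_sd * baseline$bin_sd,
    "sd-value" = threshold_sd * baseline$bin_sd
  )
  if (threshold <= 0) {
    return(list(onset = NA_real_, threshold = threshold,
                bin_start = NA_real_, flags = "floor-limited"))
  }
  low <- x$counts[sel] < threshold
  run <- NA_integer_
  acc <- 0L
  for (i in seq_along(low)) {
    acc <- if (low[i]) acc + 1L else 0L
    if (acc == run_length) {
      run <- i - run_length + 1L
      break
    }
  }
  if (is.na(run)) {
    return(list(onset = NA_real_, threshold = threshold,
                bin_start = NA_real_, flags = character()))
  }
  bs <- x$bin_start[sel[run]]
  onset <- bs + if (point == "midpoint") x$bin_width / 2 else 0
  list(onset = onset, threshold = threshold, bin_start = bs,
       flags = character())
}

#' Classify a unit's evoked response
#'
#' Runs [detect_excitation()] and [detect_inhibition()] and assigns one of
#' the four response classes: `Ex` (excitation only), `In` (inhibition
#' only), `Ex+In` (both, with excitation preceding inhibition) or `NR`
#' (neither). If inhibition is detected at or before the excitation latency
#' the unit is classified `In` and flagged `"inhibition-precedes-excitation"`.
#'
#' @param x a [psth()].
#' @param baseline a [baseline_stats()] for `x`; computed from `x` with
#'   default settings when omitted.
#' @param excitation_args,inhibition_args named lists of extra arguments for
#'   the two detectors.
#' @param unit_id identifier carried through to the result.
#' @return object of class `response_classification`: `label`,
#'   `excitation_latency` (s or `NA`), `inhibition_onset` (s or `NA`),
#'   `threshold_high`, `threshold_low`, `flags`, `unit_id`.
#' @export
classify_response <- function(x, baseline = NULL,
                              excitation_args = list(),
                              inhibition_args = list(),
                              unit_id = NA_character_) {
  stopifnot(inherits(x, "psth"))
  if (is.null(baseline)) {
    baseline <- baseline_stats(x, span = min(3, x$window[["pre"]]))
  }
  ex <- do.call(detect_excitation, c(list(x, baseline), excitation_args))
  inh <- do.call(detect_inhibition, c(list(x, baseline), inhibition_args))
  flags <- c(ex$flags, inh$flags)
  has_ex <- !is.na(ex$latency)
  has_in <- !is.na(inh$onset)
  if (has_ex && has_in) {
    if (ex$latency < inh$onset) {
      label <- "Ex+In"
    } else {
      label <- "In"
      flags <- c(flags, "inhibition-precedes-excitation")
      ex$latency <- NA_real_
    }
  } else if (has_ex) {
    label <- "Ex"
  } else if (has_in) {
    label <- "In"
  } else {
    label <- "NR"
  }
  structure(
    list(label = label,
         excitation_latency = ex$latency,
         inhibition_onset = inh$onset,
         threshold_high = ex$threshold,
         threshold_low = inh$threshold,
         flags = flags,
         unit_id = unit_id),
    class = "response_classification"
  )
}

#' @export
print.response_classification <- function(x, ...) {
  fmt_ms <- function(v) if (is.na(v)) "-" else sprintf("%.2f ms", v * 1000)
  cat(sprintf("<response_classification> %s (excitation %s, inhibition %s)%s\n",
              x$label, fmt_ms(x$excitation_latency), fmt_ms(x$inhibition_onset),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Tabulate classifications as a data frame
#'
#' Flattens a list of [classify_response()] results into a data frame with
#' columns `unit_id`, `label`, `excitation_latency_ms`, `inhibition_onset_ms`
#' and `flags` (comma-joined), suitable for delimited-text export.
#'
#' @param classifications list of `response_classification` objects.
#' @return data frame, one row per unit.
#' @export
classification_table <- function(classifications) {
  stopifnot(all(vapply(classifications, inherits, TRUE,
                       "response_classification")))
  data.frame(
    unit_id = vapply(classifications, function(x) x$unit_id, character(1)),
    label = vapply(classifications, function(x) x$label, character(1)),
    excitation_latency_ms = vapply(classifications,
      function(x) x$excitation_latency * 1000, numeric(1)),
    inhibition_onset_ms = vapply(classifications,
      function(x) x$inhibition_onset * 1000, numeric(1)),
    flags = vapply(classifications,
      function(x) paste(x$flags, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}
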