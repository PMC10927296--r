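RESPONSE_LABELS <- c("Ex", "Ex+In", "In", "NR")

#' Summarize a cohort of classified units
#'
#' Aggregates per-unit [classify_response()] results into the standard
#' cohort summary: class counts and nearest-integer percentages, the percent
#' of responsive (non-NR) cells, and excitation-latency statistics pooled
#' over the cells with an excitatory component (`Ex` together with the
#' excitatory peak of `Ex+In` cells). Inhibition onsets are summarized
#' separately. Raw fractions are returned alongside the rounded percentages.
#'
#' @param classifications non-empty list of `response_classification`
#'   objects (or a character vector of labels when only counts are needed).
#' @param n_animals optional number of animals (bookkeeping metadata only).
#' @return object of class `cohort_summary` with fields `counts`,
#'   `percentages` (integer, per label), `fractions`, `responsive_percent`,
#'   `latency_mean`, `latency_sd`, `latency_sem` (s, excitation),
#'   `inhibition_mean`, `inhibition_sd` (s), `n_cells`, `n_animals`.
#' @examples
#' labs <- rep(c("Ex", "Ex+In", "In", "NR"), c(7, 21, 5, 10))
#' summarize_cohort(labs)
#' @export
summarize_cohort <- function(classifications, n_animals = NA_integer_) {
  if (!length(classifications)) {
    stop("at least one classification is required", call. = FALSE)
  }
  if (is.character(classifications)) {
    labels <- classifications
    ex_lat <- numeric()
    in_lat <- numeric()
  } else {
    stopifnot(all(vapply(classifications, inherits, TRUE,
                         "response_classification")))
    labels <- vapply(classifications, `[[`, character(1), "label")
    ex_lat <- vapply(classifications, `[[`, numeric(1), "excitation_latency")
    ex_lat <- ex_lat[!is.na(ex_lat)]
    in_lat <- vapply(classifications, `[[`, numeric(1), "inhibition_onset")
    in_lat <- in_lat[!is.na(in_lat)]
  }
  bad <- setdiff(unique(labels), RESPONSE_LABELS)
  if (length(bad)) {
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  n <- length(labels)
  counts <- vapply(RESPONSE_LABELS, function(l) sum(labels == l), integer(1))
  fractions <- counts / n
  stat <- function(v, f) if (length(v)) f(v) else NA_real_
  structure(
    list(counts = counts,
         percentages = round(100 * fractions),
         fractions = fractions,
         responsive_percent = round(100 * (n - counts[["NR"]]) / n),
         latency_mean = stat(ex_lat, mean),
         latency_sd = if (length(ex_lat) > 1L) stats::sd(ex_lat) else NA_real_,
         latency_sem = if (length(ex_lat) > 1L)
           stats::sd(ex_lat) / sqrt(length(ex_lat)) else NA_real_,
         n_latencies = length(ex_lat),
         inhibition_mean = stat(in_lat, mean),
         inhibition_sd = if (length(in_lat) > 1L) stats::sd(in_lat) else NA_real_,
         n_cells = n,
         n_animals = n_animals),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cells: %s\n", x$n_cells,
              paste(sprintf("%s %d (%d%%)", names(x$counts), x$counts,
                            x$percentages), collapse = ", ")))
  cat(sprintf("  responsive: %d%%\n", x$responsive_percent))
  if (!is.na(x$latency_mean)) {
    cat(sprintf("  excitation latency: %.2f +/- %.2f ms (mean +/- SD, n = %d)\n",
                x$latency_mean * 1000,
                if (is.na(x$latency_sd)) 0 else x$latency_sd * 1000,
                x$n_latencies))
  }
  if (!is.na(x$inhibition_mean)) {
    cat(sprintf("  inhibition onset: %.2f ms (mean)\n", x$inhibition_mean * 1000))
  }
  invisible(x)
}

#' Latency histogram
#'
#' Bins latencies into half-open bins of `bin_width`, anchored at 0, for the
#' standard cohort latency histograms.
#'
#' @param latencies numeric vector, s (non-empty; `NA`s dropped).
#' @param bin_width bin width, s (default 0.0005).
#' @return data frame with `bin_start_s`, `bin_end_s`, `count`; the counts
#'   sum to the number of latencies.
#' @export
latency_histogram <- function(latencies, bin_width = 0.0005) {
  latencies <- latencies[!is.na(latencies)]
  if (!length(latencies)) stop("latencies must be non-empty", call. = FALSE)
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  idx <- floor(latencies / bin_width + 1e-9)
  rng <- min(idx):max(idx)
  data.frame(
    bin_start_s = rng * bin_width,
    bin_end_s = (rng + 1) * bin_width,
    count = vapply(rng, function(k) sum(idx == k), integer(1))
  )
}

#' Summarize train-following profiles across cells
#'
#' Element-wise mean and SEM of the normalized per-pulse responses of
#' several [train_profile()] (or [epsc_train_profile()]) results, plus the
#' corresponding mean depression percentages. Train and graded summaries are
#' conventionally reported as mean +/- SEM. With a single profile the SEM is
#' 0 by convention and the result is flagged `"single-profile"`; profiles
#' with undefined normalization are dropped with flag `"dropped-flagged"`.
#'
#' @param profiles list of `train_response_profile` and/or
#'   `epsc_measurement` objects.
#' @return object of class `train_summary`: `mean_normalized`,
#'   `sem_normalized`, `mean_depression_1_to_2`, `mean_depression_1_to_last`
#'   (percent), `n_profiles`, `flags`.
#' @export
summarize_train <- function(profiles) {
  ok <- vapply(profiles, function(p)
    inherits(p, c("train_response_profile", "epsc_measurement")), logical(1))
  if (!all(ok)) stop("profiles must be train/EPSC profiles", call. = FALSE)
  flags <- character()
  usable <- vapply(profiles, function(p) !anyNA(p$normalized), logical(1))
  if (any(!usable)) flags <- "dropped-flagged"
  profiles <- profiles[usable]
  if (!length(profiles)) stop("no profile has a defined normalization", call. = FALSE)
  m <- do.call(rbind, lapply(profiles, `[[`, "normalized"))
  mean_norm <- colMeans(m)
  if (nrow(m) == 1L) {
    sem <- rep(0, ncol(m))
    flags <- c(flags, "single-profile")
  } else {
    sem <- apply(m, 2L, stats::sd) / sqrt(nrow(m))
  }
  np <- ncol(m)
  structure(
    list(mean_normalized = mean_norm,
         sem_normalized = sem,
         mean_depression_1_to_2 = (1 - mean_norm[2L]) * 100,
         mean_depression_1_to_last = (1 - mean_norm[np]) * 100,
         n_profiles = nrow(m),
         flags = flags),
    class = "train_summary"
  )
}

#' @export
print.train_summary <- function(x, ...) {
  cat(sprintf("<train_summary> %d profiles; normalized mean +/- SEM:\n",
              x$n_profiles))
  cat(paste(sprintf("  pulse %d: %.3f +/- %.3f", seq_along(x$mean_normalized),
                    x$mean_normalized, x$sem_normalized), collapse = "\n"), "\n")
  cat(sprintf("  depression 1->2 %.1f%%, 1->last %.1f%%\n",
              x$mean_depression_1_to_2, x$mean_depression_1_to_last))
  invisible(x)
}

#' Export a cohort summary as JSON
#'
#' @param x a [summarize_cohort()] result.
#' @param path output path.
#' @export
write_cohort_summary <- function(x, path) {
  stopifnot(inherits(x, "cohort_summary"))
  obj <- unclass(x)
  for (f in c("counts", "percentages", "fractions")) obj[[f]] <- as.list(obj[[f]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
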