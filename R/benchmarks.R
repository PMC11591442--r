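# Published per-video evaluation results on a group-housed pig tracking
# benchmark (nine 1-min and four 10-min test sequences at 5 fps, plus a
# three-tracker comparison on the same data). Percent-scale ratio metrics as
# printed; used in examples and as regression inputs for the aggregation and
# delta conventions.

#' Reference benchmark results
#'
#' Per-video tracking metrics (HOTA, MOTA, IDF1 in percent; IDs as counts)
#' from a published group-housed-pig tracking benchmark: a three-method
#' comparison (`"trackers"`), the nine 1-min test videos (`"one_min"`), and
#' the four 10-min test videos (`"ten_min"`). Only the identity-switch
#' column can be re-aggregated exactly (by summing); the benchmark's pooled
#' ratio metrics depend on unpublished per-frame counts.
#'
#' @param set One of `"trackers"`, `"one_min"`, `"ten_min"`.
#' @return Data frame with columns `video`/`method`, `hota`, `mota`, `idf1`,
#'   `ids`.
#' @export
benchmark_results <- function(set = c("trackers", "one_min", "ten_min")) {
  set <- match.arg(set)
  switch(set,
    trackers = data.frame(
      method = c("transtrack", "bytetrack", "pig_bytetrack"),
      hota = c(49.5, 71.4, 72.9),
      mota = c(87.3, 90.6, 91.7),
      idf1 = c(68.0, 87.9, 89.0),
      ids = c(255L, 55L, 41L),
      stringsAsFactors = FALSE),
    one_min = data.frame(
      video = c("10", "11", "12", "13", "14", "15", "16", "17", "18"),
      hota = c(80.3, 72.5, 63.0, 66.2, 77.1, 81.7, 82.5, 79.6, 56.0),
      mota = c(94.5, 94.9, 88.7, 97.9, 97.9, 97.1, 97.6, 97.9, 67.7),
      idf1 = c(95.0, 87.8, 84.9, 84.9, 95.0, 90.9, 98.8, 99.0, 64.2),
      ids = c(4L, 3L, 10L, 6L, 0L, 1L, 0L, 0L, 17L),
      stringsAsFactors = FALSE),
    ten_min = data.frame(
      video = c("01", "02", "03", "04"),
      hota = c(66.1, 69.1, 50.8, 59.0),
      mota = c(90.8, 95.1, 88.4, 87.5),
      idf1 = c(47.8, 53.4, 50.8, 67.0),
      ids = c(14L, 29L, 72L, 83L),
      stringsAsFactors = FALSE))
}

#' Metric improvement of one tracker over another
#'
#' Differences on the percent scale for the ratio metrics (`a - b`, positive
#' means `a` is better) and the identity-switch reduction (`b - a`, positive
#' means `a` switches less).
#'
#' @param results Data frame as returned by
#'   `benchmark_results("trackers")`, or any with columns `method`, `hota`,
#'   `mota`, `idf1`, `ids`.
#' @param a,b Method names to compare.
#' @return Named numeric vector `hota`, `mota`, `idf1` (gains) and `ids`
#'   (reduction).
#' @export
metric_gain <- function(results, a, b) {
  ra <- results[results$method == a, ]
  rb <- results[results$method == b, ]
  if (nrow(ra) != 1L || nrow(rb) != 1L) stop("methods not found uniquely")
  c(hota = ra$hota - rb$hota, mota = ra$mota - rb$mota,
    idf1 = ra$idf1 - rb$idf1, ids = rb$ids - ra$ids)
}
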