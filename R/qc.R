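#' MAD-based quality-control flagging
#'
#' Flags samples whose QC metrics lie beyond `k` median absolute
#' deviations (MADs) from the median within a stratum (e.g. library
#' type), in the direction declared failing for each metric: `"low"`
#' flags values below `median - k * MAD`, `"high"` flags values above
#' `median + k * MAD`. The MAD uses the 1.4826 consistency constant.
#' Samples are then graded: `drop` when at least `drop_at` metrics
#' fail, `warn` when at least one (but fewer than `drop_at`) fails,
#' `pass` otherwise.
#'
#' @param metrics a data frame with a `sample_id` column and one
#'   numeric column per QC metric (plus optional stratum columns).
#' @param directions named character vector mapping metric name to
#'   `"low"` or `"high"`, the direction in which the metric fails.
#' @param k positive number of MADs defining the outlier cutoff
#'   (default 3).
#' @param group_by optional name of a stratum column in `metrics`
#'   within which medians and MADs are computed.
#' @param drop_at minimum number of failing metrics for a `drop`
#'   status (default 2).
#' @return a tibble with columns `sample_id`, `status`
#'   (`pass`/`warn`/`drop`), `n_failing`, and `failing_metrics`
#'   (list-column of metric names).
#' @export
mad_flag <- function(metrics, directions, k = 3, group_by = NULL,
                     drop_at = 2) {
  if (!is.numeric(k) || k <= 0) abort("`k` must be positive.")
  if (!"sample_id" %in% names(metrics)) {
    abort("`metrics` must have a sample_id column.")
  }
  metric_names <- names(directions)
  missing <- setdiff(metric_names, names(metrics))
  if (length(missing) > 0) {
    abort(paste0("metrics absent from table: ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(directions %in% c("low", "high"))) {
    abort("directions must be 'low' or 'high'.")
  }
  for (m in metric_names) {
    if (!is.numeric(metrics[[m]])) {
      abort(paste0("metric is not numeric: ", m))
    }
  }
  if (is.null(group_by)) {
    strata <- rep("all", nrow(metrics))
  } else {
    if (!group_by %in% names(metrics)) {
      abort(paste0("unknown stratum column: ", group_by))
    }
    strata <- as.character(metrics[[group_by]])
  }
  if (nrow(metrics) == 0) abort("empty metrics table.")

  fails <- matrix(FALSE, nrow = nrow(metrics), ncol = length(metric_names),
                  dimnames = list(NULL, metric_names))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    for (m in metric_names) {
      x <- metrics[[m]][idx]
      med <- median(x)
      dev <- mad(x, constant = 1.4826)
      fails[idx, m] <- if (directions[[m]] == "high") {
        x > med + k * dev
      } else {
        x < med - k * dev
      }
    }
  }
  n_failing <- rowSums(fails)
  tibble(
    sample_id = as.character(metrics$sample_id),
    status = case_when(
      n_failing >= drop_at ~ "drop",
      n_failing >= 1 ~ "warn",
      TRUE ~ "pass"
    ),
    n_failing = as.integer(n_failing),
    failing_metrics = lapply(seq_len(nrow(fails)), function(i) {
      metric_names[fails[i, ]]
    })
  )
}
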