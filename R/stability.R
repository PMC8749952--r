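# Bootstrap analysis: how many equimolar standard peptides are needed for
# a stable median calibrant?

#' Bootstrap the median of a peptide area pool at one subset size
#'
#' Repeatedly draws `k` distinct areas (sampling without replacement
#' within an iteration) from the pool and records the median of each draw.
#' The spread of those medians -- their CV in percent -- measures how
#' stable a median computed from only `k` peptides would be.
#'
#' @param areas positive numeric pool of XIC peak areas.
#' @param k number of peptides per draw, `1 <= k <= length(areas)`.
#' @param n_iter bootstrap iterations (default 100).
#' @param seed integer seed; results are fully reproducible from it.
#' @param replace sample with replacement instead (default FALSE).
#' @return object of class `bootstrap_run`: list with `k`, `n_iter`,
#'   `seed`, `medians` (length `n_iter`), `spread_percent`,
#'   `median_of_medians`.
#' @export
bootstrap_median <- function(areas, k, n_iter = 100L, seed = 1L,
                             replace = FALSE) {
  areas <- as.numeric(areas)
  if (!length(areas) || any(!is.finite(areas)) || any(areas <= 0))
    validation_error("areas must be a positive numeric pool")
  if (k < 1L || (!replace && k > length(areas)))
    validation_error(sprintf(
      "k = %d outside 1..%d (pool size)", k, length(areas)
    ))
  medians <- with_local_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      stats::median(sample(areas, k, replace = replace))
    }, numeric(1))
  })
  m <- mean(medians)
  spread <- if (stats::sd(medians) == 0) 0 else 100 * stats::sd(medians) / m
  structure(
    list(
      k = as.integer(k), n_iter = as.integer(n_iter), seed = as.integer(seed),
      medians = medians,
      spread_percent = spread,
      median_of_medians = stats::median(medians)
    ),
    class = "bootstrap_run"
  )
}

#' @export
print.bootstrap_run <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_run> k = %d, %d iterations: median of medians %.5g, spread %.3g%%\n",
    x$k, x$n_iter, x$median_of_medians, x$spread_percent
  ))
  invisible(x)
}

#' Median-spread profile over a range of subset sizes
#'
#' Runs [bootstrap_median()] for each `k` and tabulates the spread of the
#' bootstrap medians. On real standard digests the spread drops steeply up
#' to roughly 5-10 peptides and plateaus beyond about 30, which motivates
#' the low-count warning in [median_calibrant()].
#'
#' @inheritParams bootstrap_median
#' @param k_values subset sizes to profile (default 3..120, truncated to
#'   the pool size).
#' @return data frame with columns `k`, `spread_percent`,
#'   `median_of_medians`; each row reproducible from `seed` and `k`.
#' @export
median_spread_profile <- function(areas, k_values = 3:120, n_iter = 100L,
                                  seed = 1L, replace = FALSE) {
  if (!length(k_values))
    validation_error("k_values must be nonempty")
  if (!replace && max(k_values) > length(areas))
    validation_error(sprintf(
      "largest k (%d) exceeds pool size (%d)", max(k_values), length(areas)
    ))
  runs <- lapply(k_values, function(k)
    # derive a distinct, reproducible seed per k
    bootstrap_median(areas, k, n_iter, seed = seed + 7919L * as.integer(k),
                     replace = replace))
  data.frame(
    k = as.integer(k_values),
    spread_percent = vapply(runs, `[[`, numeric(1), "spread_percent"),
    median_of_medians = vapply(runs, `[[`, numeric(1), "median_of_medians")
  )
}

#' Recommend the minimum number of standard peptides
#'
#' Scans a [median_spread_profile()] for the smallest `k` whose spread is
#' at or below `spread_threshold_percent` and sits on a plateau: over the
#' next two larger profiled `k` the spread changes by less than 10%
#' relative (fewer than two successors are checked as available). If no
#' `k` qualifies, the largest profiled `k` is returned with a warning.
#'
#' @param profile data frame from [median_spread_profile()].
#' @param spread_threshold_percent acceptable spread of the bootstrap
#'   medians, in percent.
#' @param plateau_rel_change relative spread change under which the
#'   profile counts as flat (default 0.10).
#' @return the recommended `k` (integer).
#' @export
recommend_min_peptides <- function(profile, spread_threshold_percent,
                                   plateau_rel_change = 0.10) {
  if (is.null(profile) || nrow(profile) == 0L)
    validation_error("profile must be a nonempty data frame")
  profile <- profile[order(profile$k), , drop = FALSE]
  sp <- profile$spread_percent
  n <- nrow(profile)
  rel_change <- function(from, to) {
    if (sp[from] == 0) { if (sp[to] == 0) 0 else Inf }
    else abs(sp[to] - sp[from]) / sp[from]
  }
  for (i in seq_len(n)) {
    if (sp[i] > spread_threshold_percent) next
    nxt <- i + seq_len(min(2L, n - i))
    flat <- all(vapply(nxt, function(j) rel_change(i, j) < plateau_rel_change,
                       logical(1)))
    if (flat) return(profile$k[i])
  }
  warning("no k satisfied the spread threshold and plateau rule; returning the largest profiled k",
          call. = FALSE)
  profile$k[n]
}

#' Write a median-spread profile as TSV
#'
#' @param profile data frame from [median_spread_profile()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_spread_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
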