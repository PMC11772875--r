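# Group statistics the way the figures report them: the sampling unit is
# the image (each data point is the average over all objects detected in
# one image), compared with two-sided Mann-Whitney tests. The exact null
# distribution is used for combined n <= 20 without ties (computed by
# dynamic programming over rank-sum counts); otherwise midranks with the
# tie-corrected normal approximation and continuity correction.

#' Collapse an object table to per-image means
#'
#' One row per (image, condition): the mean of `metric` over that image's
#' objects. Pooling objects across images is never done here - images are
#' the sampling unit.
#'
#' @param object_table data frame with at least `image_id`, `condition`
#'   and the metric column.
#' @param metric metric column name.
#' @param group_keys grouping columns (default image + condition).
#' @return data frame with the group keys and `mean_value`, `n_objects`.
#' @export
per_image_means <- function(object_table, metric,
                            group_keys = c("image_id", "condition")) {
  if (!metric %in% names(object_table))
    stop("unknown metric: '", metric, "'")
  missing_keys <- setdiff(group_keys, names(object_table))
  if (length(missing_keys))
    stop("object table lacks grouping column(s): ",
         paste(missing_keys, collapse = ", "))
  tab <- object_table[!is.na(object_table[[metric]]), , drop = FALSE]
  if (nrow(tab) == 0)
    return(cbind(object_table[0, group_keys, drop = FALSE],
                 mean_value = numeric(0), n_objects = integer(0)))
  ag <- aggregate(tab[[metric]], tab[group_keys], mean)
  names(ag)[ncol(ag)] <- "mean_value"
  cnt <- aggregate(tab[[metric]], tab[group_keys], length)
  ag$n_objects <- cnt$x
  ag[do.call(order, ag[group_keys]), , drop = FALSE]
}

# counts of k-subsets of ranks 1..N by rank sum (dynamic programme)
rank_sum_counts <- function(m, N) {
  maxs <- sum(seq(N - m + 1, N))
  dp <- matrix(0, m + 1, maxs + 1)
  dp[1, 1] <- 1
  for (r in seq_len(N)) {
    for (k in rev(seq_len(min(m, r)))) {
      dp[k + 1, (r + 1):(maxs + 1)] <- dp[k + 1, (r + 1):(maxs + 1)] +
        dp[k, 1:(maxs + 1 - r)]
    }
  }
  dp[m + 1, ]
}

#' Two-sided Mann-Whitney U test
#'
#' Exact for combined n <= `exact_max` without ties; midranks plus the
#' tie-corrected normal approximation (with continuity correction)
#' otherwise. Groups smaller than 3 are still tested but flagged
#' low-power.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param exact_max largest combined n for the exact path (default 20).
#' @return list of class `mw_test`: `U` (for group A), `p` (two-sided),
#'   `method`, `flag`.
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 20L) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  m <- length(group_a)
  n <- length(group_b)
  N <- m + n
  pooled <- c(group_a, group_b)
  ties <- any(duplicated(pooled))
  r <- rank(pooled)
  W <- sum(r[seq_len(m)])
  U <- W - m * (m + 1) / 2
  flag <- if (m < 3 || n < 3) "low_power" else NA_character_

  if (!ties && N <= exact_max) {
    counts <- rank_sum_counts(m, N)
    total <- sum(counts)
    offset <- m * (m + 1) / 2  # rank sum = U + offset
    u_vals <- seq(0, m * n)
    probs <- counts[u_vals + offset + 1] / total
    lo <- sum(probs[u_vals <= U])
    hi <- sum(probs[u_vals >= U])
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sd_u <- sqrt(m * n / 12 * ((N + 1) - tie_corr))
    if (sd_u == 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sd_u
      z <- max(z, 0)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- if (ties) "normal_tie_corrected" else "normal"
  }
  structure(list(U = U, p = p, method = method, flag = flag),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-sided p = %.4g (%s)%s\n", x$U, x$p,
              x$method,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Percent difference with an explicit denominator convention
#'
#' `100 * (a - b) / denominator`, where the denominator is the larger
#' value, `a` (first) or `b` (second) - stated per call because summary
#' prose alternates conventions ("80% larger" uses the larger value as
#' denominator; "55% larger than control" uses the control).
#'
#' @param a,b values to compare.
#' @param reference denominator convention: `"larger"`, `"first"` or
#'   `"second"`.
#' @return percent difference, with the convention recorded as an
#'   attribute.
#' @export
percent_difference <- function(a, b, reference = c("larger", "first",
                                                   "second")) {
  reference <- match.arg(reference)
  den <- switch(reference, larger = max(a, b), first = a, second = b)
  if (den == 0) stop("zero denominator in percent difference")
  structure(100 * (a - b) / den, reference = reference)
}

#' Compare a metric between two conditions at the image level
#'
#' Aggregates to per-image means, runs the Mann-Whitney test, and reports
#' the percent difference of the condition means under a named convention.
#'
#' @param object_table per-object table with `image_id`, `condition` and
#'   the metric.
#' @param metric metric column name.
#' @param condition_a,condition_b the two condition labels to compare.
#' @param reference percent-difference convention (see
#'   [percent_difference()]).
#' @return list of class `group_comparison`.
#' @export
compare_groups <- function(object_table, metric, condition_a, condition_b,
                           reference = "larger") {
  pim <- per_image_means(object_table, metric)
  va <- pim$mean_value[pim$condition == condition_a]
  vb <- pim$mean_value[pim$condition == condition_b]
  if (length(va) == 0 || length(vb) == 0)
    stop("condition with no images: ",
         if (length(va) == 0) condition_a else condition_b)
  mw <- mann_whitney(va, vb)
  pd <- percent_difference(mean(va), mean(vb), reference)
  structure(list(metric = metric, condition_a = condition_a,
                 condition_b = condition_b, n_a = length(va),
                 n_b = length(vb), mean_a = mean(va), mean_b = mean(vb),
                 U = mw$U, p = mw$p, method = mw$method,
                 percent_difference = as.numeric(pd),
                 percent_reference = attr(pd, "reference"),
                 direction = if (mean(va) > mean(vb)) "a_greater"
                             else if (mean(va) < mean(vb)) "b_greater"
                             else "equal"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d) vs %s (n=%d)\n", x$metric, x$condition_a,
              x$n_a, x$condition_b, x$n_b))
  cat(sprintf("  means %.4g vs %.4g; %+.1f%% (ref=%s); U=%g, p=%.4g\n",
              x$mean_a, x$mean_b, x$percent_difference,
              x$percent_reference, x$U, x$p))
  invisible(x)
}

#' @rdname group_comparison_table
#' @name group_comparison_table
#' @title Flatten group comparisons to a data frame
#' @param comparisons list of `group_comparison` objects.
#' @return data frame, one row per comparison.
#' @export
group_comparison_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(x)
    data.frame(metric = x$metric, condition_a = x$condition_a,
               condition_b = x$condition_b, n_a = x$n_a, n_b = x$n_b,
               mean_a = x$mean_a, mean_b = x$mean_b, U = x$U, p = x$p,
               method = x$method, percent_difference = x$percent_difference,
               percent_reference = x$percent_reference)))
}
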