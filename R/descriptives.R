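#' Summary statistics for one item's ratings
#'
#' Location, spread and shape statistics backing the data-inspection
#' stage: mean, median and quartiles (linear interpolation between order
#' statistics, the "type 7" convention), interquartile range, range,
#' adjusted Fisher--Pearson sample skewness and the count at each of the
#' nine rating levels.
#'
#' @param table a [ratings_table()] object.
#' @param item item token.
#' @param rating_kind `"impaired"` or `"bothered"`.
#' @return A `wsas_summary` list with fields `item`, `rating_kind`, `n`,
#'   `mean`, `median`, `q1`, `q3`, `iqr`, `min`, `max`, `skewness`,
#'   `counts_by_level` (named vector over levels 0--8).
#' @export
summarize_ratings <- function(table, item,
                              rating_kind = c("impaired", "bothered")) {
  rating_kind <- match.arg(rating_kind)
  df <- as.data.frame(table)
  v <- df[[rating_kind]][df$item == item]
  if (length(v) == 0) stopf("no records for item '%s'", item)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  counts <- tabulate(v + 1L, nbins = 9L)
  names(counts) <- 0:8
  structure(list(item = item, rating_kind = rating_kind,
                 n = length(v), mean = mean(v),
                 median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
                 min = min(v), max = max(v),
                 skewness = sample_skewness(v),
                 counts_by_level = counts),
            class = "wsas_summary")
}

# Adjusted Fisher-Pearson coefficient G1 = g1 * sqrt(n(n-1))/(n-2).
# Constant vectors (and n < 3, where the adjustment is undefined) are
# reported as skewness 0 with a warning so degenerate inputs do not
# abort a pipeline run.
sample_skewness <- function(v) {
  n <- length(v)
  m2 <- mean((v - mean(v))^2)
  if (m2 == 0 || n < 3) {
    warning("skewness undefined (constant vector or n < 3); reporting 0")
    return(0)
  }
  g1 <- mean((v - mean(v))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' @export
print.wsas_summary <- function(x, ...) {
  cat(sprintf("%s / %s: n=%d mean=%.2f median=%.1f [q1=%.1f, q3=%.1f] range=%d-%d skew=%.2f\n",
              display_label(x$item), x$rating_kind, x$n, x$mean, x$median,
              x$q1, x$q3, x$min, x$max, x$skewness))
  invisible(x)
}

#' Compare impaired and bothered medians per item
#'
#' @param table a [ratings_table()] object.
#' @return Data frame with one row per item present: `item`,
#'   `impaired_median`, `bothered_median`, `differs` and `higher`
#'   (`"impaired"`, `"bothered"` or `"tie"`).
#' @export
compare_medians <- function(table) {
  df <- as.data.frame(table)
  items <- names(wsas_items())[names(wsas_items()) %in% unique(df$item)]
  rows <- lapply(items, function(it) {
    mi <- stats::median(df$impaired[df$item == it])
    mb <- stats::median(df$bothered[df$item == it])
    data.frame(item = it, impaired_median = mi, bothered_median = mb,
               differs = mi != mb,
               higher = if (mi == mb) "tie"
                        else if (mb > mi) "bothered" else "impaired",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
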