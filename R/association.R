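#' Tie-aware Spearman rank correlation
#'
#' Average ranks are assigned to ties in each vector independently and the
#' coefficient is the Pearson product-moment correlation of the two rank
#' vectors. This tie-exact form is used rather than the 6*sum(d^2)
#' shortcut, which is biased under ties; ordinal 0--8 ratings are heavily
#' tied.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return Spearman correlation in [-1, 1].
#' @export
#' @examples
#' spearman_rho(c(5, 2, 4, 4, 2, 5), c(5, 8, 6, 8, 5, 4))
spearman_rho <- function(x, y) {
  check_paired(x, y)
  stats::cor(rank(x), rank(y))
}

check_paired <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stopf("paired vectors must be complete")
  if (stats::sd(x) == 0)
    stopf("correlation undefined: x is constant (all values %s)", x[1])
  if (stats::sd(y) == 0)
    stopf("correlation undefined: y is constant (all values %s)", y[1])
  invisible(TRUE)
}

resample_result <- function(observed, p_value, n_resamples, n_as_extreme,
                            tail, p_convention, seed, exact, label,
                            statistic) {
  structure(list(observed = observed, p_value = p_value,
                 n_resamples = n_resamples, n_as_extreme = n_as_extreme,
                 tail = tail, p_convention = p_convention,
                 seed = seed, exact = exact, label = label,
                 statistic = statistic),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("%s (%s): observed = %.4f, p = %.4f [%s, %s, %s resamples%s]\n",
              x$statistic, x$label %||% "unlabelled", x$observed, x$p_value,
              x$tail, x$p_convention, format(x$n_resamples, big.mark = ","),
              if (x$exact) ", exact" else ""))
  invisible(x)
}

resample_p <- function(n_as_extreme, n_resamples, convention) {
  switch(convention,
         plug_in = n_as_extreme / n_resamples,
         add_one = (n_as_extreme + 1) / (n_resamples + 1),
         stopf("unknown p-value convention '%s'", convention))
}

# All permutations of 1..n as an (n! x n) integer matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# B random permutations of 1..n as an (n x B) index matrix.
random_permutations <- function(n, B) {
  vapply(seq_len(B), function(i) sample.int(n), integer(n))
}

#' Permutation test for the Spearman correlation
#'
#' One of the two paired vectors is shuffled (sampled without replacement)
#' and the rank correlation recomputed; the p-value is the proportion of
#' shuffled coefficients as large or larger than the observed one
#' (one-sided by default; a two-sided absolute-value rule is available).
#' For n at or below `exact_threshold` all n! permutations are enumerated
#' and the p-value is the exact fraction (plug-in convention).
#'
#' Tie counting is exact: permutation counts compare the centered
#' rank cross-product, whose values are integer multiples of 1/4 and
#' hence exactly representable, so "as large or larger" never suffers
#' floating-point tie misclassification.
#'
#' @param x,y paired vectors (impaired and bothered ratings).
#' @param n_resamples Monte Carlo resamples (>= 100; ignored in exact mode).
#' @param seed RNG seed for Monte Carlo shuffles (Mersenne-Twister).
#' @param tail `"one_sided_greater"` counts resampled rho >= observed;
#'   `"two_sided_absolute"` counts |resampled| >= |observed|.
#' @param p_convention `"add_one"` gives (b+1)/(B+1); `"plug_in"` gives
#'   b/B. Exact mode always reports the plug-in (exact) fraction.
#' @param exact_threshold enumerate all n! permutations when
#'   n <= this (default 7, i.e. at most 5,040 permutations).
#' @param label optional label carried into the result.
#' @return A `resample_result` with the observed rho, p-value and
#'   resampling provenance.
#' @export
permutation_test_rho <- function(x, y, n_resamples = 10000, seed = 1,
                                 tail = c("one_sided_greater",
                                          "two_sided_absolute"),
                                 p_convention = c("add_one", "plug_in"),
                                 exact_threshold = 7, label = NULL) {
  tail <- match.arg(tail)
  p_convention <- match.arg(p_convention)
  check_paired(x, y)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  observed <- stats::cor(rx, ry)
  # Which of the two vectors gets shuffled is statistically immaterial;
  # choosing it canonically (lexicographically larger rank vector) makes
  # the test exactly symmetric in its arguments at a fixed seed.
  if (rank_lex_gt(rx, ry)) { tmp <- rx; rx <- ry; ry <- tmp }
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  obs_stat <- sum(rxc * ryc)

  if (n <= exact_threshold) {
    perms <- all_permutations(n)
    stats_all <- as.numeric(matrix(ryc[perms], nrow(perms), n) %*% rxc)
    b <- count_extreme(stats_all, obs_stat, tail)
    return(resample_result(observed, b / nrow(perms), nrow(perms), b,
                           tail, "plug_in", seed = NA_integer_,
                           exact = TRUE, label = label,
                           statistic = "spearman_rho"))
  }

  if (n_resamples < 100) stopf("n_resamples must be >= 100")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  idx <- random_permutations(n, n_resamples)
  stats_mc <- as.numeric(crossprod(matrix(ryc[idx], n, n_resamples), rxc))
  b <- count_extreme(stats_mc, obs_stat, tail)
  resample_result(observed, resample_p(b, n_resamples, p_convention),
                  n_resamples, b, tail, p_convention, seed,
                  exact = FALSE, label = label, statistic = "spearman_rho")
}

rank_lex_gt <- function(a, b) {
  k <- which(a != b)
  length(k) > 0 && a[k[1]] > b[k[1]]
}

count_extreme <- function(stats, obs, tail) {
  if (tail == "one_sided_greater") sum(stats >= obs)
  else sum(abs(stats) >= abs(obs))
}

#' Pool all item-level pairs into one combined vector pair
#'
#' Concatenates every (impaired, bothered) pair across the five items, in
#' canonical item order and stable respondent order, so the same table
#' always yields the same pair order.
#'
#' @param table a [ratings_table()] object.
#' @return A list with `x` (impaired), `y` (bothered) and
#'   `label = "combined"`.
#' @export
pooled_pairs <- function(table) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) stopf("cannot pool an empty table")
  ord <- order(match(df$item, names(wsas_items())))
  df <- df[ord, , drop = FALSE]
  list(x = df$impaired, y = df$bothered, label = "combined")
}

# Per-respondent scale sums: the alternative reading of "combined".
summed_pairs <- function(table) {
  df <- as.data.frame(table)
  ids <- unique(df$respondent_id)
  list(x = as.numeric(tapply(df$impaired, factor(df$respondent_id, ids), sum)),
       y = as.numeric(tapply(df$bothered, factor(df$respondent_id, ids), sum)),
       label = "combined")
}

item_pairs <- function(table, item) {
  df <- as.data.frame(table)
  sub <- df[df$item == item, , drop = FALSE]
  if (nrow(sub) == 0) stopf("no records for item '%s'", item)
  list(x = sub$impaired, y = sub$bothered, label = item)
}
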