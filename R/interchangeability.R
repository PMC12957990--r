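#' Paired difference vector (impaired minus bothered)
#'
#' The orientation is fixed as impaired minus bothered: negative values
#' mean botheredness exceeds impairment. Statistically a sign flip is
#' immaterial to the two-sided test, but the orientation matters when
#' reading report tables, so it is fixed and documented here.
#'
#' @param table a [ratings_table()] object.
#' @param label one item token or `"combined"` (all items' differences
#'   concatenated in canonical item order).
#' @return A `difference_vector` list: `d` (integers in -8..8), `label`,
#'   `n`.
#' @export
differences <- function(table, label = "combined") {
  pv <- if (label == "combined") pooled_pairs(table)
        else item_pairs(table, label)
  structure(list(d = as.integer(pv$x - pv$y), label = label,
                 n = length(pv$x)),
            class = "difference_vector")
}

as_difference_vector <- function(dv, label = NULL) {
  if (inherits(dv, "difference_vector")) return(dv)
  structure(list(d = as.integer(dv), label = label %||% "adhoc",
                 n = length(dv)),
            class = "difference_vector")
}

#' Sign-flip randomization test of interchangeability
#'
#' Tests the null hypothesis that the two members of each pair are
#' interchangeable: each resample multiplies the paired differences by
#' independent random signs (+1 or -1, sampled with replacement with
#' probability 1/2) and recomputes the mean. The two-sided p-value is the
#' proportion of resampled means at least as large in absolute value as
#' the observed mean (ties count as extreme). Comparisons are done on
#' integer sums, so tie counting is exact.
#'
#' @param dv a `difference_vector` from [differences()], or a plain
#'   integer vector of paired differences.
#' @param n_resamples number of sign resamples (>= 100).
#' @param seed RNG seed.
#' @param p_convention `"add_one"` (default) or `"plug_in"`.
#' @return A `resample_result` with observed mean difference and p-value.
#' @export
#' @examples
#' signflip_test(c(-2, 0, -2, -3, 3, -3), n_resamples = 10000, seed = 1)
signflip_test <- function(dv, n_resamples = 10000, seed = 1,
                          p_convention = c("add_one", "plug_in")) {
  p_convention <- match.arg(p_convention)
  dv <- as_difference_vector(dv)
  if (dv$n < 1) stopf("need at least one difference")
  if (n_resamples < 100) stopf("n_resamples must be >= 100")
  d <- dv$d
  obs_sum <- sum(d)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_resamples * dv$n, replace = TRUE),
                  n_resamples, dv$n)
  sums <- as.numeric(signs %*% d)
  b <- sum(abs(sums) >= abs(obs_sum))
  resample_result(observed = obs_sum / dv$n,
                  p_value = resample_p(b, n_resamples, p_convention),
                  n_resamples = n_resamples, n_as_extreme = b,
                  tail = "two_sided_absolute", p_convention = p_convention,
                  seed = seed, exact = FALSE, label = dv$label,
                  statistic = "mean_difference")
}

#' Exact sign-flip test by exhaustive enumeration
#'
#' Enumerates all 2^n sign assignments and reports the exact fraction
#' whose mean is at least as large in absolute value as the observed mean.
#' Zero differences contribute duplicate assignments, which enumeration
#' handles naturally. Sums are compared as integers.
#'
#' @param dv a `difference_vector` or plain integer vector.
#' @param max_n refuse enumeration above this n (default 20, i.e. at most
#'   1,048,576 assignments); use [signflip_test()] beyond it.
#' @return A `resample_result` with `exact = TRUE` and the plug-in
#'   (exact-fraction) p-value.
#' @export
#' @examples
#' signflip_exact(c(-2, 0, -2, -3, 3, -3))  # p = 24/64 = 0.375
signflip_exact <- function(dv, max_n = 20) {
  dv <- as_difference_vector(dv)
  if (dv$n < 1) stopf("need at least one difference")
  if (dv$n > max_n)
    stopf("n = %d exceeds max_n = %d (2^n assignments): use the Monte Carlo signflip_test()",
          dv$n, max_n)
  sums <- 0
  for (di in dv$d) sums <- c(sums + di, sums - di)
  b <- sum(abs(sums) >= abs(sum(dv$d)))
  total <- length(sums)
  resample_result(observed = sum(dv$d) / dv$n, p_value = b / total,
                  n_resamples = total, n_as_extreme = b,
                  tail = "two_sided_absolute", p_convention = "plug_in",
                  seed = NA_integer_, exact = TRUE, label = dv$label,
                  statistic = "mean_difference")
}

#' Interchangeability tests for every item plus the pooled differences
#'
#' Runs the sign-flip test per item and on the pooled (or summed)
#' differences, in report row order (Combined first, then the five
#' items), with a rejection decision at `alpha`. Exact enumeration is
#' used when n is small enough; Monte Carlo otherwise.
#'
#' @param table a [ratings_table()] object.
#' @param n_resamples Monte Carlo resamples.
#' @param seed master seed; each label gets a derived sub-seed.
#' @param alpha significance level for the decision column.
#' @param p_convention Monte Carlo p-value convention.
#' @param exact_threshold use exact enumeration when n <= this.
#' @param combined_mode `"pooled"` concatenates item differences;
#'   `"sums"` differences the per-respondent scale sums.
#' @return A list of `resample_result`s named by label, with attribute
#'   `decisions` (logical rejections at `alpha`).
#' @export
interchangeability_table <- function(table, n_resamples = 10000, seed = 1,
                                     alpha = 0.05,
                                     p_convention = c("add_one", "plug_in"),
                                     exact_threshold = 20,
                                     combined_mode = c("pooled", "sums")) {
  p_convention <- match.arg(p_convention)
  combined_mode <- match.arg(combined_mode)
  df <- as.data.frame(table)
  items <- names(wsas_items())[names(wsas_items()) %in% unique(df$item)]
  out <- list()
  for (lab in audit_labels(items)) {
    dv <- if (lab == "combined" && combined_mode == "sums") {
      sp <- summed_pairs(table)
      structure(list(d = as.integer(sp$x - sp$y), label = "combined",
                     n = length(sp$x)), class = "difference_vector")
    } else differences(table, lab)
    out[[lab]] <- if (dv$n <= exact_threshold) signflip_exact(dv)
                  else signflip_test(dv, n_resamples,
                                     seed = derive_seed(seed, lab, "signflip"),
                                     p_convention = p_convention)
  }
  attr(out, "decisions") <- vapply(out, function(r) r$p_value <= alpha,
                                   logical(1))
  attr(out, "alpha") <- alpha
  out
}
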