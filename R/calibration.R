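#' Simulation design for calibration studies
#'
#' @param n_respondents sample size per replicate.
#' @param n_replicates independent replicates per design point (>= 100
#'   for any reported rate).
#' @param n_resamples_per_test resamples inside each test.
#' @param alpha nominal significance level, in (0, 1).
#' @param effect_grid optional vector of effects (latent shifts for the
#'   sign-flip test, latent correlations for the permutation test).
#' @param master_seed seed from which replicate seeds are derived.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_respondents = 61, n_replicates = 2000,
                              n_resamples_per_test = 2000, alpha = 0.05,
                              effect_grid = NULL, master_seed = 1) {
  if (n_replicates < 100)
    stopf("n_replicates must be >= 100 for any reported rate")
  if (alpha < 0 || alpha >= 1) stopf("alpha must lie in [0, 1)")
  structure(list(n_respondents = n_respondents,
                 n_replicates = n_replicates,
                 n_resamples_per_test = n_resamples_per_test,
                 alpha = alpha, effect_grid = effect_grid,
                 master_seed = master_seed),
            class = "simulation_design")
}

calibration_report <- function(design, test, effects, rates) {
  se <- sqrt(rates * (1 - rates) / design$n_replicates)
  structure(list(test = test, effects = effects,
                 rejection_rate = rates, monte_carlo_se = se,
                 n_replicates = design$n_replicates, design = design),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration of the %s test (n = %d, %d replicates, B = %d, alpha = %.3f)\n",
              x$test, x$design$n_respondents, x$n_replicates,
              x$design$n_resamples_per_test, x$design$alpha))
  for (k in seq_along(x$rejection_rate))
    cat(sprintf("  effect %8.4f : rejection rate %.4f (MC SE %.4f)\n",
                if (is.null(x$effects)) 0 else x$effects[k],
                x$rejection_rate[k], x$monte_carlo_se[k]))
  invisible(x)
}

# One replicate's rating pair for a single generic item under the given
# latent correlation and shift; uses the same copula path as the table
# generator.
replicate_pair <- function(n, rho, shift, seed,
                           weights = default_marginal_weights()) {
  th <- marginal_thresholds(weights)
  pair <- draw_latent_pairs(n, rho, shift, seed)
  list(x = latent_to_rating(pair$x, th), y = latent_to_rating(pair$y, th))
}

run_rejections <- function(design, test, rho, shift, stream) {
  vapply(seq_len(design$n_replicates), function(r) {
    data_seed <- derive_seed(design$master_seed, stream, "data", r)
    test_seed <- derive_seed(design$master_seed, stream, "test", r)
    pair <- replicate_pair(design$n_respondents, rho, shift, data_seed)
    p <- if (test == "signflip") {
      signflip_test(pair$x - pair$y, design$n_resamples_per_test,
                    seed = test_seed)$p_value
    } else {
      if (stats::sd(pair$x) == 0 || stats::sd(pair$y) == 0) return(FALSE)
      permutation_test_rho(pair$x, pair$y, design$n_resamples_per_test,
                           seed = test_seed, exact_threshold = 0)$p_value
    }
    p <= design$alpha
  }, logical(1))
}

#' Type-I error of a resampling test under its null
#'
#' Estimates the rejection rate when the null holds: zero latent shift
#' (with ratings still correlated) for the sign-flip test, independent
#' latents for the permutation correlation test. A well-calibrated
#' two-sided test at alpha = 0.05 should reject in about 5% of
#' replicates.
#'
#' @param design a [simulation_design()].
#' @param test `"signflip"` or `"perm_rho"`.
#' @param null_correlation latent correlation used for the sign-flip null
#'   (the paired ratings remain dependent; only the shift is zero).
#' @return A `calibration_report` with the rejection rate and its
#'   binomial Monte Carlo standard error.
#' @export
type1_error <- function(design, test = c("signflip", "perm_rho"),
                        null_correlation = 0.65) {
  test <- match.arg(test)
  rho <- if (test == "signflip") null_correlation else 0
  rej <- run_rejections(design, test, rho = rho, shift = 0,
                        stream = paste0("t1-", test))
  calibration_report(design, test, effects = 0, rates = mean(rej))
}

#' Power curve of a resampling test over a grid of effects
#'
#' For the sign-flip test the effect is the latent shift of the bothered
#' coordinate; for the permutation correlation test it is the latent
#' correlation. The zero-effect entry reproduces the type-I error within
#' simulation noise.
#'
#' @param design a [simulation_design()] with a non-empty `effect_grid`.
#' @param test `"signflip"` or `"perm_rho"`.
#' @param null_correlation latent correlation held fixed while the shift
#'   varies (sign-flip test only).
#' @return A `calibration_report` with one rejection rate per effect.
#' @export
power_curve <- function(design, test = c("signflip", "perm_rho"),
                        null_correlation = 0.65) {
  test <- match.arg(test)
  if (is.null(design$effect_grid)) stopf("design$effect_grid is required")
  rates <- vapply(seq_along(design$effect_grid), function(k) {
    eff <- design$effect_grid[k]
    if (test == "signflip")
      mean(run_rejections(design, test, rho = null_correlation,
                          shift = eff, stream = paste0("pw-", k)))
    else
      mean(run_rejections(design, test, rho = eff, shift = 0,
                          stream = paste0("pw-", k)))
  }, numeric(1))
  calibration_report(design, test, effects = design$effect_grid,
                     rates = rates)
}

#' Reproduce the study's qualitative result pattern on synthetic data
#'
#' Runs the full audit on replicated study-like synthetic tables
#' (61 respondents, study-calibrated correlations and shifts) and
#' reports, per row label, the fraction of replicates rejecting
#' interchangeability at `alpha` and the fraction where the permutation
#' correlation test yields p <= 0.0001, together with the mean sample
#' Spearman and mean difference across replicates. With the study's
#' design points, the home, relationships, work and combined rows should
#' reject in a large majority of replicates and the social-leisure row
#' (expected difference +0.03) in a minority.
#'
#' @param master_seed seed; replicate seeds are derived from it.
#' @param n_replicates number of synthetic studies (default 500).
#' @param n_resamples resamples per test (default 10,000).
#' @param alpha significance level.
#' @param n_respondents respondents per replicate (default 61).
#' @return A `study_pattern` list with per-label vectors
#'   `signflip_reject_rate`, `perm_small_p_rate`, `mean_rho`,
#'   `mean_diff`, plus `n_replicates` and `monte_carlo_se`.
#' @export
reproduce_study_pattern <- function(master_seed = 1, n_replicates = 500,
                                    n_resamples = 10000, alpha = 0.05,
                                    n_respondents = 61) {
  if (n_replicates < 100)
    stopf("n_replicates must be >= 100 for any reported rate")
  base_cfg <- study_like_config(master_seed, n_respondents = n_respondents)
  labs <- audit_labels()
  rej <- small <- matrix(FALSE, n_replicates, length(labs),
                         dimnames = list(NULL, labs))
  rho <- dbar <- matrix(NA_real_, n_replicates, length(labs),
                        dimnames = list(NULL, labs))
  for (r in seq_len(n_replicates)) {
    cfg <- base_cfg
    cfg$seed <- derive_seed(master_seed, "replicate", r)
    audit <- wsas_audit(cfg, n_resamples = n_resamples,
                        seed = derive_seed(master_seed, "audit", r),
                        alpha = alpha)
    for (lab in labs) {
      rej[r, lab] <- audit$interchangeability[[lab]]$p_value <= alpha
      small[r, lab] <- audit$association[[lab]]$p_value <= 0.0001
      rho[r, lab] <- audit$association[[lab]]$observed
      dbar[r, lab] <- audit$interchangeability[[lab]]$observed
    }
  }
  rates <- colMeans(rej)
  structure(list(signflip_reject_rate = rates,
                 perm_small_p_rate = colMeans(small),
                 mean_rho = colMeans(rho),
                 mean_diff = colMeans(dbar),
                 n_replicates = n_replicates,
                 monte_carlo_se = sqrt(rates * (1 - rates) / n_replicates),
                 alpha = alpha, n_resamples = n_resamples,
                 master_seed = master_seed),
            class = "study_pattern")
}

#' @export
print.study_pattern <- function(x, ...) {
  cat(sprintf("Study-pattern reproduction: %d replicates, B = %s, alpha = %.2f\n",
              x$n_replicates, format(x$n_resamples, big.mark = ","), x$alpha))
  cat(sprintf("  %-16s %-10s %-10s %-10s %s\n", "row", "reject", "p<=1e-4",
              "mean rho", "mean diff"))
  for (lab in names(x$signflip_reject_rate))
    cat(sprintf("  %-16s %-10.3f %-10.3f %-10.4f %+.4f\n",
                display_label(lab), x$signflip_reject_rate[lab],
                x$perm_small_p_rate[lab], x$mean_rho[lab], x$mean_diff[lab]))
  invisible(x)
}
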