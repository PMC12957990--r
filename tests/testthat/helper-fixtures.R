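# Hypothetical six-respondent home/work rating patterns used as the
# worked-example fixture throughout the suite.
worked_example_fixture <- function() {
  ratings_table(
    respondent_id = rep(sprintf("p%d", 1:6), 2),
    item     = rep(c("home", "work"), each = 6),
    impaired = c(6, 8, 4, 3, 6, 5, 5, 2, 4, 4, 2, 5),
    bothered = c(8, 8, 6, 6, 3, 8, 5, 8, 6, 8, 5, 4),
    provenance = "worked-example-fixture")
}

# Random complete five-item table for round-trip / property tests.
random_table <- function(n = 12, seed = 1) {
  set.seed(seed)
  items <- names(wsas_items())
  ratings_table(
    respondent_id = rep(sprintf("s%02d", seq_len(n)), each = length(items)),
    item     = rep(items, n),
    impaired = sample(0:8, n * length(items), replace = TRUE),
    bothered = sample(0:8, n * length(items), replace = TRUE))
}

# Independent exhaustive oracle for the sign-flip test: enumerate all
# sign rows via expand.grid and compare |sum| in integer arithmetic.
oracle_signflip_p <- function(d) {
  signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), length(d))))
  sums <- signs %*% as.integer(d)
  mean(abs(sums) >= abs(sum(d)))
}

# Independent exhaustive oracle for the permutation test on Spearman's
# rho: depth-first recursive permutation generation (distinct from the
# package's matrix construction), rho recomputed with stats::cor on the
# permuted raw values.
oracle_perm_rho_p <- function(x, y, tail = "one_sided_greater") {
  obs <- stats::cor(x, y, method = "spearman")
  perms <- list()
  recurse <- function(chosen, remaining) {
    if (length(remaining) == 0) {
      perms[[length(perms) + 1]] <<- chosen
      return(invisible())
    }
    for (k in seq_along(remaining))
      recurse(c(chosen, remaining[k]), remaining[-k])
  }
  recurse(integer(0), seq_along(y))
  stats_all <- vapply(perms, function(p)
    stats::cor(x, y[p], method = "spearman"), numeric(1))
  eps <- 1e-9
  if (tail == "one_sided_greater") mean(stats_all >= obs - eps)
  else mean(abs(stats_all) >= abs(obs) - eps)
}
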