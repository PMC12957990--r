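five_item_config <- function(n, rho = 0.6, shift = 0, seed = 1,
                             weights = default_marginal_weights()) {
  sim_config(n, lapply(names(wsas_items()), item_spec,
                       latent_correlation = rho, shift = shift,
                       marginal_weights = weights), seed = seed)
}

test_that("latent discretization respects thresholds and boundaries", {
  th_eq <- qnorm(cumsum(rep(1 / 9, 9))[1:8])
  expect_equal(latent_to_rating(-10, th_eq), 0L)
  expect_equal(latent_to_rating(10, th_eq), 8L)
  expect_equal(latent_to_rating(0, th_eq), 4L)
  z <- seq(-4, 4, length.out = 101)
  r <- latent_to_rating(z, th_eq)
  expect_true(all(r >= 0 & r <= 8))
  expect_true(all(diff(r) >= 0))
  expect_error(latent_to_rating(0, c(1, 0.5, rep(2, 6))), "increasing")
})

test_that("generation is deterministic under a fixed seed and per-item substreams are stable", {
  cfg <- five_item_config(61, seed = 7)
  t1 <- generate_ratings(cfg)
  t2 <- generate_ratings(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # changing one item's parameters must not perturb the others
  cfg2 <- cfg
  cfg2$items$work <- item_spec("work", 0.2, shift = 1)
  t3 <- generate_ratings(cfg2)
  for (it in setdiff(names(wsas_items()), "work"))
    expect_identical(t1[t1$item == it, ], t3[t3$item == it, ], info = it)
})

test_that("generated tables pass strict validation with ratings in 0-8", {
  tab <- generate_ratings(five_item_config(100, rho = 0.9, shift = 2, seed = 3))
  expect_true(validate_ratings(tab)$strict_pass)
  expect_true(all(tab$impaired %in% 0:8 & tab$bothered %in% 0:8))
  expect_equal(nrow(tab), 500)
})

test_that("near-perfect latent dependence survives discretization", {
  cfg <- five_item_config(10000, rho = 0.99, shift = 0, seed = 5)
  tab <- generate_ratings(cfg)
  home <- tab[tab$item == "home", ]
  expect_gt(spearman_rho(home$impaired, home$bothered), 0.9)
})

test_that("zero shift gives exchangeable coordinates (mean difference near zero)", {
  w <- c(0.02, 0.06, 0.12, 0.16, 0.28, 0.16, 0.12, 0.06, 0.02)  # symmetric
  cfg <- sim_config(10000, lapply(names(wsas_items()), item_spec,
                                  latent_correlation = 0.5, shift = 0,
                                  marginal_weights = w), seed = 11)
  tab <- generate_ratings(cfg)
  home <- tab[tab$item == "home", ]
  expect_lt(abs(mean(home$impaired - home$bothered)), 0.05)
})

test_that("empirical category frequencies recover the marginal weights", {
  w <- default_marginal_weights()
  cfg <- five_item_config(50000, rho = 0.6, shift = 0, seed = 2, weights = w)
  tab <- generate_ratings(cfg)
  home <- tab[tab$item == "home", ]
  freq <- tabulate(home$impaired + 1L, nbins = 9) / nrow(home)
  expect_lt(max(abs(freq - w)), 0.02)
})

test_that("sample Spearman is monotone in the latent correlation", {
  grid <- c(0, 0.3, 0.6, 0.9)
  achieved <- vapply(grid, function(r) {
    tab <- generate_ratings(five_item_config(20000, rho = r, seed = 13))
    home <- tab[tab$item == "home", ]
    spearman_rho(home$impaired, home$bothered)
  }, numeric(1))
  expect_true(all(diff(achieved) > 0))
})

test_that("mean(impaired - bothered) decreases as the latent shift grows", {
  grid <- c(-0.5, 0, 0.5, 1)
  diffs <- vapply(grid, function(s) {
    tab <- generate_ratings(five_item_config(20000, rho = 0.6, shift = s,
                                             seed = 17))
    home <- tab[tab$item == "home", ]
    mean(home$impaired - home$bothered)
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))
})

test_that("latent-correlation calibration maps independence to independence and shows attenuation", {
  r0 <- calibrate_latent_correlation(0, n_probe = 20000, seed = 3)
  expect_lt(abs(r0), 0.05)
  r <- calibrate_latent_correlation(0.7081, n_probe = 20000, seed = 3)
  expect_gte(r, 0.7081 - 0.01)  # discretization attenuates
  # recovered on a fresh large sample
  cfg <- five_item_config(10000, rho = r, seed = 19)
  tab <- generate_ratings(cfg)
  home <- tab[tab$item == "home", ]
  expect_lt(abs(spearman_rho(home$impaired, home$bothered) - 0.7081), 0.03)
})

test_that("an unreachable rank-correlation target reports the achievable bound", {
  # near-constant margins bound the attainable rank correlation; with
  # the two marginals degenerate at opposite ends no coupling of the
  # latents can push Spearman near 1
  low <- c(0.99, rep(0.01 / 8, 8))
  high <- rev(low)
  expect_error(
    calibrate_latent_correlation(0.99, marginal_weights_x = low,
                                 marginal_weights_y = high,
                                 n_probe = 5000, seed = 1),
    "unreachable.*achievable")
})

test_that("shift calibration hits fractional mean-difference targets in closed form", {
  w <- default_marginal_weights()
  for (target in c(-1.2295, -0.377, 0.0328)) {
    s <- calibrate_shift(target, w)
    m0 <- sum(0:8 * w)
    expect_equal(m0 - bothaudit:::expected_rating(w, s), target,
                 tolerance = 1e-6)
  }
  expect_error(calibrate_shift(-20), "unreachable")
})

test_that("study-like config is deterministic and carries calibrated parameters", {
  c1 <- study_like_config(5)
  c2 <- study_like_config(5)
  expect_identical(c1, c2)
  expect_equal(c1$n_respondents, 61L)
  rhos <- vapply(c1$items, function(s) s$latent_correlation, numeric(1))
  targets <- c(0.7081, 0.7558, 0.5721, 0.6379, 0.5596)
  expect_true(all(rhos >= targets - 0.01))  # latent weakly exceeds target
  shifts <- vapply(c1$items, function(s) s$shift, numeric(1))
  expect_true(all(shifts[c("home", "work")] > 0))
  expect_lt(shifts[["social_leisure"]], 0.05)
})

test_that("config validation rejects malformed specs", {
  expect_error(item_spec("home", 1.2), "latent_correlation")
  expect_error(item_spec("home", 0.5, marginal_weights = rep(0.1, 9)),
               "sum to 1")
  expect_error(item_spec("elsewhere", 0.5), "unknown item")
  expect_error(sim_config(1, lapply(names(wsas_items()), item_spec,
                                    latent_correlation = 0.5)),
               "n_respondents")
  expect_error(sim_config(10, lapply(rep("home", 5), item_spec,
                                     latent_correlation = 0.5)),
               "duplicate")
})
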