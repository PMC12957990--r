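test_that("difference vectors follow the impaired-minus-bothered orientation", {
  tab <- worked_example_fixture()
  dv <- differences(tab, "home")
  expect_equal(dv$d, c(-2L, 0L, -2L, -3L, 3L, -3L))
  expect_equal(mean(dv$d), -7 / 6)
  comb <- differences(tab, "combined")
  expect_equal(comb$n, 12)
  ident <- ratings_table(sprintf("p%d", 1:4), rep("home", 4),
                         c(1, 3, 5, 7), c(1, 3, 5, 7))
  expect_true(all(differences(ident, "home")$d == 0))
})

test_that("exhaustive sign-flip enumeration matches hand-countable cases", {
  r <- signflip_exact(c(1L, 1L))
  expect_equal(r$p_value, 0.5)       # means 1,0,0,-1; two of four at |1|
  expect_equal(r$n_resamples, 4)
  expect_equal(signflip_exact(c(0L))$p_value, 1)
  expect_equal(signflip_exact(c(5L))$p_value, 1)  # single pair: both signs extreme
  home <- signflip_exact(differences(worked_example_fixture(), "home"))
  expect_equal(home$p_value, 24 / 64)
  expect_equal(home$n_as_extreme, 24)
  expect_true(home$exact)
  expect_error(signflip_exact(rep(1L, 25)), "max_n")
})

test_that("exhaustive enumeration matches the independent expand.grid oracle", {
  set.seed(11)
  for (i in 1:8) {
    n <- sample(3:10, 1)
    d <- sample(-8:8, n, replace = TRUE)
    expect_equal(signflip_exact(d)$p_value, oracle_signflip_p(d),
                 info = paste("instance", i))
  }
})

test_that("Monte Carlo sign-flip p agrees with the exact p within binomial error", {
  set.seed(19)
  for (i in 1:5) {
    d <- sample(-8:8, 12, replace = TRUE)
    p_ex <- signflip_exact(d)$p_value
    B <- 20000
    p_mc <- signflip_test(d, n_resamples = B, seed = 200 + i,
                          p_convention = "plug_in")$p_value
    expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / B) + 1e-12)
  }
})

test_that("all-zero differences are perfectly interchangeable (p = 1)", {
  expect_equal(signflip_exact(c(0L, 0L, 0L))$p_value, 1)
  r <- signflip_test(c(0L, 0L, 0L), n_resamples = 500, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)
})

test_that("the two-sided p is invariant to negating every difference", {
  d <- c(-2L, 0L, -2L, -3L, 3L, -3L, 1L, 4L)
  expect_equal(signflip_exact(d)$p_value, signflip_exact(-d)$p_value)
  expect_equal(signflip_test(d, 2000, seed = 9)$p_value,
               signflip_test(-d, 2000, seed = 9)$p_value)
})

test_that("appending a zero difference leaves the exact p consistent", {
  # zeros only duplicate assignments: the exact fraction is unchanged
  d <- c(-2L, 3L, -1L, 4L)
  expect_equal(signflip_exact(c(d, 0L))$p_value, signflip_exact(d)$p_value)
  expect_equal(oracle_signflip_p(c(d, 0L)), oracle_signflip_p(d))
})

test_that("the per-item interchangeability table mirrors the report layout", {
  tab <- worked_example_fixture()
  res <- interchangeability_table(tab, n_resamples = 1000, seed = 3)
  expect_equal(names(res), c("combined", "home", "work"))
  expect_true(all(vapply(res, function(r) r$exact, logical(1))))  # n <= 20
  expect_equal(res$home$p_value, 0.375)
  dec <- attr(res, "decisions")
  expect_type(dec, "logical")
  expect_named(dec, c("combined", "home", "work"))

  ident <- ratings_table(rep(sprintf("p%d", 1:4), 2),
                         rep(c("home", "work"), each = 4),
                         rep(c(1, 3, 5, 7), 2), rep(c(1, 3, 5, 7), 2))
  res_id <- interchangeability_table(ident, n_resamples = 1000, seed = 3)
  expect_true(all(vapply(res_id, function(r) r$p_value, numeric(1)) == 1))
  expect_true(all(vapply(res_id, function(r) r$observed, numeric(1)) == 0))

  single <- ratings_table(sprintf("p%d", 1:5), rep("home", 5),
                          c(2, 4, 6, 8, 1), c(3, 3, 6, 7, 2))
  res_s <- interchangeability_table(single, n_resamples = 1000, seed = 3)
  expect_equal(res_s$combined$p_value, res_s$home$p_value)
  expect_equal(res_s$combined$observed, res_s$home$observed)
})

test_that("sign-flip null calibration holds at reduced scale", {
  # quick two-sided validity check; the full-size one runs with the
  # acceptance suite
  design <- simulation_design(30, 400, 500, alpha = 0.05, master_seed = 77)
  rate <- type1_error(design, "signflip")$rejection_rate
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})
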