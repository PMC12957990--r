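test_that("tie-aware Spearman matches identity, reversal and the hand-ranked fixture", {
  expect_equal(spearman_rho(0:4, 0:4), 1.0)
  expect_equal(spearman_rho(0:4, 4:0), -1.0)
  # work-item pairs: hand ranks (5.5,1.5,3.5,3.5,1.5,5.5) vs (2.5,5.5,4,5.5,2.5,1)
  x <- c(5, 2, 4, 4, 2, 5); y <- c(5, 8, 6, 8, 5, 4)
  expect_equal(spearman_rho(x, y), cor(c(5.5, 1.5, 3.5, 3.5, 1.5, 5.5),
                                       c(2.5, 5.5, 4, 5.5, 2.5, 1)))
  expect_equal(spearman_rho(x, y), -0.5539117, tolerance = 1e-6)
  # cross-check against the independent tie-handling implementation
  for (seed in 1:5) {
    set.seed(seed)
    a <- sample(0:8, 20, replace = TRUE); b <- sample(0:8, 20, replace = TRUE)
    expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"))
  }
})

test_that("constant vectors give an undefined-correlation error naming the side", {
  expect_error(spearman_rho(rep(3, 5), 1:5), "x is constant")
  expect_error(spearman_rho(1:5, rep(7, 5)), "y is constant")
  expect_error(permutation_test_rho(rep(3, 5), 1:5), "constant")
})

test_that("exact permutation enumeration matches the independent oracle", {
  set.seed(42)
  for (i in 1:6) {
    n <- sample(4:6, 1)
    x <- sample(0:8, n, replace = TRUE)
    y <- sample(0:8, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    for (tail in c("one_sided_greater", "two_sided_absolute")) {
      res <- permutation_test_rho(x, y, tail = tail, exact_threshold = 7)
      expect_true(res$exact)
      expect_equal(res$n_resamples, factorial(n))
      expect_equal(res$p_value, oracle_perm_rho_p(x, y, tail),
                   info = paste(tail, i))
    }
  }
})

test_that("with distinct values only the order-preserving permutation attains rho = 1", {
  res <- permutation_test_rho(1:8, 1:8, exact_threshold = 8)
  expect_true(res$exact)
  expect_equal(res$observed, 1.0)
  expect_equal(res$n_as_extreme, 1L)
  expect_equal(res$p_value, 1 / factorial(8))
})

test_that("Monte Carlo p agrees with exact enumeration within binomial error", {
  set.seed(7)
  for (i in 1:5) {
    x <- sample(0:8, 6, replace = TRUE)
    y <- sample(0:8, 6, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    p_ex <- permutation_test_rho(x, y, exact_threshold = 7)$p_value
    B <- 20000
    p_mc <- permutation_test_rho(x, y, n_resamples = B, seed = 100 + i,
                                 p_convention = "plug_in",
                                 exact_threshold = 0)$p_value
    expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / B) + 1e-12)
  }
})

test_that("observed rho is invariant to joint pair permutation and to swapping x and y", {
  set.seed(3)
  x <- sample(0:8, 30, replace = TRUE); y <- sample(0:8, 30, replace = TRUE)
  perm <- sample(30)
  expect_equal(spearman_rho(x[perm], y[perm]), spearman_rho(x, y))
  r1 <- permutation_test_rho(x, y, n_resamples = 2000, seed = 5)
  r2 <- permutation_test_rho(y, x, n_resamples = 2000, seed = 5)
  expect_equal(r1$observed, r2$observed)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("p-value conventions obey their defining identities", {
  x <- c(0, 3, 1, 5, 7, 2, 8, 4, 6, 1, 3, 5)
  y <- c(1, 2, 2, 6, 5, 3, 7, 3, 8, 0, 4, 6)
  r_add <- permutation_test_rho(x, y, n_resamples = 1000, seed = 2,
                                exact_threshold = 0)
  expect_equal(r_add$p_value, (r_add$n_as_extreme + 1) / 1001)
  expect_gt(r_add$p_value, 0)
  r_plug <- permutation_test_rho(x, y, n_resamples = 1000, seed = 2,
                                 p_convention = "plug_in",
                                 exact_threshold = 0)
  expect_equal(r_plug$p_value, r_plug$n_as_extreme / 1000)
  expect_error(permutation_test_rho(x, y, n_resamples = 50,
                                    exact_threshold = 0), ">= 100")
})

test_that("pooling concatenates all item pairs stably", {
  tab <- random_table(n = 61, seed = 30)
  pv <- pooled_pairs(tab)
  expect_equal(length(pv$x), 305)
  expect_equal(pv$label, "combined")
  pv2 <- pooled_pairs(tab)
  expect_identical(pv, pv2)
  # item-major order: first n pairs are the home item's
  home <- tab[tab$item == "home", ]
  expect_equal(pv$x[1:61], home$impaired)
  single <- ratings_table("p1", "home", 3, 5)
  expect_equal(length(pooled_pairs(single)$x), 1)
  expect_error(permutation_test_rho(pooled_pairs(single)$x,
                                    pooled_pairs(single)$y),
               "at least 2")
})
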