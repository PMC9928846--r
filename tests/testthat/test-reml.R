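test_that("with G = I the restricted likelihood depends only on the sum", {
  set.seed(2)
  y <- rnorm(3)
  X <- matrix(1, 3, 1)
  expect_equal(reml_loglik(y, X, diag(3), 0.7, 0.2),
               reml_loglik(y, X, diag(3), 0.2, 0.7))
})

test_that("reml_loglik equals a literal dense-algebra evaluation", {
  # fixed 5-individual toy problem
  y <- c(1.3, -0.2, 0.8, 2.1, -1.0)
  X <- cbind(1, c(0.5, -1, 0, 1, 2))
  G <- matrix(c(1.05, 0.50, 0.02, -0.01, 0.03,
                0.50, 0.98, 0.01, 0.02, -0.02,
                0.02, 0.01, 1.10, 0.25, 0.00,
                -0.01, 0.02, 0.25, 0.95, 0.04,
                0.03, -0.02, 0.00, 0.04, 1.02), 5, 5)
  for (th in list(c(0.5, 0.5), c(1.2, 0.1), c(0.05, 2))) {
    expect_equal(reml_loglik(y, X, G, th[1], th[2]),
                 oracle_loglik(y, X, G, th[1], th[2]),
                 tolerance = 1e-10)
  }
  expect_error(reml_loglik(y, X, G, -2, 0.01), "positive definite")
})

test_that("scaling y by 2 shifts the likelihood surface by a constant", {
  # implies the maximizer scales by 4 in both components with h2 unchanged
  d <- sim_dataset(10, 5, 300, 0.5, seed = 51)
  y <- d$phen$trait1
  X <- matrix(1, length(y), 1)
  grid <- expand.grid(sg = c(0.2, 0.5, 0.9), se = c(0.2, 0.5, 0.9))
  diffs <- apply(grid, 1, function(th)
    reml_loglik(2 * y, X, d$grm, 4 * th[1], 4 * th[2]) -
      reml_loglik(y, X, d$grm, th[1], th[2]))
  expect_lt(max(diffs) - min(diffs), 1e-8)
})

test_that("an identity GRM is rejected as non-identifiable", {
  set.seed(6)
  y <- rnorm(30)
  expect_error(fit_greml_univariate(y, NULL, diag(30)),
               "not separately identifiable")
})

test_that("eigen and dense fitting paths agree to 1e-8", {
  d <- sim_dataset(12, 5, 400, 0.5, seed = 61)
  y <- d$phen$trait1
  f1 <- fit_greml_univariate(y, NULL, d$grm, method = "eigen")
  f2 <- fit_greml_univariate(y, NULL, d$grm, method = "dense")
  expect_equal(f1$components, f2$components, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("estimates are invariant to individual reordering", {
  d <- sim_dataset(12, 5, 400, 0.5, seed = 62)
  y <- d$phen$trait1
  n <- length(y)
  f1 <- fit_greml_univariate(y, NULL, d$grm)
  set.seed(1); perm <- sample(n)
  G2 <- d$grm$values[perm, perm]
  f2 <- fit_greml_univariate(y[perm], NULL, G2)
  expect_equal(f1$components, f2$components, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("EM iterations never decrease the restricted likelihood", {
  d <- sim_dataset(10, 5, 300, 0.4, seed = 63)
  y <- d$phen$trait1
  lls <- sapply(1:6, function(k)
    fit_greml_univariate(y, NULL, d$grm,
                         control = greml_control(max_iterations = k,
                                                 em_warmup_iterations = k,
                                                 loglik_tolerance = 1e-12)
                         )$loglik)
  expect_true(all(diff(lls) >= -1e-9))
  # AI-accelerated fit reaches at least the EM-only likelihood
  ai <- fit_greml_univariate(y, NULL, d$grm)
  expect_gte(ai$loglik, max(lls) - 1e-6)
})

test_that("the fitted maximum matches a grid + golden-section search", {
  d <- sim_dataset(10, 5, 400, 0.5, seed = 64)
  y <- d$phen$trait1
  X <- matrix(1, length(y), 1)
  fit <- fit_greml_univariate(y, X, d$grm,
                              control = greml_control(loglik_tolerance =
                                                        1e-8))
  oracle <- oracle_grid_max(y, X, d$grm, n_grid = 60)
  expect_equal(fit$loglik, oracle$ll, tolerance = 1e-3)
  expect_gte(fit$loglik, oracle$ll - 1e-6)
})

test_that("greml() formula front end matches the low-level fitter", {
  d <- sim_dataset(10, 5, 300, 0.5, seed = 65)
  fit1 <- greml(trait1 ~ 1, data = d$phen, K = d$grm)
  fit2 <- fit_greml_univariate(d$phen$trait1, NULL, d$grm)
  expect_equal(fit1$components, fit2$components, tolerance = 1e-12)
  expect_s3_class(fit1, "greml")
  expect_equal(unname(logLik(fit1)[1]), fit1$loglik)
  expect_equal(dim(vcov(fit1)), c(2L, 2L))
  expect_length(residuals(fit1), d$cfg$n_families *
                  d$cfg$offspring_per_family)
})

test_that("records missing the trait are dropped before fitting", {
  d <- sim_dataset(12, 5, 300, 0.5, seed = 66)
  ph <- d$phen
  ph$trait1[1:4] <- NA
  expect_message(fit <- greml(trait1 ~ 1, data = ph, K = d$grm),
                 "incomplete")
  expect_equal(fit$n, nrow(ph) - 4)
})
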