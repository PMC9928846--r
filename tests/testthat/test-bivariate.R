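test_that("correlation helpers match direct arithmetic", {
  expect_equal(genetic_correlation(0, 1, 1), 0)
  expect_equal(genetic_correlation(4, 2, 8), 1)
  expect_equal(genetic_correlation(0.5, 1.25, 0.8), 0.5)
  expect_warning(genetic_correlation(5, 2, 8), "outside")
  expect_error(genetic_correlation(0.1, 0, 1), "positive")

  expect_equal(phenotypic_correlation(0, 0, 1, 1, 1, 1), 0)
  expect_equal(phenotypic_correlation(0.5, 0.5, 1, 1, 1, 1), 0.5)
  expect_equal(phenotypic_correlation(0.3, -0.3, 2, 1, 4, 2), 0)
  expect_error(phenotypic_correlation(0, 0, 0, 0, 1, 1), "positive")
})

test_that("a duplicated trait drives rG and rP to the boundary", {
  d <- sim_dataset(12, 5, 400, 0.5, seed = 71)
  y <- d$phen$trait1
  fit <- fit_greml_bivariate(y, y, K = d$grm)
  expect_equal(fit$components[["rG"]], 1, tolerance = 1e-3)
  expect_equal(fit$components[["rP"]], 1, tolerance = 1e-3)
  expect_true(fit$boundary)
})

test_that("swapping the traits maps the components and fixes rG, rP, logL", {
  d <- sim_dataset(12, 5, 400, c(0.5, 0.4), seed = 72, rg = 0.6, re = 0.3,
                   two = TRUE)
  f12 <- fit_greml_bivariate(d$phen$trait1, d$phen$trait2, K = d$grm)
  f21 <- fit_greml_bivariate(d$phen$trait2, d$phen$trait1, K = d$grm)
  expect_equal(f12$components[["V(G)_1"]], f21$components[["V(G)_2"]],
               tolerance = 1e-8)
  expect_equal(f12$components[["V(e)_1"]], f21$components[["V(e)_2"]],
               tolerance = 1e-8)
  expect_equal(f12$components[["rG"]], f21$components[["rG"]],
               tolerance = 1e-8)
  expect_equal(f12$components[["rP"]], f21$components[["rP"]],
               tolerance = 1e-8)
  expect_equal(f12$loglik, f21$loglik, tolerance = 1e-8)
})

test_that("rP equals the plug-in phenotypic correlation of the components", {
  d <- sim_dataset(12, 5, 400, c(0.5, 0.4), seed = 73, rg = 0.5, re = 0.2,
                   two = TRUE)
  fit <- fit_greml_bivariate(d$phen$trait1, d$phen$trait2, K = d$grm)
  th <- fit$theta
  expect_identical(fit$components[["rP"]],
                   phenotypic_correlation(th[2], th[5], th[1], th[4],
                                          th[3], th[6]))
  expect_identical(fit$components[["rG"]],
                   th[2] / sqrt(th[1] * th[3]))
})

test_that("bivariate eigen and dense paths agree to 1e-8", {
  d <- sim_dataset(8, 5, 300, c(0.5, 0.5), seed = 74, rg = 0.6, re = 0.3,
                   two = TRUE)
  f1 <- fit_greml_bivariate(d$phen$trait1, d$phen$trait2, K = d$grm,
                            method = "eigen")
  f2 <- fit_greml_bivariate(d$phen$trait1, d$phen$trait2, K = d$grm,
                            method = "dense")
  expect_equal(f1$components, f2$components, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("marginal variances from the joint fit match univariate fits", {
  d <- sim_dataset(25, 8, 600, c(0.5, 0.4), seed = 75, rg = 0.6, re = 0.3,
                   two = TRUE)
  joint <- fit_greml_bivariate(d$phen$trait1, d$phen$trait2, K = d$grm)
  u1 <- fit_greml_univariate(d$phen$trait1, NULL, d$grm)
  u2 <- fit_greml_univariate(d$phen$trait2, NULL, d$grm)
  vp1 <- u1$components[["V(p)"]]
  vp2 <- u2$components[["V(p)"]]
  expect_lt(abs(joint$components[["V(G)_1"]] - u1$components[["V(G)"]]),
            0.02 * vp1 + 1e-8)
  expect_lt(abs(joint$components[["V(G)_2"]] - u2$components[["V(G)"]]),
            0.02 * vp2 + 1e-8)
})

test_that("the fitted likelihood dominates the truth on simulated data", {
  d <- sim_dataset(20, 8, 600, c(0.5, 0.5), seed = 76, rg = 0.6, re = 0.3,
                   two = TRUE)
  fit <- fit_greml_bivariate(d$phen$trait1, d$phen$trait2, K = d$grm)
  # likelihood at the generating parameters, via the dense verification path
  vg <- 0.5; ve <- 0.5
  Sg_true <- matrix(c(vg, 0.6 * vg, 0.6 * vg, vg), 2)
  Se_true <- matrix(c(ve, 0.3 * ve, 0.3 * ve, ve), 2)
  n <- fit$n
  eg <- eigen(d$grm$values, symmetric = TRUE)
  ones <- crossprod(eg$vectors, matrix(1, n, 1))
  q_true <- snpgreml:::biv_quant_eigen(
    drop(crossprod(eg$vectors, d$phen$trait1)),
    drop(crossprod(eg$vectors, d$phen$trait2)),
    ones, ones, eg$values,
    snpgreml:::mats_to_theta(Sg_true, Se_true))
  expect_gte(fit$loglik, q_true$ll - 1e-6)
  # rG recovered within 3 reported SEs
  expect_lt(abs(fit$components[["rG"]] - 0.6), 3 * fit$se[["rG"]])
})

test_that("greml() dispatches two-column responses to the bivariate fitter", {
  d <- sim_dataset(12, 5, 300, c(0.5, 0.5), seed = 77, rg = 0.5, re = 0.2,
                   two = TRUE)
  fit <- greml(cbind(trait1, trait2) ~ 1, data = d$phen, K = d$grm)
  expect_equal(fit$kind, "bivariate")
  low <- fit_greml_bivariate(d$phen$trait1, d$phen$trait2, K = d$grm)
  expect_equal(fit$components, low$components, tolerance = 1e-12)
  expect_equal(dim(vcov(fit)), c(6L, 6L))
})
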