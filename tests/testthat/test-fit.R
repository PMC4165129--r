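test_that("the optimizer beats a dense grid around the reported optimum", {
  # single genotype, few fruits: profile the likelihood over mu on a grid
  # with the covariance parameters frozen at the fitted values
  des <- experiment_design("G", "G", plants_per_genotype = 8,
                           trusses_per_plant = 1, fruits_per_truss = 3,
                           observation_days = c(30, 33, 37, 40, 44, 47, 51,
                                                54, 58, 61, 65))
  par <- ripening_params(mu = c(42, 52), alpha = rbind(G = c(0, 0)),
                         sigma0 = matrix(0, 2, 2),
                         sigma = matrix(c(2, 0.5, 0.5, 2), 2))
  sim <- simulate_ripening_experiment(des, par, seed = 14)
  cens <- censor_dataset(sim$observations)
  fit <- fit_ripening_model(cens, model_spec(reference = "G",
                                             quad = quadrature_spec(9)),
                            restarts = 2, seed = 1, compute_se = FALSE)
  expect_true(fit$converged)
  step <- 0.05
  grid <- expand.grid(m1 = fit$params$mu[1] + seq(-1, 1, by = step),
                      m2 = fit$params$mu[2] + seq(-1, 1, by = step))
  ll_grid <- vapply(seq_len(nrow(grid)), function(i) {
    p <- ripening_params(mu = c(grid$m1[i], grid$m2[i]),
                         alpha = fit$params$alpha,
                         sigma0 = fit$params$sigma0,
                         sigma = fit$params$sigma)
    total_loglikelihood(cens, p, quadrature_spec(9))
  }, numeric(1))
  # no grid point beats the optimum, and the grid argmax is the optimum
  expect_gte(fit$loglik, max(ll_grid) - 1e-6)
  best <- grid[which.max(ll_grid), ]
  expect_lt(abs(best$m1 - fit$params$mu[1]), step + 1e-9)
  expect_lt(abs(best$m2 - fit$params$mu[2]), step + 1e-9)
})

test_that("shifting all observation days translates mu and nothing else", {
  ex <- toy_experiment(plants = 4, fruits_per_truss = 2, seed = 15)
  spec <- model_spec(reference = "WT", quad = quadrature_spec(5))
  fit <- fit_ripening_model(ex$cens, spec, restarts = 1, seed = 1,
                            compute_se = FALSE)
  shifted <- ex$cens
  for (v in c("L1", "R1", "L2", "R2")) shifted[[v]] <- shifted[[v]] + 10
  fit_sh <- fit_ripening_model(shifted, spec, restarts = 1, seed = 1,
                               compute_se = FALSE)
  # the likelihood is exactly translation-equivariant; the optimizer path
  # is not bit-identical, so comparisons allow its convergence tolerance
  expect_equal(fit_sh$params$mu, fit$params$mu + 10, tolerance = 1e-3)
  expect_lt(max(abs(fit_sh$params$alpha - fit$params$alpha)), 0.1)
  expect_lt(max(abs(fit_sh$params$sigma - fit$params$sigma)), 0.1)
})

test_that("fits are reproducible and report convergence honestly", {
  ex <- toy_experiment(plants = 4, fruits_per_truss = 2, seed = 16)
  spec <- model_spec(reference = "WT", quad = quadrature_spec(5))
  f1 <- fit_ripening_model(ex$cens, spec, restarts = 2, seed = 3)
  f2 <- fit_ripening_model(ex$cens, spec, restarts = 2, seed = 3)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
  expect_true(is.data.frame(f1$optimizer_trace))
  expect_equal(nrow(f1$optimizer_trace), 2)
})

test_that("non-identifiable genotype levels are rejected by name", {
  ex <- toy_experiment(plants = 4, fruits_per_truss = 2, seed = 18)
  spec <- model_spec(reference = "WT", genotypes = c("WT", "mut", "ghost"))
  expect_error(fit_ripening_model(ex$cens, spec), "ghost")
})

test_that("likelihood-ratio tests count parameters and protect against optimizer failure", {
  ex <- toy_experiment(plants = 6, fruits_per_truss = 2, trusses = 2,
                       seed = 19)
  quad <- quadrature_spec(5)
  full <- fit_ripening_model(ex$cens,
                             model_spec(reference = "WT",
                                        include_truss = TRUE, quad = quad),
                             restarts = 1, seed = 1, compute_se = FALSE)
  red <- fit_ripening_model(ex$cens,
                            model_spec(reference = "WT", quad = quad),
                            restarts = 1, seed = 1, compute_se = FALSE)
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 2)  # a 2-vector of truss effects
  expect_gte(lrt$statistic, 0)
  expect_gte(full$loglik, red$loglik - 0.02)  # monotone nested likelihoods

  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(likelihood_ratio_test(red, full), "not nested")
  # a reduced fit pretending to beat the full model signals failure
  red_fake <- red
  red_fake$loglik <- full$loglik + 5
  expect_error(likelihood_ratio_test(full, red_fake), "optimizer failure")
})

test_that("covariate selection keeps real effects and drops absent ones", {
  # strong fruit-position effect, no truss effect
  des <- experiment_design(c("WT", "mut"), "WT", plants_per_genotype = 8,
                           trusses_per_plant = 2, fruits_per_truss = 3,
                           observation_days = c(30, 33, 37, 40, 44, 47, 51,
                                                54, 58, 61, 65))
  par <- ripening_params(mu = c(42, 52),
                         alpha = rbind(WT = c(0, 0), mut = c(4, 3)),
                         gamma = rbind(`1` = c(0, 0), `2` = c(3, 3),
                                       `3` = c(6, 6)),
                         sigma0 = matrix(c(2, 0.5, 0.5, 2), 2),
                         sigma = matrix(c(1.5, 0.3, 0.3, 1.5), 2))
  # a 5%-level test drops the null truss term in most replicates while the
  # strong fruit effect is always retained
  truss_dropped <- logical(3)
  for (s in 1:3) {
    sim <- simulate_ripening_experiment(des, par, seed = 19 + s)
    cens <- censor_dataset(sim$observations)
    sel <- select_covariates(cens,
                             model_spec(reference = "WT",
                                        include_truss = TRUE,
                                        include_fruit = "categorical",
                                        quad = quadrature_spec(5)),
                             restarts = 1, seed = 1, compute_se = FALSE)
    truss_dropped[s] <- !sel$spec$include_truss
    expect_equal(sel$spec$include_fruit, "categorical")
    expect_named(sel$tests, c("truss", "fruit"))
    expect_lt(sel$tests$fruit$p_value, 0.05)
  }
  expect_gte(sum(truss_dropped), 2)

  # nothing to test: spec returned unchanged with an empty test list
  base <- model_spec(reference = "WT", quad = quadrature_spec(5))
  sel0 <- select_covariates(cens, base, restarts = 1, seed = 1,
                            compute_se = FALSE)
  expect_identical(sel0$spec, base)
  expect_length(sel0$tests, 0)
})

test_that("genotype summaries transform the fixed effects correctly", {
  ex <- toy_experiment(plants = 8, fruits_per_truss = 3, seed = 22)
  fit <- fit_ripening_model(ex$cens,
                            model_spec(reference = "WT",
                                       quad = quadrature_spec(5)),
                            restarts = 1, seed = 1)
  summ <- genotype_summary(fit)
  # wild-type row is exactly mu under reference coding
  expect_equal(summ$days_to_first_sign[summ$genotype == "WT"],
               fit$params$mu[1])
  expect_equal(summ$ripening_length[summ$genotype == "WT"],
               fit$params$mu[2] - fit$params$mu[1])
  expect_true(all(is.finite(summ$se_first_sign)))

  # with all genotype effects zeroed the rows coincide
  fit0 <- fit
  fit0$params$alpha[] <- 0
  summ0 <- genotype_summary(fit0)
  expect_equal(summ0$days_to_first_sign,
               rep(summ0$days_to_first_sign[1], nrow(summ0)))
  expect_equal(summ0$ripening_length,
               rep(summ0$ripening_length[1], nrow(summ0)))

  # mutant contrast close to the generative (+4, +3) => length diff -1
  delay <- summ$days_to_first_sign[summ$genotype == "mut"] -
    summ$days_to_first_sign[summ$genotype == "WT"]
  len_diff <- summ$ripening_length[summ$genotype == "mut"] -
    summ$ripening_length[summ$genotype == "WT"]
  # loose bounds: 4 plants per genotype leaves day-scale estimation noise
  # (precise recovery is exercised at the 30-plant scale elsewhere)
  expect_lt(abs(delay - 4), 3)
  expect_lt(abs(len_diff - (-1)), 3)
})
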