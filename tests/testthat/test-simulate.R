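test_that("simulation is deterministic under a fixed seed", {
  d <- default_design()
  p <- default_params()
  s1 <- simulate_ripening_experiment(d, p, seed = 11)
  s2 <- simulate_ripening_experiment(d, p, seed = 11)
  expect_identical(s1, s2)
  s3 <- simulate_ripening_experiment(d, p, seed = 12)
  expect_false(identical(s1$observations, s3$observations))

  q1 <- simulate_qpcr_dataset(3, c("a", "b", "r"), "r",
                              matrix(0, 3, 3), 2, 0.1, seed = 5)
  q2 <- simulate_qpcr_dataset(3, c("a", "b", "r"), "r",
                              matrix(0, 3, 3), 2, 0.1, seed = 5)
  expect_identical(q1, q2)

  e1 <- simulate_ethylene_trace(8, 50, 4, 2, 1, seed = 7)
  e2 <- simulate_ethylene_trace(8, 50, 4, 2, 1, seed = 7)
  expect_identical(e1, e2)
})

test_that("zero covariances give latent times equal to the linear predictor", {
  des <- experiment_design(c("WT", "mut"), "WT", plants_per_genotype = 2,
                           trusses_per_plant = 1, fruits_per_truss = 2,
                           observation_days = seq(30, 66, by = 1))
  par <- ripening_params(mu = c(40, 50),
                         alpha = rbind(WT = c(0, 0), mut = c(3, 4)),
                         sigma0 = matrix(0, 2, 2), sigma = matrix(0, 2, 2))
  sim <- simulate_ripening_experiment(des, par, seed = 1)
  lt <- sim$truth$latent_times
  pred <- ripetime:::fixed_effect_shift(par, lt$genotype, lt$truss, lt$fruit)
  expect_equal(lt$y1, pred[, 1])
  expect_equal(lt$y2, pred[, 2])
  # transitions fully determined: repeated simulation identical even across seeds
  sim2 <- simulate_ripening_experiment(des, par, seed = 99)
  expect_identical(sim$observations, sim2$observations)
})

test_that("empirical covariance of latent times matches sigma0 + sigma", {
  # 200 independent plants with one fruit each: Var(Y) = Sigma0 + Sigma
  des <- experiment_design("G", "G", plants_per_genotype = 200,
                           trusses_per_plant = 1, fruits_per_truss = 1,
                           observation_days = c(30, 60))
  s0 <- matrix(c(4, 1, 1, 4), 2)
  s <- matrix(c(2, 0.5, 0.5, 2), 2)
  par <- ripening_params(mu = c(40, 50), alpha = rbind(G = c(0, 0)),
                         sigma0 = s0, sigma = s)
  sim <- simulate_ripening_experiment(des, par, seed = 21)
  y <- cbind(sim$truth$latent_times$y1, sim$truth$latent_times$y2)
  tot <- s0 + s
  expect_equal(colMeans(y), c(40, 50), tolerance = 3 * sqrt(6 / 200) / 40)
  emp <- cov(y)
  n <- nrow(y)
  # SE of a normal covariance entry: sqrt((s_ii s_jj + s_ij^2) / (n - 1))
  for (i in 1:2) for (j in 1:2) {
    se <- sqrt((tot[i, i] * tot[j, j] + tot[i, j]^2) / (n - 1))
    expect_lt(abs(emp[i, j] - tot[i, j]), 3 * se)
  }
})

test_that("a daily schedule spanning the support bounds interval widths by 1", {
  des <- experiment_design("G", "G", plants_per_genotype = 30,
                           trusses_per_plant = 1, fruits_per_truss = 2,
                           observation_days = seq(20, 80, by = 1))
  par <- ripening_params(mu = c(42, 52), alpha = rbind(G = c(0, 0)),
                         sigma0 = matrix(c(3, 1, 1, 3), 2),
                         sigma = matrix(c(2, 0.5, 0.5, 2), 2))
  sim <- simulate_ripening_experiment(des, par, seed = 31)
  cens <- censor_dataset(sim$observations)
  expect_true(all(cens$R1 - cens$L1 <= 1))
  expect_true(all(cens$R2 - cens$L2 <= 1))
})

test_that("stage series are coherent and order-inverted draws are handled", {
  # strong negative cross-correlation provokes Y2 < Y1 draws
  par <- ripening_params(mu = c(45, 46), alpha = rbind(G = c(0, 0)),
                         sigma0 = matrix(0, 2, 2),
                         sigma = matrix(c(6, -5, -5, 6), 2))
  des <- experiment_design("G", "G", plants_per_genotype = 40,
                           trusses_per_plant = 1, fruits_per_truss = 2,
                           observation_days = seq(30, 64, by = 2))
  sim <- simulate_ripening_experiment(des, par, seed = 41)
  lt <- sim$truth$latent_times
  expect_true(all(lt$y2 >= lt$y1))
  expect_gte(sim$truth$n_clamped, 1)
  # every fruit's stage sequence non-decreasing
  key <- interaction(sim$observations$plant_id, sim$observations$truss,
                     sim$observations$fruit)
  for (part in split(sim$observations, key)) {
    st <- match(part$stage[order(part$obs_day)], RIPENING_STAGES)
    expect_true(all(diff(st) >= 0))
  }
})

test_that("invalid covariances and designs are rejected with clear messages", {
  expect_error(
    ripening_params(mu = c(1, 2), alpha = rbind(A = c(0, 0)),
                    sigma0 = matrix(c(1, 2, 2, 1), 2),
                    sigma = diag(2)),
    "sigma0"
  )
  expect_error(
    ripening_params(mu = c(1, 2), alpha = rbind(A = c(0, 0)),
                    sigma0 = diag(2), sigma = matrix(c(1, 0, 1, 1), 2)),
    "symmetric"
  )
  expect_error(experiment_design(c("A", "B"), "C", 2,
                                 observation_days = c(30, 40)),
               "reference")
  expect_error(experiment_design("A", "A", 2,
                                 observation_days = c(40, 30)),
               "increasing")
})

test_that("qPCR simulator obeys the Cq arithmetic of efficiency-based quantification", {
  # one doubling per cycle: log2 difference of 1 shifts Cq by exactly 1
  sim <- simulate_qpcr_dataset(2, "g", character(0),
                               matrix(c(0, 1), 2, 1), efficiency = 2,
                               noise_sd = 0, seed = 3)
  cq <- tapply(sim$wells$cq, sim$wells$sample, mean)
  expect_equal(unname(cq["S01"] - cq["S02"]), 1)

  # fold change 18 inverts exactly from noise-free Cq values
  sim <- simulate_qpcr_dataset(2, "g", character(0),
                               matrix(c(0, log2(18)), 2, 1), efficiency = 2,
                               noise_sd = 0, seed = 3)
  cq <- tapply(sim$wells$cq, sim$wells$sample, mean)
  expect_equal(unname(2^(cq["S01"] - cq["S02"])), 18)

  # replicate Cq noise has the requested spread (chi-square interval on SD)
  sim <- simulate_qpcr_dataset(1, "g", character(0), matrix(0, 1, 1),
                               efficiency = 2, noise_sd = 0.2, seed = 3,
                               n_replicates = 60)
  s <- sd(sim$wells$cq)
  df <- 59
  expect_gt(s, 0.2 * sqrt(qchisq(0.0015, df) / df))
  expect_lt(s, 0.2 * sqrt(qchisq(0.9985, df) / df))

  expect_error(simulate_qpcr_dataset(2, "g", character(0),
                                     matrix(0, 2, 1), efficiency = 1,
                                     noise_sd = 0, seed = 1),
               "no amplification")
})

test_that("ethylene simulator reproduces the steady-state mass balance", {
  m0 <- simulate_ethylene_trace(0, 50, 4, background = 7, noise_sd = 0.5,
                                seed = 5, duration = 12)
  n <- nrow(m0$trace)
  expect_lt(abs(mean(m0$trace$concentration) - 7), 3 * 0.5 / sqrt(n))

  m <- simulate_ethylene_trace(8, 50, 4, background = 2, noise_sd = 0,
                               seed = 5)
  expect_equal(mean(m$trace$concentration) - 2, 100)
  # round trip through the rate computation
  expect_equal(emission_rate(m)$value, 8)

  expect_error(simulate_ethylene_trace(8, 50, 0, seed = 1), "flow")
  expect_error(simulate_ethylene_trace(8, -1, 4, seed = 1), "weight")
})
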