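# Independent oracles used across tests. These deliberately avoid the code
# paths they check: rectangle probabilities by Monte Carlo draws of the
# bivariate normal itself, and the marginal likelihood by Monte Carlo over
# the plant random effect with exact per-fruit rectangle probabilities.

mc_rectangle_probability <- function(mean, cov, lower, upper, n = 1e6,
                                     seed = 1) {
  set.seed(seed)
  e <- eigen(cov, symmetric = TRUE)
  x <- matrix(rnorm(2 * n), n, 2) %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  x <- sweep(x, 2, mean, "+")
  inside <- x[, 1] >= lower[1] & x[, 1] <= upper[1] &
    x[, 2] >= lower[2] & x[, 2] <= upper[2]
  p <- mean(inside)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# log E_{Sigma0}[ prod_f P_Sigma(rect_f - shift_f - Z) ] by Monte Carlo
# over Z, with exact rectangle probabilities per draw.
mc_plant_loglik <- function(cens_plant, params, ndraw = 1e5, seed = 1) {
  set.seed(seed)
  s1 <- sqrt(params$sigma[1, 1])
  s2 <- sqrt(params$sigma[2, 2])
  rho <- params$sigma[1, 2] / (s1 * s2)
  e <- eigen(params$sigma0, symmetric = TRUE)
  z <- matrix(rnorm(2 * ndraw), ndraw, 2) %*%
    (sqrt(pmax(e$values, 0)) * t(e$vectors))
  shift <- ripetime:::fixed_effect_shift(params, cens_plant$genotype,
                                         cens_plant$truss, cens_plant$fruit)
  prod_p <- rep(1, ndraw)
  for (i in seq_len(nrow(cens_plant))) {
    a1 <- (cens_plant$L1[i] - shift[i, 1] - z[, 1]) / s1
    b1 <- (cens_plant$R1[i] - shift[i, 1] - z[, 1]) / s1
    a2 <- (cens_plant$L2[i] - shift[i, 2] - z[, 2]) / s2
    b2 <- (cens_plant$R2[i] - shift[i, 2] - z[, 2]) / s2
    prod_p <- prod_p * ripetime:::.rect_prob_cpp(a1, b1, a2, b2, rho)
  }
  m <- mean(prod_p)
  se_rel <- sd(prod_p) / sqrt(ndraw) / m
  # log(mean) is biased low by Var(mean)/(2 mean^2); correct to second order
  list(loglik = log(m) + se_rel^2 / 2, se_log = se_rel)
}

mc_total_loglik <- function(cens, params, ndraw = 1e5, seed = 1) {
  tot <- 0
  var_log <- 0
  for (pid in unique(cens$plant_id)) {
    r <- mc_plant_loglik(cens[cens$plant_id == pid, , drop = FALSE], params,
                         ndraw = ndraw,
                         seed = seed + match(pid, unique(cens$plant_id)))
    tot <- tot + r$loglik
    var_log <- var_log + r$se_log^2
  }
  list(loglik = tot, se_log = sqrt(var_log))
}

# small two-genotype experiment used by several fitting tests
toy_experiment <- function(plants = 4L, fruits_per_truss = 2L,
                           trusses = 1L, seed = 1,
                           alpha_mut = c(4, 3),
                           sigma0 = matrix(c(3, 1, 1, 3), 2),
                           sigma = matrix(c(2, 0.5, 0.5, 2), 2)) {
  des <- experiment_design(
    genotypes = c("WT", "mut"), reference = "WT",
    plants_per_genotype = c(ceiling(plants / 2), floor(plants / 2)),
    trusses_per_plant = trusses, fruits_per_truss = fruits_per_truss,
    observation_days = c(30, 33, 37, 40, 44, 47, 51, 54, 58, 61, 65)
  )
  par <- ripening_params(mu = c(42, 52),
                         alpha = rbind(WT = c(0, 0), mut = alpha_mut),
                         sigma0 = sigma0, sigma = sigma)
  sim <- simulate_ripening_experiment(des, par, seed = seed)
  list(design = des, params = par, sim = sim,
       cens = censor_dataset(sim$observations))
}
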