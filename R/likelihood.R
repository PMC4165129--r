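#' Gauss-Hermite quadrature specification
#'
#' Controls the fixed product Gauss-Hermite rule used to integrate the
#' plant random effect out of the likelihood. The bivariate random effect
#' is whitened through the (eigen) square root of its covariance, so
#' `nodes_per_dim^2` nodes cover the plane (fewer when the covariance is
#' singular: a rank-1 covariance needs a single line of nodes and a zero
#' covariance a single point).
#'
#' @param nodes_per_dim Number of nodes per dimension (>= 1); 15 by
#'   default, which on well-conditioned problems agrees with a 25-node rule
#'   to well below 1e-6 log-likelihood units.
#' @return Object of class `quadrature_spec`.
#' @export
quadrature_spec <- function(nodes_per_dim = 15L) {
  stopifnot(is.numeric(nodes_per_dim), nodes_per_dim >= 1L)
  structure(list(nodes_per_dim = as.integer(nodes_per_dim)),
            class = "quadrature_spec")
}

.gh_cache <- new.env(parent = emptyenv())
gh_1d <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

# Product Gauss-Hermite grid for E[f(Z)], Z ~ N2(0, sigma0), centred at the
# prior. Used when sigma0 is (near-)singular; the full-rank case uses the
# adaptive placement in quad_nodes() below.
# Returns offsets (K x 2) and log-weights with sum(exp(logw)) == 1.
gh_grid <- function(sigma0, nodes_per_dim) {
  e <- eigen(sigma0, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  keep <- which(lam > 1e-12 * max(lam, 1))
  if (length(keep) == 0L) {
    return(list(offsets = matrix(0, 1L, 2L), logw = 0))
  }
  gh <- gh_1d(nodes_per_dim)
  # E[g(Z)] = sum_k w_k / sqrt(pi) * g(sqrt(2) * sd * x_k) per kept dim
  if (length(keep) == 1L) {
    dirvec <- e$vectors[, keep] * sqrt(lam[keep])
    offsets <- sqrt(2) * outer(gh$x, dirvec)
    logw <- log(gh$w) - 0.5 * log(pi)
  } else {
    g <- expand.grid(i = seq_along(gh$x), j = seq_along(gh$x))
    xs <- cbind(gh$x[g$i], gh$x[g$j])
    croot <- e$vectors %*% (sqrt(lam) * diag(2L))
    offsets <- sqrt(2) * xs %*% t(croot)
    logw <- log(gh$w[g$i]) + log(gh$w[g$j]) - log(pi)
  }
  list(offsets = offsets, logw = logw)
}

#' Bivariate normal rectangle probability
#'
#' \eqn{P(X \in [l_1, u_1] \times [l_2, u_2])} for
#' \eqn{X \sim N_2(\mathrm{mean}, \mathrm{cov})}, computed by
#' inclusion-exclusion over four bivariate normal CDF evaluations (Genz's
#' algorithm, absolute accuracy ~5e-16) and clipped to \[0, 1\] to absorb
#' CDF round-off. Infinite bounds are allowed.
#'
#' @param mean Length-2 mean vector.
#' @param cov 2x2 positive-definite covariance.
#' @param lower,upper Length-2 bounds, `-Inf`/`Inf` allowed, with
#'   `lower <= upper` componentwise.
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' # orthant probability at rho = 0.5: 1/4 + asin(0.5) / (2 * pi) = 1/3
#' mvn_rectangle_probability(c(0, 0), matrix(c(1, .5, .5, 1), 2),
#'                           c(0, 0), c(Inf, Inf))
mvn_rectangle_probability <- function(mean, cov, lower, upper) {
  stopifnot(length(mean) == 2L, length(lower) == 2L, length(upper) == 2L)
  cov <- as.matrix(cov)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] <= 1e-12 * max(1, ev[1L])) {
    stop("`cov` must be positive definite", call. = FALSE)
  }
  if (any(lower > upper)) {
    stop("`lower` must be <= `upper` componentwise", call. = FALSE)
  }
  s <- sqrt(diag(cov))
  rho <- cov[1L, 2L] / (s[1L] * s[2L])
  std <- function(x, i) ifelse(is.finite(x), (x - mean[i]) / s[i], x)
  as.numeric(.rect_prob_cpp(std(lower[1L], 1L), std(upper[1L], 1L),
                            std(lower[2L], 2L), std(upper[2L], 2L), rho))
}

# Quadrature node placement for E_{Sigma0}[ prod_f P_f(Z) ] per plant.
#
# With a full-rank Sigma0 the integrand is the plant's posterior kernel,
# which narrows well below the prior as fruits accumulate, so prior-centred
# nodes waste resolution. Each plant's nodes are instead centred on a
# Gaussian proxy of its posterior (interval midpoints treated as Gaussian
# pseudo-observations with covariance Sigma), with the exact prior density
# restored through importance log-weights -- the rule stays a deterministic,
# parameter-smooth quadrature whatever the proxy. Near-singular Sigma0
# falls back to the prior-whitened product rule.
#
# Returns stacked plant-major nodes ((nplant*K) x 2), log-weights, and K.
quad_nodes <- function(mid_resid1, mid_resid2, plant_idx, nplant,
                       sigma0, sigma, nodes_per_dim,
                       informative = NULL) {
  ev <- eigen(sigma0, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] < 1e-10 * max(ev[1L], 1)) {
    grid <- gh_grid(sigma0, nodes_per_dim)
    K <- nrow(grid$offsets)
    return(list(nodes = grid$offsets[rep(seq_len(K), nplant), , drop = FALSE],
                logw = rep(grid$logw, nplant), K = K))
  }
  gh <- gh_1d(nodes_per_dim)
  K <- nodes_per_dim^2
  g <- expand.grid(i = seq_len(nodes_per_dim), j = seq_len(nodes_per_dim))
  x1 <- gh$x[g$i]
  x2 <- gh$x[g$j]
  wlog <- log(gh$w[g$i]) + log(gh$w[g$j]) + x1^2 + x2^2

  # only fruits with at least one finite bound inform the proxy posterior;
  # a plant with none keeps the prior itself as proxy (then the rule is the
  # plain prior-centred product rule, with unit total mass)
  if (is.null(informative)) informative <- rep(TRUE, length(mid_resid1))
  np <- tabulate(plant_idx[informative], nplant)
  sum_by <- function(x) {
    out <- numeric(nplant)
    s <- tapply(x[informative], plant_idx[informative], sum)
    out[as.integer(names(s))] <- as.numeric(s)
    out
  }
  yb1 <- ifelse(np > 0, sum_by(mid_resid1) / pmax(np, 1L), 0)
  yb2 <- ifelse(np > 0, sum_by(mid_resid2) / pmax(np, 1L), 0)
  np <- pmax(np, 1e-9)  # np = 0 plants: A ~ huge, W ~ 0, proxy = prior
  # A = Sigma0 + Sigma / n_p; W = Sigma0 A^{-1}
  a11 <- sigma0[1, 1] + sigma[1, 1] / np
  a12 <- sigma0[1, 2] + sigma[1, 2] / np
  a22 <- sigma0[2, 2] + sigma[2, 2] / np
  det_a <- a11 * a22 - a12^2
  w11 <- (sigma0[1, 1] * a22 - sigma0[1, 2] * a12) / det_a
  w12 <- (-sigma0[1, 1] * a12 + sigma0[1, 2] * a11) / det_a
  w21 <- (sigma0[1, 2] * a22 - sigma0[2, 2] * a12) / det_a
  w22 <- (-sigma0[1, 2] * a12 + sigma0[2, 2] * a11) / det_a
  m1 <- w11 * yb1 + w12 * yb2
  m2 <- w21 * yb1 + w22 * yb2
  # proxy posterior covariance V = Sigma0 - W Sigma0, Cholesky per plant
  v11 <- pmax(sigma0[1, 1] - (w11 * sigma0[1, 1] + w12 * sigma0[1, 2]),
              1e-12)
  v12 <- sigma0[1, 2] - (w11 * sigma0[1, 2] + w12 * sigma0[2, 2])
  v22 <- sigma0[2, 2] - (w21 * sigma0[1, 2] + w22 * sigma0[2, 2])
  l11 <- sqrt(v11)
  l21 <- v12 / l11
  l22 <- sqrt(pmax(v22 - l21^2, 1e-12))

  ip <- rep(seq_len(nplant), each = K)
  ik <- rep(seq_len(K), nplant)
  s2rt <- sqrt(2)
  z1 <- m1[ip] + s2rt * l11[ip] * x1[ik]
  z2 <- m2[ip] + s2rt * (l21[ip] * x1[ik] + l22[ip] * x2[ik])
  # prior density of Sigma0 at the nodes
  det0 <- sigma0[1, 1] * sigma0[2, 2] - sigma0[1, 2]^2
  i11 <- sigma0[2, 2] / det0
  i12 <- -sigma0[1, 2] / det0
  i22 <- sigma0[1, 1] / det0
  log_prior <- -log(2 * pi) - 0.5 * log(det0) -
    0.5 * (i11 * z1^2 + 2 * i12 * z1 * z2 + i22 * z2^2)
  logw <- log(2) + log(l11[ip]) + log(l22[ip]) + wlog[ik] + log_prior
  list(nodes = cbind(z1, z2), logw = logw, K = K)
}

# interval-midpoint residual used to centre a plant's quadrature; an
# uninformative (doubly infinite) interval contributes a zero residual
mid_residual <- function(L, R, shift) {
  ifelse(!is.finite(L) & !is.finite(R), 0,
         interval_midpoints(L, R) - shift)
}

# shared worker: marginal log-likelihood given a censored table
loglik_internal <- function(cens, params, quad, warn_zero = TRUE) {
  req <- c("plant_id", "genotype", "truss", "fruit", "L1", "R1", "L2", "R2")
  if (!all(req %in% names(cens))) {
    stop("censored data must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cens) == 0L) stop("censored dataset is empty", call. = FALSE)
  check_cov(params$sigma, "sigma", definite = TRUE)
  ord <- order(cens$plant_id)
  cens <- cens[ord, , drop = FALSE]
  plant_f <- factor(cens$plant_id, levels = unique(cens$plant_id))
  shift <- fixed_effect_shift(params, cens$genotype, cens$truss, cens$fruit)
  s1 <- sqrt(params$sigma[1L, 1L])
  s2 <- sqrt(params$sigma[2L, 2L])
  rho <- params$sigma[1L, 2L] / (s1 * s2)
  qn <- quad_nodes(mid_residual(cens$L1, cens$R1, shift[, 1L]),
                   mid_residual(cens$L2, cens$R2, shift[, 2L]),
                   as.integer(plant_f), nlevels(plant_f),
                   params$sigma0, params$sigma, quad$nodes_per_dim,
                   informative = is.finite(cens$L1) | is.finite(cens$R1) |
                     is.finite(cens$L2) | is.finite(cens$R2))
  res <- .total_loglik_cpp(cens$L1, cens$R1, cens$L2, cens$R2,
                           shift[, 1L], shift[, 2L],
                           as.integer(plant_f), nlevels(plant_f),
                           qn$nodes, qn$logw, qn$K, s1, s2, rho)
  if (warn_zero && any(!is.finite(res$per_plant))) {
    warning(sprintf("likelihood is exactly zero for plant(s) %s",
                    paste(levels(plant_f)[!is.finite(res$per_plant)],
                          collapse = ", ")), call. = FALSE)
  }
  names(res$per_plant) <- levels(plant_f)
  res
}

#' Marginal log-likelihood contribution of one plant
#'
#' Evaluates \eqn{\log E_{\Sigma_0}[\prod_{b,f} P_\Sigma(Y_{pbf} \in
#' [L,R]\times[L,R])]} for the fruits of a single plant: the product over
#' fruits of the rectangle probability of the censoring rectangle shifted
#' by the fixed effects and the random-effect node, averaged over the
#' Gauss-Hermite nodes on the log scale (log-sum-exp, so products of many
#' small probabilities do not underflow).
#'
#' @param fruits_of_plant Censored data frame (see [censor_dataset()]) whose
#'   rows all share one `plant_id`.
#' @param params A [ripening_params()] object.
#' @param quad A [quadrature_spec()].
#' @return The log-likelihood contribution (may be `-Inf`, with a warning
#'   naming the plant, if every node gives an exactly-zero product).
#' @export
plant_loglikelihood <- function(fruits_of_plant, params,
                                quad = quadrature_spec()) {
  if (length(unique(fruits_of_plant$plant_id)) != 1L) {
    stop("all fruits must share one plant_id", call. = FALSE)
  }
  loglik_internal(fruits_of_plant, params, quad)$total
}

#' Total marginal log-likelihood of a censored dataset
#'
#' Sum of [plant_loglikelihood()] over the plants of the dataset (the
#' plant random effect makes plants, not fruits, the independent units).
#'
#' @param cens Censored data frame from [censor_dataset()] (any number of
#'   plants).
#' @inheritParams plant_loglikelihood
#' @return The total log-likelihood.
#' @export
total_loglikelihood <- function(cens, params, quad = quadrature_spec()) {
  loglik_internal(cens, params, quad)$total
}
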