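#' Model specification for fitting
#'
#' Declares which fixed-effect terms enter the bivariate ripening model.
#' Genotype is always included (it is the quantity of interest) and the
#' plant random effect is structural and never dropped; the truss and
#' fruit-position covariates are optional.
#'
#' @param reference Wild-type genotype label (reference level of the
#'   genotype coding). If `NULL`, the first genotype in sorted order of the
#'   data is used.
#' @param genotypes Optional explicit genotype level list (reference
#'   first); defaults to the levels present in the data.
#' @param include_truss Logical: include a categorical truss effect.
#' @param include_fruit `"none"`, `"categorical"` or `"linear"`
#'   fruit-position effect.
#' @param quad A [quadrature_spec()].
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(reference = NULL, genotypes = NULL,
                       include_truss = FALSE,
                       include_fruit = c("none", "categorical", "linear"),
                       quad = quadrature_spec()) {
  include_fruit <- match.arg(include_fruit)
  if (!is.null(genotypes) && !is.null(reference) &&
      !(reference %in% genotypes)) {
    stop("reference genotype must be among `genotypes`", call. = FALSE)
  }
  structure(list(reference = reference, genotypes = genotypes,
                 include_truss = isTRUE(include_truss),
                 include_fruit = include_fruit, quad = quad),
            class = "model_spec")
}

# Fixed-effect design matrix (treatment coding) + bookkeeping
build_design <- function(cens, spec) {
  glev <- spec$genotypes
  if (is.null(glev)) {
    glev <- sort(unique(as.character(cens$genotype)))
    ref <- spec$reference %||% glev[1L]
    if (!(ref %in% glev)) {
      stop(sprintf("reference genotype '%s' not present in data", ref),
           call. = FALSE)
    }
    glev <- c(ref, setdiff(glev, ref))
  } else {
    ref <- spec$reference %||% glev[1L]
    glev <- c(ref, setdiff(glev, ref))
    absent <- setdiff(glev, unique(as.character(cens$genotype)))
    if (length(absent)) {
      stop(sprintf("genotype level '%s' is not identifiable (never observed)",
                   absent[1L]), call. = FALSE)
    }
  }
  g <- factor(as.character(cens$genotype), levels = glev)
  if (anyNA(g)) {
    stop(sprintf("unknown genotype level '%s'",
                 as.character(cens$genotype)[which(is.na(g))[1L]]),
         call. = FALSE)
  }
  X <- if (nlevels(g) > 1L) stats::model.matrix(~g)
       else matrix(1, nrow(cens), 1L)
  cols <- list(list(term = "mu", level = NA_character_))
  if (nlevels(g) > 1L) {
    for (l in glev[-1L]) cols <- c(cols, list(list(term = "genotype",
                                                   level = l)))
  }
  if (spec$include_truss) {
    tl <- sort(unique(as.numeric(cens$truss)))
    if (length(tl) < 2L) {
      stop("truss effect requested but only one truss level observed",
           call. = FALSE)
    }
    tf <- factor(as.numeric(cens$truss), levels = tl)
    X <- cbind(X, stats::model.matrix(~tf)[, -1L, drop = FALSE])
    for (l in tl[-1L]) cols <- c(cols, list(list(term = "truss",
                                                 level = as.character(l))))
  }
  if (spec$include_fruit == "categorical") {
    fl <- sort(unique(as.numeric(cens$fruit)))
    if (length(fl) < 2L) {
      stop("fruit effect requested but only one fruit position observed",
           call. = FALSE)
    }
    ff <- factor(as.numeric(cens$fruit), levels = fl)
    X <- cbind(X, stats::model.matrix(~ff)[, -1L, drop = FALSE])
    for (l in fl[-1L]) cols <- c(cols, list(list(term = "fruit",
                                                 level = as.character(l))))
  } else if (spec$include_fruit == "linear") {
    X <- cbind(X, fruit_lin = as.numeric(cens$fruit) - 1)
    cols <- c(cols, list(list(term = "fruit", level = "linear")))
  }
  dimnames(X) <- NULL
  list(X = X, cols = cols, genotypes = glev,
       truss_levels = sort(unique(as.numeric(cens$truss))),
       fruit_levels = sort(unique(as.numeric(cens$fruit))))
}

# log-Cholesky <-> covariance: L = [[exp(t1), 0], [t2, exp(t3)]], C = L L'
chol_to_cov <- function(t3) {
  l11 <- exp(t3[1L]); l21 <- t3[2L]; l22 <- exp(t3[3L])
  matrix(c(l11^2, l11 * l21, l11 * l21, l21^2 + l22^2), 2L)
}
cov_to_chol <- function(C, floor = 1e-6) {
  C <- C + diag(2L) * 0
  l11 <- sqrt(max(C[1L, 1L], floor))
  l21 <- C[1L, 2L] / l11
  rest <- C[2L, 2L] - l21^2
  l22 <- sqrt(max(rest, floor))
  c(log(l11), l21, log(l22))
}

# interval midpoints used for starting values and quadrature centring;
# censoring-aware heuristic (half a typical twice-weekly observation gap
# beyond the finite bound, 0 for an uninformative interval)
interval_midpoints <- function(L, R) {
  half <- 3.5
  out <- numeric(length(L))
  both <- is.finite(L) & is.finite(R)
  out[both] <- ifelse(R[both] - L[both] <= 4 * half,
                      (L[both] + R[both]) / 2, R[both] - half)
  out[is.finite(L) & !is.finite(R)] <- L[is.finite(L) & !is.finite(R)] + half
  out[!is.finite(L) & is.finite(R)] <- R[!is.finite(L) & is.finite(R)] - half
  out
}

#' Maximum-likelihood fit of the bivariate ripening model
#'
#' Maximizes the Gauss-Hermite marginal likelihood over the fixed effects
#' and the two covariance matrices. \eqn{\Sigma} and \eqn{\Sigma_0} are
#' parameterized by log-Cholesky factors, so \eqn{\Sigma} stays positive
#' definite and \eqn{\Sigma_0} may approach the positive-semidefinite
#' boundary. Optimization uses a quasi-Newton method (PORT `nlminb`) on the
#' unconstrained parameter vector from a midpoint-regression start, with
#' optional jittered restarts; the best run is returned. Identical data,
#' options and seed give an identical fit.
#'
#' @param cens Censored dataset from [censor_dataset()].
#' @param spec A [model_spec()].
#' @param restarts Number of optimizer runs (first from the deterministic
#'   start, the rest jittered).
#' @param seed Integer seed controlling the jitter.
#' @param control Passed to [nlminb()]; defaults to
#'   `list(rel.tol = 1e-8, iter.max = 500, eval.max = 4000)`.
#' @param compute_se Compute delta-method standard errors from the observed
#'   information (numerical Hessian at the optimum)?
#' @return Object of class `ripening_fit` with elements `params`
#'   (a [ripening_params()]), `loglik`, `n_free_params`, `converged`,
#'   `stderr_fixed` (matrix like the fixed-effect layout, or `NULL`),
#'   `vcov_fixed`, `spec`, `optimizer_trace` and `seed`.
#' @export
fit_ripening_model <- function(cens, spec = model_spec(), restarts = 3L,
                               seed = 1L, control = list(),
                               compute_se = TRUE) {
  des <- build_design(cens, spec)
  k <- ncol(des$X)
  n_theta <- 2L * k + 6L
  ctrl <- utils::modifyList(list(rel.tol = 1e-8, iter.max = 500L,
                                 eval.max = 4000L), control)

  ord <- order(cens$plant_id)
  cens_o <- cens[ord, , drop = FALSE]
  X <- des$X[ord, , drop = FALSE]
  plant_f <- factor(cens_o$plant_id, levels = unique(cens_o$plant_id))
  nplant <- nlevels(plant_f)
  nodes <- spec$quad$nodes_per_dim

  mid <- cbind(interval_midpoints(cens_o$L1, cens_o$R1),
               interval_midpoints(cens_o$L2, cens_o$R2))
  plant_i <- as.integer(plant_f)
  informative <- is.finite(cens_o$L1) | is.finite(cens_o$R1) |
    is.finite(cens_o$L2) | is.finite(cens_o$R2)

  negll <- function(theta) {
    B <- matrix(theta[seq_len(2L * k)], k, 2L)
    sig <- chol_to_cov(theta[2L * k + 1:3])
    sig0 <- chol_to_cov(theta[2L * k + 4:6])
    shift <- X %*% B
    s1 <- sqrt(sig[1L, 1L]); s2 <- sqrt(sig[2L, 2L])
    rho <- sig[1L, 2L] / (s1 * s2)
    if (!is.finite(rho) || abs(rho) >= 1) return(1e10)
    qn <- quad_nodes(mid_residual(cens_o$L1, cens_o$R1, shift[, 1L]),
                     mid_residual(cens_o$L2, cens_o$R2, shift[, 2L]),
                     plant_i, nplant, sig0, sig, nodes,
                     informative = informative)
    res <- .total_loglik_cpp(cens_o$L1, cens_o$R1, cens_o$L2, cens_o$R2,
                             shift[, 1L], shift[, 2L], plant_i, nplant,
                             qn$nodes, qn$logw, qn$K, s1, s2, rho)
    if (!is.finite(res$total)) return(1e10)
    -res$total
  }

  # starting values: regress interval midpoints on the design
  B0 <- tryCatch(qr.solve(X, mid), error = function(e) {
    rbind(colMeans(mid), matrix(0, k - 1L, 2L))
  })
  E <- mid - X %*% B0
  S <- cov(E)
  S <- S / 2 + diag(2L) * 0.25  # split between plant and residual, keep PD
  theta0 <- c(as.vector(B0), cov_to_chol(S), cov_to_chol(S))

  # box constraints: fixed effects free; log-Cholesky diagonals bounded so
  # the residual SD stays above ~0.01 day (and below e^6) while the plant
  # covariance may sink to an effective zero at the PSD boundary
  lower <- c(rep(-Inf, 2L * k), c(-4.5, -Inf, -4.5), c(-12, -Inf, -12))
  upper <- c(rep(Inf, 2L * k), rep(c(6, Inf, 6), 2L))
  runs <- vector("list", max(1L, restarts))
  for (r in seq_along(runs)) {
    th <- theta0
    if (r > 1L) {
      th <- with_seed(seed + r, theta0 + c(rnorm(2L * k, 0, 0.5),
                                           rnorm(6L, 0, 0.15)))
    }
    runs[[r]] <- nlminb(th, negll, lower = lower, upper = upper,
                        control = ctrl)
  }
  objs <- vapply(runs, function(x) x$objective, numeric(1))
  best <- runs[[which.min(objs)]]
  converged <- best$convergence == 0L && is.finite(best$objective)

  theta_hat <- best$par
  B_hat <- matrix(theta_hat[seq_len(2L * k)], k, 2L)
  sig_hat <- chol_to_cov(theta_hat[2L * k + 1:3])
  sig0_hat <- chol_to_cov(theta_hat[2L * k + 4:6])
  params_hat <- design_to_params(B_hat, sig0_hat, sig_hat, des, spec)

  stderr_fixed <- NULL
  vcov_fixed <- NULL
  se_flag <- NA
  if (compute_se) {
    H <- tryCatch(optimHess(theta_hat, negll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V)[seq_len(2L * k)] > 0)) {
      vcov_fixed <- V[seq_len(2L * k), seq_len(2L * k), drop = FALSE]
      stderr_fixed <- matrix(sqrt(diag(vcov_fixed)), k, 2L)
      se_flag <- FALSE
    } else {
      se_flag <- TRUE  # singular observed information
    }
  }

  structure(list(
    params = params_hat, loglik = -best$objective,
    n_free_params = n_theta, converged = converged,
    stderr_fixed = stderr_fixed, vcov_fixed = vcov_fixed,
    information_singular = se_flag,
    design = des, spec = spec, seed = seed,
    n_fruits = nrow(cens_o), n_plants = nplant,
    optimizer_trace = data.frame(
      restart = seq_along(runs),
      objective = objs,
      iterations = vapply(runs, function(x) x$iterations, numeric(1)),
      convergence = vapply(runs, function(x) x$convergence, numeric(1)),
      message = vapply(runs, function(x) x$message %||% "", character(1))
    )
  ), class = "ripening_fit")
}

# fold the estimated coefficient matrix back into a ripening_params object
design_to_params <- function(B, sigma0, sigma, des, spec) {
  terms <- vapply(des$cols, `[[`, character(1), "term")
  levels_ <- vapply(des$cols, function(c) as.character(c$level), character(1))
  mu <- B[1L, ]
  alpha <- matrix(0, length(des$genotypes), 2L,
                  dimnames = list(des$genotypes, NULL))
  gi <- which(terms == "genotype")
  if (length(gi)) alpha[levels_[gi], ] <- B[gi, , drop = FALSE]
  beta <- NULL
  ti <- which(terms == "truss")
  if (length(ti)) {
    beta <- matrix(0, length(des$truss_levels), 2L,
                   dimnames = list(as.character(des$truss_levels), NULL))
    beta[levels_[ti], ] <- B[ti, , drop = FALSE]
  }
  gamma <- NULL
  fi <- which(terms == "fruit")
  if (length(fi)) {
    if (identical(levels_[fi], "linear")) {
      gamma <- as.numeric(B[fi, ])
    } else {
      gamma <- matrix(0, length(des$fruit_levels), 2L,
                      dimnames = list(as.character(des$fruit_levels), NULL))
      gamma[levels_[fi], ] <- B[fi, , drop = FALSE]
    }
  }
  ripening_params(mu = mu, alpha = alpha, beta = beta, gamma = gamma,
                  sigma0 = sigma0, sigma = sigma)
}

#' @export
print.ripening_fit <- function(x, ...) {
  cat("Interval-censored bivariate ripening model fit\n")
  cat(sprintf("  %d fruits on %d plants; %d free parameters; log-likelihood %.3f\n",
              x$n_fruits, x$n_plants, x$n_free_params, x$loglik))
  cat(sprintf("  converged: %s\n", x$converged))
  print(x$params)
  invisible(x)
}

#' @export
logLik.ripening_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_params, class = "logLik")
}

#' Likelihood-ratio test between nested ripening-model fits
#'
#' The statistic \eqn{2(\ell_{full} - \ell_{reduced})} is referred to the
#' asymptotic \eqn{\chi^2} distribution whose degrees of freedom equal the
#' difference in free-parameter counts. Small negative statistics (within
#' optimizer tolerance) are clamped to zero; larger ones signal optimizer
#' failure and raise an error.
#'
#' @param full,reduced `ripening_fit` objects; `reduced` must be nested in
#'   `full` (term set a subset, fewer free parameters) and both converged.
#' @param tol Clamp tolerance for slightly negative statistics.
#' @return Object of class `ripening_lrt` with `statistic`, `df`,
#'   `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced, tol = 0.02) {
  stopifnot(inherits(full, "ripening_fit"), inherits(reduced, "ripening_fit"))
  if (!full$converged || !reduced$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  terms_of <- function(f) {
    vapply(f$design$cols, function(c) paste(c$term, c$level), character(1))
  }
  if (!all(terms_of(reduced) %in% terms_of(full)) ||
      reduced$n_free_params > full$n_free_params) {
    stop("`reduced` is not nested in `full`", call. = FALSE)
  }
  df <- full$n_free_params - reduced$n_free_params
  if (df < 1L) {
    # identical model specs: statistic 0 by convention
    df <- 0L
  }
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -tol) {
    stop(sprintf(paste0("full-model log-likelihood is below the reduced ",
                        "model's by %.4f: optimizer failure"), -stat / 2),
         call. = FALSE)
  }
  stat <- max(stat, 0)
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p),
            class = "ripening_lrt")
}

#' @export
print.ripening_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chi2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Backward covariate selection by likelihood-ratio testing
#'
#' Fits the full specification, then tests dropping the truss and the
#' fruit-position terms in turn against it; terms whose drop is not
#' significant at level `alpha` are removed, and the retained model is
#' refitted. The plant random effect and the genotype term are structural
#' and never dropped.
#'
#' @param cens Censored dataset.
#' @param base_spec Full [model_spec()] (its `include_*` flags define which
#'   terms are candidates).
#' @param alpha Significance level for retaining a term.
#' @param ... Passed to [fit_ripening_model()].
#' @return List with `spec` (retained specification), `tests` (named list
#'   of `ripening_lrt`), and `fit` (fit under the retained spec).
#' @export
select_covariates <- function(cens, base_spec, alpha = 0.05, ...) {
  full_fit <- fit_ripening_model(cens, base_spec, ...)
  tests <- list()
  keep_truss <- base_spec$include_truss
  keep_fruit <- base_spec$include_fruit != "none"
  if (base_spec$include_truss) {
    red_spec <- base_spec
    red_spec$include_truss <- FALSE
    red_fit <- fit_ripening_model(cens, red_spec, ...)
    tests$truss <- likelihood_ratio_test(full_fit, red_fit)
    keep_truss <- tests$truss$p_value < alpha
  }
  if (base_spec$include_fruit != "none") {
    red_spec <- base_spec
    red_spec$include_fruit <- "none"
    red_fit <- fit_ripening_model(cens, red_spec, ...)
    tests$fruit <- likelihood_ratio_test(full_fit, red_fit)
    keep_fruit <- tests$fruit$p_value < alpha
  }
  final_spec <- base_spec
  final_spec$include_truss <- keep_truss
  final_spec$include_fruit <- if (keep_fruit) base_spec$include_fruit else "none"
  final_fit <- if (keep_truss == base_spec$include_truss &&
                   keep_fruit == (base_spec$include_fruit != "none")) {
    full_fit
  } else {
    fit_ripening_model(cens, final_spec, ...)
  }
  list(spec = final_spec, tests = tests, fit = final_fit)
}

#' Per-genotype ripening-time summary
#'
#' Transforms the fitted fixed effects into the two reported quantities per
#' genotype: the estimated days from anthesis to the first ripening sign,
#' \eqn{\mu^{(1)} + \alpha^{(1)}_g}, and the estimated length of the
#' climacteric ripening phase,
#' \eqn{(\mu^{(2)} + \alpha^{(2)}_g) - (\mu^{(1)} + \alpha^{(1)}_g)}.
#' Uncertainties are delta-method standard errors from the observed
#' information (the transforms are linear, so the delta method is exact
#' given the information matrix). When `cens` is supplied, each mutant is
#' compared to the wild type by a likelihood-ratio test of dropping its
#' genotype effect (2 df), starred at 0.05 / 0.01 / 0.001.
#'
#' @param fit A converged `ripening_fit`.
#' @param cens Optional censored dataset enabling the per-genotype LRTs.
#' @param ... Passed to the refits behind the LRTs.
#' @return Data frame of class `genotype_summary` with columns `genotype`,
#'   `days_to_first_sign`, `se_first_sign`, `ripening_length`, `se_length`,
#'   `p_vs_reference`, `signif`. If the observed information was singular,
#'   the SE columns are `NA` and the result carries
#'   `attr(, "information_singular") = TRUE`.
#' @export
genotype_summary <- function(fit, cens = NULL, ...) {
  stopifnot(inherits(fit, "ripening_fit"))
  if (!fit$converged) stop("fit has not converged", call. = FALSE)
  des <- fit$design
  k <- length(des$cols)
  terms <- vapply(des$cols, `[[`, character(1), "term")
  levels_ <- vapply(des$cols, function(c) as.character(c$level), character(1))
  glev <- des$genotypes
  p <- fit$params
  out <- data.frame(genotype = glev,
                    days_to_first_sign = NA_real_, se_first_sign = NA_real_,
                    ripening_length = NA_real_, se_length = NA_real_,
                    p_vs_reference = NA_real_, signif = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(glev)) {
    a <- p$alpha[glev[i], ]
    out$days_to_first_sign[i] <- p$mu[1L] + a[1L]
    out$ripening_length[i] <- (p$mu[2L] + a[2L]) - (p$mu[1L] + a[1L])
    if (!is.null(fit$vcov_fixed)) {
      # contrast vectors over vec(B) = (column 1, column 2)
      c1 <- numeric(2L * k); c2 <- numeric(2L * k)
      rows <- c(1L, if (i > 1L) which(terms == "genotype" &
                                        levels_ == glev[i]))
      c1[rows] <- 1                      # first-sign time, event-1 block
      c2[rows + k] <- 1; c2[rows] <- -1  # length = event2 - event1
      out$se_first_sign[i] <- sqrt(drop(t(c1) %*% fit$vcov_fixed %*% c1))
      out$se_length[i] <- sqrt(drop(t(c2) %*% fit$vcov_fixed %*% c2))
    }
  }
  if (!is.null(cens)) {
    for (i in seq_along(glev)[-1L]) {
      cens2 <- cens
      cens2$genotype <- as.character(cens2$genotype)
      cens2$genotype[cens2$genotype == glev[i]] <- glev[1L]
      spec2 <- fit$spec
      spec2$genotypes <- NULL
      spec2$reference <- glev[1L]
      red <- fit_ripening_model(cens2, spec2, ...)
      lrt <- likelihood_ratio_test(fit, red)
      out$p_vs_reference[i] <- lrt$p_value
      out$signif[i] <- stars(lrt$p_value)
    }
  }
  structure(out, class = c("genotype_summary", "data.frame"),
            information_singular = isTRUE(fit$information_singular))
}

stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}
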