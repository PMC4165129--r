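#' Parameters of the bivariate ripening-time model
#'
#' Bundles the fixed effects and covariance matrices of the model
#' \deqn{Y_{pbf} = \mu + \alpha_{m(p)} + \beta_b + \gamma_f + Z_p + U_{pbf},}
#' where \eqn{Y_{pbf} = (Y^{(1)}, Y^{(2)})} are the days from anthesis to the
#' first ripening sign and to the red stage for fruit \eqn{f} on truss
#' \eqn{b} of plant \eqn{p}, \eqn{m(p)} is the plant's genotype,
#' \eqn{Z_p \sim N_2(0, \Sigma_0)} is a plant random effect and
#' \eqn{U_{pbf} \sim N_2(0, \Sigma)} is the fruit-level residual.
#'
#' Fixed effects use reference (treatment) coding: the first row of
#' `alpha`, `beta` and `gamma` corresponds to the reference level (wild
#' type, truss 1, fruit position 1) and must be zero.
#'
#' @param mu Numeric length-2: baseline days to the two events for the
#'   reference genotype.
#' @param alpha Matrix with one row per genotype (2 columns); row names are
#'   the genotype labels, the first row is the reference and must be zero.
#' @param beta Optional truss-effect matrix (rows = truss positions 1..B),
#'   first row zero, or `NULL` for no truss effect.
#' @param gamma Optional fruit-position effect: either a matrix (rows =
#'   positions 1..F, first row zero, categorical coding) or a numeric
#'   length-2 slope applied as `(position - 1) * gamma` (linear coding), or
#'   `NULL`.
#' @param sigma0 2x2 symmetric positive semidefinite covariance of the
#'   plant random effect.
#' @param sigma 2x2 symmetric positive definite residual covariance.
#'
#' @return An object of class `ripening_params`.
#' @export
#' @examples
#' ripening_params(
#'   mu = c(42, 52),
#'   alpha = rbind(WT = c(0, 0), mut = c(4, 3)),
#'   sigma0 = matrix(c(3, 1, 1, 3), 2),
#'   sigma = matrix(c(2, 0.5, 0.5, 2), 2)
#' )
ripening_params <- function(mu, alpha, beta = NULL, gamma = NULL,
                            sigma0, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 2L)
  alpha <- as.matrix(alpha)
  if (ncol(alpha) != 2L || is.null(rownames(alpha))) {
    stop("`alpha` must be a 2-column matrix with genotype row names",
         call. = FALSE)
  }
  if (any(alpha[1L, ] != 0)) {
    stop("the reference genotype (first row of `alpha`) must be zero",
         call. = FALSE)
  }
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    stopifnot(ncol(beta) == 2L)
    if (any(beta[1L, ] != 0)) {
      stop("the first truss level (first row of `beta`) must be zero",
           call. = FALSE)
    }
    if (is.null(rownames(beta))) rownames(beta) <- seq_len(nrow(beta))
  }
  gamma_linear <- FALSE
  if (!is.null(gamma)) {
    if (is.matrix(gamma)) {
      stopifnot(ncol(gamma) == 2L)
      if (any(gamma[1L, ] != 0)) {
        stop("the first fruit position (first row of `gamma`) must be zero",
             call. = FALSE)
      }
      if (is.null(rownames(gamma))) rownames(gamma) <- seq_len(nrow(gamma))
    } else {
      stopifnot(is.numeric(gamma), length(gamma) == 2L)
      gamma_linear <- TRUE
    }
  }
  # both covariances may be singular for simulation (degenerate noise);
  # the likelihood itself additionally requires a positive-definite sigma
  check_cov(sigma0, "sigma0", definite = FALSE)
  check_cov(sigma, "sigma", definite = FALSE)
  structure(
    list(mu = as.numeric(mu), alpha = alpha, beta = beta, gamma = gamma,
         gamma_linear = gamma_linear,
         sigma0 = unname(as.matrix(sigma0)), sigma = unname(as.matrix(sigma))),
    class = "ripening_params"
  )
}

check_cov <- function(m, name, definite = FALSE) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 2L)) || any(!is.finite(m))) {
    stop(sprintf("`%s` must be a finite 2x2 matrix", name), call. = FALSE)
  }
  if (abs(m[1L, 2L] - m[2L, 1L]) > 1e-8 * (1 + max(abs(m)))) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(1, abs(ev[1L]))
  if (definite && ev[2L] <= tol) {
    stop(sprintf("`%s` must be positive definite", name), call. = FALSE)
  }
  if (!definite && ev[2L] < -tol) {
    stop(sprintf("`%s` must be positive semidefinite", name), call. = FALSE)
  }
  invisible(m)
}

#' @export
print.ripening_params <- function(x, ...) {
  cat("Bivariate ripening-time model parameters\n")
  cat(sprintf("  mu (first sign, red): %.2f, %.2f days\n", x$mu[1L], x$mu[2L]))
  cat(sprintf("  genotypes: %s (reference: %s)\n",
              paste(rownames(x$alpha), collapse = ", "), rownames(x$alpha)[1L]))
  if (!is.null(x$beta)) cat(sprintf("  truss effects: %d levels\n", nrow(x$beta)))
  if (!is.null(x$gamma)) {
    if (x$gamma_linear) cat("  fruit-position effect: linear\n")
    else cat(sprintf("  fruit-position effects: %d levels\n", nrow(x$gamma)))
  }
  cat("  sigma0 (plant):   ", fmt_cov(x$sigma0), "\n")
  cat("  sigma  (residual):", fmt_cov(x$sigma), "\n")
  invisible(x)
}

fmt_cov <- function(m) {
  sprintf("[[%.3g, %.3g], [%.3g, %.3g]]", m[1, 1], m[1, 2], m[2, 1], m[2, 2])
}

# Per-fruit fixed-effect shift mu + alpha + beta + gamma as an n x 2 matrix.
# Errors name the offending unknown level.
fixed_effect_shift <- function(params, genotype, truss, fruit) {
  n <- length(genotype)
  shift <- matrix(rep(params$mu, each = n), n, 2L)
  ia <- match(as.character(genotype), rownames(params$alpha))
  if (anyNA(ia)) {
    stop(sprintf("unknown genotype level '%s' not present in params",
                 as.character(genotype)[which(is.na(ia))[1L]]), call. = FALSE)
  }
  shift <- shift + params$alpha[ia, , drop = FALSE]
  if (!is.null(params$beta)) {
    ib <- match(as.character(truss), rownames(params$beta))
    if (anyNA(ib)) {
      stop(sprintf("unknown truss level '%s' not present in params",
                   as.character(truss)[which(is.na(ib))[1L]]), call. = FALSE)
    }
    shift <- shift + params$beta[ib, , drop = FALSE]
  }
  if (!is.null(params$gamma)) {
    if (params$gamma_linear) {
      shift <- shift + outer(as.numeric(fruit) - 1, params$gamma)
    } else {
      ig <- match(as.character(fruit), rownames(params$gamma))
      if (anyNA(ig)) {
        stop(sprintf("unknown fruit level '%s' not present in params",
                     as.character(fruit)[which(is.na(ig))[1L]]), call. = FALSE)
      }
      shift <- shift + params$gamma[ig, , drop = FALSE]
    }
  }
  unname(shift)
}
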