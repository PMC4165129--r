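#' Ripening stage labels
#'
#' The ordinal colour stages scored per fruit: mature green (MG), turning
#' (T), orange (O), light red (LR) and red (R).
#' @export
RIPENING_STAGES <- c("MG", "T", "O", "LR", "R")

# draw n samples from N2(0, cov) allowing a singular covariance
rmvn2 <- function(n, cov) {
  e <- eigen(cov, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(rnorm(2L * n), n, 2L)
  z %*% (sqrt(lam) * t(e$vectors))
}

#' Simulate a ripening-time experiment
#'
#' Draws latent event-time pairs \eqn{(Y^{(1)}, Y^{(2)})} for every fruit in
#' the design from the bivariate Gaussian model (fixed effects + plant
#' random effect + fruit residual) and discretizes them by the observation
#' schedule into ordinal colour stages: a fruit is mature green before
#' \eqn{Y^{(1)}}, red from \eqn{Y^{(2)}} on, and passes through turning,
#' orange and light red in three equal sub-intervals of
#' \eqn{[Y^{(1)}, Y^{(2)})} in between (only the turning and red transitions
#' carry information for the model; the sub-stages sharpen the red bound).
#'
#' An unconstrained bivariate Gaussian can produce \eqn{Y^{(2)} < Y^{(1)}};
#' such a fruit has its residual redrawn once and, if the inversion recurs,
#' \eqn{Y^{(2)}} is clamped to \eqn{Y^{(1)}}. Clamps are counted in the
#' returned ground truth.
#'
#' @param design An [experiment_design()].
#' @param params A [ripening_params()] object; covariances are validated on
#'   construction.
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#' @return A list with `observations` (data frame `plant_id`, `genotype`,
#'   `truss`, `fruit`, `obs_day`, `stage`) and `truth` (list with `params`,
#'   `latent_times` data frame holding the true `y1`, `y2` per fruit, and
#'   `n_clamped`).
#' @export
#' @examples
#' sim <- simulate_ripening_experiment(default_design(), default_params(),
#'                                     seed = 1)
#' head(sim$observations)
simulate_ripening_experiment <- function(design, params, seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "ripening_params"))
  check_cov(params$sigma0, "sigma0", definite = FALSE)
  check_cov(params$sigma, "sigma", definite = FALSE)
  missing_g <- setdiff(design$genotypes, rownames(params$alpha))
  if (length(missing_g)) {
    stop(sprintf("design genotype '%s' has no row in params$alpha",
                 missing_g[1L]), call. = FALSE)
  }
  with_seed(seed, {
    grid <- expand.grid(
      fruit = seq_len(design$fruits_per_truss),
      truss = seq_len(design$trusses_per_plant),
      plant_in_geno = NA_integer_, genotype = NA_character_,
      stringsAsFactors = FALSE
    )[, c("truss", "fruit")]
    rows <- list()
    plant_no <- 0L
    n_clamped <- 0L
    for (gi in seq_along(design$genotypes)) {
      g <- design$genotypes[gi]
      for (pi in seq_len(design$plants_per_genotype[gi])) {
        plant_no <- plant_no + 1L
        z <- drop(rmvn2(1L, params$sigma0))
        shift <- fixed_effect_shift(params, rep(g, nrow(grid)),
                                    grid$truss, grid$fruit)
        u <- rmvn2(nrow(grid), params$sigma)
        y <- shift + matrix(z, nrow(grid), 2L, byrow = TRUE) + u
        bad <- which(y[, 2L] < y[, 1L])
        if (length(bad)) {
          u2 <- rmvn2(length(bad), params$sigma)
          y[bad, ] <- shift[bad, , drop = FALSE] +
            matrix(z, length(bad), 2L, byrow = TRUE) + u2
          still <- bad[y[bad, 2L] < y[bad, 1L]]
          if (length(still)) {
            y[still, 2L] <- y[still, 1L]
            n_clamped <- n_clamped + length(still)
          }
        }
        rows[[plant_no]] <- data.frame(
          plant_id = sprintf("P%02d", plant_no), genotype = g,
          truss = grid$truss, fruit = grid$fruit,
          y1 = y[, 1L], y2 = y[, 2L], stringsAsFactors = FALSE
        )
      }
    }
    latent <- do.call(rbind, rows)
    obs <- latent[rep(seq_len(nrow(latent)),
                      each = length(design$observation_days)), ]
    obs$obs_day <- rep(design$observation_days, nrow(latent))
    obs$stage <- stage_at(obs$obs_day, obs$y1, obs$y2)
    obs <- obs[, c("plant_id", "genotype", "truss", "fruit", "obs_day",
                   "stage")]
    rownames(obs) <- NULL
    rownames(latent) <- NULL
    list(observations = obs,
         truth = list(params = params, latent_times = latent,
                      n_clamped = n_clamped))
  })
}

# colour stage of a fruit at day d given its latent transition times
stage_at <- function(day, y1, y2) {
  out <- character(length(day))
  out[day < y1] <- "MG"
  out[day >= y2] <- "R"
  mid <- which(day >= y1 & day < y2)
  if (length(mid)) {
    frac <- (day[mid] - y1[mid]) / (y2[mid] - y1[mid])
    out[mid] <- c("T", "O", "LR")[pmin(floor(frac * 3), 2) + 1L]
  }
  out
}

#' Simulate a qPCR dataset with amplification curves
#'
#' Generates per-well quantification cycles and matching
#' logistic-plateau amplification curves whose exponential phase has the
#' requested per-cycle amplification base. A gene's quantification cycle is
#' \eqn{Cq_{s,g} = Cq_0 - \log_2(q_{s,g}) \log 2 / \log E_g + \epsilon},
#' so one extra log2 unit of template advances Cq by exactly one cycle at
#' efficiency 2. Curves follow \eqn{F(c) = B + P F_0 E^c / (P + F_0 E^c)}
#' with \eqn{F_0} chosen so that the curve crosses 10% of the plateau
#' \eqn{P} exactly at the (noisy) Cq of the well.
#'
#' @param n_samples Number of biological samples.
#' @param genes Character vector of gene labels.
#' @param reference_genes Subset of `genes` acting as normalization
#'   references (constant true expression in the default usage).
#' @param true_log2_expression Matrix (`n_samples` x `length(genes)`) of
#'   true log2 expression levels.
#' @param efficiency Per-gene amplification base in (1, 2.2], recycled.
#' @param noise_sd Standard deviation of Cq-scale technical noise (cycles).
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per sample x gene.
#' @param n_cycles Cycles recorded per curve.
#' @param plateau,baseline_level Curve plateau and additive baseline
#'   fluorescence.
#' @param curve_noise_sd Multiplicative (log-scale) noise on curve
#'   fluorescence.
#' @param cq0 Baseline quantification cycle for a sample at log2 expression
#'   zero.
#' @return List with data frames `wells` (`well_id`, `sample`, `gene`,
#'   `replicate`, `cq`) and `curves` (`well_id`, `cycle`, `fluorescence`).
#' @export
simulate_qpcr_dataset <- function(n_samples, genes, reference_genes,
                                  true_log2_expression, efficiency,
                                  noise_sd, seed, n_replicates = 2L,
                                  n_cycles = 40L, plateau = 10,
                                  baseline_level = 0.05,
                                  curve_noise_sd = 0, cq0 = 25) {
  stopifnot(n_samples >= 1L, length(genes) >= 1L, noise_sd >= 0)
  if (!all(reference_genes %in% genes)) {
    stop("`reference_genes` must be a subset of `genes`", call. = FALSE)
  }
  eff <- rep_len(efficiency, length(genes))
  if (any(eff <= 1)) {
    stop("efficiency must be > 1 (no amplification)", call. = FALSE)
  }
  if (any(eff > 2.2)) {
    stop("efficiency must be <= 2.2", call. = FALSE)
  }
  expr <- as.matrix(true_log2_expression)
  stopifnot(nrow(expr) == n_samples, ncol(expr) == length(genes))
  with_seed(seed, {
    wells <- expand.grid(replicate = seq_len(n_replicates),
                         gene = genes, sample = sprintf("S%02d", 1:n_samples),
                         stringsAsFactors = FALSE)[, c("sample", "gene",
                                                       "replicate")]
    si <- match(wells$sample, sprintf("S%02d", 1:n_samples))
    gi <- match(wells$gene, genes)
    wells$cq <- cq0 - expr[cbind(si, gi)] * log(2) / log(eff[gi]) +
      rnorm(nrow(wells), 0, noise_sd)
    wells$well_id <- sprintf("W%04d", seq_len(nrow(wells)))
    wells <- wells[, c("well_id", "sample", "gene", "replicate", "cq")]

    cyc <- seq_len(n_cycles)
    curves <- do.call(rbind, lapply(seq_len(nrow(wells)), function(i) {
      e <- eff[gi[i]]
      f0 <- plateau / (9 * e^wells$cq[i])
      amp <- plateau * f0 * e^cyc / (plateau + f0 * e^cyc)
      if (curve_noise_sd > 0) amp <- amp * exp(rnorm(n_cycles, 0, curve_noise_sd))
      data.frame(well_id = wells$well_id[i], cycle = cyc,
                 fluorescence = baseline_level + amp,
                 stringsAsFactors = FALSE)
    }))
    rownames(curves) <- NULL
    list(wells = wells, curves = curves)
  })
}

#' Simulate an ethylene cuvette concentration trace
#'
#' At steady state, a fruit of fresh weight `weight` emitting
#' `true_rate` (nL of ethylene per hour per gram) into a cuvette flushed at
#' `flow` L/h raises the outflow concentration by
#' `true_rate * weight / flow` nL/L above background. The simulated trace
#' is that steady-state level plus Gaussian sensor noise.
#'
#' @param true_rate Emission rate (nL h^-1 g^-1).
#' @param weight Fruit fresh weight (g); must be positive.
#' @param flow Cuvette flow (L/h); must be positive.
#' @param background Background ethylene concentration in the air (nL/L).
#' @param noise_sd Concentration noise SD (nL/L).
#' @param duration Trace duration in minutes; must be positive.
#' @param seed Integer seed.
#' @param dt Sampling interval in seconds.
#' @param stage,genotype,plant_id Optional labels carried through.
#' @return An object of class `ethylene_measurement` (see
#'   [ethylene_measurement()]).
#' @export
simulate_ethylene_trace <- function(true_rate, weight, flow, background = 0,
                                    noise_sd = 0, duration = 12, seed = 1,
                                    dt = 5, stage = NA, genotype = NA,
                                    plant_id = NA) {
  if (flow <= 0) stop("`flow` must be positive", call. = FALSE)
  if (weight <= 0) stop("`weight` must be positive", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  with_seed(seed, {
    time_s <- seq(0, duration * 60, by = dt)
    conc <- background + true_rate * weight / flow +
      rnorm(length(time_s), 0, noise_sd)
    ethylene_measurement(
      trace = data.frame(time_s = time_s, concentration = conc),
      background = background, flow = flow, fresh_weight = weight,
      stage = stage, genotype = genotype, plant_id = plant_id
    )
  })
}
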