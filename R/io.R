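#' Read and write stage-observation tables
#'
#' The canonical CSV schema for ripening observations has columns
#' `plant_id`, `genotype`, `truss`, `fruit`, `obs_day`, `stage`. Reading
#' validates the stage vocabulary (MG/T/O/LR/R, reported with the offending
#' line number), sorts each fruit's records by day, and checks that every
#' fruit's stage sequence is non-decreasing.
#'
#' @param path CSV file path.
#' @return `read_stage_observations()` returns the validated data frame
#'   (possibly with zero rows); the writers return `path` invisibly.
#' @export
read_stage_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obs <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("plant_id", "genotype", "truss", "fruit", "obs_day", "stage")
  if (!all(req %in% names(obs))) {
    stop("expected columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(obs) == 0L) return(obs[, req])
  bad <- which(!(obs$stage %in% RIPENING_STAGES))
  if (length(bad)) {
    stop(sprintf("unknown stage label '%s' at line %d", obs$stage[bad[1L]],
                 bad[1L] + 1L), call. = FALSE)  # +1 for the header line
  }
  obs <- obs[order(obs$plant_id, obs$truss, obs$fruit, obs$obs_day), req]
  key <- interaction(obs$plant_id, obs$truss, obs$fruit, drop = TRUE)
  for (part in split(obs, key)) {
    st <- match(part$stage, RIPENING_STAGES)
    if (any(diff(st) < 0)) {
      stop(sprintf("decreasing stage sequence for plant %s truss %s fruit %s",
                   part$plant_id[1L], part$truss[1L], part$fruit[1L]),
           call. = FALSE)
    }
  }
  rownames(obs) <- NULL
  obs
}

#' @rdname read_stage_observations
#' @param observations Data frame in the schema above.
#' @export
write_stage_observations <- function(observations, path) {
  req <- c("plant_id", "genotype", "truss", "fruit", "obs_day", "stage")
  stopifnot(all(req %in% names(observations)))
  write.csv(observations[, req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write censored-observation tables
#'
#' Censored fruit records (`plant_id`, `genotype`, `truss`, `fruit`, `L1`,
#' `R1`, `L2`, `R2`) are serialized with the literal `inf` for right
#' censoring and parsed back losslessly.
#'
#' @param cens Censored data frame ([censor_dataset()] output).
#' @param path CSV file path.
#' @export
write_censored_observations <- function(cens, path) {
  req <- c("plant_id", "genotype", "truss", "fruit", "L1", "R1", "L2", "R2")
  stopifnot(all(req %in% names(cens)))
  out <- cens[, req]
  for (v in c("L1", "R1", "L2", "R2")) {
    out[[v]] <- ifelse(is.infinite(out[[v]]), "inf",
                       format(out[[v]], digits = 15, trim = TRUE,
                              scientific = FALSE))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_censored_observations
#' @export
read_censored_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cens <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = list(L1 = "character", R1 = "character",
                                     L2 = "character", R2 = "character"))
  for (v in c("L1", "R1", "L2", "R2")) {
    x <- cens[[v]]
    cens[[v]] <- ifelse(tolower(x) == "inf", Inf, suppressWarnings(as.numeric(x)))
  }
  if (any(cens$L1 > cens$R1) || any(cens$L2 > cens$R2)) {
    stop("invalid censoring intervals: L > R", call. = FALSE)
  }
  cens
}

#' Ground-truth sidecar for simulated experiments
#'
#' Stores the generative parameters and per-fruit latent event times of a
#' simulation as JSON, so recovery analyses can compare estimates with the
#' truth.
#'
#' @param truth The `truth` element of [simulate_ripening_experiment()].
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  p <- truth$params
  payload <- list(
    params = list(mu = p$mu,
                  alpha = apply(p$alpha, 1L, identity, simplify = FALSE),
                  beta = if (!is.null(p$beta))
                    apply(p$beta, 1L, identity, simplify = FALSE),
                  gamma = if (is.null(p$gamma)) NULL
                    else if (p$gamma_linear) list(linear = p$gamma)
                    else apply(p$gamma, 1L, identity, simplify = FALSE),
                  sigma0 = p$sigma0, sigma = p$sigma),
    latent_times = truth$latent_times,
    n_clamped = truth$n_clamped
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- raw$params
  gamma <- pr$gamma
  if (!is.null(gamma) && !is.null(gamma$linear)) gamma <- as.numeric(gamma$linear)
  else if (!is.null(gamma)) gamma <- do.call(rbind, gamma)
  params <- ripening_params(
    mu = as.numeric(pr$mu),
    alpha = do.call(rbind, pr$alpha),
    beta = if (!is.null(pr$beta)) do.call(rbind, pr$beta),
    gamma = gamma,
    sigma0 = matrix(unlist(pr$sigma0), 2L),
    sigma = matrix(unlist(pr$sigma), 2L)
  )
  list(params = params, latent_times = as.data.frame(raw$latent_times),
       n_clamped = raw$n_clamped)
}

#' Read and write qPCR well and curve tables
#'
#' Well tables carry `well_id`, `sample`, `gene`, `replicate`, `cq`;
#' curve tables are long format `well_id`, `cycle`, `fluorescence`.
#'
#' @param wells,curves Data frames in those schemas.
#' @param path CSV file path.
#' @export
write_qpcr_wells <- function(wells, path) {
  write.csv(wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_wells
#' @export
read_qpcr_wells <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  w <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "gene", "cq") %in% names(w)))
  w
}

#' @rdname write_qpcr_wells
#' @export
write_qpcr_curves <- function(curves, path) {
  write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_wells
#' @export
read_qpcr_curves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cv <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("well_id", "cycle", "fluorescence") %in% names(cv)))
  cv
}

#' Read and write ethylene traces
#'
#' A trace CSV holds `time_s`, `concentration`; the accompanying metadata
#' (background, flow, weight, labels) travels in the pipeline config or a
#' metadata CSV with columns `plant_id`, `genotype`, `stage`, `weight_g`,
#' `flow_lph`, `background`, `trace_file`.
#'
#' @param m An [ethylene_measurement()].
#' @param path CSV path.
#' @export
write_ethylene_trace <- function(m, path) {
  write.csv(m$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ethylene_trace
#' @param background,flow,fresh_weight,stage,genotype,plant_id Metadata for
#'   the measurement being read.
#' @export
read_ethylene_trace <- function(path, background, flow, fresh_weight,
                                stage = NA, genotype = NA, plant_id = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "concentration") %in% names(tr)))
  ethylene_measurement(tr, background = background, flow = flow,
                       fresh_weight = fresh_weight, stage = stage,
                       genotype = genotype, plant_id = plant_id)
}
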