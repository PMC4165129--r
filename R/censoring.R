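#' Interval-censoring bounds for one fruit's stage series
#'
#' A fruit is only seen at the scheduled observation days, so the day it
#' entered a stage is known up to an interval. Event 1 is entry into the
#' turning stage (the first sign of ripening), event 2 entry into the red
#' stage. For each event, the lower bound `L` is the last observation day on
#' which the fruit was still at a stage strictly before the event's stage
#' (orange and light-red observations therefore sharpen the lower bound for
#' the red event), and the upper bound `R` is the first observation day at
#' or past it. With no pre-event observation `L = 0` (no fruit ripens
#' before anthesis); if the event was never observed `R = +Inf`
#' (right censoring).
#'
#' @param series Data frame with columns `obs_day` and `stage` (one fruit;
#'   identifier columns `plant_id`, `genotype`, `truss`, `fruit` are carried
#'   through when present). Days must be strictly increasing and stages
#'   non-decreasing in the order MG < T < O < LR < R.
#' @return One-row data frame with `L1`, `R1`, `L2`, `R2` (days) plus any
#'   identifier columns.
#' @export
#' @examples
#' s <- data.frame(obs_day = c(35, 38, 42, 45),
#'                 stage = c("MG", "T", "O", "R"))
#' derive_censoring_intervals(s)  # L = (35, 42), R = (38, 45)
derive_censoring_intervals <- function(series) {
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop("`series` must be a non-empty data frame of observations",
         call. = FALSE)
  }
  stopifnot(all(c("obs_day", "stage") %in% names(series)))
  series <- series[order(series$obs_day), , drop = FALSE]
  if (any(diff(series$obs_day) <= 0)) {
    stop("observation days must be strictly increasing", call. = FALSE)
  }
  st <- match(series$stage, RIPENING_STAGES)
  if (anyNA(st)) {
    stop(sprintf("unknown stage label '%s'",
                 series$stage[which(is.na(st))[1L]]), call. = FALSE)
  }
  if (any(diff(st) < 0)) {
    stop("stage sequence must be non-decreasing", call. = FALSE)
  }
  ev <- function(threshold) {
    pre <- series$obs_day[st < threshold]
    post <- series$obs_day[st >= threshold]
    c(L = if (length(pre)) max(pre) else 0,
      R = if (length(post)) min(post) else Inf)
  }
  e1 <- ev(match("T", RIPENING_STAGES))
  e2 <- ev(match("R", RIPENING_STAGES))
  out <- data.frame(L1 = e1[["L"]], R1 = e1[["R"]],
                    L2 = e2[["L"]], R2 = e2[["R"]])
  ids <- intersect(c("plant_id", "genotype", "truss", "fruit"), names(series))
  for (v in ids) out[[v]] <- series[[v]][1L]
  out[, c(ids, "L1", "R1", "L2", "R2"), drop = FALSE]
}

#' Censoring intervals for a whole stage-observation table
#'
#' Applies [derive_censoring_intervals()] to every fruit (grouped by
#' `plant_id`, `truss`, `fruit`) of a long stage-observation table.
#'
#' @param observations Data frame with columns `plant_id`, `genotype`,
#'   `truss`, `fruit`, `obs_day`, `stage`.
#' @return Data frame with one row per fruit: identifiers plus `L1`, `R1`,
#'   `L2`, `R2`.
#' @export
censor_dataset <- function(observations) {
  req <- c("plant_id", "genotype", "truss", "fruit", "obs_day", "stage")
  if (!all(req %in% names(observations))) {
    stop("observations must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(observations$plant_id, observations$truss,
                     observations$fruit, drop = TRUE)
  parts <- split(observations, key)
  out <- do.call(rbind, lapply(parts, derive_censoring_intervals))
  out <- out[order(out$plant_id, out$truss, out$fruit), , drop = FALSE]
  rownames(out) <- NULL
  out
}
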