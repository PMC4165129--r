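#' Ethylene cuvette measurement
#'
#' One fruit's measurement on the flow-through cuvette system: the
#' concentration trace of the outflowing air (volume-fraction units, e.g.
#' nL/L = ppbv), the background ethylene concentration of the incoming
#' air, the flow through the cuvette and the fruit's fresh weight.
#'
#' @param trace Data frame with columns `time_s` and `concentration`.
#' @param background Background concentration (same units as the trace).
#' @param flow Flow in L/h; must be positive.
#' @param fresh_weight Fresh weight in g; must be positive.
#' @param stage,genotype,plant_id Optional labels carried through to the
#'   emission rate.
#' @return Object of class `ethylene_measurement`.
#' @export
ethylene_measurement <- function(trace, background, flow, fresh_weight,
                                 stage = NA, genotype = NA, plant_id = NA) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "concentration") %in% names(trace)))
  if (nrow(trace) == 0L) stop("empty concentration trace", call. = FALSE)
  if (!is.numeric(flow) || flow <= 0) {
    stop("`flow` must be positive", call. = FALSE)
  }
  if (!is.numeric(fresh_weight) || fresh_weight <= 0) {
    stop("`fresh_weight` must be positive", call. = FALSE)
  }
  structure(list(trace = trace, background = background, flow = flow,
                 fresh_weight = fresh_weight, stage = stage,
                 genotype = genotype, plant_id = plant_id),
            class = "ethylene_measurement")
}

#' @export
print.ethylene_measurement <- function(x, ...) {
  cat(sprintf(paste0("Ethylene measurement: %d points over %.1f min, ",
                     "flow %.1f L/h, weight %.1f g, background %.2f\n"),
              nrow(x$trace), diff(range(x$trace$time_s)) / 60, x$flow,
              x$fresh_weight, x$background))
  invisible(x)
}

#' Ethylene emission rate of a fruit
#'
#' At steady state the fruit's emission equals the excess concentration it
#' adds to the air stream times the flow, per gram of fresh weight:
#' \deqn{rate = (\bar{c} - c_{bg}) \times flow / weight,}
#' with \eqn{\bar{c}} the mean concentration over the final stable part of
#' the trace (the last `window_s` seconds). With the trace in nL/L, flow
#' in L/h and weight in g, the rate is in nL h^-1 g^-1; any volume-fraction
#' unit (e.g. ppbv) gives the same rate in the matching unit. A mean
#' concentration more than two standard errors *below* background (over-
#' correction beyond the noise floor) flags the rate.
#'
#' @param m An [ethylene_measurement()].
#' @param window_s Length of the summarization window in seconds (default:
#'   final 5 minutes).
#' @return Object of class `emission_rate`: `value`, `flagged`, plus the
#'   carried-through `stage`, `genotype`, `plant_id`.
#' @export
emission_rate <- function(m, window_s = 300) {
  stopifnot(inherits(m, "ethylene_measurement"))
  tr <- m$trace
  win <- tr$time_s >= max(tr$time_s) - window_s
  conc <- tr$concentration[win]
  excess <- mean(conc) - m$background
  noise_floor <- if (length(conc) > 1L) 2 * sd(conc) / sqrt(length(conc)) else 0
  rate <- excess * m$flow / m$fresh_weight
  structure(list(value = rate, flagged = excess < -noise_floor,
                 stage = m$stage, genotype = m$genotype,
                 plant_id = m$plant_id),
            class = "emission_rate")
}

#' Emission rates for a list of measurements
#'
#' @param measurements List of [ethylene_measurement()] objects.
#' @param window_s Passed to [emission_rate()].
#' @return Data frame `plant_id`, `genotype`, `stage`, `rate`, `flagged`.
#' @export
emission_rates <- function(measurements, window_s = 300) {
  rows <- lapply(measurements, function(m) {
    r <- emission_rate(m, window_s)
    data.frame(plant_id = as.character(r$plant_id %||% NA),
               genotype = as.character(r$genotype %||% NA),
               stage = as.character(r$stage %||% NA),
               rate = r$value, flagged = r$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare genotype ethylene emissions within one ripening stage
#'
#' Emission rates are compared across genotypes on the log scale by
#' one-way ANOVA with Fisher's protected LSD ([anova_lsd()]). Because
#' pre-climacteric (mature green) emissions sit at the noise level,
#' nonpositive rates are replaced by half the smallest positive rate
#' before the log transform; the number of such replacements is reported.
#'
#' @param rates Data frame with columns `rate`, `genotype`, `stage`
#'   (see [emission_rates()]); all rows must share one stage, with >= 2
#'   genotypes of >= 2 fruits each.
#' @param alpha Significance level.
#' @return List with `letters` (per genotype), `anova` (the [anova_lsd()]
#'   result) and `n_shifted`.
#' @export
compare_stage_emissions <- function(rates, alpha = 0.05) {
  stopifnot(all(c("rate", "genotype", "stage") %in% names(rates)))
  if (length(unique(rates$stage)) != 1L) {
    stop("all rates must come from a single ripening stage", call. = FALSE)
  }
  x <- rates$rate
  nonpos <- x <= 0
  if (all(nonpos)) {
    stop("no positive emission rates to compare", call. = FALSE)
  }
  if (any(nonpos)) x[nonpos] <- min(x[!nonpos]) / 2
  res <- anova_lsd(log(x), rates$genotype, alpha = alpha)
  list(letters = res$letters, anova = res, n_shifted = sum(nonpos))
}
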