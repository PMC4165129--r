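#' Design of a ripening-time observation experiment
#'
#' Describes the layout of the greenhouse experiment: which genotypes are
#' grown (one marked as the wild-type reference), how many plants carry each
#' genotype, how many trusses per plant and fruits per truss are followed,
#' and on which days from anthesis the colour stage of every fruit is
#' scored.
#'
#' @param genotypes Character vector of genotype labels.
#' @param reference The wild-type genotype; must occur exactly once in
#'   `genotypes`. Defaults to the first label.
#' @param plants_per_genotype Integer count, either a single number or one
#'   per genotype.
#' @param trusses_per_plant,fruits_per_truss Integer counts.
#' @param observation_days Strictly increasing nonnegative days from
#'   anthesis on which every fruit's stage is recorded.
#'
#' @return An object of class `experiment_design`.
#' @seealso [default_design()] for the layout mirroring the original
#'   greenhouse study.
#' @export
experiment_design <- function(genotypes,
                              reference = genotypes[1L],
                              plants_per_genotype,
                              trusses_per_plant = 2L,
                              fruits_per_truss = 3L,
                              observation_days) {
  stopifnot(is.character(genotypes), length(genotypes) >= 1L)
  if (sum(genotypes == reference) != 1L) {
    stop("the reference genotype must appear exactly once in `genotypes`",
         call. = FALSE)
  }
  if (anyDuplicated(genotypes)) {
    stop("genotype labels must be unique", call. = FALSE)
  }
  plants <- rep_len(as.integer(plants_per_genotype), length(genotypes))
  stopifnot(all(plants >= 1L), trusses_per_plant >= 1L, fruits_per_truss >= 1L)
  observation_days <- as.numeric(observation_days)
  if (length(observation_days) < 1L || any(observation_days < 0) ||
      any(diff(observation_days) <= 0)) {
    stop("`observation_days` must be strictly increasing and nonnegative",
         call. = FALSE)
  }
  # reference listed first so that reference coding lines up everywhere
  ord <- c(which(genotypes == reference), which(genotypes != reference))
  structure(
    list(genotypes = genotypes[ord], reference = reference,
         plants_per_genotype = plants[ord],
         trusses_per_plant = as.integer(trusses_per_plant),
         fruits_per_truss = as.integer(fruits_per_truss),
         observation_days = observation_days),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Ripening experiment design\n")
  cat(sprintf("  genotypes: %s (reference: %s)\n",
              paste(sprintf("%s x%d", x$genotypes, x$plants_per_genotype),
                    collapse = ", "), x$reference))
  cat(sprintf("  %d trusses/plant, %d fruits/truss, %d plants, %d fruits\n",
              x$trusses_per_plant, x$fruits_per_truss,
              sum(x$plants_per_genotype),
              sum(x$plants_per_genotype) * x$trusses_per_plant *
                x$fruits_per_truss))
  cat(sprintf("  observation days (from anthesis): %s\n",
              paste(x$observation_days, collapse = ", ")))
  invisible(x)
}

#' Default experiment design and generative parameters
#'
#' `default_design()` mirrors the original greenhouse layout: four genotypes
#' (wild type, an `acs4-1` ACC-synthase mutant and two `rin` alleles), five
#' plants per genotype except two for `rin-3`, six fruits per plant (two
#' trusses of three), and twice-weekly stage scoring. The schedule starts at
#' day 30 from anthesis; because in the greenhouse fruits have staggered
#' anthesis dates, per-fruit coverage extends beyond four calendar weeks, so
#' the default schedule runs twice weekly to day 65.
#'
#' `default_params()` provides generative parameters consistent with the
#' phenotypes of those genotypes: the wild type shows its first ripening
#' sign around day 42 and reaches red around day 52; `acs4-1` is delayed in
#' both the start and the progression of ripening, `rin-2` strongly delayed
#' in both, and `rin-3` slowed mainly in progression. Earlier fruit
#' positions on a truss ripen slightly faster; no truss effect is present.
#'
#' @return An `experiment_design` or `ripening_params` object.
#' @export
default_design <- function() {
  experiment_design(
    genotypes = c("WT", "acs4-1", "rin-2", "rin-3"),
    reference = "WT",
    plants_per_genotype = c(5L, 5L, 5L, 2L),
    trusses_per_plant = 2L,
    fruits_per_truss = 3L,
    observation_days = c(30, 33, 37, 40, 44, 47, 51, 54, 58, 61, 65)
  )
}

#' @rdname default_design
#' @export
default_params <- function() {
  ripening_params(
    mu = c(42, 52),
    alpha = rbind(`WT` = c(0, 0), `acs4-1` = c(3, 6),
                  `rin-2` = c(6, 12), `rin-3` = c(0.5, 6)),
    beta = NULL,
    gamma = rbind(`1` = c(0, 0), `2` = c(0.7, 0.7), `3` = c(1.4, 1.4)),
    sigma0 = matrix(c(3, 1, 1, 3), 2L),
    sigma = matrix(c(2, 0.5, 0.5, 2), 2L)
  )
}
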