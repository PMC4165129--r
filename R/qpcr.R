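#' Amplification efficiency by the window-of-linearity method
#'
#' Estimates the per-cycle amplification base of one reaction from its raw
#' amplification curve: the baseline (mean fluorescence of the first
#' cycles) is subtracted, and within the usable region (above the baseline
#' noise, below 80% of the plateau) every contiguous window of
#' `window_sizes` cycles is regressed as log10(fluorescence) on cycle. The
#' *earliest* window whose fit reaches `r2_threshold` defines the
#' efficiency \eqn{E = 10^{slope}} (ties broken towards wider windows and
#' higher R-squared); taking the lowest qualifying window keeps the
#' estimate in the truly exponential phase, before the approach to the
#' plateau bends the curve and biases the slope down. A doubling reaction
#' gives \eqn{E = 2}.
#'
#' @param curve Data frame with columns `cycle` and `fluorescence`
#'   (>= 10 cycles).
#' @param window_sizes Candidate window widths (cycles).
#' @param r2_threshold Minimum R-squared for an acceptable window; if no
#'   window reaches it the curve has no exponential phase and an error is
#'   raised.
#' @param baseline_cycles Cycles averaged for the baseline estimate.
#' @return The amplification base (per-cycle fold change), typically in
#'   (1, 2.2].
#' @export
#' @examples
#' curve <- data.frame(cycle = 1:40, fluorescence = 1e-6 * 2^(1:40))
#' qpcr_efficiency(curve)  # 2.0
qpcr_efficiency <- function(curve, window_sizes = 4:6,
                            r2_threshold = 0.995, baseline_cycles = 1:5) {
  stopifnot(all(c("cycle", "fluorescence") %in% names(curve)))
  curve <- curve[order(curve$cycle), , drop = FALSE]
  if (nrow(curve) < 10L) {
    stop("curve must have at least 10 cycles", call. = FALSE)
  }
  base <- mean(curve$fluorescence[curve$cycle %in% baseline_cycles])
  f <- curve$fluorescence - base
  top <- max(f)
  if (!(top > 0)) stop("no exponential phase", call. = FALSE)
  usable <- which(f > top * 1e-4 & f < top * 0.8)
  if (length(usable) < min(window_sizes)) {
    stop("no exponential phase", call. = FALSE)
  }
  lf <- log10(f[usable])
  cyc <- curve$cycle[usable]
  cand <- NULL
  for (w in sort(window_sizes)) {
    if (length(usable) < w) next
    for (s in seq_len(length(usable) - w + 1L)) {
      idx <- s:(s + w - 1L)
      # windows must be contiguous in cycle number
      if (cyc[idx[w]] - cyc[idx[1L]] != w - 1L) next
      x <- cyc[idx]; y <- lf[idx]
      sl <- cov(x, y) / stats::var(x)
      r2 <- cov(x, y)^2 / (stats::var(x) * stats::var(y))
      cand <- rbind(cand, c(start = x[1L], w = w, r2 = r2, slope = sl))
    }
  }
  if (is.null(cand)) stop("no exponential phase", call. = FALSE)
  ok <- cand[is.finite(cand[, "r2"]) & cand[, "r2"] >= r2_threshold, ,
             drop = FALSE]
  if (nrow(ok) == 0L) stop("no exponential phase", call. = FALSE)
  ok <- ok[order(ok[, "start"], -ok[, "w"], -ok[, "r2"]), , drop = FALSE]
  unname(10^ok[1L, "slope"])
}

#' Plate-average amplification efficiency
#'
#' Per-gene efficiencies on one plate are noisy; averaging the per-reaction
#' estimates of the whole plate and applying the single average to every
#' gene stabilizes the calculation.
#'
#' @param efficiencies Numeric vector of per-reaction efficiency estimates.
#' @return Their arithmetic mean (non-finite values dropped).
#' @export
plate_mean_efficiency <- function(efficiencies) {
  eff <- efficiencies[is.finite(efficiencies)]
  if (length(eff) == 0L) {
    stop("no finite efficiencies supplied", call. = FALSE)
  }
  mean(eff)
}

#' Normalized relative quantities
#'
#' Technical replicates are averaged on the Cq scale; per gene the relative
#' quantity of a sample is \eqn{RQ_{s,g} = E_g^{\bar{Cq}_g - Cq_{s,g}}}
#' (calibrated to the across-sample mean Cq, so RQs are centred; ratios
#' between samples do not depend on this choice). The normalization factor
#' of a sample is the geometric mean of its reference-gene RQs, and
#' \eqn{NRQ_{s,g} = RQ_{s,g} / NF_s}.
#'
#' @param wells Data frame with columns `sample`, `gene`, `cq` (and
#'   optionally `replicate`).
#' @param reference_genes Character vector of reference gene labels; every
#'   sample must have a Cq for each of them.
#' @param efficiency Named per-gene efficiency vector, or a single value
#'   applied to all genes (e.g. a plate average).
#' @return Data frame of class `nrq_table`: `sample`, `gene`, `efficiency`,
#'   `rq`, `nf`, `nrq`, `is_reference`.
#' @export
compute_nrq <- function(wells, reference_genes, efficiency) {
  stopifnot(all(c("sample", "gene", "cq") %in% names(wells)))
  if (!all(reference_genes %in% wells$gene)) {
    stop("reference genes missing from wells: ",
         paste(setdiff(reference_genes, wells$gene), collapse = ", "),
         call. = FALSE)
  }
  cq <- aggregate(cq ~ sample + gene, data = wells, FUN = mean)
  genes <- sort(unique(cq$gene))
  if (is.null(names(efficiency))) {
    if (length(efficiency) != 1L) {
      stop("`efficiency` must be named per gene or a single value",
           call. = FALSE)
    }
    eff <- setNames(rep(efficiency, length(genes)), genes)
  } else {
    miss <- setdiff(genes, names(efficiency))
    if (length(miss)) {
      stop("no efficiency for gene(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    eff <- efficiency[genes]
  }
  if (any(eff <= 1)) stop("efficiencies must be > 1", call. = FALSE)
  for (s in unique(cq$sample)) {
    have <- cq$gene[cq$sample == s]
    miss <- setdiff(reference_genes, have)
    if (length(miss)) {
      stop(sprintf("sample '%s' is missing reference gene(s) %s", s,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  cqbar <- tapply(cq$cq, cq$gene, mean)
  cq$rq <- as.numeric(eff[cq$gene]^(cqbar[cq$gene] - cq$cq))
  cq$efficiency <- unname(eff[cq$gene])
  nf <- tapply(
    seq_len(nrow(cq)), cq$sample,
    function(ix) {
      r <- cq[ix, ]
      exp(mean(log(r$rq[r$gene %in% reference_genes])))
    }
  )
  cq$nf <- as.numeric(nf[cq$sample])
  cq$nrq <- cq$rq / cq$nf
  cq$is_reference <- cq$gene %in% reference_genes
  out <- cq[order(cq$sample, cq$gene),
            c("sample", "gene", "efficiency", "rq", "nf", "nrq",
              "is_reference")]
  rownames(out) <- NULL
  class(out) <- c("nrq_table", "data.frame")
  out
}

#' geNORM reference-gene stability
#'
#' For each candidate reference gene \eqn{g}, the stability measure
#' \eqn{M_g} is the mean over the other genes \eqn{h} of the standard
#' deviation across samples of \eqn{\log_2(Q_g/Q_h)}; a perfectly
#' co-regulated pair has a constant ratio and contributes zero. Iteratively
#' excluding the least stable gene yields the stability ranking, and the
#' pairwise variation \eqn{V_{n/n+1}} (SD across samples of
#' \eqn{\log_2(NF_n/NF_{n+1})}, with \eqn{NF_k} the geometric mean of the
#' \eqn{k} most stable genes) indicates how many reference genes are needed
#' (the conventional cut-off is 0.15).
#'
#' @param quantities Matrix of positive relative quantities, samples in
#'   rows, candidate genes in columns (>= 3 genes, >= 2 samples).
#' @return Object of class `genorm_result`: `M` (per-gene stability on the
#'   full panel), `ranking` (most stable first; the final two genes are
#'   tied and listed alphabetically), `V` (named `V2/3`, `V3/4`, ...).
#' @export
genorm <- function(quantities) {
  q <- as.matrix(quantities)
  if (is.null(colnames(q))) colnames(q) <- paste0("G", seq_len(ncol(q)))
  if (ncol(q) < 3L || nrow(q) < 2L) {
    stop("geNORM needs >= 3 candidate genes and >= 2 samples", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("quantities must be positive and finite", call. = FALSE)
  }
  lq <- log2(q)
  m_of <- function(cols) {
    vapply(cols, function(g) {
      mean(vapply(setdiff(cols, g),
                  function(h) sd(lq[, g] - lq[, h]), numeric(1)))
    }, numeric(1), USE.NAMES = TRUE)
  }
  genes <- colnames(q)
  M_full <- setNames(m_of(genes), genes)
  remaining <- genes
  excluded <- character(0)
  while (length(remaining) > 2L) {
    m <- setNames(m_of(remaining), remaining)
    worst <- names(which.max(m))
    excluded <- c(worst, excluded)
    remaining <- setdiff(remaining, worst)
  }
  ranking <- c(sort(remaining), excluded)
  nf_log <- function(k) rowMeans(lq[, ranking[seq_len(k)], drop = FALSE])
  ks <- 2:(length(genes) - 1L)
  V <- vapply(ks, function(k) sd(nf_log(k) - nf_log(k + 1L)), numeric(1))
  names(V) <- sprintf("V%d/%d", ks, ks + 1L)
  structure(list(M = M_full, ranking = ranking, V = V),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNORM reference-gene stability\n  M:\n")
  print(round(x$M, 4))
  cat("  ranking (most stable first):", paste(x$ranking, collapse = " > "),
      "\n  pairwise variation:\n")
  print(round(x$V, 4))
  invisible(x)
}

#' Combine NRQ datasets by mean centring
#'
#' Runs measured in different batches share the genes but not a common
#' calibrator; centring each dataset's log NRQs per gene removes the batch
#' offset so the runs can be analysed together. Within each dataset and
#' gene the mean log NRQ is subtracted, and the centred tables are
#' concatenated.
#'
#' @param datasets List (>= 1) of NRQ tables ([compute_nrq()] output or any
#'   data frame with `sample`, `gene`, `nrq`) sharing the same gene set,
#'   with disjoint samples.
#' @return Data frame `dataset`, `sample`, `gene`, `log_nrq` (centred
#'   natural-log scale).
#' @export
mean_center_combine <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  gene_sets <- lapply(datasets, function(d) sort(unique(d$gene)))
  if (length(unique(vapply(gene_sets, paste, character(1),
                           collapse = "\r"))) != 1L) {
    stop("datasets must share the same gene set", call. = FALSE)
  }
  all_samples <- unlist(lapply(datasets, function(d) unique(d$sample)))
  if (anyDuplicated(all_samples)) {
    stop("datasets must have disjoint samples", call. = FALSE)
  }
  nm <- names(datasets) %||% paste0("D", seq_along(datasets))
  out <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    d <- as.data.frame(datasets[[i]])[, c("sample", "gene", "nrq")]
    d$log_nrq <- log(d$nrq)
    mg <- tapply(d$log_nrq, d$gene, mean)
    d$log_nrq <- d$log_nrq - mg[d$gene]
    data.frame(dataset = nm[i], sample = d$sample, gene = d$gene,
               log_nrq = as.numeric(d$log_nrq), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Fisher's protected LSD
#'
#' Standard one-way ANOVA on (typically log-scale) values; when the omnibus
#' F test is significant at `alpha`, all pairwise comparisons are made with
#' t tests on the pooled mean-squared error (Fisher's least significant
#' difference). The protection means no pair is ever declared different
#' when the omnibus test is not significant. Group letters follow the usual
#' compact-letter convention: groups sharing a letter are not significantly
#' different.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups with >= 2 values each).
#' @param alpha Significance level.
#' @return Object of class `anova_lsd`: `F`, `p_omnibus`, `df`, `mse`,
#'   `pairwise` (data frame `group1`, `group2`, `diff`, `t`, `p`,
#'   `significant`), `letters` (named by group, ordered by decreasing
#'   mean).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  cnt <- table(g)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(cnt < 2L)) {
    stop(sprintf("group '%s' has fewer than 2 values",
                 names(cnt)[which(cnt < 2L)[1L]]), call. = FALSE)
  }
  fit <- lm(values ~ g)
  an <- anova(fit)
  Fv <- an$`F value`[1L]
  p_omni <- an$`Pr(>F)`[1L]
  df_err <- an$Df[2L]
  mse <- an$`Mean Sq`[2L]
  means <- tapply(values, g, mean)
  lev <- names(sort(means, decreasing = TRUE))
  pairs <- utils::combn(lev, 2L)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   stringsAsFactors = FALSE)
  pw$diff <- means[pw$group1] - means[pw$group2]
  pw$t <- pw$diff / sqrt(mse * (1 / cnt[pw$group1] + 1 / cnt[pw$group2]))
  pw$p <- 2 * pt(-abs(pw$t), df_err)
  pw$significant <- (p_omni < alpha) & (pw$p < alpha)
  rownames(pw) <- NULL
  letters_v <- cld_letters(lev, pw)
  structure(list(F = Fv, p_omnibus = p_omni, df = c(an$Df[1L], df_err),
                 mse = mse, means = means[lev], pairwise = pw,
                 letters = letters_v, alpha = alpha),
            class = "anova_lsd")
}

# compact-letter display: maximal runs of mutually non-different groups
# along the mean-ordered sequence get one letter each
cld_letters <- function(lev, pw) {
  k <- length(lev)
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(nrow(pw))) {
    if (pw$significant[i]) {
      sig[pw$group1[i], pw$group2[i]] <- TRUE
      sig[pw$group2[i], pw$group1[i]] <- TRUE
    }
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1L), i:(j + 1L)])) j <- j + 1L
    runs[[i]] <- i:j
  }
  # drop runs contained in another
  keep <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b) {
      b != a && all(runs[[a]] %in% runs[[b]])
    }, logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  out <- setNames(rep("", k), lev)
  for (r in seq_along(runs)) {
    out[runs[[r]]] <- paste0(out[runs[[r]]], letters[r])
  }
  out
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p_omnibus))
  cat("Group means and LSD letters:\n")
  print(data.frame(mean = round(x$means, 4), letters = x$letters))
  invisible(x)
}
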