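test_that("window-of-linearity efficiency recovers known amplification bases", {
  curve <- data.frame(cycle = 1:40, fluorescence = 1e-6 * 2^(1:40))
  expect_equal(qpcr_efficiency(curve), 2, tolerance = 1e-6)

  expect_error(qpcr_efficiency(data.frame(cycle = 1:40,
                                          fluorescence = rep(1, 40))),
               "no exponential phase")
  expect_error(qpcr_efficiency(data.frame(cycle = 1:5,
                                          fluorescence = 2^(1:5))),
               "at least 10 cycles")

  # recovery from simulated curves with optical noise
  sim <- simulate_qpcr_dataset(4, "g1", character(0), matrix(0, 4, 1),
                               efficiency = 1.9, noise_sd = 0.1, seed = 2,
                               curve_noise_sd = 0.01)
  effs <- vapply(split(sim$curves, sim$curves$well_id), qpcr_efficiency,
                 numeric(1))
  expect_lt(abs(mean(effs) - 1.9), 0.02)
})

test_that("plate-average efficiency is the arithmetic mean of reactions", {
  expect_equal(plate_mean_efficiency(c(2, 2, 2)), 2)
  expect_equal(plate_mean_efficiency(c(1.8, 2.0)), 1.9)
  expect_equal(plate_mean_efficiency(c(1.8, NA, 2.0)), 1.9)
  expect_error(plate_mean_efficiency(NA_real_), "no finite")
  # estimated plate mean is close to the generative base
  sim <- simulate_qpcr_dataset(6, "g1", character(0), matrix(0, 6, 1),
                               efficiency = 1.85, noise_sd = 0.1, seed = 4,
                               curve_noise_sd = 0.01)
  effs <- vapply(split(sim$curves, sim$curves$well_id), qpcr_efficiency,
                 numeric(1))
  est <- plate_mean_efficiency(effs)
  expect_lt(abs(est - 1.85), 3 * sd(effs) / sqrt(length(effs)) + 0.005)
})

test_that("normalized relative quantities follow the efficiency arithmetic", {
  # no variation at all: every NRQ is 1
  wells <- expand.grid(sample = c("A", "B"), gene = c("t", "r1", "r2"),
                       stringsAsFactors = FALSE)
  wells$cq <- 25
  nrq <- compute_nrq(wells, c("r1", "r2"), efficiency = 2)
  expect_equal(nrq$nrq, rep(1, nrow(nrq)))

  # one cycle earlier at efficiency 2 doubles the target NRQ
  wells$cq[wells$sample == "A" & wells$gene == "t"] <- 24
  nrq <- compute_nrq(wells, c("r1", "r2"), efficiency = 2)
  ratio <- nrq$nrq[nrq$sample == "A" & nrq$gene == "t"] /
    nrq$nrq[nrq$sample == "B" & nrq$gene == "t"]
  expect_equal(ratio, 2)

  # technical replicates are averaged on the Cq scale first: a 24/26 pair
  # averages back to 25, erasing the sample-A advantage
  w2 <- rbind(wells, data.frame(sample = "A", gene = "t", cq = 26))
  nrq2 <- compute_nrq(w2, c("r1", "r2"), efficiency = 2)
  expect_equal(nrq2$nrq[nrq2$sample == "A" & nrq2$gene == "t"],
               nrq2$nrq[nrq2$sample == "B" & nrq2$gene == "t"])
  expect_equal(nrq2$nrq[nrq2$sample == "A" & nrq2$gene == "t"], 1)

  expect_error(compute_nrq(wells[wells$gene != "r1" |
                                   wells$sample != "A", ],
                           c("r1", "r2"), 2), "'A'")
})

test_that("NRQ recovers a known fold change from noisy simulated data", {
  refs <- paste0("ref", 1:5)
  genes <- c(refs, "target")
  n <- 8  # 4 per group
  expr <- cbind(matrix(0, n, 5), rep(c(0, log2(18)), each = 4))
  sim <- simulate_qpcr_dataset(n, genes, refs, expr, efficiency = 2,
                               noise_sd = 0.15, seed = 6)
  nrq <- compute_nrq(sim$wells, refs, efficiency = 2)
  tg <- nrq[nrq$gene == "target", ]
  grp <- rep(c("low", "high"), each = 4)[match(tg$sample,
                                               sprintf("S%02d", 1:n))]
  fc <- exp(mean(log(tg$nrq[grp == "high"])) -
              mean(log(tg$nrq[grp == "low"])))
  expect_lt(abs(fc / 18 - 1), 0.05)
})

test_that("NRQ ratios are invariant to per-sample scaling of RQs", {
  # multiplying one sample's quantities through (a global Cq offset for
  # every gene of that sample) cancels in the normalization factor
  wells <- expand.grid(sample = c("A", "B"), gene = c("t", "r1", "r2"),
                       stringsAsFactors = FALSE)
  wells$cq <- c(24, 25, 25.5, 26, 24.8, 25.2)
  nrq <- compute_nrq(wells, c("r1", "r2"), efficiency = 1.9)
  wells2 <- wells
  off <- 1.7
  wells2$cq[wells2$sample == "A"] <- wells2$cq[wells2$sample == "A"] - off
  nrq2 <- compute_nrq(wells2, c("r1", "r2"), efficiency = 1.9)
  expect_equal(nrq2$nrq, nrq$nrq, tolerance = 1e-12)
})

test_that("geNORM stability behaves per its defining formulas", {
  # perfectly proportional genes: all pairwise log-ratios constant, M = 0
  set.seed(7)
  base <- exp(rnorm(6))
  q <- outer(base, c(1, 2, 0.5, 4))
  colnames(q) <- paste0("g", 1:4)
  gn <- genorm(q)
  expect_equal(unname(gn$M), rep(0, 4))

  # one deliberately destabilized gene has the largest M and leaves first
  q2 <- cbind(q, bad = base * exp(rnorm(6, 0, 1.5)))
  gn2 <- genorm(q2)
  expect_equal(names(which.max(gn2$M)), "bad")
  expect_equal(gn2$ranking[length(gn2$ranking)], "bad")

  # M and the V ladder match a direct spreadsheet-style evaluation
  set.seed(8)
  qq <- matrix(exp(rnorm(24, 0, 0.4)), 6, 4,
               dimnames = list(NULL, paste0("g", 1:4)))
  gn3 <- genorm(qq)
  for (g in colnames(qq)) {
    others <- setdiff(colnames(qq), g)
    m_direct <- mean(sapply(others, function(h) {
      sd(log2(qq[, g] / qq[, h]))
    }))
    expect_equal(unname(gn3$M[g]), m_direct, tolerance = 1e-12)
  }
  for (k in 2:(ncol(qq) - 1)) {
    nf_k <- apply(qq[, gn3$ranking[1:k], drop = FALSE], 1,
                  function(r) prod(r)^(1 / k))
    nf_k1 <- apply(qq[, gn3$ranking[1:(k + 1)], drop = FALSE], 1,
                   function(r) prod(r)^(1 / (k + 1)))
    expect_equal(unname(gn3$V[sprintf("V%d/%d", k, k + 1)]),
                 sd(log2(nf_k / nf_k1)), tolerance = 1e-12)
  }

  expect_error(genorm(q[, 1:2]), ">= 3")
  q_bad <- q; q_bad[1, 1] <- 0
  expect_error(genorm(q_bad), "positive")
})

test_that("mean centring removes batch offsets and keeps group effects", {
  d1 <- expand.grid(sample = paste0("a", 1:4), gene = c("x", "y"),
                    stringsAsFactors = FALSE)
  set.seed(9)
  d1$nrq <- exp(rnorm(8))
  # same data with a constant multiplicative batch offset and new names
  d2 <- d1
  d2$sample <- paste0("b", 1:4)
  d2$nrq <- d1$nrq * exp(1.3)
  comb <- mean_center_combine(list(run1 = d1, run2 = d2))
  v1 <- comb$log_nrq[comb$dataset == "run1"]
  v2 <- comb$log_nrq[comb$dataset == "run2"]
  expect_equal(v1, v2, tolerance = 1e-12)
  # per-gene grand mean is zero
  gm <- tapply(comb$log_nrq, comb$gene, mean)
  expect_equal(as.numeric(gm), c(0, 0), tolerance = 1e-12)

  # a single dataset is simply centred
  c1 <- mean_center_combine(list(d1))
  expect_equal(tapply(c1$log_nrq, c1$gene, mean), tapply(d1$nrq, d1$gene,
               function(x) mean(log(x) - mean(log(x)))), tolerance = 1e-12)

  # group contrasts survive combining across batches
  set.seed(10)
  mk <- function(batch_off, samples) {
    d <- expand.grid(sample = samples, gene = "x", stringsAsFactors = FALSE)
    grp_eff <- ifelse(seq_along(samples) <= length(samples) / 2, 0, 1)
    d$nrq <- exp(grp_eff + batch_off + rnorm(length(samples), 0, 0.05))
    d
  }
  b1 <- mk(0, paste0("s", 1:6)); b2 <- mk(2.5, paste0("t", 1:6))
  cc <- mean_center_combine(list(b1, b2))
  grp <- rep(rep(c("g0", "g1"), each = 3), 2)
  est <- mean(cc$log_nrq[grp == "g1"]) - mean(cc$log_nrq[grp == "g0"])
  expect_lt(abs(est - 1), 0.1)

  d3 <- d1; d3$gene <- sub("y", "z", d3$gene)
  expect_error(mean_center_combine(list(d1, d3)), "same gene set")
  expect_error(mean_center_combine(list(d1, d1)), "disjoint")
})

test_that("ANOVA with LSD matches its textbook identities", {
  # two groups: LSD pairwise p equals the pooled-variance t-test p
  set.seed(11)
  x <- c(rnorm(5), rnorm(6, 1))
  g <- rep(c("a", "b"), c(5, 6))
  res <- anova_lsd(x, g)
  tt <- t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)
  expect_equal(res$pairwise$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$p_omnibus, tt$p.value, tolerance = 1e-12)

  # balanced 3-group case against brute-force ANOVA identities
  y <- c(12.1, 13.4, 12.8, 15.2, 16.1, 15.7, 12.5, 12.9, 13.1)
  gg <- rep(c("A", "B", "C"), each = 3)
  res3 <- anova_lsd(y, gg)
  grand <- mean(y)
  ssb <- sum(3 * (tapply(y, gg, mean) - grand)^2)
  ssw <- sum((y - ave(y, gg))^2)
  F_direct <- (ssb / 2) / (ssw / 6)
  expect_equal(res3$F, F_direct, tolerance = 1e-12)
  expect_equal(res3$p_omnibus, pf(F_direct, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  mse <- ssw / 6
  tAB <- (mean(y[gg == "A"]) - mean(y[gg == "B"])) / sqrt(mse * (2 / 3))
  row <- res3$pairwise[res3$pairwise$group1 %in% c("A", "B") &
                         res3$pairwise$group2 %in% c("A", "B"), ]
  expect_equal(abs(row$t), abs(tAB), tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(-abs(tAB), 6), tolerance = 1e-12)
  # B clearly above A and C: it gets its own letter
  expect_true(res3$letters[["B"]] != res3$letters[["A"]])
  expect_true(res3$letters[["B"]] != res3$letters[["C"]])

  expect_error(anova_lsd(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("protected LSD never separates groups without a significant omnibus test", {
  set.seed(12)
  for (rep_i in 1:10) {
    x <- rnorm(12)
    g <- rep(c("a", "b", "c"), each = 4)
    res <- anova_lsd(x, g)
    if (res$p_omnibus >= 0.05) {
      expect_false(any(res$pairwise$significant))
      expect_true(all(res$letters == res$letters[1]))
    }
  }
})
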