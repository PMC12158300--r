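# Assumption checks, weight-wise tests, BH-FDR and weight ratios.

test_that("assumption checks behave on null and heavy-tailed data", {
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  out <- assumption_checks(a, b)
  expect_length(out$shapiro_p, 2)
  expect_true(out$levene_p > 0 && out$levene_p <= 1)
  expect_error(assumption_checks(rnorm(2), rnorm(50)), "n >= 3")

  # identical groups: no variance difference
  expect_gt(levene_test(list(a, a))$p.value, 0.99)

  # Shapiro-Wilk calibration: ~5% rejections under the null,
  # near-certain rejection for Cauchy-tailed samples (reduced replicate
  # count keeps the suite fast; the acceptance suite runs the full one)
  set.seed(2)
  rej_null <- mean(replicate(300, stats::shapiro.test(rnorm(50))$p.value < 0.05))
  expect_lt(abs(rej_null - 0.05), 0.03)
  rej_t1 <- mean(replicate(100, stats::shapiro.test(rt(50, df = 1))$p.value < 0.05))
  expect_gt(rej_t1, 0.5)
})

test_that("weight-wise t-tests: identical, degenerate and null behavior", {
  set.seed(3)
  w <- matrix(rnorm(10 * 43), 10)
  res <- weightwise_ttests(w, w)
  expect_true(all(res$t_stat == 0))
  expect_true(all(res$p_value == 1))
  expect_equal(res$block[1], "mc")
  expect_equal(res$row[1], "C3")

  a <- matrix(0, 2, 3); b <- matrix(1, 2, 3)
  res2 <- weightwise_ttests(a, b)
  expect_true(all(res2$degenerate))
  expect_true(all(is.na(res2$p_value)))

  # null p-values are uniform
  set.seed(4)
  m <- 4000
  n1 <- matrix(rnorm(30 * m), 30); n2 <- matrix(rnorm(30 * m), 30)
  p <- weightwise_ttests(n1, n2)$p_value
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("weightwise t equals stats::t.test (Welch) per column", {
  set.seed(5)
  a <- matrix(rnorm(12 * 5), 12); b <- matrix(rnorm(15 * 5, 0.5), 15)
  res <- weightwise_ttests(a, b)
  for (j in 1:5) {
    ref <- stats::t.test(a[, j], b[, j])
    expect_equal(res$t_stat[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[j], ref$p.value, tolerance = 1e-12)
  }
})

test_that("BH-FDR matches brute-force step-up enumeration", {
  bh_oracle <- function(p, alpha = 0.05) {
    m <- length(p)
    o <- order(p)
    passes <- which(p[o] <= seq_len(m) * alpha / m)
    rej <- logical(m)
    if (length(passes)) rej[o[seq_len(max(passes))]] <- TRUE
    rej
  }
  expect_true(all(fdr_bh(rep(0.001, 7))$reject))
  empty <- fdr_bh(numeric(0))
  expect_length(empty$q_values, 0)
  expect_length(empty$reject, 0)
  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")

  ref <- fdr_bh(c(0.01, 0.02, 0.04, 0.2))
  expect_equal(ref$reject, bh_oracle(c(0.01, 0.02, 0.04, 0.2)))
  expect_equal(ref$q_values, stats::p.adjust(c(0.01, 0.02, 0.04, 0.2), "BH"))

  # exhaustive small instances: all permutations of several 4-element grids
  grids <- list(c(0.001, 0.012, 0.03, 0.2), c(0.01, 0.02, 0.04, 0.05),
                c(0.5, 0.6, 0.7, 0.8), c(0.012, 0.0125, 0.049, 0.051))
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  for (g in grids) for (i in seq_len(nrow(perms))) {
    p <- g[perms[i, ]]
    out <- fdr_bh(p)
    expect_identical(out$reject, bh_oracle(p))
    expect_equal(out$q_values, stats::p.adjust(p, "BH"))
  }
})

test_that("BH controls the null discovery rate in simulation", {
  set.seed(6)
  frac <- replicate(400, {
    p <- weightwise_ttests(matrix(rnorm(20 * 43), 20),
                           matrix(rnorm(20 * 43), 20))$p_value
    mean(fdr_bh(p)$reject)
  })
  expect_lte(mean(frac), 0.07)
})

test_that("weight ratios are group-mean ratios with sane flags", {
  a <- matrix(1, 10, 4); b <- matrix(1, 10, 4)
  r <- weight_ratio(a, b, mask = c(TRUE, TRUE, FALSE, TRUE), boot = 0)
  expect_equal(r$ratio[1], 1)
  expect_true(is.na(r$ratio[3]))
  a2 <- matrix(0.5, 10, 2); b2 <- matrix(1, 10, 2)
  expect_equal(weight_ratio(a2, b2, c(TRUE, TRUE), boot = 0)$ratio, c(0.5, 0.5))
  b3 <- matrix(0, 10, 2)
  r3 <- weight_ratio(a2, b3, c(TRUE, TRUE), boot = 0)
  expect_true(all(r3$undefined))
  expect_true(all(is.na(r3$ratio)))
})

test_that("the presentation matrices apply the zero-fill convention", {
  cfg <- sim_config(n_sessions = 6, seed = 21)
  fits <- fit_dataset(make_two_class_dataset(cfg))
  conds <- vapply(fits, `[[`, "", "condition")
  rep <- weight_stats_report(fits[conds == "NFT"], fits[conds == "resting"],
                             boot = 100)
  mats <- ratio_presentation_matrix(rep)
  expect_named(mats, c("mc", "loc", "mc_loc", "mnet"))
  nonsig <- rep[!rep$significant, ]
  if (nrow(nonsig) > 0) {
    i <- nonsig[1, ]
    expect_equal(mats[[i$block]][i$row, i$col], 0)
  }
  sig <- rep[rep$significant & !is.na(rep$ratio_nft_over_rest), ]
  if (nrow(sig) > 0) {
    i <- sig[1, ]
    expect_equal(mats[[i$block]][i$row, i$col], i$ratio_nft_over_rest)
  }
})
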