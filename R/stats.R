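# Mass-univariate comparison of transition weights between NFT and
# resting: assumption checks (Shapiro-Wilk, Levene), Welch t-tests per
# linearized weight position, Benjamini-Hochberg FDR control, and
# NFT/resting weight ratios at the significant positions.

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group and Levene's test across groups, flagging
#' violations at the 0.05 level.
#'
#' @param samples_a,samples_b numeric vectors (n >= 3 each).
#' @param alpha flag level (default 0.05).
#' @param center centering statistic for Levene (`"mean"` classical,
#'   `"median"` Brown-Forsythe).
#' @return list with `shapiro_p` (length 2), `levene_p`, and logical
#'   flags `normality_violated`, `variance_violated`.
#' @export
assumption_checks <- function(samples_a, samples_b, alpha = 0.05,
                              center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(samples_a) < 3 || length(samples_b) < 3)
    stopf("assumption_checks needs n >= 3 per group")
  sh <- c(stats::shapiro.test(samples_a)$p.value,
          stats::shapiro.test(samples_b)$p.value)
  lev <- levene_test(list(samples_a, samples_b), center = center)
  list(shapiro_p = sh, levene_p = lev$p.value,
       normality_violated = any(sh < alpha),
       variance_violated = lev$p.value < alpha)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group center.
#'
#' @param groups list of numeric vectors.
#' @param center `"mean"` (classical Levene) or `"median"`
#'   (Brown-Forsythe).
#' @return list with `statistic` (F), `df`, `p.value`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  cfun <- if (center == "mean") mean else stats::median
  z <- lapply(groups, function(g) abs(g - cfun(g)))
  k <- length(z)
  ni <- lengths(z)
  n <- sum(ni)
  zi <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / n
  ss_between <- sum(ni * (zi - zbar)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zi[i])^2), numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  list(statistic = f, df = c(df1, df2),
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Vectorized two-sample t over matrix columns.
col_ttests <- function(a, b, var_equal = FALSE) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  if (var_equal) {
    sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0 | !is.finite(se)
  tstat[degenerate & (ma == mb)] <- 0
  p[degenerate & (ma == mb)] <- 1
  tstat[degenerate & (ma != mb)] <- NA_real_
  p[degenerate & (ma != mb)] <- NA_real_
  list(t = tstat, p = p, df = df, mean_a = ma, mean_b = mb,
       degenerate = degenerate)
}

#' Weight-wise two-sample t-tests
#'
#' Two-tailed independent-sample t-test (Welch by default) at every
#' linearized transition-weight position. Identical groups give t = 0,
#' p = 1; positions with zero variance in both groups and different
#' means are flagged degenerate with undefined p.
#'
#' @param nft_weights,rest_weights matrices with one row per observation
#'   (transition) and 43 columns in the [linearize()] layout.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return data.frame with block, row, col labels, `t_stat`, `p_value`,
#'   `mean_nft`, `mean_rest`, `degenerate`.
#' @export
weightwise_ttests <- function(nft_weights, rest_weights, var_equal = FALSE) {
  nft_weights <- as.matrix(nft_weights)
  rest_weights <- as.matrix(rest_weights)
  if (nrow(nft_weights) < 2 || nrow(rest_weights) < 2)
    stopf("need >= 2 observations per group")
  if (ncol(nft_weights) != ncol(rest_weights))
    stopf("groups must have the same number of weight positions")
  tt <- col_ttests(nft_weights, rest_weights, var_equal)
  lay <- linearize_layout()
  if (ncol(nft_weights) != nrow(lay))
    lay <- data.frame(block = NA_character_, row = NA_character_,
                      col = NA_character_,
                      position = seq_len(ncol(nft_weights)))
  data.frame(lay[, c("block", "row", "col", "position")],
             t_stat = tt$t, p_value = tt$p,
             mean_nft = tt$mean_a, mean_rest = tt$mean_b,
             degenerate = tt$degenerate,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up procedure: q-values are the monotone BH adjustment
#' and the rejection mask marks p_(i) <= i * alpha / m up to the largest
#' such i. NA p-values are passed through as NA and never rejected.
#'
#' @param p_values numeric vector in [0, 1] (NA allowed).
#' @param alpha FDR level (default 0.05).
#' @return list with `q_values` and logical `reject`.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0)
    return(list(q_values = numeric(0), reject = logical(0)))
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(p_values))
  rej <- rep(NA, length(p_values))
  if (m > 0) {
    o <- order(p)
    ranked <- p[o] * m / seq_len(m)
    qs <- rev(cummin(rev(ranked)))
    qs <- pmin(qs, 1)
    qv <- numeric(m)
    qv[o] <- qs
    passes <- which(p[o] <= seq_len(m) * alpha / m)
    cut <- if (length(passes)) max(passes) else 0L
    rj <- logical(m)
    if (cut > 0) rj[o[seq_len(cut)]] <- TRUE
    q[ok] <- qv
    rej[ok] <- rj
  }
  list(q_values = q, reject = rej)
}

#' NFT/resting weight ratios at significant positions
#'
#' Ratio of group means per significant position with a bootstrap
#' confidence interval. Positions whose resting mean is (numerically)
#' zero get an undefined ratio with a flag; non-significant positions
#' are reported as NA here (the zero-fill display convention lives in
#' [ratio_presentation_matrix()]).
#'
#' @param nft_weights,rest_weights observation x position matrices.
#' @param mask logical vector of significant positions.
#' @param boot bootstrap replicates for the CI (default 1000; 0 skips).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @param groups_nft,groups_rest optional grouping labels (e.g. session
#'   ids), one per row; when given the bootstrap resamples whole groups
#'   (cluster bootstrap), which is the correct unit when transitions
#'   within a session are not independent.
#' @return data.frame with `position`, `ratio`, `ci_lo`, `ci_hi`,
#'   `undefined`.
#' @export
weight_ratio <- function(nft_weights, rest_weights, mask,
                         boot = 1000L, conf = 0.95, seed = 1L,
                         groups_nft = NULL, groups_rest = NULL) {
  nft_weights <- as.matrix(nft_weights)
  rest_weights <- as.matrix(rest_weights)
  m <- ncol(nft_weights)
  stopifnot(length(mask) == m)
  ratio <- rep(NA_real_, m)
  lo <- rep(NA_real_, m)
  hi <- rep(NA_real_, m)
  undef <- rep(FALSE, m)
  mn <- colMeans(nft_weights)
  mr <- colMeans(rest_weights)
  eps <- 1e-12
  sel <- which(mask)
  undef[sel] <- abs(mr[sel]) < eps
  ratio[sel] <- ifelse(undef[sel], NA_real_, mn[sel] / mr[sel])
  resampler <- function(w, groups) {
    if (is.null(groups)) {
      function() w[sample(nrow(w), replace = TRUE), , drop = FALSE]
    } else {
      idx <- split(seq_len(nrow(w)), groups)
      function() w[unlist(idx[sample(length(idx), replace = TRUE)]), ,
                   drop = FALSE]
    }
  }
  if (boot > 0 && length(sel) > 0) {
    set.seed(seed)
    draw_nft <- resampler(nft_weights, groups_nft)
    draw_rest <- resampler(rest_weights, groups_rest)
    B <- matrix(NA_real_, boot, m)
    for (b in seq_len(boot)) {
      bm <- colMeans(draw_nft())
      br <- colMeans(draw_rest())
      B[b, sel] <- ifelse(abs(br[sel]) < eps, NA, bm[sel] / br[sel])
    }
    a2 <- (1 - conf) / 2
    lo[sel] <- apply(B[, sel, drop = FALSE], 2, stats::quantile,
                     probs = a2, na.rm = TRUE)
    hi[sel] <- apply(B[, sel, drop = FALSE], 2, stats::quantile,
                     probs = 1 - a2, na.rm = TRUE)
  }
  data.frame(position = seq_len(m), ratio = ratio,
             ci_lo = lo, ci_hi = hi, undefined = undef)
}

#' Complete weight-statistics report for two groups of fits
#'
#' Pools the per-transition linearized weights of each group (one
#' observation per transition per session), runs the weight-wise Welch
#' tests, applies BH-FDR at `alpha`, and attaches ratios at the
#' significant positions.
#'
#' @param fits_nft,fits_rest lists of `pnda_fit`s.
#' @param alpha FDR level.
#' @param boot bootstrap replicates for ratio CIs.
#' @param seed bootstrap seed.
#' @return data.frame combining test results, q-values, significance
#'   flags and ratios.
#' @export
weight_stats_report <- function(fits_nft, fits_rest, alpha = 0.05,
                                boot = 1000L, seed = 1L) {
  W <- function(fits) do.call(rbind, lapply(fits, function(f)
    t(vapply(f$final_transitions, linearize, numeric(43)))))
  G <- function(fits) do.call(c, lapply(seq_along(fits), function(i) {
    gid <- fits[[i]]$session_id
    if (is.null(gid) || is.na(gid)) gid <- as.character(i)
    rep(gid, length(fits[[i]]$final_transitions))
  }))
  wn <- W(fits_nft)
  wr <- W(fits_rest)
  res <- weightwise_ttests(wn, wr)
  bh <- fdr_bh(res$p_value, alpha)
  res$q_value <- bh$q_values
  res$significant <- bh$reject %in% TRUE
  rat <- weight_ratio(wn, wr, res$significant, boot = boot, seed = seed,
                      groups_nft = G(fits_nft), groups_rest = G(fits_rest))
  res$ratio_nft_over_rest <- rat$ratio
  res$ratio_ci_lo <- rat$ci_lo
  res$ratio_ci_hi <- rat$ci_hi
  res
}

#' Figure-ready ratio matrices with the zero-fill convention
#'
#' Returns one matrix per block whose entries are the NFT/resting weight
#' ratios at significant positions and 0 elsewhere (a displayed ratio of
#' 0 marks "no statistical difference").
#'
#' @param report output of [weight_stats_report()].
#' @return named list of matrices (mc, loc, mc_loc, mnet).
#' @export
ratio_presentation_matrix <- function(report) {
  out <- list()
  for (b in BLOCK_NAMES) {
    dims <- TRANS_BLOCK_DIMS[[b]]
    rows <- report[report$block == b, ]
    m <- matrix(0, dims[1], dims[2],
                dimnames = block_dimnames(b, transition = TRUE))
    for (i in seq_len(nrow(rows))) {
      if (isTRUE(rows$significant[i]) && !is.na(rows$ratio_nft_over_rest[i]))
        m[rows$row[i], rows$col[i]] <- rows$ratio_nft_over_rest[i]
    }
    out[[b]] <- m
  }
  out
}
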