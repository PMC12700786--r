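#' Configuration for the permutation inference engine
#'
#' @param alpha significance threshold (top 5% of the permutation
#'   distribution by default).
#' @param n_permutations Monte-Carlo iterations (default 10000).
#' @param mcs_p cluster-correction p-value: significant clusters exceed
#'   the `1 - mcs_p` (99.9th) percentile of the null maximum-cluster-size
#'   distribution.
#' @param fdr_alpha Benjamini-Hochberg false-discovery-rate level.
#' @param seed optional RNG seed recorded in every result.
#' @return A list of class `StatsConfig`.
#' @export
stats_config <- function(alpha = 0.05, n_permutations = 10000,
                         mcs_p = 0.001, fdr_alpha = 0.05, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100)
  structure(list(alpha = alpha, n_permutations = n_permutations,
                 mcs_p = mcs_p, fdr_alpha = fdr_alpha, seed = seed),
            class = "StatsConfig")
}

.with_cfg_seed <- function(cfg, code) {
  if (is.null(cfg$seed)) code else withr::with_seed(cfg$seed, code)
}

.stat_result <- function(statistic, df, p_mc, n_perm, tails, cfg,
                         flag = NULL) {
  structure(list(statistic = statistic, df = df, p_mc = p_mc,
                 n_permutations_used = n_perm, tails = tails,
                 seed = cfg$seed, flag = flag),
            class = "StatResult")
}

#' Monte-Carlo permutation paired t-test
#'
#' Computes the observed paired t statistic and builds its null by random
#' sign-flips of the within-pair differences (equivalent to permuting the
#' condition affiliation within each pair). The two-sided Monte-Carlo
#' p-value is the proportion of permuted `|t|` at or above the observed
#' `|t|`, counting the observed labelling itself, so `p >= 1/(n_perm+1)`.
#'
#' @param x,y paired samples of equal length `n >= 2`.
#' @param cfg a `StatsConfig`.
#' @return A `StatResult` with `statistic` (t), `df = n - 1`, `p_mc`.
#' @export
perm_ttest_paired <- function(x, y, cfg = stats_config()) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  ss <- sum(d^2)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(.stat_result(if (mean(d) == 0) 0 else NA_real_, n - 1, 1,
                        0L, "two-sided", cfg,
                        flag = "zero-variance differences"))
  }
  t_obs <- mean(d) / (sd_d / sqrt(n))
  n_perm <- cfg$n_permutations
  p <- .with_cfg_seed(cfg, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    m <- as.vector(signs %*% d) / n
    varp <- (ss - n * m^2) / (n - 1)            # sum(d^2) is flip-invariant
    t_perm <- m / sqrt(varp / n)
    t_perm[varp <= 0] <- Inf
    (sum(abs(t_perm) >= abs(t_obs) - 1e-12) + 1) / (n_perm + 1)
  })
  .stat_result(t_obs, n - 1, p, n_perm, "two-sided", cfg)
}

# all n! permutations of 1..n as a matrix (rows); n <= 8 in practice
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlation with exact or Monte-Carlo permutation p-value
#'
#' The coefficient is Spearman's rho on average ranks. For `n <= 8` the
#' two-sided p-value is exact: all `n!` orderings of `y` are enumerated
#' and `p` is the proportion with `|rho|` at or above the observed value
#' (the identity ordering is one of them, so exact p is a multiple of
#' `1/n!`). For larger `n`, `cfg$n_permutations` random orderings are
#' drawn and the observed ordering is counted into the null.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; neither constant.
#' @param cfg a `StatsConfig`.
#' @param exact_n_max maximal `n` for full enumeration (default 8).
#' @return A list of class `CorrelationResult`: `rho`, `p`, `n`, `exact`.
#' @export
perm_spearman <- function(x, y, cfg = stats_config(), exact_n_max = 8) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  rho_of <- function(perm_mat) {           # rows = permutations of y
    as.vector(perm_mat %*% rxc) / denom
  }
  if (n <= exact_n_max) {
    perms <- .permutations(n)
    ryp <- matrix(ryc[perms], nrow(perms), n)
    rho_all <- rho_of(ryp)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    exact <- TRUE
    n_used <- nrow(perms)
  } else {
    n_perm <- cfg$n_permutations
    p <- .with_cfg_seed(cfg, {
      rho_perm <- vapply(seq_len(n_perm), function(i)
        sum(rxc * ryc[sample.int(n)]) / denom, numeric(1))
      (sum(abs(rho_perm) >= abs(rho) - 1e-12) + 1) / (n_perm + 1)
    })
    exact <- FALSE
    n_used <- n_perm
  }
  structure(list(rho = rho, p = p, n = n, exact = exact,
                 n_permutations_used = n_used),
            class = "CorrelationResult")
}

# ---- permutation ANOVA ------------------------------------------------

# sum-contrast columns for a factor
.fac_cols <- function(f) {
  f <- as.factor(f)
  if (nlevels(f) < 2L) stop("factor with fewer than 2 levels")
  stats::contr.sum(nlevels(f))[as.integer(f), , drop = FALSE]
}

# row-wise Khatri-Rao product of a list of column blocks
.kr_prod <- function(blocks) {
  out <- blocks[[1]]
  for (b in blocks[-1]) {
    p <- ncol(out); q <- ncol(b)
    out <- out[, rep(seq_len(p), each = q), drop = FALSE] *
      b[, rep(seq_len(q), times = p), drop = FALSE]
  }
  out
}

.rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Monte-Carlo permutation multi-way ANOVA
#'
#' Fixed-effects ANOVA over all main effects and interactions of the
#' supplied factors, with Type II sums of squares (each effect is tested
#' against the model containing every effect that does not contain it,
#' which reduces to the textbook decomposition for balanced designs and
#' stays interpretable under hemisphere imbalance). For each effect the
#' null is built by randomly permuting the tested factor's labels — for an
#' interaction, by permuting the first-listed factor's labels within the
#' cells of the other factors in that interaction — and recomputing the
#' effect's F over `cfg$n_permutations` iterations.
#'
#' @param y numeric response.
#' @param factors data frame of factors aligned with `y`.
#' @param cfg a `StatsConfig`.
#' @param max_order highest interaction order to include (default: all).
#' @return A named list of `StatResult`s, one per effect (names like
#'   `"Condition"`, `"Condition:Frequency"`).
#' @export
perm_anova <- function(y, factors, cfg = stats_config(),
                       max_order = ncol(factors)) {
  factors <- as.data.frame(lapply(factors, as.factor))
  if (nrow(factors) != length(y)) stop("factor table not aligned with y")
  fnames <- names(factors)
  if (any(table(interaction(factors, drop = FALSE)) == 0))
    stop("empty design cell")
  effects <- unlist(lapply(seq_len(max_order), function(k)
    utils::combn(fnames, k, simplify = FALSE)), recursive = FALSE)
  enames <- vapply(effects, paste, "", collapse = ":")

  fcols <- lapply(factors, .fac_cols)
  blocks_for <- function(cols) lapply(effects, function(e)
    .kr_prod(cols[e]))
  blocks <- blocks_for(fcols)
  n <- length(y)
  X_full <- cbind(1, do.call(cbind, blocks))
  if (qr(X_full)$rank < ncol(X_full)) stop("collinear design")
  df_res <- n - ncol(X_full)
  if (df_res < 1L) stop("no residual degrees of freedom")
  rss_full <- .rss(X_full, y)
  mse <- rss_full / df_res

  f_of <- function(blks, e_idx, keep, rss1 = NULL) {
    X1 <- cbind(1, do.call(cbind, blks[keep]))
    if (is.null(rss1)) rss1 <- .rss(X1, y)
    X2 <- cbind(X1, blks[[e_idx]])
    ss <- rss1 - .rss(X2, y)
    (ss / ncol(blks[[e_idx]])) / mse
  }

  res <- vector("list", length(effects))
  names(res) <- enames
  n_perm <- cfg$n_permutations
  .with_cfg_seed(cfg, {
    for (i in seq_along(effects)) {
      e <- effects[[i]]
      keep <- which(vapply(effects, function(o)
        !all(e %in% o), logical(1)))          # Type II: effects w/o e
      f_obs <- f_of(blocks, i, keep)
      pf <- e[1]                              # permuted factor
      touched <- vapply(effects, function(o) pf %in% o, logical(1))
      # the reduced model is permutation-invariant unless a kept effect
      # involves the permuted factor (only happens for interactions)
      rss1_fixed <- if (!any(touched[keep]))
        .rss(cbind(1, do.call(cbind, blocks[keep])), y) else NULL
      strata <- if (length(e) > 1L)
        interaction(factors[e[-1]], drop = TRUE) else factor(rep(1, n))
      idx_by_stratum <- split(seq_len(n), strata)
      count <- 0L
      for (it in seq_len(n_perm)) {
        perm <- seq_len(n)
        for (s in idx_by_stratum) perm[s] <- s[sample.int(length(s))]
        cols_p <- fcols
        cols_p[[pf]] <- fcols[[pf]][perm, , drop = FALSE]
        blks_p <- blocks
        blks_p[touched] <- lapply(effects[touched], function(o)
          .kr_prod(cols_p[o]))
        if (f_of(blks_p, i, keep, rss1_fixed) >= f_obs - 1e-12)
          count <- count + 1L
      }
      # permuted-F null uses the full-model MSE from the observed fit;
      # the observed labelling is counted into the null
      res[[i]] <- .stat_result(f_obs, c(ncol(blocks[[i]]), df_res),
                               (count + 1) / (n_perm + 1), n_perm,
                               "upper", cfg)
    }
  })
  res
}

#' Permutation post-hoc pairwise comparisons
#'
#' For each requested pair of cells of an effect, the observed difference
#' of cell means is compared with a null built by shuffling the cell
#' membership of the two cells' pooled observations (`cfg$n_permutations`
#' iterations, two-sided). All p-values are returned unadjusted so they
#' can enter one FDR family together with the omnibus tests.
#'
#' @param y numeric response.
#' @param factors data frame of factors aligned with `y`.
#' @param effect character vector of factor names defining the cells.
#' @param cfg a `StatsConfig`.
#' @param pairs optional 2-column character matrix of cell labels to
#'   compare (default: all pairs).
#' @return A data frame with `cell_a`, `cell_b`, `difference`, `p_mc`.
#' @export
perm_posthoc <- function(y, factors, effect, cfg = stats_config(),
                         pairs = NULL) {
  cells <- interaction(as.data.frame(factors)[effect], drop = TRUE,
                       sep = ":")
  sizes <- table(cells)
  if (any(sizes < 2L)) stop("post-hoc cell with fewer than 2 observations")
  levs <- levels(cells)
  if (is.null(pairs))
    pairs <- t(utils::combn(levs, 2))
  n_perm <- cfg$n_permutations
  out <- .with_cfg_seed(cfg, {
    rows <- lapply(seq_len(nrow(pairs)), function(r) {
      a <- y[cells == pairs[r, 1]]
      b <- y[cells == pairs[r, 2]]
      d_obs <- mean(a) - mean(b)
      pool <- c(a, b)
      na <- length(a)
      d_perm <- vapply(seq_len(n_perm), function(i) {
        g <- sample.int(length(pool), na)
        mean(pool[g]) - mean(pool[-g])
      }, numeric(1))
      p <- (sum(abs(d_perm) >= abs(d_obs) - 1e-12) + 1) / (n_perm + 1)
      data.frame(cell_a = pairs[r, 1], cell_b = pairs[r, 2],
                 difference = d_obs, p_mc = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Classic step-up procedure: with ordered p-values `p_(1) <= ... <=
#' p_(m)`, reject all hypotheses up to the largest `i` with
#' `p_(i) <= i * q / m`. Adjusted p-values are the usual monotone
#' `min_k>=i (m/k) p_(k)` capped at 1.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A list with `rejected` (logical, original order) and
#'   `adjusted` (numeric).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  m <- length(pvals)
  if (!m) stop("empty p-value vector")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  o <- order(pvals)
  ps <- pvals[o]
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  thresh_ok <- ps <= seq_len(m) * q / m
  rejected <- rep(FALSE, m)
  if (any(thresh_ok)) {
    k <- max(which(thresh_ok))
    rejected[o[seq_len(k)]] <- TRUE
  }
  list(rejected = rejected, adjusted = adjusted)
}

#' Cluster-based Monte-Carlo multiple-comparison correction
#'
#' Binarizes an ordered p-value series at `cfg$alpha`, identifies maximal
#' runs of significant windows (clusters, measured by run length), then
#' shuffles the binarized sequence `cfg$n_permutations` times, recording
#' the maximum run length of each shuffle. Clusters whose size exceeds
#' the `1 - cfg$mcs_p` (99.9th) percentile of that null distribution are
#' flagged significant.
#'
#' @param pvals ordered p-value series (one per time window), length >= 2.
#' @param cfg a `StatsConfig`.
#' @return A list of class `ClusterResult`: `clusters` (data frame with
#'   `start`, `end`, `size`, `significant`), `null_max_sizes`,
#'   `threshold_size`, `alpha`, `mcs_p`.
#' @export
cluster_mcs <- function(pvals, cfg = stats_config()) {
  if (length(pvals) < 2L) stop("p-value series shorter than 2")
  b <- pvals < cfg$alpha
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  clusters <- data.frame(start = starts[keep], end = ends[keep],
                         size = r$lengths[keep])
  null_max <- .with_cfg_seed(cfg, {
    vapply(seq_len(cfg$n_permutations), function(i) {
      rp <- rle(sample(b))
      mx <- rp$lengths[rp$values]
      if (length(mx)) max(mx) else 0L
    }, integer(1))
  })
  threshold <- as.integer(stats::quantile(null_max, 1 - cfg$mcs_p,
                                          type = 1))
  clusters$significant <- clusters$size > threshold
  structure(list(clusters = clusters, null_max_sizes = null_max,
                 threshold_size = threshold, alpha = cfg$alpha,
                 mcs_p = cfg$mcs_p),
            class = "ClusterResult")
}

#' Linear trend regression
#'
#' Ordinary least squares `v = a + b t` with the model F statistic on
#' `df = (1, n - 2)`, adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - 2)` (which can print as a signed zero when
#' F is 0), and a Monte-Carlo permutation p-value obtained by permuting
#' `v` against `t`.
#'
#' @param t predictor (time), not constant.
#' @param v response.
#' @param cfg a `StatsConfig`.
#' @return A list of class `TrendResult`: `slope`, `intercept`, `F`,
#'   `df`, `r2`, `r2_adjusted`, `p_mc`, `n`.
#' @export
linreg_trend <- function(t, v, cfg = stats_config()) {
  n <- length(t)
  if (length(v) != n) stop("t and v must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(t) == 0) stop("constant predictor")
  tc <- t - mean(t); vc <- v - mean(v)
  slope <- sum(tc * vc) / sum(tc^2)
  intercept <- mean(v) - slope * mean(t)
  ss_tot <- sum(vc^2)
  ss_mod <- slope^2 * sum(tc^2)
  ss_res <- ss_tot - ss_mod
  r2 <- if (ss_tot > 0) ss_mod / ss_tot else 0
  f <- if (ss_res > 0) ss_mod / (ss_res / (n - 2)) else Inf
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  n_perm <- cfg$n_permutations
  p <- .with_cfg_seed(cfg, {
    r2_perm <- vapply(seq_len(n_perm), function(i) {
      s <- sum(tc * vc[sample.int(n)])
      s^2 / (sum(tc^2) * ss_tot)
    }, numeric(1))
    (sum(r2_perm >= r2 - 1e-15) + 1) / (n_perm + 1)
  })
  structure(list(slope = slope, intercept = intercept, F = f,
                 df = c(1, n - 2), r2 = r2, r2_adjusted = r2_adj,
                 p_mc = p, n = n),
            class = "TrendResult")
}

#' Shapiro-Wilk normality diagnostic
#'
#' Reported descriptively alongside the permutation tests (inference
#' never branches on it: permutation tests are used throughout).
#'
#' @param x numeric sample, `3 <= n <= 5000`.
#' @return A list with `W`, `p`, `normal` (`p > 0.05`).
#' @export
shapiro_gate <- function(x) {
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, normal = sw$p.value > 0.05)
}
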