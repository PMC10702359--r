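# Causal estimators for two-sample MR on harmonized summary statistics:
# Wald ratio, inverse-variance weighted (multiplicative random effects),
# MR-Egger, weighted median, weighted mode, and MR-PRESSO.
#
# Throughout, per-SNP ratio estimates use first-order weights: the ratio
# theta_j = beta_out_j / beta_exp_j has approximate standard error
# se_out_j / |beta_exp_j|, so inverse-variance weights are
# beta_exp_j^2 / se_out_j^2.

.Z975 <- stats::qnorm(0.975)

mr_result <- function(method, beta, se, pval, n_snp, df = NULL,
                      extras = list()) {
  mult <- if (is.null(df)) .Z975 else stats::qt(0.975, df)
  ci_low <- beta - mult * se
  ci_high <- beta + mult * se
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high,
                 or_value = exp(beta), or_ci_low = exp(ci_low),
                 or_ci_high = exp(ci_high), pval = pval,
                 n_snp = as.integer(n_snp), extras = extras),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta %.4f (se %.4f), OR %.3f [%.3f, %.3f], p %.3g, %d SNP(s)\n",
              x$method, x$beta, x$se, x$or_value, x$or_ci_low, x$or_ci_high,
              x$pval, x$n_snp))
  invisible(x)
}

# Extract aligned effect vectors (sorted by rsid for order invariance of
# every seeded procedure).
.hset_vectors <- function(hset) {
  s <- if (inherits(hset, "harmonized_set")) hset$snps else hset
  s <- s[order(s$rsid), , drop = FALSE]
  list(rsid = s$rsid, bx = s$beta_exp, sx = s$se_exp,
       by = s$beta_out, sy = s$se_out)
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_out / beta_exp` with first-order delta-method standard
#' error `se_out / |beta_exp|`; two-sided normal p.
#'
#' @param hset a 1-SNP `harmonized_set` (or a `data.frame` of harmonized
#'   tuples with one row).
#' @return an `mr_result`.
#' @export
wald_ratio <- function(hset) {
  v <- .hset_vectors(hset)
  stopifnot(length(v$bx) == 1L)
  if (v$bx == 0) stop("Wald ratio undefined: exposure effect is zero")
  beta <- v$by / v$bx
  se <- v$sy / abs(v$bx)
  mr_result("wald_ratio", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

#' Inverse-variance weighted estimate
#'
#' The precision-weighted mean of per-SNP Wald ratios, algebraically
#' identical to the weighted-least-squares slope of `beta_out` on
#' `beta_exp` through the origin with weights `1/se_out^2`. The standard
#' error uses multiplicative random effects: the fixed-effect standard
#' error `1/sqrt(sum(w))` inflated by `max(1, sqrt(Q/(J-1)))` with Q the
#' fixed-effect Cochran heterogeneity statistic (`model = "fe"` disables
#' the inflation). Normal-theory p and CI.
#'
#' @param hset a `harmonized_set` with at least 2 SNPs.
#' @param model `"mre"` (multiplicative random effects, default) or
#'   `"fe"`.
#' @return an `mr_result`; `extras` carries `q_stat`, `q_df`, `phi`.
#' @export
ivw <- function(hset, model = c("mre", "fe")) {
  model <- match.arg(model)
  v <- .hset_vectors(hset)
  J <- length(v$bx)
  if (J < 2L) stop("IVW requires at least 2 SNPs; use wald_ratio()")
  w <- v$bx^2 / v$sy^2
  theta <- v$by / v$bx
  beta <- sum(w * theta) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  q <- sum(w * (theta - beta)^2)
  phi <- if (model == "mre") max(1, sqrt(q / (J - 1))) else 1
  se <- se_fe * phi
  mr_result("ivw", beta, se, 2 * stats::pnorm(-abs(beta / se)), J,
            extras = list(q_stat = q, q_df = J - 1, phi = phi,
                          model = model))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects
#' *with* a free intercept (weights `1/se_out^2`), after orienting every
#' exposure effect to be non-negative (flipping the sign of both betas
#' of any SNP with a negative exposure effect, which the intercept's
#' interpretation requires). The slope is the causal estimate; a nonzero
#' intercept indicates directional horizontal pleiotropy. Inference uses
#' a t distribution with J-2 df and multiplicative residual inflation
#' bounded below by 1.
#'
#' @param hset a `harmonized_set` with at least 3 SNPs.
#' @return an `mr_result`; `extras` carries `intercept`, `intercept_se`,
#'   `intercept_p`, `sigma` (residual scale before the lower bound).
#' @export
egger <- function(hset) {
  v <- .hset_vectors(hset)
  J <- length(v$bx)
  if (J < 3L) stop("MR-Egger requires at least 3 SNPs")
  flip <- sign(v$bx)
  flip[flip == 0] <- 1
  bx <- v$bx * flip
  by <- v$by * flip
  w <- 1 / v$sy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  V0 <- solve(XtWX)
  coef <- unname(drop(V0 %*% crossprod(X, w * by)))
  resid <- by - drop(X %*% coef)
  sigma2 <- sum(w * resid^2) / (J - 2)
  # slope: residual inflation bounded below by 1 (conservative under
  # under-dispersion); intercept: plain weighted-lm t-test, which is
  # exactly t(J-2)-calibrated under the no-pleiotropy null
  se <- unname(sqrt(diag(V0) * c(sigma2, max(1, sigma2))))
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df = J - 2)
  mr_result("egger", coef[2], se[2], pval[2], J, df = J - 2,
            extras = list(intercept = coef[1], intercept_se = se[1],
                          intercept_p = pval[1], sigma = sqrt(sigma2)))
}

# Weighted median of order statistics: linear interpolation of the
# ordered theta at cumulative weight 0.5 (midpoint convention).
.weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(theta[1])
  if (0.5 >= cw[length(cw)]) return(theta[length(theta)])
  stats::approx(cw, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' Consistent when at least half the total instrument weight comes from
#' valid instruments. Ratio estimates are ordered and the estimate is
#' interpolated at cumulative weight 0.5; the standard error comes from
#' a parametric bootstrap resampling each ratio from
#' `N(theta_j, se_j^2)` under a fixed seed.
#'
#' @param hset a `harmonized_set` with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 5000; 0 skips the
#'   bootstrap and returns `NA` se/p, for point-estimate-only studies).
#' @param seed bootstrap RNG seed.
#' @return an `mr_result`.
#' @export
weighted_median <- function(hset, n_boot = 5000, seed = 42L) {
  v <- .hset_vectors(hset)
  J <- length(v$bx)
  if (J < 3L) stop("weighted median requires at least 3 SNPs")
  theta <- v$by / v$bx
  se_ratio <- v$sy / abs(v$bx)
  w <- 1 / se_ratio^2
  beta <- .weighted_median_point(theta, w)
  if (n_boot <= 0) {
    return(mr_result("weighted_median", beta, NA_real_, NA_real_, J))
  }
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(n_boot * J, mean = theta, sd = se_ratio),
                    nrow = n_boot, byrow = TRUE)
    apply(draws, 1L, .weighted_median_point, w = w)
  })
  se <- stats::sd(boots)
  mr_result("weighted_median", beta, se,
            2 * stats::pnorm(-abs(beta / se)), J)
}

# Kernel-density mode of the ratio estimates. The maximum of a Gaussian
# mixture lies within the convex hull of its means, so a fine grid over
# [min(theta), max(theta)] brackets it; a local optimize() refines.
.weighted_mode_point <- function(theta, w, h, n_grid = 2048, refine = TRUE) {
  if (h <= 0 || diff(range(theta)) == 0) {
    return(sum(w * theta) / sum(w))
  }
  grid <- seq(min(theta), max(theta), length.out = n_grid)
  dens <- function(x) {
    vapply(x, function(xx) sum(w * stats::dnorm(xx, theta, h)), numeric(1))
  }
  d <- colSums(w * stats::dnorm(outer(theta, grid, function(a, b) b - a) /
                                  h) / h)
  i <- which.max(d)
  if (!refine) return(grid[i])
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  if (lo == hi) return(grid[i])
  stats::optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted mode estimate
#'
#' Consistent when the largest cluster of instruments (by weight) is
#' valid. Ratio estimates are smoothed with an inverse-variance-weighted
#' Gaussian kernel whose bandwidth is `bandwidth_factor` times the
#' median absolute pairwise deviation of the ratios; the estimate is the
#' density mode. Standard error by parametric bootstrap as in
#' [weighted_median()].
#'
#' @param hset a `harmonized_set` with at least 3 SNPs.
#' @param bandwidth_factor kernel bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 5000; 0 skips).
#' @param seed bootstrap RNG seed.
#' @return an `mr_result`.
#' @export
weighted_mode <- function(hset, bandwidth_factor = 1, n_boot = 5000,
                          seed = 42L) {
  v <- .hset_vectors(hset)
  J <- length(v$bx)
  if (J < 3L) stop("weighted mode requires at least 3 SNPs")
  theta <- v$by / v$bx
  se_ratio <- v$sy / abs(v$bx)
  w <- 1 / se_ratio^2
  w <- w / sum(w)
  pd <- abs(outer(theta, theta, "-"))
  s <- stats::median(pd[lower.tri(pd)])
  h <- bandwidth_factor * s
  beta <- .weighted_mode_point(theta, w, h)
  if (n_boot <= 0) {
    return(mr_result("weighted_mode", beta, NA_real_, NA_real_, J,
                     extras = list(bandwidth = h)))
  }
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(n_boot * J, mean = theta, sd = se_ratio),
                    nrow = n_boot, byrow = TRUE)
    apply(draws, 1L, function(th)
      .weighted_mode_point(th, w, h, n_grid = 512, refine = FALSE))
  })
  se <- stats::sd(boots)
  mr_result("weighted_mode", beta, se,
            2 * stats::pnorm(-abs(beta / se)), J,
            extras = list(bandwidth = h))
}

# Leave-one-out fixed-effect IVW estimates, vectorized. `wiv` are the
# first-order IVW weights and `theta` the ratios; returns the J-vector
# of estimates each omitting one SNP.
.loo_ivw <- function(theta, wiv) {
  s1 <- sum(wiv * theta)
  s0 <- sum(wiv)
  (s1 - wiv * theta) / (s0 - wiv)
}

# One PRESSO residual-sum evaluation: observed (or simulated) effects
# against leave-one-out predictions. Returns per-SNP weighted squared
# residuals.
.presso_residuals <- function(bx, by, sy) {
  wiv <- bx^2 / sy^2
  theta <- by / bx
  loo <- .loo_ivw(theta, wiv)
  (1 / sy^2) * (by - loo * bx)^2
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed residual sum of squares against
#' leave-one-out IVW predictions is compared with its parametric-
#' simulation distribution (`beta_X* ~ N(beta_X, se_exp^2)`,
#' `beta_Y* ~ N(loo_estimate * beta_X, se_out^2)`); the global p is the
#' fraction of simulated sums at least as large. Outlier test: per-SNP
#' simulated residual contributions give per-SNP p-values, Bonferroni-
#' adjusted across instruments. While the global test rejects at 0.05
#' and adjusted outliers below `outlier_p` remain (and at least 4 SNPs
#' survive), the SNP with the smallest outlier p is removed and the
#' tests recomputed -- removal is strictly one-at-a-time in ascending
#' outlier-p order. Distortion test: the difference between pre- and
#' post-removal IVW estimates is compared with the differences obtained
#' by removing equally many randomly chosen SNPs.
#'
#' @param hset a `harmonized_set` with at least 4 SNPs.
#' @param n_sim simulation replicates for the global/outlier tests
#'   (default 1000).
#' @param seed RNG seed (default 42).
#' @param outlier_p threshold on the Bonferroni-adjusted outlier p
#'   (default 0.05).
#' @param n_perm permutations for the distortion test (default 1000).
#' @return an `mr_result` (method `presso_corrected`: IVW on the
#'   retained SNPs); `extras` carries `global_p` (initial), `global_p_final`,
#'   `outliers` (rsids in removal order), `outlier_p_table`,
#'   `distortion_p` (`NA` when nothing was removed), and `n_removed`.
#' @export
mr_presso <- function(hset, n_sim = 1000, seed = 42L, outlier_p = 0.05,
                      n_perm = 1000) {
  v <- .hset_vectors(hset)
  if (length(v$bx) < 4L) stop("insufficient instruments for PRESSO (need >= 4)")
  full <- ivw(hset)
  with_seed(seed, {
    rsid <- v$rsid; bx <- v$bx; sx <- v$sx; by <- v$by; sy <- v$sy
    removed <- character(0)
    global_p_initial <- NA_real_
    outlier_table <- NULL
    repeat {
      J <- length(bx)
      res_obs <- .presso_residuals(bx, by, sy)
      rss_obs <- sum(res_obs)
      # simulate the null residual distribution
      wiv <- bx^2 / sy^2
      loo <- .loo_ivw(by / bx, wiv)
      BX <- matrix(stats::rnorm(n_sim * J, mean = rep(bx, each = n_sim),
                                sd = rep(sx, each = n_sim)), nrow = n_sim)
      BY <- matrix(stats::rnorm(n_sim * J, mean = rep(loo * bx, each = n_sim),
                                sd = rep(sy, each = n_sim)), nrow = n_sim)
      WIV <- sweep(BX^2, 2L, sy^2, "/")
      TH <- BY / BX
      S1 <- rowSums(WIV * TH)
      S0 <- rowSums(WIV)
      LOO <- (S1 - WIV * TH) / (S0 - WIV)
      RES <- sweep((BY - LOO * BX)^2, 2L, sy^2, "/")
      RSS <- rowSums(RES)
      global_p <- mean(RSS >= rss_obs)
      out_p_raw <- colMeans(sweep(RES, 2L, res_obs, ">="))
      out_p <- pmin(1, out_p_raw * J)
      tab <- data.frame(rsid = rsid, p_raw = out_p_raw, p_adj = out_p,
                        stringsAsFactors = FALSE)
      if (is.na(global_p_initial)) {
        global_p_initial <- global_p
        outlier_table <- tab
      }
      global_p_final <- global_p
      candidate <- which(out_p < outlier_p)
      if (global_p >= 0.05 || length(candidate) == 0L || J <= 4L) break
      # ascending outlier p; ties (common at simulated p = 0) broken by
      # the largest observed residual contribution
      worst <- candidate[order(out_p[candidate],
                               -res_obs[candidate])][1L]
      removed <- c(removed, rsid[worst])
      keep <- -worst
      rsid <- rsid[keep]; bx <- bx[keep]; sx <- sx[keep]
      by <- by[keep]; sy <- sy[keep]
    }
    corrected <- ivw(harmonized_set(bx, sx, by, sy, rsid = rsid,
                                    exposure_id = hset$exposure_id,
                                    outcome_id = hset$outcome_id))
    distortion_p <- NA_real_
    if (length(removed) > 0) {
      d_obs <- corrected$beta - full$beta
      Jf <- length(v$bx)
      k <- length(removed)
      d_perm <- replicate(n_perm, {
        drop_idx <- sample.int(Jf, k)
        sub <- ivw(harmonized_set(v$bx[-drop_idx], v$sx[-drop_idx],
                                  v$by[-drop_idx], v$sy[-drop_idx],
                                  rsid = v$rsid[-drop_idx]))
        sub$beta - full$beta
      })
      distortion_p <- mean(abs(d_perm) >= abs(d_obs))
    }
    mr_result("presso_corrected", corrected$beta, corrected$se,
              corrected$pval, corrected$n_snp,
              extras = list(global_p = global_p_initial,
                            global_p_final = global_p_final,
                            outliers = removed,
                            outlier_p_table = outlier_table,
                            distortion_p = distortion_p,
                            n_removed = length(removed),
                            uncorrected_beta = full$beta))
  })
}

#' Run every applicable estimator on a harmonized set
#'
#' One instrument: Wald ratio only. Two: IVW only. Three or more adds
#' MR-Egger, weighted median and weighted mode; four or more adds
#' MR-PRESSO. The IVW result (Wald ratio when only one instrument
#' exists) is flagged as the primary analysis.
#'
#' @param hset a `harmonized_set`.
#' @param config list: `n_boot` (5000), `n_sim_presso` (1000),
#'   `presso_outlier_p` (0.05), `seed` (42), `ivw_model` ("mre"),
#'   `bandwidth_factor` (1).
#' @return list of `mr_result`s, each with a `primary` flag; an empty
#'   set returns a skip record (`list(skipped = TRUE, reason = ...)`).
#' @export
run_all_estimators <- function(hset, config = list()) {
  cfg <- utils::modifyList(list(n_boot = 5000, n_sim_presso = 1000,
                                presso_outlier_p = 0.05, seed = 42L,
                                ivw_model = "mre", bandwidth_factor = 1),
                           config)
  J <- nrow(hset$snps)
  if (J == 0L) {
    return(structure(list(skipped = TRUE, reason = "no instruments"),
                     class = "mr_skip"))
  }
  results <- list()
  if (J == 1L) {
    r <- wald_ratio(hset)
    r$primary <- TRUE
    return(list(r))
  }
  r <- ivw(hset, model = cfg$ivw_model)
  r$primary <- TRUE
  results[[length(results) + 1L]] <- r
  if (J >= 3L) {
    for (fn in list(
      function() egger(hset),
      function() weighted_median(hset, n_boot = cfg$n_boot,
                                 seed = cfg$seed),
      function() weighted_mode(hset, bandwidth_factor = cfg$bandwidth_factor,
                               n_boot = cfg$n_boot, seed = cfg$seed))) {
      r <- fn()
      r$primary <- FALSE
      results[[length(results) + 1L]] <- r
    }
  }
  if (J >= 4L) {
    r <- mr_presso(hset, n_sim = cfg$n_sim_presso, seed = cfg$seed,
                   outlier_p = cfg$presso_outlier_p)
    r$primary <- FALSE
    results[[length(results) + 1L]] <- r
  }
  results
}
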