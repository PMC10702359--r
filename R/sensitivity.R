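# Heterogeneity and pleiotropy diagnostics: Cochran's Q, the MR-Egger
# intercept test, and leave-one-out re-estimation.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (theta_j - theta_FE)^2` over per-SNP ratio estimates,
#' with fixed-effect IVW weights (Q's chi-square null requires the
#' fixed-effect weighting even when the headline IVW is random-effects);
#' p from chi-square with J-1 df.
#'
#' @param hset a `harmonized_set` with at least 2 SNPs.
#' @return list `(q_stat, q_df, q_pval)`.
#' @export
cochran_q <- function(hset) {
  fe <- ivw(hset, model = "fe")
  q <- fe$extras$q_stat
  df <- fe$extras$q_df
  list(q_stat = q, q_df = df,
       q_pval = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression estimates the average direct
#' (pleiotropic) effect of the instruments on the outcome; a two-sided
#' t(J-2) p below 0.05 flags horizontal pleiotropy.
#'
#' @param hset a `harmonized_set` with at least 3 SNPs.
#' @return list `(intercept, intercept_se, intercept_p,
#'   pleiotropy_detected)`.
#' @export
egger_intercept_test <- function(hset) {
  e <- egger(hset)
  list(intercept = e$extras$intercept,
       intercept_se = e$extras$intercept_se,
       intercept_p = e$extras$intercept_p,
       pleiotropy_detected = e$extras$intercept_p < 0.05)
}

#' Leave-one-out IVW analysis
#'
#' Refits the (random-effects) IVW estimate J times, each omitting one
#' SNP. The stability flag is set when every omission preserves both the
#' sign and the nominal (p < 0.05) significance status of the full
#' estimate, i.e. no single SNP drives the finding.
#'
#' @param hset a `harmonized_set` with at least 3 SNPs.
#' @return `data.frame` (`left_out_rsid`, `beta`, `se`, `pval`) with
#'   attribute `"stable"`.
#' @export
leave_one_out <- function(hset) {
  v <- .hset_vectors(hset)
  J <- length(v$bx)
  if (J < 3L) stop("leave-one-out requires at least 3 SNPs")
  full <- ivw(hset)
  rows <- lapply(seq_len(J), function(j) {
    sub <- ivw(harmonized_set(v$bx[-j], v$sx[-j], v$by[-j], v$sy[-j],
                              rsid = v$rsid[-j]))
    data.frame(left_out_rsid = v$rsid[j], beta = sub$beta, se = sub$se,
               pval = sub$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stable <- all(sign(out$beta) == sign(full$beta)) &&
    all((out$pval < 0.05) == (full$pval < 0.05))
  attr(out, "stable") <- stable
  out
}

#' Full sensitivity report for one harmonized set
#'
#' Bundles Cochran's Q, the Egger intercept test (J >= 3), the MR-PRESSO
#' global/outlier/distortion results (J >= 4) and the leave-one-out
#' table (J >= 3) into one object. Diagnostics whose minimum instrument
#' count is not met are `NULL`.
#'
#' @param hset a `harmonized_set`.
#' @param config estimator configuration as in [run_all_estimators()].
#' @return list of class `sensitivity_report` with fields `q_stat`,
#'   `q_df`, `q_pval`, `heterogeneity_detected`, `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p`, `pleiotropy_detected`,
#'   `presso`, `loo`, `loo_stable`.
#' @export
sensitivity_report <- function(hset, config = list()) {
  cfg <- utils::modifyList(list(n_sim_presso = 1000, presso_outlier_p = 0.05,
                                seed = 42L), config)
  J <- nrow(hset$snps)
  rep <- list(q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
              heterogeneity_detected = NA,
              egger_intercept = NA_real_, egger_intercept_se = NA_real_,
              egger_intercept_p = NA_real_, pleiotropy_detected = NA,
              presso = NULL, loo = NULL, loo_stable = NA)
  if (J >= 2L) {
    q <- cochran_q(hset)
    rep$q_stat <- q$q_stat
    rep$q_df <- q$q_df
    rep$q_pval <- q$q_pval
    rep$heterogeneity_detected <- q$q_pval < 0.05
  }
  if (J >= 3L) {
    ei <- egger_intercept_test(hset)
    rep$egger_intercept <- ei$intercept
    rep$egger_intercept_se <- ei$intercept_se
    rep$egger_intercept_p <- ei$intercept_p
    rep$pleiotropy_detected <- ei$pleiotropy_detected
    loo <- leave_one_out(hset)
    rep$loo <- loo
    rep$loo_stable <- attr(loo, "stable")
  }
  if (J >= 4L) {
    pr <- mr_presso(hset, n_sim = cfg$n_sim_presso, seed = cfg$seed,
                    outlier_p = cfg$presso_outlier_p)
    rep$presso <- pr$extras
  }
  structure(rep, class = "sensitivity_report")
}
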