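test_that("the Wald ratio follows the delta-method arithmetic", {
  h <- harmonized_set(0.1, 0.01, 0.05, 0.02)
  r <- wald_ratio(h)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.2)
  expect_equal(r$or_value, exp(0.5))
  # null outcome effect -> p exactly 1
  expect_equal(wald_ratio(harmonized_set(0.1, 0.01, 0, 0.02))$pval, 1)
  # z = 6 against the normal-tail oracle
  r6 <- wald_ratio(harmonized_set(0.1, 0.01, 0.3, 0.05))
  expect_equal(r6$beta, 3)
  expect_equal(r6$se, 0.5)
  expect_equal(r6$pval, 2 * pnorm(-6), tolerance = 1e-10)
  expect_error(wald_ratio(harmonized_set(0, 0.01, 0.1, 0.02)), "zero")
})

test_that("IVW equals the precision-weighted mean of Wald ratios and the origin-WLS slope", {
  h <- sim_hset(101, n_snps = 8, theta = 0.25)
  s <- h$snps
  r <- ivw(h)
  # oracle 1: precision-weighted mean of per-SNP ratios
  w <- s$beta_exp^2 / s$se_out^2
  expect_equal(r$beta, sum(w * (s$beta_out / s$beta_exp)) / sum(w),
               tolerance = 1e-12)
  # oracle 2: weighted least squares through the origin
  fit <- lm(beta_out ~ 0 + beta_exp, data = s, weights = 1 / s$se_out^2)
  expect_equal(r$beta, unname(coef(fit)), tolerance = 1e-12)
  expect_error(ivw(harmonized_set(0.1, 0.01, 0.1, 0.02)), "at least 2")
})

test_that("IVW degenerate cases: equal ratios and symmetric ratios", {
  h <- harmonized_set(c(0.1, 0.2, 0.4), c(0.01, 0.01, 0.01),
                      0.3 * c(0.1, 0.2, 0.4), c(0.02, 0.02, 0.02))
  r <- ivw(h)
  expect_equal(r$beta, 0.3, tolerance = 1e-12)
  expect_equal(r$extras$phi, 1)      # zero heterogeneity: no inflation
  expect_equal(r$extras$q_stat, 0, tolerance = 1e-20)
  # equal weights, ratios {0.2, 0.4, 0.6} -> mean 0.4
  bx <- c(1, 1, 1)
  h2 <- harmonized_set(bx, rep(0.01, 3), c(0.2, 0.4, 0.6), rep(0.1, 3))
  expect_equal(ivw(h2)$beta, 0.4, tolerance = 1e-12)
})

test_that("Egger is exact on affine data and reduces to FE-IVW when constrained", {
  bx <- c(0.1, 0.15, 0.22, 0.3)
  by <- 0.04 + 0.6 * bx
  h <- harmonized_set(bx, rep(0.01, 4), by, c(0.02, 0.03, 0.02, 0.04))
  e <- egger(h)
  expect_equal(e$beta, 0.6, tolerance = 1e-10)
  expect_equal(e$extras$intercept, 0.04, tolerance = 1e-10)
  expect_equal(e$extras$sigma, 0, tolerance = 1e-6)
  # constraining the intercept to zero reproduces the FE-IVW slope
  h2 <- sim_hset(55, n_snps = 6, theta = 0.2)
  s <- h2$snps
  fit0 <- lm(beta_out ~ 0 + beta_exp, data = s, weights = 1 / s$se_out^2)
  expect_equal(ivw(h2, model = "fe")$beta, unname(coef(fit0)),
               tolerance = 1e-12)
  expect_error(egger(harmonized_set(1:2 / 10, c(.01, .01),
                                    1:2 / 10, c(.02, .02))), "at least 3")
})

test_that("the weighted median interpolates at cumulative weight one half", {
  # equal weights, ratios {1, 2, 9}: median 2
  h <- harmonized_set(c(1, 1, 1), rep(0.01, 3), c(1, 2, 9), rep(1, 3))
  expect_equal(weighted_median(h, n_boot = 0)$beta, 2)
  # one SNP holding most of the weight pins the estimate near its ratio
  h2 <- harmonized_set(c(1, 1, 1), rep(0.01, 3), c(1, 5, 9),
                       c(0.05, 10, 10))
  expect_lt(abs(weighted_median(h2, n_boot = 0)$beta - 1), 0.5)
  # bootstrap se is reproducible given the seed
  h3 <- sim_hset(66, n_snps = 10, theta = 0.3)
  r1 <- weighted_median(h3, n_boot = 500, seed = 7)
  r2 <- weighted_median(h3, n_boot = 500, seed = 7)
  expect_identical(r1$se, r2$se)
  expect_error(weighted_median(harmonized_set(1, .01, 1, .02)), "at least 3")
})

test_that("the weighted mode finds the plurality cluster", {
  theta <- c(rep(0.3, 7), -2, 1.8, 4)
  h <- harmonized_set(rep(1, 10), rep(0.01, 10), theta, rep(1, 10))
  m <- weighted_mode(h, n_boot = 0)
  # density-grid oracle: equal weights, the mode must sit in the cluster
  expect_lt(abs(m$beta - 0.3), 0.15)
  # all ratios identical -> that value exactly
  hid <- harmonized_set(rep(1, 4), rep(0.01, 4), rep(0.7, 4), rep(1, 4))
  expect_equal(weighted_mode(hid, n_boot = 0)$beta, 0.7)
  # enormous bandwidth -> estimate approaches the weighted mean
  s <- sim_hset(31, n_snps = 12, theta = 0.2)$snps
  h2 <- harmonized_set(s$beta_exp, s$se_exp, s$beta_out, s$se_out)
  th <- s$beta_out / s$beta_exp
  w <- s$beta_exp^2 / s$se_out^2
  wide <- weighted_mode(h2, bandwidth_factor = 200, n_boot = 0)
  expect_equal(wide$beta, sum(w * th) / sum(w), tolerance = 0.01)
})

test_that("MR-PRESSO detects and removes an injected outlier", {
  st <- simulate_study(simulation_scenario(n_snps = 16, theta = 0.3,
                                           outlier_frac = 1 / 16,
                                           outlier_sign = "positive",
                                           seed = 9))
  h <- harmonized_set(st$exposure$beta, st$exposure$se,
                      st$outcome$beta, st$outcome$se,
                      rsid = st$exposure$rsid)
  pr <- mr_presso(h, n_sim = 500, seed = 3)
  bad <- st$truth$rsid[st$truth$outlier]
  expect_lt(pr$extras$global_p, 0.05)
  expect_equal(pr$extras$outliers[1], bad)
  expect_equal(pr$n_snp, 15L)
  # corrected estimate moves toward the true effect
  expect_lt(abs(pr$beta - 0.3), abs(pr$extras$uncorrected_beta - 0.3))
  expect_true(is.finite(pr$extras$distortion_p))
  expect_error(mr_presso(sim_hset(1, n_snps = 3)), "insufficient")
})

test_that("estimators are sign-equivariant", {
  h <- sim_hset(88, n_snps = 12, theta = 0.4)
  s <- h$snps
  hneg <- harmonized_set(s$beta_exp, s$se_exp, -s$beta_out, s$se_out,
                         rsid = s$rsid)
  for (pair in list(
    list(ivw(h), ivw(hneg)),
    list(egger(h), egger(hneg)),
    list(weighted_median(h, n_boot = 300, seed = 1),
         weighted_median(hneg, n_boot = 300, seed = 1)),
    list(weighted_mode(h, n_boot = 100, seed = 1),
         weighted_mode(hneg, n_boot = 100, seed = 1)))) {
    expect_equal(pair[[1]]$beta, -pair[[2]]$beta, tolerance = 1e-8)
    expect_equal(pair[[1]]$pval, pair[[2]]$pval, tolerance = 1e-8)
  }
})

test_that("estimators are invariant to SNP input order", {
  h <- sim_hset(89, n_snps = 10, theta = 0.2)
  s <- h$snps[sample.int(10), ]
  hperm <- structure(list(exposure_id = "e", outcome_id = "o", snps = s,
                          removed = h$removed), class = "harmonized_set")
  expect_equal(ivw(h)$beta, ivw(hperm)$beta, tolerance = 1e-14)
  expect_equal(egger(h)$se, egger(hperm)$se, tolerance = 1e-14)
  expect_identical(weighted_median(h, 500, seed = 2)$se,
                   weighted_median(hperm, 500, seed = 2)$se)
  expect_identical(mr_presso(h, n_sim = 200, seed = 2)$extras$global_p,
                   mr_presso(hperm, n_sim = 200, seed = 2)$extras$global_p)
})

test_that("run_all_estimators dispatches on the instrument count", {
  cfg <- list(n_boot = 100, n_sim_presso = 100)
  r1 <- run_all_estimators(sim_hset(1, n_snps = 1), cfg)
  expect_length(r1, 1)
  expect_equal(r1[[1]]$method, "wald_ratio")
  expect_true(r1[[1]]$primary)
  r2 <- run_all_estimators(sim_hset(2, n_snps = 2), cfg)
  expect_equal(vapply(r2, `[[`, "", "method"), "ivw")
  r3 <- run_all_estimators(sim_hset(3, n_snps = 3), cfg)
  expect_setequal(vapply(r3, `[[`, "", "method"),
                  c("ivw", "egger", "weighted_median", "weighted_mode"))
  r10 <- run_all_estimators(sim_hset(4, n_snps = 10), cfg)
  expect_length(r10, 5)
  expect_equal(vapply(r10, `[[`, "", "method")[vapply(r10, `[[`, TRUE,
                                                      "primary")], "ivw")
  skip <- run_all_estimators(harmonized_set(numeric(0), numeric(0),
                                            numeric(0), numeric(0)))
  expect_s3_class(skip, "mr_skip")
})

test_that("estimators recover a planted effect across the theta grid", {
  for (theta in c(-0.5, 0.3)) {
    est <- replicate_sims(60, 2500 + round(1000 * theta),
                          function(h, st) ivw(h)$beta,
                          n_snps = 15, theta = theta)
    expect_lt(abs(mean(est) - theta), 2 * sd(est) / sqrt(60) + 0.01)
  }
})
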