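test_that("the p-value screen uses a strict inequality", {
  df <- toy_gwas(3)
  df$pval <- c(1e-6, 1e-5, 1e-4)
  expect_equal(select_by_pvalue(df, 1e-5)$rsid, "rs001")
  expect_equal(nrow(select_by_pvalue(df, 1)), 3L)
  expect_equal(nrow(select_by_pvalue(df[0, ], 1e-5)), 0L)
})

test_that("clumping keeps the best SNP of a correlated same-chromosome trio", {
  df <- toy_gwas(3)
  df$pval <- c(1e-8, 1e-7, 1e-6)
  r2 <- matrix(0.9, 3, 3); diag(r2) <- 1
  ld <- ld_matrix(df$rsid, r2)
  got <- clump(df, ld)
  expect_equal(got$rsid, "rs001")
  # brute-force oracle: among subsets with all pairwise r2 < threshold
  # within the window, greedy-by-p keeps exactly the p-minimal SNP here
  expect_equal(nrow(attr(got, "audit")), 2L)
})

test_that("the clump window does not cross chromosomes", {
  df <- toy_gwas(2)
  df$chrom <- c("1", "2")
  ld <- ld_matrix(df$rsid, matrix(c(1, 0.9, 0.9, 1), 2))
  expect_equal(nrow(clump(df, ld)), 2L)
})

test_that("sub-threshold correlation and absent LD entries retain SNPs", {
  df <- toy_gwas(2)
  ld <- ld_matrix(df$rsid, matrix(c(1, 5e-4, 5e-4, 1), 2))
  expect_equal(nrow(clump(df, ld)), 2L)
  # pair absent from the panel -> treated as r2 = 0
  expect_equal(nrow(clump(df, ld_matrix("rsX", matrix(1)))), 2L)
  expect_equal(nrow(clump(df, NULL)), 2L)
})

test_that("clumping is invariant to input row order and audits missing positions", {
  set.seed(42)
  df <- toy_gwas(8)
  df$pos <- 1e6 + (seq_len(8) %% 4) * 1e5   # force window overlaps
  df$pval <- runif(8, 1e-9, 1e-6)
  r2 <- matrix(runif(64), 8, 8); r2 <- (r2 + t(r2)) / 2
  r2[r2 > 1] <- 1; diag(r2) <- 1
  ld <- ld_matrix(df$rsid, r2)
  ref <- clump(df, ld, r2_threshold = 0.3)
  for (s in 1:3) {
    perm <- df[sample.int(8), ]
    got <- clump(perm, ld, r2_threshold = 0.3)
    expect_equal(sort(got$rsid), sort(ref$rsid))
  }
  # retained set never contains a violating same-chromosome pair
  kept <- ref$rsid
  for (a in kept) for (b in kept) if (a < b) {
    pa <- df$pos[df$rsid == a]; pb <- df$pos[df$rsid == b]
    if (abs(pa - pb) <= 1e7) expect_lt(ld$r2[a, b], 0.3)
  }
  df$pos[1] <- NA
  got <- clump(df, ld, r2_threshold = 0.3)
  aud <- attr(got, "audit")
  expect_true("missing genomic position" %in% aud$reason)
})

test_that("the blacklist removes and annotates exactly its hits", {
  df <- toy_gwas(5)
  bl <- data.frame(rsid = "rs003", confounder_trait = "diabetes",
                   source = "static")
  got <- apply_blacklist(df, bl)
  expect_equal(nrow(got), 4L)
  expect_equal(attr(got, "audit")$reason, "confounder: diabetes")
  expect_equal(nrow(apply_blacklist(df, character(0))), 5L)
  noop <- apply_blacklist(df, "rs999")
  expect_equal(nrow(noop), 5L)
  expect_equal(nrow(attr(noop, "audit")), 0L)
})

test_that("per-SNP F follows beta^2/se^2", {
  expect_equal(snp_f_statistic(0.1, 0.02), 25)
  expect_equal(snp_f_statistic(0, 0.02), 0)
  expect_equal(snp_f_statistic(0.05, 0.01), 25)
})

test_that("the two algebraic forms of per-SNP R^2 agree to machine precision", {
  set.seed(1)
  beta <- rnorm(50, 0, 0.1); se <- runif(50, 0.005, 0.02)
  f <- runif(50, 0.05, 0.95); n <- 18340
  full <- (2 * f * (1 - f) * beta^2) /
    (2 * f * (1 - f) * beta^2 + 2 * f * (1 - f) * n * se^2)
  simplified <- snp_variance_explained(beta, se, f, n)
  expect_equal(simplified, full, tolerance = 1e-12)
  expect_equal(snp_variance_explained(0.1, 0.01, 0.5, 18340),
               0.01 / (0.01 + 1.834), tolerance = 1e-12)
  expect_equal(snp_variance_explained(0, 0.01, 0.5, 100), 0)
  # n * se^2 == beta^2 -> exactly one half
  expect_equal(snp_variance_explained(0.1, 0.01, 0.5, 100), 0.5)
  expect_true(is.na(snp_variance_explained(0.1, 0.01, NA, 100)))
})

test_that("the aggregate F-statistic uses the standard estimator", {
  expect_equal(aggregate_f_statistic(0.5, 102, 1), 100)
  expect_equal(aggregate_f_statistic(0, 500, 5), 0)
  expect_equal(aggregate_f_statistic(0.01, 18340, 10),
               (0.01 / 0.99) * (18340 - 11) / 10, tolerance = 1e-12)
  expect_equal(round(aggregate_f_statistic(0.01, 18340, 10), 3), 18.514)
  # audit-only literal form is exposed but off by default
  expect_equal(aggregate_f_statistic(0.5, 102, 1, literal_form = TRUE),
               100^2 / 0.5)
  expect_error(aggregate_f_statistic(1, 100, 2), "R\\^2")
})

test_that("the filter cascade audits every removed SNP exactly once", {
  df <- toy_gwas(8)
  df$pval[7:8] <- c(1e-4, 0.5)          # fail p screen
  df$beta[1] <- 0.02                    # F = 4 < 10
  bl <- data.frame(rsid = "rs002", confounder_trait = "cholestasis")
  iset <- build_instrument_set(df, blacklist = bl)
  expect_s3_class(iset, "instrument_set")
  expect_equal(sort(iset$records$rsid), c("rs003", "rs004", "rs005", "rs006"))
  expect_true(all(iset$per_snp_f >= 10))
  aud <- iset$audit
  expect_equal(sort(aud$rsid), c("rs001", "rs002", "rs007", "rs008"))
  expect_equal(aud$reason[aud$rsid == "rs001"], "weak instrument")
  expect_match(aud$reason[aud$rsid == "rs002"], "cholestasis")
  # audit + retained partition the input
  expect_equal(sort(c(aud$rsid, iset$records$rsid)), sort(df$rsid))
  expect_false(iset$no_instruments)
  expect_gt(iset$aggregate_f, 10)
})

test_that("strong synthetic instruments all survive the F filter", {
  # common-variant, large-effect scenario: every instrument is strong
  st <- simulate_study(simulation_scenario(n_snps = 50, seed = 17,
                                           gamma_range = c(0.12, 0.2),
                                           maf_range = c(0.2, 0.5)))
  iset <- build_instrument_set(st$exposure, ld = st$ld)
  expect_equal(nrow(iset$records), 50L)
  expect_true(all(iset$per_snp_f >= 10))
})

test_that("a fully blacklisted input yields an empty flagged set", {
  df <- toy_gwas(3)
  iset <- build_instrument_set(df, blacklist = df$rsid)
  expect_true(iset$no_instruments)
  expect_equal(nrow(iset$records), 0L)
})
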