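# Summary-level GWAS simulator. Statistics are simulated directly at the
# summary level (no individual-level genotypes): two-sample MR consumes
# only summary data, and this keeps every test sub-second.

# Run `expr` under a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Define a simulation scenario
#'
#' Encodes the data-generating conditions for one exposure-outcome pair:
#' instrument count, cohort sizes matching the consortium GWAS being
#' emulated (18,340 exposure participants; case-control outcome sizes for
#' acute pancreatitis, 3,022 cases / 195,144 controls, by default), the
#' true causal effect on the log-odds scale, the SNP-exposure effect
#' range, pleiotropy and outlier contamination, and optional LD blocks.
#'
#' The default `gamma_range` of 0.08--0.15 per-allele SD units yields
#' exposure associations comfortably below the p < 1e-5 instrument
#' threshold at the default exposure sample size (per-SNP F roughly
#' 50--180), i.e. strong instruments, the regime the pipeline's p-value
#' screen enforces on real data.
#'
#' @param n_snps instrument count J.
#' @param n_exposure exposure GWAS sample size.
#' @param n_cases,n_controls outcome GWAS case-control sizes.
#' @param theta true causal effect (log-odds per unit exposure).
#' @param gamma_range magnitude interval for true SNP-exposure effects;
#'   signs are random.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct
#'   effects) or `"directional"` (mean `mu_pleio`).
#' @param tau pleiotropy SD; `mu_pleio` directional pleiotropy mean.
#' @param mu_pleio directional pleiotropy mean.
#' @param outlier_frac fraction of SNPs given large idiosyncratic outcome
#'   effects; the outlier count is `round(outlier_frac * n_snps)`.
#' @param outlier_scale outlier magnitude as a multiple of the median
#'   |theta * gamma| (median |gamma| when theta = 0).
#' @param outlier_sign `"random"` (balanced contamination, the default),
#'   `"positive"` or `"negative"` (directional contamination, i.e.
#'   invalid instruments sharing a pleiotropic direction).
#' @param maf_range minor-allele-frequency interval.
#' @param ld_blocks optional list of blocks, each
#'   `list(size = , r2 = )`; SNPs in a block share a chromosome and
#'   nearby positions. SNPs outside blocks are independent.
#' @param seed RNG seed; the same seed reproduces the study bit-for-bit.
#' @return list of class `sim_scenario`.
#' @export
simulation_scenario <- function(n_snps = 15, n_exposure = 18340,
                                n_cases = 3022, n_controls = 195144,
                                theta = 0, gamma_range = c(0.08, 0.15),
                                pleiotropy_mode = c("none", "balanced",
                                                    "directional"),
                                tau = 0, mu_pleio = 0,
                                outlier_frac = 0, outlier_scale = 10,
                                outlier_sign = c("random", "positive",
                                                 "negative"),
                                maf_range = c(0.05, 0.5),
                                ld_blocks = NULL, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outlier_sign <- match.arg(outlier_sign)
  stopifnot(n_snps >= 1, n_exposure > 0, n_cases > 0, n_controls > 0,
            tau >= 0, outlier_frac >= 0, outlier_frac < 1,
            length(gamma_range) == 2, gamma_range[1] > 0,
            gamma_range[2] >= gamma_range[1],
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(n_snps = as.integer(n_snps), n_exposure = n_exposure,
                 n_cases = n_cases, n_controls = n_controls, theta = theta,
                 gamma_range = gamma_range,
                 pleiotropy_mode = pleiotropy_mode, tau = tau,
                 mu_pleio = mu_pleio, outlier_frac = outlier_frac,
                 outlier_scale = outlier_scale, outlier_sign = outlier_sign,
                 maf_range = maf_range,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "sim_scenario")
}

# Non-palindromic allele pairs available to the simulator.
.NONPAL_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate one exposure-outcome study at the summary level
#'
#' For SNP j with effect-allele frequency f_j the exposure standard error
#' is `1/sqrt(2 f_j (1-f_j) n_X)` and the outcome standard error uses the
#' effective sample size `n_eff = 4 / (1/n_cases + 1/n_controls)`, the
#' standard approximation for log-odds summary statistics. Observed
#' effects are `beta_X,j ~ N(gamma_j, se_X,j^2)` and
#' `beta_Y,j ~ N(theta * gamma_j + alpha_j + outlier_j, se_Y,j^2)`,
#' with `alpha_j ~ N(mu_pleio, tau^2)` under pleiotropy and 0 otherwise.
#' P-values are two-sided Wald tests.
#'
#' @param scenario a [simulation_scenario()].
#' @return list of class `sim_study` with `exposure` and `outcome` GWAS
#'   tables, an `ld` matrix (`ld_matrix`), and `truth` (per-SNP gamma,
#'   alpha, outlier flag and effect, flip/palindrome flags, and theta).
#' @export
simulate_study <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(scenario$seed, {
    J <- scenario$n_snps
    rsid <- sprintf("rs%07d", seq_len(J) * 13 + 100000)
    # spread SNPs across chromosomes far apart unless LD blocks say otherwise
    chrom <- as.character(rep_len(1:22, J))
    pos <- 1e6 + seq_len(J) * 2e7
    r2 <- diag(1, J)
    if (!is.null(scenario$ld_blocks)) {
      at <- 1L
      blk <- 0L
      for (b in scenario$ld_blocks) {
        blk <- blk + 1L
        idx <- seq.int(at, length.out = b$size)
        idx <- idx[idx <= J]
        if (length(idx) > 1) {
          r2[idx, idx] <- b$r2
          diag(r2)[idx] <- 1
        }
        chrom[idx] <- as.character(blk)
        pos[idx] <- 1e6 + seq_along(idx) * 1e4
        at <- at + b$size
      }
    }
    f <- stats::runif(J, scenario$maf_range[1], scenario$maf_range[2])
    pair <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), J, replace = TRUE), ,
                          drop = FALSE]
    gamma <- sample(c(-1, 1), J, replace = TRUE) *
      stats::runif(J, scenario$gamma_range[1], scenario$gamma_range[2])
    n_eff <- 4 / (1 / scenario$n_cases + 1 / scenario$n_controls)
    se_x <- 1 / sqrt(2 * f * (1 - f) * scenario$n_exposure)
    se_y <- 1 / sqrt(2 * f * (1 - f) * n_eff)
    # directional pleiotropy is defined relative to the exposure-raising
    # allele: its mean is carried by sign(gamma), so that re-orienting
    # instruments (as MR-Egger does) exposes rather than cancels it
    alpha <- switch(scenario$pleiotropy_mode,
                    none = numeric(J),
                    balanced = stats::rnorm(J, 0, scenario$tau),
                    directional = sign(gamma) *
                      stats::rnorm(J, scenario$mu_pleio, scenario$tau))
    n_out <- round(scenario$outlier_frac * J)
    outlier <- rep(FALSE, J)
    outlier_effect <- numeric(J)
    if (n_out > 0) {
      outlier[sample.int(J, n_out)] <- TRUE
      base <- stats::median(abs(scenario$theta * gamma))
      if (base == 0) base <- stats::median(abs(gamma))
      sgn <- switch(scenario$outlier_sign,
                    random = sample(c(-1, 1), n_out, replace = TRUE),
                    positive = rep(1, n_out),
                    negative = rep(-1, n_out))
      outlier_effect[outlier] <- scenario$outlier_scale * base * sgn
    }
    beta_x <- stats::rnorm(J, gamma, se_x)
    beta_y <- stats::rnorm(J, scenario$theta * gamma + alpha + outlier_effect,
                           se_y)
    exposure <- gwas_table(rsid = rsid, chrom = chrom, pos = pos,
                           effect_allele = pair[, 1], other_allele = pair[, 2],
                           eaf = f, beta = beta_x, se = se_x,
                           pval = 2 * stats::pnorm(-abs(beta_x / se_x)),
                           n = scenario$n_exposure)
    outcome <- gwas_table(rsid = rsid, chrom = chrom, pos = pos,
                          effect_allele = pair[, 1], other_allele = pair[, 2],
                          eaf = f, beta = beta_y, se = se_y,
                          pval = 2 * stats::pnorm(-abs(beta_y / se_y)),
                          n = scenario$n_cases + scenario$n_controls)
    truth <- data.frame(rsid = rsid, gamma = gamma, alpha = alpha,
                        outlier = outlier, outlier_effect = outlier_effect,
                        flipped = FALSE, palindromic = FALSE,
                        stringsAsFactors = FALSE)
    structure(list(exposure = exposure, outcome = outcome,
                   ld = ld_matrix(rsid, r2), truth = truth,
                   theta = scenario$theta, scenario = scenario),
              class = "sim_study")
  })
}

#' Scramble a simulated study so harmonization has work to do
#'
#' A *flipped* SNP has its outcome record re-expressed on the opposite
#' allele: effect/other alleles swapped, beta negated, EAF replaced by
#' 1 - EAF. This is information-preserving, and harmonization must undo
#' it exactly. A *palindrome-injected* SNP has its alleles replaced by an
#' A/T or C/G pair in both studies; harmonization must remove it.
#'
#' @param study a `sim_study`.
#' @param flip_frac,palindrome_frac fractions of SNPs (rounded counts,
#'   drawn without replacement) to flip / palindromize.
#' @param seed RNG seed for the SNP draws.
#' @return the modified `sim_study`; `truth$flipped` / `truth$palindromic`
#'   mark the affected SNPs.
#' @export
scramble_for_harmonization <- function(study, flip_frac = 0,
                                       palindrome_frac = 0, seed = 1L) {
  stopifnot(inherits(study, "sim_study"),
            flip_frac >= 0, flip_frac <= 1,
            palindrome_frac >= 0, palindrome_frac <= 1)
  J <- nrow(study$exposure)
  with_seed(seed, {
    n_pal <- round(palindrome_frac * J)
    pal_idx <- if (n_pal > 0) sample.int(J, n_pal) else integer(0)
    n_flip <- round(flip_frac * J)
    flip_idx <- if (n_flip > 0) {
      if (n_flip >= J) seq_len(J)
      else sample(seq_len(J), n_flip)
    } else integer(0)
    if (length(pal_idx) > 0) {
      pal_pair <- rbind(c("A", "T"), c("C", "G"))
      pick <- pal_pair[sample.int(2, length(pal_idx), replace = TRUE), ,
                       drop = FALSE]
      study$exposure$effect_allele[pal_idx] <- pick[, 1]
      study$exposure$other_allele[pal_idx] <- pick[, 2]
      study$outcome$effect_allele[pal_idx] <- pick[, 1]
      study$outcome$other_allele[pal_idx] <- pick[, 2]
      study$truth$palindromic[pal_idx] <- TRUE
    }
    if (length(flip_idx) > 0) {
      ea <- study$outcome$effect_allele[flip_idx]
      study$outcome$effect_allele[flip_idx] <-
        study$outcome$other_allele[flip_idx]
      study$outcome$other_allele[flip_idx] <- ea
      study$outcome$beta[flip_idx] <- -study$outcome$beta[flip_idx]
      study$outcome$eaf[flip_idx] <- 1 - study$outcome$eaf[flip_idx]
      study$truth$flipped[flip_idx] <- !study$truth$flipped[flip_idx]
    }
  })
  study
}

#' Load the packaged association fixture
#'
#' The package ships transcriptions of the published IVW association
#' tables for the gut-microbiota / pancreatitis analysis: 28 distinct
#' forward (taxon to pancreatitis) and 30 distinct reverse (pancreatitis
#' to taxon) suggestive-or-stronger associations, with OR, 95% CI and
#' raw p. Duplicated textual mentions in the source are collapsed to
#' single rows. `beta` is recovered as `log(OR)`, `se` from the CI width,
#' and per-level Bonferroni and Benjamini-Hochberg adjustments plus
#' significance tiers are computed from the packaged taxa registry.
#'
#' @param which `"forward"`, `"reverse"` or `"both"`.
#' @return an association `data.frame` (see [write_association_table]);
#'   for `"both"`, forward and reverse rows stacked.
#' @export
load_paper_fixture <- function(which = c("both", "forward", "reverse")) {
  which <- match.arg(which)
  path <- system.file("extdata", "published_associations.tsv",
                      package = "mrbiome")
  if (path == "") stop("packaged association fixture is missing")
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  counts <- taxa_level_counts(load_taxa_registry())
  build <- function(df) {
    if (nrow(df) == 0L) return(df)
    z <- stats::qnorm(0.975)
    beta <- log(df$or)
    se <- (log(df$ci_high) - log(df$ci_low)) / (2 * z)
    n_tests <- unname(counts[df$level])
    p_bonf <- mapply(bonferroni_adjust, df$pval, n_tests)
    out <- data.frame(exposure = df$exposure, outcome = df$outcome,
                      direction = df$direction, level = df$level,
                      method = "ivw", n_snp = NA_real_,
                      beta = beta, se = se, or = df$or,
                      ci_low = df$ci_low, ci_high = df$ci_high,
                      pval = df$pval, p_bonferroni = p_bonf,
                      stringsAsFactors = FALSE)
    # BH within each (direction, outcome-or-exposure panel, level) family,
    # mirroring the per-level Bonferroni family
    out$p_fdr <- NA_real_
    disease <- ifelse(out$direction == "forward", out$outcome, out$exposure)
    for (key in unique(paste(out$direction, disease, out$level))) {
      idx <- paste(out$direction, disease, out$level) == key
      out$p_fdr[idx] <- fdr_adjust(out$pval[idx])
    }
    out$tier <- mapply(classify_tier, out$pval, out$p_bonferroni)
    out
  }
  fwd <- build(raw[raw$direction == "forward", , drop = FALSE])
  rev <- build(raw[raw$direction == "reverse", , drop = FALSE])
  switch(which,
         forward = fwd,
         reverse = rev,
         both = rbind(fwd, rev))
}
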