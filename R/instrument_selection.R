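# Instrument selection: p-value screen, greedy LD clumping, confounder
# blacklist, and instrument-strength (F / R^2) filtering.

#' Screen SNPs by association p-value
#'
#' Retains records with `pval` strictly below `threshold` (the instrument
#' threshold is printed with a strict "<"; default 1e-5, the inclusive
#' threshold commonly used for microbiome taxa whose genome-wide-
#' significant hit counts are tiny).
#'
#' @param records GWAS table.
#' @param threshold p-value threshold in (0,1); default `1e-5`.
#' @return the retained subset.
#' @export
select_by_pvalue <- function(records, threshold = 1e-5) {
  stopifnot(threshold > 0, threshold <= 1)
  out <- records[!is.na(records$pval) & records$pval < threshold, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p (ties broken lexicographically by
#' rsid, so the output is invariant to input row order), repeatedly takes
#' the best remaining SNP as an index, and removes all remaining SNPs on
#' the same chromosome within `window_kb` whose r-squared against the
#' index is at least `r2_threshold`. Pairs absent from the LD panel are
#' treated as linkage equilibrium (r^2 = 0); reference panels are sparse
#' and dropping unmatched SNPs would silently discard instruments.
#'
#' @param records GWAS table with `chrom`/`pos` (records lacking
#'   positions are excluded and audited).
#' @param ld an `ld_matrix` (or `NULL` for no LD information).
#' @param r2_threshold clumping threshold; default 0.001.
#' @param window_kb genomic window in kilobases; default 10,000.
#' @return retained records, with attribute `"audit"` listing removals as
#'   (`rsid`, `filter`, `reason`).
#' @export
clump <- function(records, ld = NULL, r2_threshold = 0.001,
                  window_kb = 10000) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, window_kb > 0)
  audit <- data.frame(rsid = character(0), filter = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    attr(records, "audit") <- audit
    return(records)
  }
  no_pos <- is.na(records$chrom) | is.na(records$pos)
  if (any(no_pos)) {
    audit <- rbind(audit, data.frame(
      rsid = records$rsid[no_pos], filter = "clump",
      reason = "missing genomic position", stringsAsFactors = FALSE))
    records <- records[!no_pos, , drop = FALSE]
  }
  ord <- order(records$pval, records$rsid)
  pool <- records[ord, , drop = FALSE]
  keep <- character(0)
  while (nrow(pool) > 0L) {
    index <- pool[1L, ]
    keep <- c(keep, index$rsid)
    pool <- pool[-1L, , drop = FALSE]
    if (nrow(pool) == 0L) break
    same_chr <- pool$chrom == index$chrom
    within <- same_chr & abs(pool$pos - index$pos) <= window_kb * 1000
    r2 <- .ld_lookup(ld, index$rsid, pool$rsid)
    prune <- within & r2 >= r2_threshold
    if (any(prune)) {
      audit <- rbind(audit, data.frame(
        rsid = pool$rsid[prune], filter = "clump",
        reason = sprintf("r2 %.4g with index %s", r2[prune], index$rsid),
        stringsAsFactors = FALSE))
      pool <- pool[!prune, , drop = FALSE]
    }
  }
  out <- records[records$rsid %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Remove SNPs on a confounder blacklist
#'
#' Stands in for an interactive phenome-scan: SNPs known to associate
#' with confounders of the microbiota-pancreatitis relationship (e.g.
#' diabetes, cholestasis) are listed in a static file and excluded.
#'
#' @param records GWAS table.
#' @param blacklist `data.frame` with columns `rsid` and optionally
#'   `confounder_trait` (and `source`), or a character vector of rsids.
#' @return retained records with an `"audit"` attribute.
#' @export
apply_blacklist <- function(records, blacklist) {
  if (is.character(blacklist)) {
    blacklist <- data.frame(rsid = blacklist,
                            confounder_trait = rep_len(NA_character_,
                                                       length(blacklist)),
                            stringsAsFactors = FALSE)
  }
  hit <- records$rsid %in% blacklist$rsid
  ann <- blacklist$confounder_trait[match(records$rsid[hit], blacklist$rsid)]
  audit <- data.frame(
    rsid = records$rsid[hit], filter = rep("blacklist", sum(hit)),
    reason = ifelse(is.na(ann), "confounder-associated",
                    paste0("confounder: ", ann)),
    stringsAsFactors = FALSE)
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Read a confounder blacklist file
#'
#' TSV with columns `rsid`, `confounder_trait`, `source`.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
read_blacklist <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' Per-SNP instrument strength
#'
#' The single-SNP F-statistic is `beta^2 / se^2` on the exposure scale;
#' F < 10 conventionally signals a weak instrument.
#'
#' @param beta,se exposure effect and its standard error (vectors OK);
#'   alternatively pass a GWAS table as `beta` and both are taken from it.
#' @return numeric F value(s).
#' @export
snp_f_statistic <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  stopifnot(all(se > 0))
  beta^2 / se^2
}

#' Per-SNP variance explained
#'
#' `R^2 = 2 f (1-f) beta^2 / (2 f (1-f) beta^2 + 2 f (1-f) n se^2)`,
#' which simplifies to `beta^2 / (beta^2 + n se^2)`; both forms agree to
#' machine precision and the simplified one is returned.
#'
#' @param beta,se,eaf,n exposure effect, SE, effect-allele frequency and
#'   sample size (vectors OK); alternatively a GWAS table as `beta`.
#' @return numeric R^2 value(s); `NA` where `eaf` or `n` is missing.
#' @export
snp_variance_explained <- function(beta, se = NULL, eaf = NULL, n = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se; eaf <- beta$eaf; n <- beta$n; beta <- beta$beta
  }
  stopifnot(all(se > 0))
  out <- beta^2 / (beta^2 + n * se^2)
  out[is.na(eaf) | is.na(n)] <- NA_real_
  out
}

#' Aggregate (multi-instrument) F-statistic
#'
#' The standard estimator `F = (R^2 / (1 - R^2)) * ((n - k - 1) / k)`
#' with `r2_total` the summed per-SNP variance explained. A
#' non-default `literal_form = TRUE` switches to the alternative
#' expression `(n - k - 1)^2 / (1 - R^2)`, exposed purely for audit
#' comparisons; it is not a valid strength estimator (see vignette).
#'
#' @param r2_total total variance explained in `[0, 1)`.
#' @param n exposure sample size; `k` instrument count; requires
#'   `n > k + 1`.
#' @param k instrument count.
#' @param literal_form audit-only compatibility switch (default `FALSE`).
#' @return numeric F.
#' @export
aggregate_f_statistic <- function(r2_total, n, k, literal_form = FALSE) {
  if (r2_total < 0 || r2_total >= 1)
    stop("total R^2 must lie in [0, 1)")
  stopifnot(k >= 1, n > k + 1)
  if (literal_form) return((n - k - 1)^2 / (1 - r2_total))
  (r2_total / (1 - r2_total)) * ((n - k - 1) / k)
}

#' Build an instrument set for one exposure
#'
#' Applies the full filter cascade in a fixed, logged order:
#' p-value screen, LD clumping, confounder blacklist, then per-SNP
#' F-statistic computation with exclusion of weak instruments (F below
#' `min_f`). Per-SNP R^2 and, where every retained SNP carries EAF and
#' n, an aggregate F are attached.
#'
#' @param records exposure GWAS table.
#' @param ld `ld_matrix` or `NULL`.
#' @param blacklist blacklist `data.frame`/character vector or `NULL`.
#' @param config list of thresholds: `iv_p_threshold` (1e-5), `clump_r2`
#'   (0.001), `clump_window_kb` (10000), `min_f` (10).
#' @param exposure_id trait identifier carried into the result.
#' @return list of class `instrument_set`: `exposure_id`, `records`,
#'   `per_snp_f`, `per_snp_r2`, `aggregate_f` (or `NA`), `audit`, and
#'   `no_instruments` flag.
#' @export
build_instrument_set <- function(records, ld = NULL, blacklist = NULL,
                                 config = list(), exposure_id = "exposure") {
  cfg <- utils::modifyList(list(iv_p_threshold = 1e-5, clump_r2 = 0.001,
                                clump_window_kb = 10000, min_f = 10),
                           config)
  audit <- data.frame(rsid = character(0), filter = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  kept <- select_by_pvalue(records, cfg$iv_p_threshold)
  dropped <- setdiff(records$rsid, kept$rsid)
  if (length(dropped)) {
    audit <- rbind(audit, data.frame(
      rsid = dropped, filter = "pvalue",
      reason = sprintf("p >= %g", cfg$iv_p_threshold),
      stringsAsFactors = FALSE))
  }
  kept <- clump(kept, ld, cfg$clump_r2, cfg$clump_window_kb)
  audit <- rbind(audit, attr(kept, "audit"))
  if (!is.null(blacklist)) {
    kept <- apply_blacklist(kept, blacklist)
    audit <- rbind(audit, attr(kept, "audit"))
  }
  f <- snp_f_statistic(kept)
  weak <- f < cfg$min_f
  if (any(weak)) {
    audit <- rbind(audit, data.frame(
      rsid = kept$rsid[weak], filter = "f_statistic",
      reason = "weak instrument", stringsAsFactors = FALSE))
    kept <- kept[!weak, , drop = FALSE]
    f <- f[!weak]
  }
  rownames(kept) <- NULL
  r2 <- snp_variance_explained(kept)
  agg <- NA_real_
  if (nrow(kept) > 0 && !anyNA(r2) &&
      !anyNA(kept$n) && sum(r2) < 1 &&
      min(kept$n) > nrow(kept) + 1) {
    agg <- aggregate_f_statistic(sum(r2), min(kept$n), nrow(kept))
  }
  attr(kept, "audit") <- NULL
  structure(list(exposure_id = exposure_id, records = kept,
                 per_snp_f = stats::setNames(f, kept$rsid),
                 per_snp_r2 = stats::setNames(r2, kept$rsid),
                 aggregate_f = agg, audit = audit,
                 no_instruments = nrow(kept) == 0L),
            class = "instrument_set")
}
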