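# Effect-allele harmonization: align exposure and outcome summary
# statistics to a common effect allele before any ratio is formed.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' Palindromic (strand-ambiguous) SNPs carry complementary alleles, so
#' the strand cannot be resolved from summary data: the pair is `{A,T}`
#' or `{C,G}`.
#'
#' @param effect_allele,other_allele single-base allele strings
#'   (vectorized).
#' @return logical.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  unname(.COMPLEMENT[ea] == oa)
}

#' Harmonize exposure and outcome effects to a common effect allele
#'
#' For each exposure SNP, in order: missing from the outcome study ->
#' removed (`missing_in_outcome`); duplicated in the outcome -> removed
#' (`duplicate`); palindromic -> removed unconditionally (`palindromic`;
#' no allele-frequency rescue window is applied); same allele pair in the
#' same orientation -> kept as-is; same pair with swapped orientation ->
#' outcome beta negated and outcome EAF replaced by 1-EAF, kept. For
#' non-palindromic SNPs whose outcome alleles match neither orientation,
#' a strand flip (A<->T, C<->G complement of the outcome alleles) is
#' attempted before declaring `allele_mismatch`.
#'
#' @param exposure,outcome GWAS tables; `exposure` is typically an
#'   [build_instrument_set()] `$records`.
#' @param exposure_id,outcome_id trait identifiers carried through.
#' @return list of class `harmonized_set` with `snps` (a `data.frame` of
#'   `rsid`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`,
#'   `eaf_out`, sorted by rsid) and `removed` (`rsid`, `reason`).
#' @export
harmonize_effects <- function(exposure, outcome,
                              exposure_id = "exposure",
                              outcome_id = "outcome") {
  removed <- data.frame(rsid = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(rsids, reason) {
    if (length(rsids))
      removed <<- rbind(removed, data.frame(rsid = rsids, reason = reason,
                                            stringsAsFactors = FALSE))
  }
  dup_out <- unique(outcome$rsid[duplicated(outcome$rsid)])
  keep <- list()
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    if (ex$rsid %in% dup_out) {
      drop(ex$rsid, "duplicate")
      next
    }
    j <- match(ex$rsid, outcome$rsid)
    if (is.na(j)) {
      drop(ex$rsid, "missing_in_outcome")
      next
    }
    if (is_palindromic(ex$effect_allele, ex$other_allele)) {
      drop(ex$rsid, "palindromic")
      next
    }
    ot <- outcome[j, ]
    o_ea <- ot$effect_allele
    o_oa <- ot$other_allele
    aligned <- NULL
    if (o_ea == ex$effect_allele && o_oa == ex$other_allele) {
      aligned <- list(beta = ot$beta, eaf = ot$eaf)
    } else if (o_ea == ex$other_allele && o_oa == ex$effect_allele) {
      aligned <- list(beta = -ot$beta,
                      eaf = if (is.na(ot$eaf)) NA_real_ else 1 - ot$eaf)
    } else {
      # strand flip: the outcome study may report the opposite strand
      c_ea <- unname(.COMPLEMENT[o_ea])
      c_oa <- unname(.COMPLEMENT[o_oa])
      if (identical(c_ea, ex$effect_allele) && identical(c_oa, ex$other_allele)) {
        aligned <- list(beta = ot$beta, eaf = ot$eaf)
      } else if (identical(c_ea, ex$other_allele) &&
                 identical(c_oa, ex$effect_allele)) {
        aligned <- list(beta = -ot$beta,
                        eaf = if (is.na(ot$eaf)) NA_real_ else 1 - ot$eaf)
      }
    }
    if (is.null(aligned)) {
      drop(ex$rsid, "allele_mismatch")
      next
    }
    keep[[length(keep) + 1L]] <- data.frame(
      rsid = ex$rsid, beta_exp = ex$beta, se_exp = ex$se,
      beta_out = aligned$beta, se_out = ot$se,
      eaf_exp = ex$eaf, eaf_out = aligned$eaf,
      effect_allele = ex$effect_allele, other_allele = ex$other_allele,
      stringsAsFactors = FALSE)
  }
  snps <- if (length(keep)) do.call(rbind, keep) else
    data.frame(rsid = character(0), beta_exp = numeric(0),
               se_exp = numeric(0), beta_out = numeric(0),
               se_out = numeric(0), eaf_exp = numeric(0),
               eaf_out = numeric(0), effect_allele = character(0),
               other_allele = character(0), stringsAsFactors = FALSE)
  snps <- snps[order(snps$rsid), , drop = FALSE]
  rownames(snps) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 snps = snps, removed = removed),
            class = "harmonized_set")
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' For tests and small worked examples where harmonization has already
#' happened (or is not at issue).
#'
#' @param beta_exp,se_exp,beta_out,se_out aligned per-SNP effects/SEs.
#' @param rsid identifiers (defaults to `snp_1..J`).
#' @param eaf_exp,eaf_out optional frequencies.
#' @param exposure_id,outcome_id trait identifiers.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           rsid = NULL, eaf_exp = NA_real_,
                           eaf_out = NA_real_,
                           exposure_id = "exposure",
                           outcome_id = "outcome") {
  J <- length(beta_exp)
  if (is.null(rsid)) rsid <- sprintf("snp_%03d", seq_len(J))
  snps <- data.frame(rsid = as.character(rsid), beta_exp = beta_exp,
                     se_exp = se_exp, beta_out = beta_out, se_out = se_out,
                     eaf_exp = rep_len(eaf_exp, J),
                     eaf_out = rep_len(eaf_out, J),
                     effect_allele = rep_len(NA_character_, J),
                     other_allele = rep_len(NA_character_, J),
                     stringsAsFactors = FALSE)
  snps <- snps[order(snps$rsid), , drop = FALSE]
  rownames(snps) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 snps = snps,
                 removed = data.frame(rsid = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s (%d SNPs retained, %d removed)\n",
              x$exposure_id, x$outcome_id, nrow(x$snps), nrow(x$removed)))
  invisible(x)
}
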