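# Orchestration: run every exposure-outcome pair in both directions,
# apply per-taxonomic-level multiplicity control, classify significance
# tiers, and emit association tables plus a run manifest.

#' Bonferroni adjustment with a per-level divisor
#'
#' `min(1, pval * n_tests)`, where `n_tests` is the number of analyzable
#' taxa at the exposure's taxonomic level (class 16, order 20, family 32,
#' genus 119, phylum 9 for the packaged registry).
#'
#' @param pval raw p-value.
#' @param n_tests number of tests in the family (>= 1).
#' @return adjusted p.
#' @export
bonferroni_adjust <- function(pval, n_tests) {
  stopifnot(n_tests >= 1)
  pmin(1, pval * n_tests)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone after sorting and capped at 1.
#'
#' @param pvals vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(length(pvals) >= 1)
  stats::p.adjust(pvals, method = "BH")
}

#' Classify a result into a significance tier
#'
#' `significant` when the Bonferroni-corrected p is below 0.05;
#' `suggestive` when only the raw p is below 0.05; `null` otherwise.
#'
#' @param pval raw p-value.
#' @param p_bonferroni Bonferroni-adjusted p-value.
#' @return one of `"significant"`, `"suggestive"`, `"null"`.
#' @export
classify_tier <- function(pval, p_bonferroni) {
  if (p_bonferroni < 0.05) return("significant")
  if (pval < 0.05) return("suggestive")
  "null"
}

.mr_result_row <- function(res, exposure_id, outcome_id, direction, level) {
  data.frame(exposure = exposure_id, outcome = outcome_id,
             direction = direction, level = level, method = res$method,
             n_snp = res$n_snp, beta = res$beta, se = res$se,
             or = res$or_value, ci_low = res$or_ci_low,
             ci_high = res$or_ci_high, pval = res$pval,
             p_bonferroni = NA_real_, p_fdr = NA_real_,
             tier = NA_character_, stringsAsFactors = FALSE)
}

.skip_row <- function(exposure_id, outcome_id, direction, level) {
  data.frame(exposure = exposure_id, outcome = outcome_id,
             direction = direction, level = level, method = "skipped",
             n_snp = 0L, beta = NA_real_, se = NA_real_, or = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
             p_bonferroni = NA_real_, p_fdr = NA_real_,
             tier = NA_character_, stringsAsFactors = FALSE)
}

#' Run one analysis direction across all exposure-outcome pairs
#'
#' For each pair: instrument selection on the exposure GWAS,
#' harmonization against the outcome GWAS, all applicable estimators,
#' and a sensitivity report. Pairs with no surviving instruments are
#' emitted as first-class skip records (method `"skipped"`), never
#' silently dropped. Multiplicity control is per taxonomic level: the
#' Bonferroni divisor is the analyzable-taxa count at the microbial
#' trait's level (the exposure's level in the forward direction, the
#' outcome's in the reverse), and BH-FDR is applied within each
#' (disease, level, method) family.
#'
#' @param exposures,outcomes `data.frame`s with `trait_id` and `level`
#'   (`NA` level for disease traits).
#' @param stats named list mapping `trait_id` to a GWAS table.
#' @param direction `"forward"` or `"reverse"`.
#' @param registry taxa registry for the Bonferroni divisors.
#' @param ld optional `ld_matrix` used during clumping.
#' @param blacklist optional confounder blacklist.
#' @param config thresholds for [build_instrument_set()] and
#'   [run_all_estimators()].
#' @return list: `rows` (association `data.frame`), `sensitivity`
#'   (named list of `sensitivity_report`s keyed `exposure|outcome`),
#'   `audit` (per-pair filter audit).
#' @export
run_direction <- function(exposures, outcomes, stats,
                          direction = c("forward", "reverse"),
                          registry = load_taxa_registry(),
                          ld = NULL, blacklist = NULL, config = list()) {
  direction <- match.arg(direction)
  counts <- taxa_level_counts(registry)
  rows <- list()
  sens <- list()
  audit <- list()
  for (i in seq_len(nrow(exposures))) {
    ex_id <- exposures$trait_id[i]
    ex_level <- exposures$level[i]
    ex_stats <- stats[[ex_id]]
    if (is.null(ex_stats)) {
      warning("no summary statistics for exposure ", ex_id, "; skipped")
      next
    }
    iset <- build_instrument_set(ex_stats, ld = ld, blacklist = blacklist,
                                 config = config, exposure_id = ex_id)
    audit[[ex_id]] <- iset$audit
    for (j in seq_len(nrow(outcomes))) {
      out_id <- outcomes$trait_id[j]
      out_level <- outcomes$level[j]
      level <- if (direction == "forward") ex_level else out_level
      out_stats <- stats[[out_id]]
      if (is.null(out_stats)) {
        warning("no summary statistics for outcome ", out_id, "; skipped")
        next
      }
      if (iset$no_instruments) {
        rows[[length(rows) + 1L]] <- .skip_row(ex_id, out_id, direction, level)
        next
      }
      hset <- harmonize_effects(iset$records, out_stats,
                                exposure_id = ex_id, outcome_id = out_id)
      results <- run_all_estimators(hset, config = config)
      if (inherits(results, "mr_skip")) {
        rows[[length(rows) + 1L]] <- .skip_row(ex_id, out_id, direction, level)
        next
      }
      for (res in results) {
        rows[[length(rows) + 1L]] <-
          .mr_result_row(res, ex_id, out_id, direction, level)
      }
      if (nrow(hset$snps) >= 2L) {
        sens[[paste(ex_id, out_id, sep = "|")]] <-
          sensitivity_report(hset, config = config)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    read_association_table(write_association_table(NULL, tempfile()))
  # per-level Bonferroni on every scored row
  scored <- !is.na(tab$pval)
  n_tests <- unname(counts[tab$level])
  n_tests[is.na(n_tests)] <- 1
  tab$p_bonferroni[scored] <-
    bonferroni_adjust(tab$pval[scored], n_tests[scored])
  # BH within (disease, level, method) families
  disease <- if (direction == "forward") tab$outcome else tab$exposure
  fam <- paste(disease, tab$level, tab$method)
  for (key in unique(fam[scored])) {
    idx <- scored & fam == key
    tab$p_fdr[idx] <- fdr_adjust(tab$pval[idx])
  }
  if (any(scored)) {
    tab$tier[scored] <- mapply(classify_tier, tab$pval[scored],
                               tab$p_bonferroni[scored])
  }
  rownames(tab) <- NULL
  list(rows = tab, sensitivity = sens, audit = audit)
}

#' Run the full bidirectional analysis
#'
#' Forward (microbial taxa as exposures, disease phenotypes as outcomes)
#' and reverse (phenotypes as exposures, taxa as outcomes) analyses with
#' identical machinery, plus a run manifest recording thresholds, seed
#' and filter audit totals. Optionally writes both association tables
#' and the manifest to `out_dir`.
#'
#' @param taxa `data.frame` with `trait_id`, `level` for microbial traits.
#' @param diseases character vector of disease trait ids.
#' @param stats named list mapping every trait id to a GWAS table.
#' @param registry taxa registry (Bonferroni divisors).
#' @param ld,blacklist optional LD panel and confounder blacklist.
#' @param config thresholds and seeds (see [build_instrument_set()],
#'   [run_all_estimators()]).
#' @param out_dir optional output directory.
#' @return list: `forward`, `reverse` (association tables),
#'   `sensitivity` (both directions), `manifest`.
#' @export
run_bidirectional <- function(taxa, diseases, stats,
                              registry = load_taxa_registry(),
                              ld = NULL, blacklist = NULL,
                              config = list(), out_dir = NULL) {
  disease_df <- data.frame(trait_id = diseases, level = NA_character_,
                           stringsAsFactors = FALSE)
  fwd <- run_direction(taxa, disease_df, stats, "forward",
                       registry = registry, ld = ld,
                       blacklist = blacklist, config = config)
  rev <- run_direction(disease_df, taxa, stats, "reverse",
                       registry = registry, ld = ld,
                       blacklist = blacklist, config = config)
  cfg <- utils::modifyList(list(iv_p_threshold = 1e-5, clump_r2 = 0.001,
                                clump_window_kb = 10000, min_f = 10,
                                n_boot = 5000, n_sim_presso = 1000,
                                presso_outlier_p = 0.05, seed = 42L),
                           config)
  audit_totals <- function(audit) {
    all_audit <- do.call(rbind, c(audit,
                                  list(data.frame(rsid = character(0),
                                                  filter = character(0),
                                                  reason = character(0)))))
    as.list(table(all_audit$filter))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("mrbiome")),
    thresholds = cfg[c("iv_p_threshold", "clump_r2", "clump_window_kb",
                       "min_f", "presso_outlier_p")],
    seed = cfg$seed,
    n_taxa = nrow(taxa), n_diseases = length(diseases),
    forward_rows = nrow(fwd$rows), reverse_rows = nrow(rev$rows),
    forward_skips = sum(fwd$rows$method == "skipped"),
    reverse_skips = sum(rev$rows$method == "skipped"),
    forward_filter_exclusions = audit_totals(fwd$audit),
    reverse_filter_exclusions = audit_totals(rev$audit))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_association_table(fwd$rows, file.path(out_dir, "forward.tsv"))
    write_association_table(rev$rows, file.path(out_dir, "reverse.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(forward = fwd$rows, reverse = rev$rows,
       sensitivity = list(forward = fwd$sensitivity,
                          reverse = rev$sensitivity),
       manifest = manifest)
}

#' Read a YAML run or scenario configuration
#'
#' Flat key-value YAML; keys matching [simulation_scenario()] arguments
#' can be splashed straight into it via `do.call`.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
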