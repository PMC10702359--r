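#' GWAS summary-statistic tables
#'
#' A GWAS summary table is a plain `data.frame` with one row per SNP and
#' columns `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`. Effects on case-control traits are on the
#' log-odds scale; positions follow the 1-based build-37 convention and
#' chromosomes are character labels ("1".."22", "X"). `eaf`, `chrom`,
#' `pos` and `n` may be `NA`; operations that need them exclude (and
#' audit) the affected SNPs rather than failing globally.
#'
#' @name gwas-tables
NULL

.GWAS_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
.MANDATORY_COLS <- c("rsid", "effect_allele", "other_allele",
                     "beta", "se", "pval")
.VALID_ALLELES <- c("A", "C", "G", "T")
.TAXON_LEVELS <- c("phylum", "class", "order", "family", "genus")

#' Assemble a validated GWAS summary table from vectors
#'
#' Convenience constructor used throughout the test-suite and simulator.
#' Missing optional columns are filled with `NA`.
#'
#' @param rsid,effect_allele,other_allele,beta,se,pval mandatory per-SNP
#'   fields (recycled to a common length by `data.frame()` rules).
#' @param chrom,pos,eaf,n optional per-SNP fields.
#' @return A `data.frame` in canonical column order.
#' @export
gwas_table <- function(rsid, effect_allele, other_allele, beta, se, pval,
                       chrom = NA_character_, pos = NA_real_,
                       eaf = NA_real_, n = NA_real_) {
  data.frame(rsid = as.character(rsid),
             chrom = as.character(chrom),
             pos = as.numeric(pos),
             effect_allele = toupper(as.character(effect_allele)),
             other_allele = toupper(as.character(other_allele)),
             eaf = as.numeric(eaf),
             beta = as.numeric(beta),
             se = as.numeric(se),
             pval = as.numeric(pval),
             n = as.numeric(n),
             stringsAsFactors = FALSE)
}

# Per-row validity screen. Returns a character vector with "" for valid
# rows and the first failing reason otherwise; rejection is total (every
# row gets exactly one verdict).
.validate_gwas_rows <- function(df) {
  reason <- rep("", nrow(df))
  flag <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    ifelse(reason == "" & bad, msg, reason)
  }
  reason <- flag(is.na(df$rsid) | df$rsid == "", "missing rsid")
  reason <- flag(!(df$effect_allele %in% .VALID_ALLELES), "invalid effect allele")
  reason <- flag(!(df$other_allele %in% .VALID_ALLELES), "invalid other allele")
  reason <- flag(df$effect_allele == df$other_allele, "identical alleles")
  reason <- flag(is.na(df$beta), "missing beta")
  reason <- flag(is.na(df$se) | df$se <= 0, "nonpositive SE")
  reason <- flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "p-value outside (0,1]")
  # optional fields are only checked when present
  bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  reason <- ifelse(reason == "" & bad_eaf, "EAF outside (0,1)", reason)
  bad_n <- !is.na(df$n) & df$n <= 0
  reason <- ifelse(reason == "" & bad_n, "nonpositive sample size", reason)
  reason
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads a header-equipped TSV of per-SNP associations, remaps column
#' names via `column_map`, validates each row, drops invalid rows with a
#' per-row reason, and drops *all* copies of any duplicated rsid (a
#' duplicated identifier is ambiguous; no tie-break is attempted).
#'
#' @param path path to the TSV file. `"."` and empty cells are missing.
#' @param column_map named character vector mapping canonical names
#'   (`rsid`, `effect_allele`, ..., `n`) to the file's column names.
#'   Canonical names absent from the map are looked up literally.
#' @return A validated GWAS table (see [gwas-tables]) with attribute
#'   `"rejected"`: a `data.frame` of (`rsid`, `row`, `reason`) for every
#'   dropped input row.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("summary-statistic file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = c("NA", ".", ""),
                           colClasses = "character",
                           check.names = FALSE, quote = "",
                           comment.char = "")
  if (nrow(raw) == 0L) stop("summary-statistic file is empty: ", path)
  resolve <- function(canon) {
    nm <- if (!is.null(column_map) && canon %in% names(column_map))
      column_map[[canon]] else canon
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  for (canon in .MANDATORY_COLS) {
    if (is.null(resolve(canon)))
      stop("mandatory column not resolvable: ", canon)
  }
  grab <- function(canon) {
    v <- resolve(canon)
    if (is.null(v)) rep(NA_character_, nrow(raw)) else v
  }
  df <- gwas_table(rsid = grab("rsid"),
                   chrom = grab("chrom"),
                   pos = suppressWarnings(as.numeric(grab("pos"))),
                   effect_allele = grab("effect_allele"),
                   other_allele = grab("other_allele"),
                   eaf = suppressWarnings(as.numeric(grab("eaf"))),
                   beta = suppressWarnings(as.numeric(grab("beta"))),
                   se = suppressWarnings(as.numeric(grab("se"))),
                   pval = suppressWarnings(as.numeric(grab("pval"))),
                   n = suppressWarnings(as.numeric(grab("n"))))
  reason <- .validate_gwas_rows(df)
  dup <- df$rsid %in% df$rsid[duplicated(df$rsid)] & !is.na(df$rsid)
  reason <- ifelse(reason == "" & dup, "duplicated rsid", reason)
  if (any(dup)) {
    warning(sum(dup), " rows dropped for duplicated rsids (all copies)")
  }
  keep <- reason == ""
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(rsid = df$rsid[!keep],
                                      row = which(!keep),
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

.ASSOC_COLS <- c("exposure", "outcome", "direction", "level", "method",
                 "n_snp", "beta", "se", "or", "ci_low", "ci_high", "pval",
                 "p_bonferroni", "p_fdr", "tier")

#' Write / read an association-result table
#'
#' The association TSV has a fixed column order (`exposure`, `outcome`,
#' `direction`, `level`, `method`, `n_snp`, `beta`, `se`, `or`, `ci_low`,
#' `ci_high`, `pval`, `p_bonferroni`, `p_fdr`, `tier`) so that
#' write-then-read is the identity on valid tables. Odds ratios and CI
#' bounds are on the OR (exponentiated) scale.
#'
#' @param rows `data.frame` of association rows (may be empty).
#' @param path output (or input) file path.
#' @return `write_association_table` returns `path` invisibly;
#'   `read_association_table` returns the table.
#' @export
write_association_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.ASSOC_COLS)), .ASSOC_COLS))
  }
  missing_cols <- setdiff(.ASSOC_COLS, names(rows))
  for (mc in missing_cols) rows[[mc]] <- NA
  rows <- rows[, .ASSOC_COLS, drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) stop("association table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ".", ""),
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  if (nrow(df) == 0L) {
    # read.table drops column types for empty bodies; rebuild the frame
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.ASSOC_COLS)), .ASSOC_COLS))
  }
  for (col in c("exposure", "outcome", "direction", "level", "method", "tier"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("n_snp", "beta", "se", "or", "ci_low", "ci_high",
                "pval", "p_bonferroni", "p_fdr"))
    df[[col]] <- as.numeric(df[[col]])
  df[, .ASSOC_COLS, drop = FALSE]
}

#' Load a taxa registry
#'
#' The registry lists every microbial trait in scope: `taxon_id`, `level`
#' (one of phylum/class/order/family/genus), `name`, and `is_unknown`
#' (unidentified groups, which are excluded from analysis sets).
#'
#' @param path registry TSV; defaults to the packaged registry, which
#'   emulates the MiBioGen composition (9 phyla, 16 classes, 20 orders,
#'   35 families, 131 genera; 3 unknown families and 12 unknown genera).
#' @return `data.frame` with the four registry columns.
#' @export
load_taxa_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "taxa_registry.tsv", package = "mrbiome")
    if (path == "") stop("packaged taxa registry is missing")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0L) return(df)
  bad <- !(df$level %in% .TAXON_LEVELS)
  if (any(bad)) {
    stop("unknown taxonomic level label(s): ",
         paste(unique(df$level[bad]), collapse = ", "))
  }
  df$is_unknown <- as.logical(df$is_unknown)
  df
}

#' Count analyzable (non-unknown) taxa per taxonomic level
#'
#' Used as the Bonferroni divisor: the number of distinct analyzable taxa
#' at the corresponding level.
#'
#' @param registry a taxa registry `data.frame`.
#' @return named integer vector over the five ranks.
#' @export
taxa_level_counts <- function(registry) {
  analyzable <- registry[!registry$is_unknown, , drop = FALSE]
  vapply(.TAXON_LEVELS, function(lv) sum(analyzable$level == lv), integer(1))
}

#' Read a squared-correlation LD matrix
#'
#' Square numeric TSV with rsids as both header row and first column.
#' Validates symmetry, unit diagonal and the \eqn{[0,1]} range.
#'
#' @param path TSV path.
#' @return list with `rsids` (character) and `r2` (matrix), class
#'   `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  ld_matrix(rownames(m), m)
}

#' Construct an LD matrix object
#'
#' @param rsids SNP identifiers (order defines the matrix order).
#' @param r2 symmetric matrix of squared correlations with unit diagonal.
#' @return class `ld_matrix` list.
#' @export
ld_matrix <- function(rsids, r2) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != length(rsids) || ncol(r2) != length(rsids))
    stop("r2 dimensions do not match rsids")
  if (any(r2 < 0 | r2 > 1)) stop("r2 entries must lie in [0,1]")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1")
  dimnames(r2) <- list(rsids, rsids)
  structure(list(rsids = as.character(rsids), r2 = r2), class = "ld_matrix")
}

# r^2 lookup for one index SNP against several others; pairs absent from
# the panel are treated as linkage equilibrium (r^2 = 0).
.ld_lookup <- function(ld, index_rsid, other_rsids) {
  out <- numeric(length(other_rsids))
  if (is.null(ld) || !(index_rsid %in% ld$rsids)) return(out)
  present <- other_rsids %in% ld$rsids
  out[present] <- ld$r2[index_rsid, other_rsids[present]]
  out
}

#' Describe a GWAS trait
#'
#' @param trait_id identifier string.
#' @param trait_type `"exposure"` or `"outcome"`.
#' @param n_cases,n_controls case-control sizes (NA for quantitative traits).
#' @param n_total total sample size; inferred from cases+controls when
#'   absent.
#' @return a one-row `data.frame`.
#' @export
trait_info <- function(trait_id, trait_type = c("exposure", "outcome"),
                       n_cases = NA_integer_, n_controls = NA_integer_,
                       n_total = NA_integer_) {
  trait_type <- match.arg(trait_type)
  if (is.na(n_total) && !is.na(n_cases) && !is.na(n_controls))
    n_total <- n_cases + n_controls
  if (!is.na(n_cases) && !is.na(n_controls) && !is.na(n_total) &&
      n_cases + n_controls != n_total)
    stop("n_cases + n_controls must equal n_total for case-control traits")
  data.frame(trait_id = trait_id, trait_type = trait_type,
             n_cases = as.integer(n_cases),
             n_controls = as.integer(n_controls),
             n_total = as.integer(n_total), stringsAsFactors = FALSE)
}
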