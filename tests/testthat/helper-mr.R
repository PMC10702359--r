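# Shared test helpers: quick simulated harmonized sets and replicate
# loops. Simulated exposure/outcome tables share rsids and allele
# orientation, so a harmonized set can be assembled directly without
# exercising the harmonizer (which has its own tests).

sim_hset <- function(seed, ...) {
  st <- simulate_study(simulation_scenario(seed = seed, ...))
  harmonized_set(st$exposure$beta, st$exposure$se,
                 st$outcome$beta, st$outcome$se,
                 rsid = st$exposure$rsid)
}

# Run `fn(hset, study)` over n_rep seeded replicates of one scenario and
# collect the results in a vector.
replicate_sims <- function(n_rep, base_seed, fn, ...) {
  vapply(seq_len(n_rep), function(r) {
    st <- simulate_study(simulation_scenario(seed = base_seed + r, ...))
    h <- harmonized_set(st$exposure$beta, st$exposure$se,
                        st$outcome$beta, st$outcome$se,
                        rsid = st$exposure$rsid)
    fn(h, st)
  }, numeric(1))
}

# A small deterministic GWAS table for filter tests.
toy_gwas <- function(n = 6) {
  gwas_table(rsid = sprintf("rs%03d", seq_len(n)),
             chrom = "1", pos = 1e6 + seq_len(n) * 1e5,
             effect_allele = "A", other_allele = "G",
             eaf = 0.3, beta = 0.1 * seq_len(n), se = 0.01,
             pval = 10^(-6 - seq_len(n)), n = 18340)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
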