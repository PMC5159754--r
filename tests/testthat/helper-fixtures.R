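# Fixtures built in code: tiny summary-statistics tables and small
# simulated studies reused across test files.

# A well-formed 5-SNP record table; tweak fields per test.
tiny_records <- function() {
  data.frame(
    snp = paste0("rs", 1:5),
    chr = c("1", "1", "2", "2", "3"),
    bp = c(1000L, 250000L, 5000L, 300000L, 7000L),
    a1 = c("A", "C", "G", "T", "A"),
    a2 = c("G", "T", "A", "C", "C"),
    freq = c(0.2, 0.5, 0.7, 0.4, 0.9),
    beta = c(0.10, -0.05, 0.02, 0.30, -0.12),
    se = c(0.05, 0.04, 0.06, 0.05, 0.04),
    n = 1000L)
}

tiny_cohort <- function(id = "c1", ...) {
  cohort_summary(tiny_records(), cohort_id = id, ...)
}

# Small two-population reference panel + matching cohorts for Fst/meta-PCA
# tests; freqs are population (not sample) frequencies.
small_two_pop_setup <- function(m = 4000, f = 0.02, seed = 42) {
  set.seed(seed)
  snps <- sim_snp_map(m)
  fr <- sim_ref_freqs(m, pops = c(P1 = f, P2 = f))
  list(snps = snps, freqs = fr)
}

# Cohort summary whose reported frequencies are binomial samples from a
# population frequency vector (no GWAS needed).
freq_only_cohort <- function(snps, p, n, id) {
  rec <- data.frame(snp = snps$snp, chr = snps$chr, bp = snps$bp,
                    a1 = snps$a1, a2 = snps$a2,
                    freq = sample_freqs(p, n),
                    beta = 0, se = 1, n = n)
  cohort_summary(rec, cohort_id = id)
}
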