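# Reading, validation, allele harmonization and marker thinning for
# per-cohort GWAS summary statistics. Everything downstream (Fst, meta-PCA,
# lambda_meta, PPSR candidate SNPs) consumes cohort_summary objects built
# here.

#' Default header-name mapping for summary-statistics files
#'
#' Maps internal field names to the column headers expected in a
#' GWAMA-style tab-delimited file. Override entries to read files with
#' different headers, e.g. `default_column_map(freq = "EAF", n = "NMISS")`.
#'
#' @param ... named overrides, internal name = file header.
#' @return named character vector (internal name -> file column).
#' @export
default_column_map <- function(...) {
  map <- c(snp = "SNP", chr = "CHR", bp = "BP", a1 = "A1", a2 = "A2",
           freq = "FREQ", beta = "BETA", se = "SE", n = "N")
  dots <- c(...)
  map[names(dots)] <- dots
  map
}

#' Construct a cohort_summary object
#'
#' A `cohort_summary` holds one cohort's per-SNP summary statistics (effect
#' allele a1, other allele a2, effect-allele frequency, allelic effect with
#' its standard error, and sample size) plus cohort metadata. Records are
#' validated against field invariants; offending rows are dropped and
#' tallied in the attached load report.
#'
#' Rules enforced per row: alleles are single upper-case A/C/G/T and
#' distinct; bp > 0; se > 0 when present; freq in \[0,1\] when present;
#' n >= 1; SNP ids unique within the cohort. Missing freq is allowed (such
#' records are excluded from frequency-based metrics only); missing beta/se
#' marks a monomorphic or failed regression and is excluded from
#' effect-size metrics.
#'
#' @param records data.frame with columns snp, chr, bp, a1, a2, freq, beta,
#'   se, n.
#' @param cohort_id cohort identifier.
#' @param trait trait name.
#' @param declared_ancestry optional self-declared ancestry label.
#' @return object of class `cohort_summary`: list with `cohort_id`,
#'   `trait`, `records` (data.table sorted by chr, bp), `declared_ancestry`,
#'   `n_median`, and `load_report` (named counts of dropped rows).
#' @export
cohort_summary <- function(records, cohort_id, trait = "trait",
                           declared_ancestry = NULL) {
  dt <- data.table::as.data.table(records)
  need <- c("snp", "chr", "bp", "a1", "a2", "freq", "beta", "se", "n")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stopf("records lack mandatory column(s): %s", paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, `:=`(snp = as.character(snp), chr = as.character(chr),
            bp = as.integer(bp), a1 = toupper(as.character(a1)),
            a2 = toupper(as.character(a2)), freq = as.numeric(freq),
            beta = as.numeric(beta), se = as.numeric(se),
            n = as.integer(n))]

  report <- c(bad_allele = 0L, bad_bp = 0L, bad_se = 0L, bad_freq = 0L,
              bad_n = 0L, duplicate_snp = 0L)
  ok_allele <- dt$a1 %in% c("A", "C", "G", "T") &
    dt$a2 %in% c("A", "C", "G", "T") & dt$a1 != dt$a2
  ok_bp <- !is.na(dt$bp) & dt$bp > 0L
  ok_se <- is.na(dt$se) | dt$se > 0
  ok_freq <- is.na(dt$freq) | (dt$freq >= 0 & dt$freq <= 1)
  ok_n <- !is.na(dt$n) & dt$n >= 1L
  report["bad_allele"] <- sum(!ok_allele)
  report["bad_bp"] <- sum(ok_allele & !ok_bp)
  report["bad_se"] <- sum(ok_allele & ok_bp & !ok_se)
  report["bad_freq"] <- sum(ok_allele & ok_bp & ok_se & !ok_freq)
  report["bad_n"] <- sum(ok_allele & ok_bp & ok_se & ok_freq & !ok_n)
  dt <- dt[ok_allele & ok_bp & ok_se & ok_freq & ok_n]
  dup <- duplicated(dt$snp)
  report["duplicate_snp"] <- sum(dup)
  dt <- dt[!dup]
  if (nrow(dt) == 0L) stopf("cohort '%s': no valid records", cohort_id)
  data.table::setorder(dt, chr, bp)

  structure(list(cohort_id = as.character(cohort_id),
                 trait = as.character(trait),
                 records = dt,
                 declared_ancestry = declared_ancestry,
                 n_median = as.integer(stats::median(dt$n)),
                 load_report = report),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s (%s): %d SNPs, median n = %d\n",
              x$cohort_id, x$trait, nrow(x$records), x$n_median))
  dropped <- sum(x$load_report)
  if (dropped > 0)
    cat(sprintf("  load report: %d row(s) dropped (%s)\n", dropped,
                paste(sprintf("%s=%d", names(x$load_report),
                              x$load_report)[x$load_report > 0],
                      collapse = ", ")))
  invisible(x)
}

#' Read a GWAMA-style summary-statistics file
#'
#' Delimited text with a header row; leading `#` comment lines (provenance
#' headers written by this package) are skipped. Rows violating field
#' invariants are dropped and counted in the load report.
#'
#' @param path file path.
#' @param column_map internal-name -> header mapping, see
#'   [default_column_map()]. The `freq` column may be absent from the file
#'   (recorded as missing).
#' @param cohort_id cohort identifier; defaults to the file name.
#' @param trait trait label.
#' @return a [cohort_summary()].
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          cohort_id = NULL, trait = "trait") {
  dt <- read_table_skip_comments(path)
  mandatory <- setdiff(names(default_column_map()), "freq")
  missing_cols <- setdiff(column_map[mandatory], names(dt))
  if (length(missing_cols))
    stopf("'%s' lacks mandatory column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  out <- data.table::data.table(
    snp = dt[[column_map["snp"]]], chr = dt[[column_map["chr"]]],
    bp = dt[[column_map["bp"]]], a1 = dt[[column_map["a1"]]],
    a2 = dt[[column_map["a2"]]],
    freq = if (column_map["freq"] %in% names(dt))
      dt[[column_map["freq"]]] else NA_real_,
    beta = dt[[column_map["beta"]]], se = dt[[column_map["se"]]],
    n = dt[[column_map["n"]]])
  cohort_summary(out, cohort_id %||% sub("\\.[^.]*$", "", basename(path)),
                 trait = trait)
}

#' Write a cohort_summary to a tab-delimited file
#'
#' Writes the standard header (SNP CHR BP A1 A2 FREQ BETA SE N) preceded by
#' provenance comment lines; [read_sumstats()] round-trips the records.
#'
#' @param x a [cohort_summary()].
#' @param path output path.
#' @param provenance optional named list added to the comment header.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, provenance = list()) {
  stopifnot(inherits(x, "cohort_summary"))
  out <- data.table::copy(x$records)
  data.table::setnames(out, c("snp", "chr", "bp", "a1", "a2", "freq",
                              "beta", "se", "n"),
                       c("SNP", "CHR", "BP", "A1", "A2", "FREQ", "BETA",
                         "SE", "N"))
  write_table_with_header(out, path,
                          c(list(cohort_id = x$cohort_id, trait = x$trait),
                            provenance))
}

#' Harmonize two cohorts' summary statistics to a shared allele orientation
#'
#' Matches records by SNP id and re-expresses cohort 2 on cohort 1's effect
#' allele so that effect sizes and frequencies are directly comparable:
#' where cohort 2 reports the allele pair swapped, its beta is sign-flipped
#' and its frequency becomes 1 - freq; strand flips (both alleles
#' complemented) are resolved the same way. Strand-ambiguous (A/T, C/G)
#' SNPs cannot be resolved from allele letters and are dropped when
#' `drop_ambiguous` (the default); SNPs whose allele pairs are
#' irreconcilable are always dropped. Both drop counts are reported.
#'
#' @param c1,c2 [cohort_summary()] objects.
#' @param drop_ambiguous drop palindromic SNPs (default TRUE).
#' @return object of class `aligned_pair`: cohort ids, and per shared SNP
#'   the keys (cohort 1 orientation) plus beta1/se1/freq1/n1 and aligned
#'   beta2/se2/freq2/n2, with `n_dropped_ambiguous` and
#'   `n_dropped_mismatch` counts.
#' @export
harmonize_pair <- function(c1, c2, drop_ambiguous = TRUE) {
  stopifnot(inherits(c1, "cohort_summary"), inherits(c2, "cohort_summary"))
  m <- merge(c1$records, c2$records, by = "snp", suffixes = c("", ".2"))
  if (nrow(m) == 0L)
    stopf("cohorts '%s' and '%s' share no SNP ids", c1$cohort_id, c2$cohort_id)

  same <- m$a1.2 == m$a1 & m$a2.2 == m$a2
  swap <- m$a1.2 == m$a2 & m$a2.2 == m$a1
  flip_same <- m$a1.2 == dna_complement(m$a1) & m$a2.2 == dna_complement(m$a2)
  flip_swap <- m$a1.2 == dna_complement(m$a2) & m$a2.2 == dna_complement(m$a1)
  pal <- is_palindromic(m$a1, m$a2)

  resolvable <- same | swap | flip_same | flip_swap
  n_mismatch <- sum(!resolvable)
  keep <- resolvable
  n_ambiguous <- 0L
  if (drop_ambiguous) {
    n_ambiguous <- sum(resolvable & pal)
    keep <- keep & !pal
  }
  m <- m[keep]
  flip_effect <- (swap | flip_swap)[keep]
  m[flip_effect, `:=`(beta.2 = -beta.2, freq.2 = 1 - freq.2)]

  data.table::setorder(m, chr, bp)
  structure(list(cohort1_id = c1$cohort_id, cohort2_id = c2$cohort_id,
                 snp = m$snp, chr = m$chr, bp = m$bp, a1 = m$a1, a2 = m$a2,
                 beta1 = m$beta, se1 = m$se, freq1 = m$freq, n1 = m$n,
                 beta2 = m$beta.2, se2 = m$se.2, freq2 = m$freq.2,
                 n2 = m$n.2,
                 n_dropped_ambiguous = n_ambiguous,
                 n_dropped_mismatch = n_mismatch),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %s vs %s: %d shared SNPs (%d ambiguous, %d mismatched dropped)\n",
              x$cohort1_id, x$cohort2_id, length(x$snp),
              x$n_dropped_ambiguous, x$n_dropped_mismatch))
  invisible(x)
}

#' Thin markers to an approximately independent subset
#'
#' Distance-based thinning standing in for LD pruning when no genotype
#' reference is available: selects up to `target_m` SNPs such that any two
#' selected SNPs on the same chromosome are at least `min_gap_bp` apart.
#' Candidates are visited in uniform-random order under `seed`, so the
#' selection is an unbiased draw among gap-respecting subsets and is
#' deterministic given the seed.
#'
#' @param x a [cohort_summary()], [harmonize_pair()] result, or data.frame
#'   with columns snp, chr, bp.
#' @param target_m maximum number of SNPs to return (default 30000, the
#'   count used for the lambda_meta T statistics).
#' @param min_gap_bp minimum separation in base pairs (default 1e5).
#' @param seed RNG seed.
#' @return character vector of selected SNP ids. Warns when supply falls
#'   short of `target_m`.
#' @export
prune_independent <- function(x, target_m = 30000L, min_gap_bp = 1e5,
                              seed = 2016L) {
  stopifnot(target_m >= 1)
  if (inherits(x, "cohort_summary")) {
    dt <- x$records[, .(snp, chr, bp)]
  } else if (inherits(x, "aligned_pair")) {
    dt <- data.table::data.table(snp = x$snp, chr = x$chr, bp = x$bp)
  } else {
    dt <- data.table::as.data.table(x)[, .(snp, chr, bp)]
  }
  set.seed(seed)
  ord <- sample.int(nrow(dt))
  chr_f <- as.integer(factor(dt$chr))
  taken_bp <- vector("list", max(chr_f))
  picked <- integer(min(target_m, nrow(dt)))
  n_picked <- 0L
  for (i in ord) {
    ch <- chr_f[i]
    pos <- dt$bp[i]
    bps <- taken_bp[[ch]]
    if (is.null(bps) || all(abs(bps - pos) >= min_gap_bp)) {
      taken_bp[[ch]] <- c(bps, pos)
      n_picked <- n_picked + 1L
      picked[n_picked] <- i
      if (n_picked >= target_m) break
    }
  }
  picked <- picked[seq_len(n_picked)]
  if (length(picked) < target_m)
    warnf("prune_independent: only %d of %d requested SNPs available under the %g bp gap",
          length(picked), target_m, min_gap_bp)
  dt$snp[sort(picked)]
}

#' Flip the stored allele orientation of selected records
#'
#' Re-expresses records on the other allele (a1 and a2 exchanged, beta
#' negated, freq complemented). The underlying association is unchanged;
#' this is the representation change that [harmonize_pair()] must undo,
#' and the simulator uses it to plant known allele swaps.
#'
#' @param x a [cohort_summary()].
#' @param idx integer or logical row index into the (chr, bp)-sorted records.
#' @return a new `cohort_summary` with flipped representation on `idx`.
#' @export
flip_alleles <- function(x, idx) {
  stopifnot(inherits(x, "cohort_summary"))
  rec <- data.table::copy(x$records)
  tmp <- rec$a1[idx]
  rec[idx, `:=`(a1 = rec$a2[idx])]
  rec[idx, `:=`(a2 = tmp)]
  rec[idx, `:=`(beta = -rec$beta[idx], freq = 1 - rec$freq[idx])]
  cohort_summary(rec, x$cohort_id, x$trait, x$declared_ancestry)
}
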