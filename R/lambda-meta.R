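# lambda_meta: a median-based pairwise statistic on summary statistics.
# For each SNP shared by two cohorts, T = (b1 - b2)^2 / (se1^2 + se2^2);
# under independent, homogeneous cohorts T ~ chi-square(1 df), so the
# ratio of the median T to the chi-square(1) median has expectation 1.
# Overlapping samples correlate the two estimates and deflate lambda
# below 1; effect-size heterogeneity inflates it above 1.

#' Median of the chi-square distribution with 1 degree of freedom
#'
#' Computed from the inverse CDF at full double precision
#' (0.45493642...; the value usually quoted as 0.455).
#'
#' @return scalar.
#' @export
chisq1_median <- function() qchisq(0.5, df = 1)

#' Per-SNP T statistics for a harmonized cohort pair
#'
#' \eqn{T_i = (b_{1i} - b_{2i})^2 / (\sigma_{1i}^2 + \sigma_{2i}^2)}:
#' the squared difference of reported allelic effects over the sum of the
#' reported sampling variances. Effects must already be on the same allele
#' (see [harmonize_pair()]).
#'
#' @param beta1,se1,beta2,se2 aligned numeric vectors; all se > 0.
#' @return numeric vector of T values (NA where any input is NA).
#' @export
t_stats <- function(beta1, se1, beta2, se2) {
  stopifnot(length(beta1) == length(beta2), length(se1) == length(beta1),
            length(se2) == length(beta1))
  if (any(se1 <= 0 | se2 <= 0, na.rm = TRUE))
    stopf("t_stats: standard errors must be positive")
  (beta1 - beta2)^2 / (se1^2 + se2^2)
}

#' lambda_meta from a vector of T statistics
#'
#' The median of the T values divided by the chi-square(1 df) median.
#'
#' @param t_values numeric vector (NAs dropped).
#' @return lambda scalar (>= 0).
#' @export
compute_lambda <- function(t_values) {
  t_values <- t_values[!is.na(t_values)]
  stopifnot(length(t_values) > 0)
  stats::median(t_values) / chisq1_median()
}

#' Allele-frequency parameterization of lambda_meta
#'
#' Replaces effect-size differences by allele-frequency differences:
#' \eqn{T_i = (p_{1i} - p_{2i})^2 / (p_{1i}(1-p_{1i})/2n_1 +
#' p_{2i}(1-p_{2i})/2n_2)}. SNPs monomorphic in either cohort carry no
#' information and are excluded (count returned as an attribute).
#'
#' @param freq1,freq2 allele-frequency vectors on the same allele.
#' @param n1,n2 diploid sample sizes (scalar or per-SNP).
#' @return lambda scalar with attributes `n_excluded` and `m` (SNPs used).
#' @export
lambda_af <- function(freq1, n1, freq2, n2) {
  stopifnot(length(freq1) == length(freq2))
  poly <- !is.na(freq1) & !is.na(freq2) &
    freq1 > 0 & freq1 < 1 & freq2 > 0 & freq2 < 1
  n_excluded <- sum(!poly)
  p1 <- freq1[poly]; p2 <- freq2[poly]
  if (length(n1) > 1) n1 <- n1[poly]
  if (length(n2) > 1) n2 <- n2[poly]
  if (length(p1) == 0) stopf("lambda_af: no polymorphic SNPs")
  tv <- (p1 - p2)^2 / (p1 * (1 - p1) / (2 * n1) + p2 * (1 - p2) / (2 * n2))
  structure(compute_lambda(tv), n_excluded = n_excluded, m = length(tv))
}

#' Genomic-control inflation factor
#'
#' Median of association chi-square statistics over the chi-square(1 df)
#' median; the within-cohort companion diagnostic to the pairwise
#' lambda_meta.
#'
#' @param chi2 non-negative association statistics (1 df).
#' @return lambda_GC scalar.
#' @export
lambda_gc <- function(chi2) {
  chi2 <- chi2[!is.na(chi2)]
  stopifnot(all(chi2 >= 0))
  stats::median(chi2) / chisq1_median()
}

#' Theoretical standard error of lambda_meta
#'
#' From the asymptotic variance of a sample median of m iid chi-square(1)
#' draws: \eqn{SE(\lambda) = \frac{1}{q} \sqrt{1 / (4 m f(q)^2)}} with q
#' the chi-square(1) median and f its density there. At m = 30000 this is
#' 0.0135 (the "theoretical SD of 0.014").
#'
#' @param m number of independent T statistics.
#' @return standard error of lambda under the null.
#' @export
lambda_se <- function(m) {
  q <- chisq1_median()
  (1 / q) * sqrt(1 / (4 * m * dchisq(q, df = 1)^2))
}

#' Transform lambda_meta into a correlation and an overlap count
#'
#' With overlapping samples the two reported effects satisfy
#' \eqn{Var(b_1 - b_2) = \sigma_1^2 + \sigma_2^2 - 2\gamma\sigma_1\sigma_2}
#' and \eqn{\sigma^2 \propto 1/n}, so
#' \eqn{E[\lambda] = 1 - \gamma\, 2\sqrt{n_1 n_2}/(n_1 + n_2)}. Inverting:
#' \eqn{\hat\gamma = (1-\lambda)(n_1+n_2)/(2\sqrt{n_1 n_2})} and, since
#' pure overlap of n_o individuals gives \eqn{\gamma = n_o/\sqrt{n_1 n_2}},
#' \eqn{\hat n_o = (1-\lambda)(n_1+n_2)/2}. A negative \eqn{\hat\gamma}
#' (lambda > 1) indicates heterogeneity rather than overlap, so no overlap
#' count is reported then. Valid for quantitative traits; in case-control
#' designs the case/control ratio breaks the n_o interpretation.
#'
#' @param lambda lambda_meta value.
#' @param n1,n2 cohort sample sizes.
#' @return list with `gamma_hat` (estimated summary-statistic correlation)
#'   and `n_o_hat` (effective overlapping samples; NA when lambda >= 1).
#' @export
gamma_from_lambda <- function(lambda, n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  gamma_hat <- (1 - lambda) * (n1 + n2) / (2 * sqrt(n1 * n2))
  n_o_hat <- if (lambda < 1) (1 - lambda) * (n1 + n2) / 2 else NA_real_
  list(gamma_hat = gamma_hat, n_o_hat = n_o_hat)
}

#' Full lambda_meta analysis of one cohort pair
#'
#' Harmonizes alleles, thins to approximately independent markers,
#' computes the T statistics and lambda_meta, its theoretical standard
#' error, the z/p against 1, and the overlap transformation.
#'
#' @param c1,c2 [cohort_summary()] objects.
#' @param mode `"beta"` (effect-size T) or `"af"` (allele-frequency T,
#'   usable when betas are unavailable; requires freq and n).
#' @param target_m markers to retain after thinning (default 30000).
#' @param min_gap_bp thinning gap, see [prune_independent()].
#' @param seed seed for the marker draw.
#' @param gc_adjusted set TRUE to annotate that the input SEs were genomic-
#'   control adjusted (lambda_meta is then deflated relative to unadjusted
#'   inputs; the flag travels with the result, no automatic un-correction).
#' @return object of class `lambda_result`: lambda_meta, m_snps,
#'   theoretical_se, z_vs_1, p_vs_1, gamma_hat, n_o_hat, mode, gc_adjusted,
#'   and the T quantiles (`t_sorted`) for QQ-style plots.
#' @export
pair_lambda <- function(c1, c2, mode = c("beta", "af"), target_m = 30000L,
                        min_gap_bp = 1e5, seed = 2016L,
                        gc_adjusted = FALSE) {
  mode <- match.arg(mode)
  ap <- harmonize_pair(c1, c2)
  ok <- if (mode == "beta") !is.na(ap$beta1) & !is.na(ap$beta2) &
    !is.na(ap$se1) & !is.na(ap$se2)
  else !is.na(ap$freq1) & !is.na(ap$freq2)
  keep_dt <- data.table::data.table(snp = ap$snp, chr = ap$chr,
                                    bp = ap$bp)[ok]
  sel <- prune_independent(keep_dt, target_m = target_m,
                           min_gap_bp = min_gap_bp, seed = seed)
  idx <- which(ap$snp %in% sel)
  tv <- if (mode == "beta") {
    t_stats(ap$beta1[idx], ap$se1[idx], ap$beta2[idx], ap$se2[idx])
  } else {
    p1 <- ap$freq1[idx]; p2 <- ap$freq2[idx]
    poly <- p1 > 0 & p1 < 1 & p2 > 0 & p2 < 1
    (p1[poly] - p2[poly])^2 /
      (p1[poly] * (1 - p1[poly]) / (2 * ap$n1[idx][poly]) +
         p2[poly] * (1 - p2[poly]) / (2 * ap$n2[idx][poly]))
  }
  lam <- compute_lambda(tv)
  m <- length(tv)
  se_t <- lambda_se(m)
  z <- (lam - 1) / se_t
  n1 <- stats::median(ap$n1[idx]); n2 <- stats::median(ap$n2[idx])
  tr <- gamma_from_lambda(lam, n1, n2)
  structure(list(cohort1_id = ap$cohort1_id, cohort2_id = ap$cohort2_id,
                 lambda_meta = lam, m_snps = m, theoretical_se = se_t,
                 z_vs_1 = z, p_vs_1 = 2 * pnorm(-abs(z)),
                 gamma_hat = tr$gamma_hat, n_o_hat = tr$n_o_hat,
                 mode = mode, gc_adjusted = gc_adjusted,
                 t_sorted = sort(tv)),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("<lambda_result> %s vs %s (%s mode%s)\n", x$cohort1_id,
              x$cohort2_id, x$mode,
              if (x$gc_adjusted) ", GC-adjusted inputs" else ""))
  cat(sprintf("  lambda_meta = %.4f (m = %d, theoretical SE = %.4f)\n",
              x$lambda_meta, x$m_snps, x$theoretical_se))
  cat(sprintf("  z vs 1 = %.2f, p = %.3g\n", x$z_vs_1, x$p_vs_1))
  cat(sprintf("  gamma_hat = %.4f, n_o_hat = %s\n", x$gamma_hat,
              if (is.na(x$n_o_hat)) "NA (lambda >= 1: heterogeneity)"
              else sprintf("%.1f", x$n_o_hat)))
  invisible(x)
}

#' All-pairs lambda_meta scan across cohorts
#'
#' Computes [pair_lambda()] for every unordered cohort pair and assembles
#' a symmetric lambda matrix plus a long-format table with two z tests per
#' pair: against the theoretical null SE and against the empirical
#' across-pair mean and SD (useful when mild study-wide heterogeneity
#' shifts the whole distribution). Pair flags use Bonferroni correction
#' over the number of pairs.
#'
#' @param cohorts list of >= 2 [cohort_summary()] objects.
#' @param mode `"beta"` or `"af"`.
#' @param target_m,min_gap_bp,seed see [pair_lambda()]; each pair draws
#'   its markers with seed + pair index for reproducibility.
#' @param gc_adjusted annotation flag, see [pair_lambda()].
#' @param min_m pairs with fewer shared thinned markers are skipped with a
#'   warning (default 100).
#' @return object of class `lambda_scan`: `matrix` (symmetric, NA
#'   diagonal/skips), `pairs` (data.table: id1, id2, m, lambda, se_theo,
#'   z_theo, p_theo, z_emp, p_emp, gamma_hat, n_o_hat, sig_bonferroni),
#'   `mode`, `seed`.
#' @export
pairwise_scan <- function(cohorts, mode = c("beta", "af"),
                          target_m = 30000L, min_gap_bp = 1e5,
                          seed = 2016L, gc_adjusted = FALSE, min_m = 100L) {
  mode <- match.arg(mode)
  stopifnot(length(cohorts) >= 2)
  ids <- vapply(cohorts, `[[`, character(1), "cohort_id")
  k <- length(cohorts)
  lam_mat <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  rows <- list()
  pair_idx <- 0L
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pair_idx <- pair_idx + 1L
    res <- tryCatch(
      pair_lambda(cohorts[[i]], cohorts[[j]], mode = mode,
                  target_m = target_m, min_gap_bp = min_gap_bp,
                  seed = (seed + pair_idx) %% .Machine$integer.max,
                  gc_adjusted = gc_adjusted),
      error = function(e) e)
    if (inherits(res, "error") || res$m_snps < min_m) {
      warnf("pairwise_scan: pair %s/%s skipped (%s)", ids[i], ids[j],
            if (inherits(res, "error")) conditionMessage(res)
            else sprintf("only %d markers", res$m_snps))
      next
    }
    lam_mat[i, j] <- lam_mat[j, i] <- res$lambda_meta
    rows[[length(rows) + 1L]] <- data.table::data.table(
      id1 = ids[i], id2 = ids[j], m = res$m_snps,
      lambda = res$lambda_meta, se_theo = res$theoretical_se,
      z_theo = res$z_vs_1, p_theo = res$p_vs_1,
      gamma_hat = res$gamma_hat, n_o_hat = res$n_o_hat)
  }
  if (length(rows) == 0L) stopf("pairwise_scan: no computable pairs")
  pairs <- data.table::rbindlist(rows)
  mu <- mean(pairs$lambda); s <- stats::sd(pairs$lambda)
  pairs[, z_emp := if (is.na(s) || s == 0) NA_real_ else (lambda - mu) / s]
  pairs[, p_emp := 2 * pnorm(-abs(z_emp))]
  pairs[, sig_bonferroni := p_theo < 0.05 / nrow(pairs)]
  structure(list(matrix = lam_mat, pairs = pairs[], mode = mode,
                 seed = seed, empirical_mean = mu, empirical_sd = s),
            class = "lambda_scan")
}

#' @export
print.lambda_scan <- function(x, ...) {
  cat(sprintf("<lambda_scan> %d cohorts, %d pairs (%s mode)\n",
              nrow(x$matrix), nrow(x$pairs), x$mode))
  cat(sprintf("  lambda: mean %.4f, empirical SD %.4f, theoretical SE %.4f\n",
              x$empirical_mean, x$empirical_sd, x$pairs$se_theo[1]))
  nsig <- sum(x$pairs$sig_bonferroni)
  if (nsig > 0)
    cat(sprintf("  %d pair(s) significant after Bonferroni correction\n", nsig))
  invisible(x)
}
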