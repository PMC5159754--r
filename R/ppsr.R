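# Pseudo profile score regression (PPSR). The analysis hub draws K random
# standard-normal weight vectors over M SNPs and distributes them; each
# cohort returns, per individual, the K weighted combinations of its
# standardized genotypes ("pseudo profile scores"). Regressing one
# individual's K scores on another's estimates their genome-wide genetic
# relationship (about 1 for duplicates, 0.5 for first-degree relatives),
# so duplicates can be pinpointed across cohorts without genotype sharing.

#' Generate hub-side random SNP weights
#'
#' K i.i.d. standard-normal weight vectors over M candidate SNPs,
#' reproducible under `seed`. Candidate SNPs should be directly genotyped
#' in all cohorts; strand-ambiguous (A/T, C/G) SNPs are rejected because
#' cohorts could not harmonize them reliably. The hub also fixes the
#' standardization frequencies so that scores are computed on the same
#' scale in every cohort.
#'
#' @param snps data.frame with columns snp, a1, a2.
#' @param K number of scores (see [required_scores()] for choosing it).
#' @param seed RNG seed.
#' @param ref_freq numeric vector, reference frequency of a1 per SNP, used
#'   for centering/scaling in [compute_scores()]; values in (0,1).
#' @return object of class `weight_set`: `snps`, `weights` (M x K),
#'   `seed`, `freq`.
#' @export
generate_weights <- function(snps, K, seed, ref_freq) {
  snps <- data.table::as.data.table(snps)
  stopifnot(nrow(snps) >= 1, K >= 1, length(ref_freq) == nrow(snps),
            all(ref_freq > 0 & ref_freq < 1))
  pal <- is_palindromic(toupper(snps$a1), toupper(snps$a2))
  if (any(pal))
    stopf("generate_weights: %d palindromic SNP(s) in candidate list (e.g. %s); supply non-ambiguous SNPs",
          sum(pal), snps$snp[which(pal)[1]])
  set.seed(seed)
  w <- matrix(rnorm(nrow(snps) * K), nrow(snps), K,
              dimnames = list(snps$snp, paste0("PPS", seq_len(K))))
  structure(list(snps = snps, weights = w, seed = seed,
                 freq = stats::setNames(ref_freq, snps$snp)),
            class = "weight_set")
}

#' Compute pseudo profile scores for a cohort
#'
#' Each genotype is standardized with the hub's reference frequency p:
#' \eqn{x = (g - 2p)/\sqrt{2p(1-p)}}; missing genotypes become 0 after
#' centering (mean imputation), which keeps the method robust to the
#' percent-level missingness that defeats exact-hash matching. Score k of
#' an individual is \eqn{\sum_m x_m w_{mk} / \sqrt{M}}; the \eqn{1/\sqrt M}
#' scaling makes regression coefficients comparable across M.
#'
#' @param genotypes n x M matrix of 0/1/2 dosages of each SNP's a1 allele,
#'   columns named and ordered as `w$snps$snp`; NA = missing. Row names
#'   are individual ids.
#' @param w a [weight_set()][generate_weights()].
#' @return n x K score matrix (class `score_matrix`), individual ids as
#'   row names.
#' @export
compute_scores <- function(genotypes, w) {
  stopifnot(inherits(w, "weight_set"), is.matrix(genotypes),
            ncol(genotypes) == nrow(w$weights))
  if (!is.null(colnames(genotypes)) &&
      !identical(colnames(genotypes), w$snps$snp))
    stopf("compute_scores: genotype columns do not match the weight set's SNP list/order; harmonize first")
  p <- w$freq
  x <- sweep(genotypes, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  scores <- x %*% w$weights / sqrt(nrow(w$weights))
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("ind", seq_len(nrow(scores)))
  class(scores) <- c("score_matrix", class(scores))
  scores
}

#' All-pairs pseudo profile score regression between two cohorts
#'
#' For individuals i (cohort a) and j (cohort b), the regression
#' coefficient of j's K scores on i's, \eqn{b_{ij} =
#' cov(s_i, s_j)/var(s_i)}, estimates their genome-wide relationship on
#' the standardized-genotype (GRM) scale. All n_a x n_b coefficients are
#' obtained in one matrix product of the row-centered score matrices. The
#' classification of a pair uses the larger of the two directed
#' coefficients, which is robust to one-sided missingness deflating a
#' row's score variance.
#'
#' @param a,b score matrices from [compute_scores()] built with the same
#'   weight set.
#' @param thresholds named vector: `duplicate` (default 0.95) and
#'   `first_degree` (default 0.45) coefficient cutoffs.
#' @param return_matrix also return the dense coefficient matrix (memory:
#'   n_a x n_b doubles; default FALSE).
#' @return object of class `match_result`: `matches` (data.table: id1,
#'   id2, b, b12, b21, relation), `n_tests`, `n_skipped` (zero-variance
#'   score rows), `thresholds`, and with `return_matrix` the dense
#'   `b_matrix` (pairwise max) plus the directed `b12_matrix` and
#'   `b21_matrix`.
#' @export
match_pairs <- function(a, b,
                        thresholds = c(duplicate = 0.95, first_degree = 0.45),
                        return_matrix = FALSE) {
  stopifnot(ncol(a) == ncol(b), ncol(a) >= 2)
  K <- ncol(a)
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  va <- rowSums(ac^2) / (K - 1)
  vb <- rowSums(bc^2) / (K - 1)
  skip_a <- va == 0
  skip_b <- vb == 0
  cov_ab <- tcrossprod(ac, bc) / (K - 1)          # n_a x n_b covariances
  b12 <- cov_ab / ifelse(va == 0, NA_real_, va)   # regress b's scores on a's
  b21 <- cov_ab / rep(ifelse(vb == 0, NA_real_, vb), each = nrow(a))
  bmax <- pmax(b12, b21, na.rm = TRUE)
  bmax[skip_a, ] <- NA_real_
  bmax[, skip_b] <- NA_real_

  hit <- which(!is.na(bmax) & bmax >= thresholds[["first_degree"]],
               arr.ind = TRUE)
  matches <- data.table::data.table(
    id1 = rownames(a)[hit[, 1]], id2 = rownames(b)[hit[, 2]],
    b = bmax[hit], b12 = b12[hit], b21 = b21[hit])
  matches[, relation := ifelse(b >= thresholds[["duplicate"]], "duplicate",
                               "first_degree")]
  data.table::setorder(matches, -b)
  structure(list(matches = matches[], n_tests = nrow(a) * nrow(b),
                 n_skipped = sum(skip_a) * ncol(b) +
                   sum(skip_b) * nrow(a),
                 thresholds = thresholds,
                 b_matrix = if (return_matrix) bmax else NULL,
                 b12_matrix = if (return_matrix) b12 else NULL,
                 b21_matrix = if (return_matrix) b21 else NULL),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pair tests: %d duplicate, %d first-degree candidates\n",
              x$n_tests, sum(x$matches$relation == "duplicate"),
              sum(x$matches$relation == "first_degree")))
  if (nrow(x$matches)) print(head(x$matches, 10))
  invisible(x)
}

#' Minimum number of pseudo profile scores for a detection design
#'
#' With K scores the regression coefficient has variance 1/K under the
#' null (unrelated pair) and \eqn{(1-\rho^2)/K} under the alternative that
#' the true relationship is \eqn{\rho}. A one-sided test with per-test
#' level \eqn{\alpha = \alpha_{exp}/n_{tests}} (Bonferroni over all
#' individual-pair tests) and power \eqn{1-\beta} therefore needs
#' \deqn{K = \lceil ((z_{1-\alpha} + z_{1-\beta}\sqrt{1-\rho^2})/\rho)^2
#' \rceil.}
#' For duplicate detection across half a billion pair tests at
#' experiment-wise level 0.01 and power 0.95 with \eqn{\rho = 0.95}, this
#' gives K = 57.
#'
#' @param n_tests total number of individual-pair tests across all cohort
#'   pairs.
#' @param alpha_exp experiment-wise type I error rate (default 0.01).
#' @param beta type II error rate (default 0.05).
#' @param rho_threshold true coefficient to be detected (0.95 for
#'   duplicates, 0.45-0.5 for first-degree relatives).
#' @return list of class `ppsr_design`: `K_required` plus the inputs and
#'   the per-test alpha.
#' @export
required_scores <- function(n_tests, alpha_exp = 0.01, beta = 0.05,
                            rho_threshold = 0.95) {
  stopifnot(n_tests >= 1, alpha_exp > 0, alpha_exp < 1, beta > 0, beta < 1,
            rho_threshold > 0, rho_threshold <= 1)
  alpha <- alpha_exp / n_tests
  z_a <- qnorm(1 - alpha)
  z_b <- qnorm(1 - beta)
  K <- ceiling(((z_a + z_b * sqrt(1 - rho_threshold^2)) / rho_threshold)^2)
  structure(list(K_required = as.integer(K), n_tests = n_tests,
                 alpha_exp = alpha_exp, alpha_per_test = alpha,
                 beta = beta, rho_threshold = rho_threshold),
            class = "ppsr_design")
}

#' @export
print.ppsr_design <- function(x, ...) {
  cat(sprintf("<ppsr_design> K = %d scores (n_tests = %.0f, experiment-wise alpha = %g, power = %g, rho = %g)\n",
              x$K_required, x$n_tests, x$alpha_exp, 1 - x$beta,
              x$rho_threshold))
  invisible(x)
}

#' How much genotype information the scores leak back to the hub
#'
#' An analyst who knows the weight matrix S can attempt to reconstruct
#' standardized genotypes from the K scores by solving the linear system
#' s = S'x/sqrt(M) per individual in the least-squares sense (for K >= M
#' the solution is exact; for K < M the minimum-norm solution recovers the
#' projection of x onto the K-dimensional random subspace, so accuracy
#' scales with K/M). With true genotypes supplied, the per-SNP squared
#' correlation between reconstructed and true standardized genotypes is
#' reported, averaged within MAF bins.
#'
#' @param w a weight set.
#' @param scores score matrix from [compute_scores()].
#' @param true_genotypes optional n x M dosage matrix matching `scores`.
#' @param maf_breaks MAF bin edges (default 0, 0.1, 0.3, 0.5).
#' @return list of class `decode_risk`: `x_hat` (n x M reconstructed
#'   standardized genotypes), and with truth: `r2` per SNP, `by_maf_bin`
#'   (data.table: bin, mean_r2, n_snps), `mean_r2`.
#' @export
decode_risk <- function(w, scores, true_genotypes = NULL,
                        maf_breaks = c(0, 0.1, 0.3, 0.5)) {
  stopifnot(inherits(w, "weight_set"), ncol(scores) >= 2)
  W <- w$weights
  M <- nrow(W); K <- ncol(W)
  S <- unclass(scores) * sqrt(M)        # undo the 1/sqrt(M) scaling
  if (K >= M) {
    # over-determined: exact least squares via the M x M normal equations
    x_hat <- t(solve(W %*% t(W), W %*% t(S)))
  } else {
    # under-determined: minimum-norm solution in the weight row space
    x_hat <- t(W %*% solve(crossprod(W), t(S)))
  }
  colnames(x_hat) <- rownames(W)
  out <- list(x_hat = x_hat, K = K, M = M)
  if (!is.null(true_genotypes)) {
    p <- w$freq
    x_true <- sweep(sweep(true_genotypes, 2, 2 * p), 2,
                    sqrt(2 * p * (1 - p)), "/")
    r2 <- vapply(seq_len(M), function(m) {
      if (stats::sd(x_true[, m]) == 0 || stats::sd(x_hat[, m]) == 0)
        return(NA_real_)
      stats::cor(x_hat[, m], x_true[, m])^2
    }, numeric(1))
    maf <- pmin(p, 1 - p)
    bin <- cut(maf, breaks = maf_breaks, include.lowest = TRUE)
    by_bin <- data.table::data.table(bin = bin, r2 = r2)[
      , .(mean_r2 = mean(r2, na.rm = TRUE), n_snps = .N), by = bin]
    out$r2 <- r2
    out$by_maf_bin <- by_bin[]
    out$mean_r2 <- mean(r2, na.rm = TRUE)
  }
  structure(out, class = "decode_risk")
}

#' @export
print.decode_risk <- function(x, ...) {
  cat(sprintf("<decode_risk> K = %d scores over M = %d SNPs (K/M = %.2f)\n",
              x$K, x$M, x$K / x$M))
  if (!is.null(x$mean_r2)) {
    cat(sprintf("  mean decode R2 = %.3f\n", x$mean_r2))
    print(x$by_maf_bin)
  }
  invisible(x)
}
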