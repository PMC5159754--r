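# Pseudo profile scores: weights, scores, all-pairs regression, design
# calculation and decoding risk.

make_weight_setup <- function(M = 200, K = 57, n = 50, seed = 71,
                              miss_rate = 0) {
  set.seed(seed)
  snps <- sim_snp_map(M)
  p <- runif(M, 0.1, 0.9)
  w <- generate_weights(snps[, .(snp, a1, a2)], K = K, seed = seed + 1,
                        ref_freq = p)
  G <- sim_genotypes(p, n)
  colnames(G) <- snps$snp
  rownames(G) <- sprintf("i%03d", seq_len(n))
  if (miss_rate > 0) G[runif(length(G)) < miss_rate] <- NA
  list(snps = snps, p = p, w = w, G = G)
}

test_that("weights are reproducible, well-shaped and reject palindromic SNPs", {
  s <- make_weight_setup(M = 500, K = 57)
  expect_identical(s$w$weights,
                   generate_weights(s$snps[, .(snp, a1, a2)], K = 57,
                                    seed = 72, ref_freq = s$p)$weights)
  w_other <- generate_weights(s$snps[, .(snp, a1, a2)], K = 57, seed = 73,
                              ref_freq = s$p)
  expect_false(identical(s$w$weights, w_other$weights))
  expect_equal(dim(w_other$weights), c(500L, 57L))
  # column means over a large M are near zero (CLT bound 4/sqrt(M))
  big <- generate_weights(sim_snp_map(10000)[, .(snp, a1, a2)], K = 3,
                          seed = 5, ref_freq = runif(10000, 0.2, 0.8))
  expect_true(all(abs(colMeans(big$weights)) < 4 / sqrt(10000)))
  bad <- data.frame(snp = "rsX", a1 = "A", a2 = "T")
  expect_error(generate_weights(bad, 2, 1, 0.5), "palindromic")
})

test_that("scores: all-missing rows give 0, duplicated rows identical scores", {
  s <- make_weight_setup(n = 30)
  G <- s$G
  G[1, ] <- NA
  G[2, ] <- G[3, ]
  sc <- compute_scores(G, s$w)
  expect_equal(unname(unclass(sc)[1, ]), rep(0, ncol(sc)))
  expect_equal(unclass(sc)[2, ], unclass(sc)[3, ], ignore_attr = TRUE)
  # column order mismatch is an error, not a silent misalignment
  expect_error(compute_scores(G[, rev(seq_len(ncol(G)))], s$w),
               "match the weight set")
})

test_that("per-individual score variance matches the conditional analytic value", {
  s <- make_weight_setup(M = 400, K = 800, n = 20, seed = 73)
  sc <- unclass(compute_scores(s$G, s$w))
  x <- sweep(sweep(s$G, 2, 2 * s$p), 2, sqrt(2 * s$p * (1 - s$p)), "/")
  # conditional on genotypes, Var(score) over weight draws = (1/M) sum x^2
  v_expected <- rowSums(x^2) / ncol(s$G)
  v_obs <- apply(sc, 1, var)
  # K = 800 draws estimate each variance with SE ~ v*sqrt(2/K)
  expect_true(all(abs(v_obs - v_expected) < 4 * v_expected * sqrt(2 / 800)))
})

test_that("identical individuals regress with b = 1 exactly", {
  s <- make_weight_setup(n = 10)
  sc <- compute_scores(s$G, s$w)
  res <- match_pairs(sc, sc)
  self <- res$matches[id1 == id2]
  expect_equal(nrow(self), 10L)
  expect_equal(self$b, rep(1, 10))
  expect_true(all(self$relation == "duplicate"))
})

test_that("matrix-product coefficients equal a per-pair regression loop", {
  s1 <- make_weight_setup(M = 150, K = 40, n = 20, seed = 74)
  sc_a <- compute_scores(s1$G, s1$w)
  set.seed(99)
  G_b <- sim_genotypes(s1$p, 20)
  colnames(G_b) <- s1$snps$snp
  rownames(G_b) <- sprintf("j%03d", 1:20)
  sc_b <- compute_scores(G_b, s1$w)
  res <- match_pairs(sc_a, sc_b, thresholds = c(duplicate = 0.95,
                                                first_degree = -Inf),
                     return_matrix = TRUE)
  for (i in seq_len(20)) for (j in seq_len(20)) {
    fit_ij <- unname(coef(lm(unclass(sc_b)[j, ] ~ unclass(sc_a)[i, ]))[2])
    fit_ji <- unname(coef(lm(unclass(sc_a)[i, ] ~ unclass(sc_b)[j, ]))[2])
    expect_equal(res$b_matrix[i, j], max(fit_ij, fit_ji), tolerance = 1e-10)
  }
})

test_that("the PPSR coefficient estimates the standardized-genotype relationship", {
  set.seed(75)
  M <- 300
  snps <- sim_snp_map(M)
  p <- runif(M, 0.1, 0.9)
  G1 <- sim_genotypes(p, 6); colnames(G1) <- snps$snp
  G2 <- rbind(G1[1:2, ], sim_offspring(G1[3:4, , drop = FALSE], p),
              sim_genotypes(p, 2))
  colnames(G2) <- snps$snp
  rownames(G1) <- paste0("a", 1:6); rownames(G2) <- paste0("b", 1:6)
  std <- function(g) sweep(sweep(g, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(std(G1), std(G2)) / M   # true pairwise relationship
  # conditional on genotypes the scores are Gaussian, so the directed
  # slope is unbiased for A_ij normalized by i's realized self-
  # relatedness a_ii = (1/M) sum x_i^2 (which fluctuates around 1);
  # average over independent weight redraws with per-cell MC SEs
  a_ii <- rowSums(std(G1)^2) / M
  A_expect <- A / a_ii
  n_draws <- 50
  draws <- array(NA_real_, c(6, 6, n_draws))
  for (d in seq_len(n_draws)) {
    w <- generate_weights(snps[, .(snp, a1, a2)], K = 57, seed = 1000 + d,
                          ref_freq = p)
    res <- match_pairs(compute_scores(G1, w), compute_scores(G2, w),
                       thresholds = c(duplicate = 2, first_degree = -Inf),
                       return_matrix = TRUE)
    draws[, , d] <- res$b12_matrix
  }
  bbar <- apply(draws, c(1, 2), mean)
  mc_se <- apply(draws, c(1, 2), sd) / sqrt(n_draws)
  expect_true(all(abs(bbar - A_expect) < 4 * mc_se + 0.005))
  # duplicates regress with b = 1 exactly; parent-offspring near 0.5
  expect_equal(diag(bbar)[1:2], c(1, 1), tolerance = 1e-10)
  expect_equal(bbar[3, 3], A_expect[3, 3], tolerance = 0.1)
})

test_that("duplicate detection is stable across weight seeds at K = 57", {
  set.seed(76)
  sh <- sim_shared_controls(2, n_controls = 40, n_cases = 60, m_snps = 500,
                            seed = 76)
  for (sd in 1:5) {
    w <- generate_weights(sh$snps[, .(snp, a1, a2)], K = 57, seed = sd,
                          ref_freq = sh$p)
    res <- match_pairs(compute_scores(sh$genotypes[[1]], w),
                       compute_scores(sh$genotypes[[2]], w))
    dup <- res$matches[relation == "duplicate"]
    expect_setequal(dup$id1, sh$shared_ids)
    expect_true(all(dup$id1 == dup$id2))
  }
})

test_that("required_scores reproduces the closed-form design and is monotone", {
  d <- required_scores(488587090, alpha_exp = 0.01, beta = 0.05,
                       rho_threshold = 0.95)
  expect_identical(d$K_required, 57L)
  # doubling the allowed error rate never increases K
  d2 <- required_scores(488587090, alpha_exp = 0.02)
  expect_lte(d2$K_required, d$K_required)
  # more tests or a weaker target coefficient require more scores
  expect_gte(required_scores(1e10)$K_required, d$K_required)
  expect_gt(required_scores(488587090, rho_threshold = 0.45)$K_required,
            d$K_required)
})

test_that("the designed K delivers its power and the 0.95 rule its error control", {
  n_tests <- 2e5
  d <- required_scores(n_tests, alpha_exp = 0.01, beta = 0.05,
                       rho_threshold = 0.95)
  K <- d$K_required
  boundary <- qnorm(1 - d$alpha_per_test) / sqrt(K)
  set.seed(80)
  slope <- function(a, b) {
    ac <- a - rowMeans(a); bc <- b - rowMeans(b)
    rowSums(ac * bc) / rowSums(ac^2)
  }
  # null pairs: none reach the operational duplicate threshold 0.95
  a <- matrix(rnorm(n_tests * K), n_tests)
  b <- matrix(rnorm(n_tests * K), n_tests)
  expect_equal(sum(slope(a, b) >= 0.95), 0L)
  # power side of the design: true-duplicate pairs (coefficient 0.95)
  # clear the detection boundary at least 1 - beta of the time
  n_alt <- 2e4
  a2 <- matrix(rnorm(n_alt * K), n_alt)
  b2 <- 0.95 * a2 + sqrt(1 - 0.95^2) * matrix(rnorm(n_alt * K), n_alt)
  pow <- mean(slope(a2, b2) > boundary)
  expect_gte(pow, 0.95 - 3 * sqrt(0.05 * 0.95 / n_alt))
})

test_that("decode risk: exact recovery at K >= M, ~0 when decoupled, monotone in K", {
  s <- make_weight_setup(M = 60, K = 80, n = 40, seed = 81)
  sc <- compute_scores(s$G, s$w)
  risk_full <- decode_risk(s$w, sc, true_genotypes = s$G)
  expect_gt(risk_full$mean_r2, 0.999)
  # shuffling individuals decouples scores from genotypes
  set.seed(82)
  risk_null <- decode_risk(s$w, sc[sample(nrow(sc)), ],
                           true_genotypes = s$G)
  expect_lt(risk_null$mean_r2, 0.1)
  # monotone in K at fixed M
  s2 <- make_weight_setup(M = 500, K = 10, n = 60, seed = 83)
  r10 <- decode_risk(s2$w, compute_scores(s2$G, s2$w),
                     true_genotypes = s2$G)
  w50 <- generate_weights(s2$snps[, .(snp, a1, a2)], K = 50, seed = 84,
                          ref_freq = s2$p)
  r50 <- decode_risk(w50, compute_scores(s2$G, w50),
                     true_genotypes = s2$G)
  expect_gt(r50$mean_r2, r10$mean_r2)
  # privacy margin: K/M = 0.1 recovers far less than K/M = 1, and larger
  # M at fixed K leaks less
  expect_lt(r50$mean_r2, risk_full$mean_r2 - 0.5)
  s3 <- make_weight_setup(M = 1000, K = 10, n = 60, seed = 85)
  r10_bigM <- decode_risk(s3$w, compute_scores(s3$G, s3$w),
                          true_genotypes = s3$G)
  expect_lt(r10_bigM$mean_r2, r10$mean_r2)
})
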