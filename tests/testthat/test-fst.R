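# Hudson-type Fst, cohort distance profiles and the F_PC cartographer.

test_that("fst_pair hits the analytic endpoints", {
  p <- runif(100, 0.1, 0.9)
  # identical populations, huge n: correction terms vanish, estimate 0
  expect_equal(as.numeric(fst_pair(p, 1e9, p, 1e9)), 0, tolerance = 1e-9)
  # fixed difference at a single SNP
  expect_equal(as.numeric(fst_pair(1, 1e9, 0, 1e9)), 1, tolerance = 1e-9)
  expect_error(fst_pair(c(0, 0), 100, c(0, 0), 100), "monomorphic")
})

test_that("fst_pair is symmetric and de-inflates self-comparisons", {
  set.seed(21)
  p1 <- sample_freqs(runif(2000, 0.1, 0.9), 80)
  p2 <- sample_freqs(runif(2000, 0.1, 0.9), 120)
  expect_identical(as.numeric(fst_pair(p1, 80, p2, 120)),
                   as.numeric(fst_pair(p2, 120, p1, 80)))
  # same finite sample against itself: correction pushes raw value <= 0
  f_self <- fst_pair(p1, 80, p1, 80)
  expect_lte(attr(f_self, "raw"), 0)
  expect_equal(as.numeric(f_self), 0)
})

test_that("Balding-Nichols F is recovered and the estimate is monotone in F", {
  set.seed(77)
  m <- 30000
  fr <- sim_ref_freqs(m, pops = c(A = 0.01, B = 0.01))
  p1 <- sample_freqs(fr$pops[, "A"], 100)
  p2 <- sample_freqs(fr$pops[, "B"], 100)
  est <- as.numeric(fst_pair(p1, 100, p2, 100))
  expect_lt(abs(est - 0.01), 0.001)    # within 10% of the target F

  # monotonicity over replicates at increasing F
  mean_est <- vapply(c(0.005, 0.02, 0.08), function(f) {
    mean(vapply(1:20, function(r) {
      fr <- sim_ref_freqs(3000, pops = c(A = f, B = f))
      as.numeric(fst_pair(sample_freqs(fr$pops[, "A"], 100), 100,
                          sample_freqs(fr$pops[, "B"], 100), 100))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_est) > 0))
})

test_that("fst_profile ranks reference populations by proximity", {
  set.seed(5)
  m <- 5000
  snps <- sim_snp_map(m)
  fr <- sim_ref_freqs(m, pops = c(NEAR = 0.002, MID = 0.05, FAR = 0.15))
  refs <- ref_panel(snps, fr$pops, c(NEAR = 200L, MID = 200L, FAR = 200L))
  ch <- freq_only_cohort(snps, fr$pops[, "NEAR"], 500, "coh")
  pr <- fst_profile(ch, refs)
  fst <- with(pr$profile, setNames(fst, pop))
  expect_lt(fst["NEAR"], 0.005)
  expect_true(fst["NEAR"] < fst["MID"] && fst["MID"] < fst["FAR"])
  expect_equal(length(unique(pr$profile$n_snps)), 1L)  # identical subset
})

test_that("an admixed cohort sits between its two source populations", {
  set.seed(6)
  m <- 8000
  snps <- sim_snp_map(m)
  fr <- sim_ref_freqs(m, pops = c(P1 = 0.05, P2 = 0.05))
  p_mix <- 0.5 * fr$pops[, "P1"] + 0.5 * fr$pops[, "P2"]
  refs <- ref_panel(snps, fr$pops, c(P1 = 300L, P2 = 300L))
  ch <- freq_only_cohort(snps, p_mix, 500, "admixed")
  pr <- fst_profile(ch, refs)
  f12 <- as.numeric(fst_pair(fr$pops[, "P1"], 300, fr$pops[, "P2"], 300))
  expect_true(all(pr$profile$fst > 0.1 * f12))
  expect_true(all(pr$profile$fst < 0.9 * f12))
})

test_that("disjoint SNP subsets give concordant Fst estimates", {
  set.seed(15)
  m <- 30000
  snps <- sim_snp_map(m)
  fr <- sim_ref_freqs(m, pops = c(R = 0.01))
  refs <- ref_panel(snps, fr$pops, c(R = 200L))
  ch <- freq_only_cohort(snps, fr$ancestral, 400, "coh")
  half1 <- snps$snp[seq(1, m, 2)]
  half2 <- snps$snp[seq(2, m, 2)]
  f1 <- fst_profile(ch, refs, snp_subset = half1)$profile$fst
  f2 <- fst_profile(ch, refs, snp_subset = half2)$profile$fst
  # crude SE of an Fst of this size over 15k SNPs is a few 1e-4
  expect_lt(abs(f1 - f2), 3 * 3e-4)
})

test_that("MDS embedding of the reference triangle reproduces input distances", {
  d <- matrix(c(0, 0.10, 0.16,
                0.10, 0, 0.12,
                0.16, 0.12, 0), 3, 3,
              dimnames = rep(list(c("A", "B", "C")), 2))
  emb <- gwamaqc:::cmds_embed(d, 2)
  got <- as.matrix(dist(emb$coords))^2
  expect_equal(unname(got), unname(d), tolerance = 1e-10)
})

test_that("forward-then-invert recovers a planted configuration (Procrustes)", {
  pts <- rbind(c(0, 0), c(1, 0.2), c(0.4, 0.9))
  d2 <- as.matrix(dist(pts))^2
  rownames(d2) <- colnames(d2) <- c("A", "B", "C")
  emb <- gwamaqc:::cmds_embed(d2, 2)$coords
  # Procrustes: center, then find best rotation via SVD
  ctr <- function(x) sweep(x, 2, colMeans(x))
  a <- ctr(pts); b <- ctr(emb)
  sv <- svd(crossprod(b, a))
  rmsd <- sqrt(mean((b %*% sv$u %*% t(sv$v) - a)^2))
  expect_lt(rmsd, 1e-8)
})

test_that("a cohort on a reference vertex projects onto that vertex", {
  set.seed(25)
  m <- 6000
  snps <- sim_snp_map(m)
  fr <- sim_ref_freqs(m, pops = c(CEU = 0.004, FIN = 0.006, TSI = 0.008))
  refs <- ref_panel(snps, fr$pops,
                    c(CEU = 10000L, FIN = 10000L, TSI = 10000L))
  rf <- ref_fst_matrix(refs)
  # profile built from CEU's own frequencies: Fst(CEU)=0, others = pair Fst
  prof <- structure(list(cohort_id = "like_CEU", n_snps = m,
                         profile = data.table::data.table(
                           pop = colnames(rf),
                           fst = c(0, rf["CEU", "FIN"], rf["CEU", "TSI"]),
                           n_snps = m)),
                    class = "fst_profile")
  proj <- fpc_project(list(prof), rf)
  ceu_vertex <- proj$ref_coords["CEU", ]
  expect_equal(unname(proj$coords[1, ]), unname(ceu_vertex),
               tolerance = 1e-6)
  expect_lt(proj$residual[1], 1e-10)
})

test_that("trilateration matches a dense grid search on the symmetric objective", {
  v <- rbind(A = c(0, 0), B = c(1, 0), C = c(0.5, 0.9))
  # equidistant case: distances taken from the circumcenter, so an exact
  # solution exists and the linearized solve is the global minimizer
  f <- function(y) (0.25 + y^2) - (0.25 + (y - 0.9)^2)  # |x-A|=|x-C| at x=0.5
  y0 <- uniroot(f, c(-5, 5))$root
  cc <- c(0.5, y0)
  d2 <- colSums((t(v) - cc)^2)
  rf <- as.matrix(dist(v))^2
  prof <- structure(list(cohort_id = "eq", n_snps = 100,
                         profile = data.table::data.table(
                           pop = rownames(v), fst = d2, n_snps = 100)),
                    class = "fst_profile")
  proj <- fpc_project(list(prof), rf)
  # embedding is a rigid motion of v; compare via the objective instead:
  obj <- function(x, vv) sum((colSums((t(vv) - x)^2) - d2)^2)
  gr <- expand.grid(x = seq(-1.5, 1.5, by = 0.002),
                    y = seq(-1.5, 1.5, by = 0.002))
  vv <- proj$ref_coords
  e1 <- outer(gr$x, vv[, 1], "-")^2 + outer(gr$y, vv[, 2], "-")^2
  vals <- (e1[, 1] - d2[1])^2 + (e1[, 2] - d2[2])^2 + (e1[, 3] - d2[3])^2
  best <- unlist(gr[which.min(vals), ])
  expect_equal(unname(proj$coords[1, ]), unname(best), tolerance = 0.005)
  expect_lt(obj(proj$coords[1, ], vv), min(vals) + 1e-12)
})

test_that("collinear reference vertices are rejected", {
  d <- as.matrix(dist(rbind(c(0, 0), c(1, 0), c(2, 0))))^2
  rownames(d) <- colnames(d) <- c("A", "B", "C")
  prof <- structure(list(cohort_id = "x", n_snps = 10,
                         profile = data.table::data.table(
                           pop = c("A", "B", "C"), fst = c(1, 1, 1),
                           n_snps = 10)),
                    class = "fst_profile")
  expect_error(fpc_project(list(prof), d), "collinear")
})

test_that("outlier_scan flags only cohorts beyond the threshold, sorted", {
  set.seed(30)
  m <- 20000
  snps <- sim_snp_map(m)
  fr <- sim_ref_freqs(m, pops = c(POOL = 0))
  refs <- ref_panel(snps, fr$pops, c(POOL = 2000L))
  inliers <- lapply(1:3, function(i)
    freq_only_cohort(snps, fr$ancestral, 800, paste0("in", i)))
  iso <- sim_ref_freqs(m, pops = c(ISO = 0.02), seed = 31)
  # re-center the isolate around the same ancestral frequencies
  set.seed(31)
  p_iso <- rbeta(m, fr$ancestral * 49, (1 - fr$ancestral) * 49)  # F=0.02
  outlier <- freq_only_cohort(snps, p_iso, 800, "isolate")
  res <- outlier_scan(c(inliers, list(outlier)), pooled_ref = refs)
  expect_identical(res$cohort_id[1], "isolate")
  expect_identical(res[flagged == TRUE, cohort_id], "isolate")
  # threshold 0: every positive estimate flagged (monotone in threshold)
  res0 <- outlier_scan(setNames(res$fst, res$cohort_id), flag_threshold = 0)
  expect_true(all(res0$flagged[res0$fst > 0]))
  expect_gte(sum(res0$flagged), sum(res$flagged))
})
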