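# Fst genetic distance between cohort-reported allele frequencies and
# reference populations, and the 2-D "cartographer" projection of cohorts
# into Fst-derived principal-component (F_PC) space.

#' Construct a reference panel of population allele frequencies
#'
#' @param snps data.frame with columns snp, chr, bp, a1, a2 (a1 is the
#'   allele the frequencies refer to).
#' @param freqs numeric matrix, SNPs x populations, columns named by
#'   population id; all frequencies in \[0,1\] on the shared SNP list.
#' @param n named integer vector of diploid sample sizes per population.
#' @return object of class `ref_panel`.
#' @export
ref_panel <- function(snps, freqs, n) {
  snps <- data.table::as.data.table(snps)[, .(snp, chr, bp, a1, a2)]
  freqs <- as.matrix(freqs)
  stopifnot(nrow(snps) == nrow(freqs), !is.null(colnames(freqs)),
            all(colnames(freqs) %in% names(n)))
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE))
    stopf("reference frequencies outside [0,1]")
  rownames(freqs) <- snps$snp
  structure(list(snps = snps, freqs = freqs,
                 n = n[colnames(freqs)]),
            class = "ref_panel")
}

#' Build a reference panel from 0/1/2 genotype matrices
#'
#' @param genotypes named list of n x M dosage matrices (columns = SNPs in
#'   the order of `snps`), one per population; dosages count copies of a1.
#' @param snps SNP key table as in [ref_panel()].
#' @return a [ref_panel()] with observed sample frequencies.
#' @export
ref_panel_from_genotypes <- function(genotypes, snps) {
  freqs <- vapply(genotypes, function(g) colMeans(g, na.rm = TRUE) / 2,
                  numeric(ncol(genotypes[[1]])))
  n <- vapply(genotypes, nrow, integer(1))
  ref_panel(snps, freqs, n)
}

#' Hudson-type Fst between two allele-frequency vectors
#'
#' Ratio-of-averages estimator with a finite-sample correction: per SNP i,
#' the numerator is \eqn{(p_{1i}-p_{2i})^2 - p_{1i}(1-p_{1i})/(2n_1-1) -
#' p_{2i}(1-p_{2i})/(2n_2-1)} and the denominator
#' \eqn{p_{1i}(1-p_{2i}) + p_{2i}(1-p_{1i})}; Fst is the summed numerator
#' over the summed denominator, clamped to \[0,1\]. Negative per-SNP
#' numerators are deliberately retained (only the final ratio is clamped)
#' so the combined estimator stays unbiased; the correction terms remove
#' the sampling inflation of squared frequency differences, which makes the
#' estimate for a population against itself slightly negative on finite
#' samples (reported as 0 after clamping).
#'
#' @param p1,p2 allele-frequency vectors on the same SNPs.
#' @param n1,n2 diploid sample sizes (scalar or per-SNP).
#' @return Fst scalar in \[0,1\]; attribute `n_snps` gives the SNP count
#'   used (pairwise-complete), attribute `raw` the pre-clamp value.
#' @export
fst_pair <- function(p1, n1, p2, n2) {
  stopifnot(length(p1) == length(p2), length(p1) >= 1, all(n1 >= 2),
            all(n2 >= 2))
  ok <- !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  if (length(n1) > 1) n1 <- n1[ok]
  if (length(n2) > 1) n2 <- n2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
    p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(den) == 0) stopf("Fst undefined: all SNPs monomorphic")
  raw <- sum(num) / sum(den)
  structure(min(max(raw, 0), 1), n_snps = sum(ok), raw = raw)
}

#' Fst genetic-distance spectrum of a cohort against reference populations
#'
#' Harmonizes the cohort's reported frequencies to the panel's allele
#' orientation (frequency complemented on swapped pairs; palindromic and
#' irreconcilable SNPs dropped) and computes one [fst_pair()] per reference
#' population, all on the identical shared SNP subset so the distances are
#' comparable.
#'
#' @param cohort a [cohort_summary()] with reported frequencies.
#' @param refs a [ref_panel()].
#' @param snp_subset optional character vector restricting the SNPs used
#'   (e.g. from [prune_independent()]).
#' @return object of class `fst_profile`: `cohort_id`, `n_snps`, and a
#'   data.table (pop, fst, n_snps).
#' @export
fst_profile <- function(cohort, refs, snp_subset = NULL) {
  stopifnot(inherits(cohort, "cohort_summary"), inherits(refs, "ref_panel"))
  rec <- cohort$records[!is.na(freq)]
  m <- merge(rec[, .(snp, a1, a2, freq, n)], refs$snps, by = "snp",
             suffixes = c("", ".r"))
  same <- m$a1 == m$a1.r & m$a2 == m$a2.r
  swap <- m$a1 == m$a2.r & m$a2 == m$a1.r
  flip_same <- dna_complement(m$a1) == m$a1.r & dna_complement(m$a2) == m$a2.r
  flip_swap <- dna_complement(m$a1) == m$a2.r & dna_complement(m$a2) == m$a1.r
  pal <- is_palindromic(m$a1, m$a2)
  keep <- (same | swap | flip_same | flip_swap) & !pal
  m <- m[keep]
  p_cohort <- ifelse((swap | flip_swap)[keep], 1 - m$freq, m$freq)
  names(p_cohort) <- m$snp
  if (!is.null(snp_subset)) p_cohort <- p_cohort[names(p_cohort) %in% snp_subset]
  n_shared <- length(p_cohort)
  if (n_shared < 10) stopf("fst_profile: only %d shared SNPs with the panel",
                           n_shared)
  if (n_shared < 1000)
    warnf("fst_profile: only %d shared SNPs; Fst estimates may be noisy",
          n_shared)
  n_coh <- cohort$n_median
  prof <- data.table::rbindlist(lapply(colnames(refs$freqs), function(pop) {
    f <- fst_pair(p_cohort, n_coh, refs$freqs[names(p_cohort), pop],
                  refs$n[pop])
    data.table::data.table(pop = pop, fst = as.numeric(f),
                           n_snps = attr(f, "n_snps"))
  }))
  structure(list(cohort_id = cohort$cohort_id, n_snps = n_shared,
                 profile = prof),
            class = "fst_profile")
}

#' @export
print.fst_profile <- function(x, ...) {
  cat(sprintf("<fst_profile> %s (%d SNPs)\n", x$cohort_id, x$n_snps))
  print(x$profile)
  invisible(x)
}

#' Pairwise Fst matrix among the populations of a reference panel
#'
#' @param refs a [ref_panel()].
#' @return symmetric matrix of [fst_pair()] values, zero diagonal.
#' @export
ref_fst_matrix <- function(refs) {
  pops <- colnames(refs$freqs)
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[i, j] <- out[j, i] <- fst_pair(refs$freqs[, i], refs$n[i],
                                       refs$freqs[, j], refs$n[j])
  }
  out
}

# Classical metric MDS of a squared-distance matrix into `k` dimensions.
# Returns coordinates plus the eigenvalues of the centered Gram matrix.
cmds_embed <- function(d2, k = 2) {
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(k)], 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  rownames(coords) <- rownames(d2)
  list(coords = coords, eigenvalues = e$values)
}

#' Project cohorts into 2-D Fst-derived principal-component (F_PC) space
#'
#' The "Fst cartographer": squared Euclidean distance in F_PC space is
#' taken proportional to Fst (the convention that links Fst to genotype
#' principal components). The three reference populations are embedded by
#' classical metric MDS of their pairwise Fst matrix (double-centering,
#' top-2 eigenpairs, negative eigenvalues clipped to zero); each cohort is
#' then placed at the least-squares trilateration point for its three Fst
#' distances, solved by the standard linearization that subtracts the first
#' anchor's sphere equation, with the per-cohort residual misfit reported.
#'
#' @param profiles list of [fst_profile()] objects over the same three
#'   reference populations.
#' @param ref_fst symmetric 3 x 3 Fst matrix among the references
#'   (e.g. [ref_fst_matrix()]); zero diagonal.
#' @return object of class `fpc_projection`: `ref_coords` (3 x 2),
#'   `coords` (cohorts x 2), `residual` (root-mean-square misfit of the
#'   squared-distance equations per cohort), `ref_eigenvalues`.
#' @export
fpc_project <- function(profiles, ref_fst) {
  if (inherits(profiles, "fst_profile")) profiles <- list(profiles)
  stopifnot(nrow(ref_fst) == 3, ncol(ref_fst) == 3,
            isTRUE(all.equal(ref_fst, t(ref_fst))),
            all(diag(ref_fst) == 0))
  pops <- rownames(ref_fst)
  emb <- cmds_embed(ref_fst, k = 2)
  v <- emb$coords
  # rank-1 Gram matrix means the three anchors are collinear: no 2-D fix
  if (emb$eigenvalues[2] <= 1e-12 * max(emb$eigenvalues[1], 1e-300))
    stopf("fpc_project: reference vertices are collinear (degenerate geometry)")

  A <- 2 * cbind(v[2, ] - v[1, ], v[3, ] - v[1, ])  # 2 x 2, columns = eqs
  A <- t(A)
  nv <- rowSums(v^2)
  coords <- matrix(NA_real_, length(profiles), 2)
  resid <- numeric(length(profiles))
  ids <- character(length(profiles))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    stopifnot(inherits(pr, "fst_profile"))
    d2 <- pr$profile$fst[match(pops, pr$profile$pop)]
    if (anyNA(d2))
      stopf("fst_profile '%s' lacks one of the reference populations",
            pr$cohort_id)
    bvec <- c((nv[2] - nv[1]) - (d2[2] - d2[1]),
              (nv[3] - nv[1]) - (d2[3] - d2[1]))
    x <- solve(A, bvec)
    coords[i, ] <- x
    err <- colSums((t(v) - x)^2) - d2
    resid[i] <- sqrt(mean(err^2))
    ids[i] <- pr$cohort_id
  }
  rownames(coords) <- ids
  structure(list(ref_coords = v, coords = coords, residual = resid,
                 ref_eigenvalues = emb$eigenvalues),
            class = "fpc_projection")
}

#' @export
print.fpc_projection <- function(x, ...) {
  cat("<fpc_projection> squared distance in F_PC space ~ Fst\n")
  cat("reference vertices:\n"); print(round(x$ref_coords, 6))
  cat("cohorts:\n"); print(round(x$coords, 6))
  invisible(x)
}

#' Flag cohorts unusually differentiated from a pooled reference
#'
#' Cohorts whose Fst against a pooled ("averaged") reference panel exceeds
#' `flag_threshold` are flagged, sorted by decreasing Fst. The default
#' threshold 0.005 corresponds to the typical within-continental-ancestry
#' differentiation below which cohorts are unremarkable; genetically
#' isolated populations show Fst several-fold larger.
#'
#' @param fst_pooled named numeric vector of cohort-vs-pooled-panel Fst
#'   values, or a list of cohorts plus `pooled_ref` to compute them.
#' @param flag_threshold Fst above which a cohort is flagged (default
#'   0.005).
#' @param pooled_ref optional single-population [ref_panel()]; required
#'   when `fst_pooled` is a list of [cohort_summary()] objects.
#' @return data.table (cohort_id, fst, flagged) sorted by decreasing Fst.
#' @export
outlier_scan <- function(fst_pooled, flag_threshold = 0.005,
                         pooled_ref = NULL) {
  if (is.list(fst_pooled) && !is.null(pooled_ref)) {
    vals <- vapply(fst_pooled, function(ch) {
      as.numeric(fst_profile(ch, pooled_ref)$profile$fst[1])
    }, numeric(1))
    names(vals) <- vapply(fst_pooled, `[[`, character(1), "cohort_id")
    fst_pooled <- vals
  }
  out <- data.table::data.table(cohort_id = names(fst_pooled),
                                fst = as.numeric(fst_pooled))
  out[, flagged := fst > flag_threshold]
  data.table::setorder(out, -fst)
  out[]
}
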