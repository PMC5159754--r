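# meta-PCA: principal component analysis in which each cohort -- not each
# individual -- is one observation and its reported allele frequencies are
# the features. Reference-panel populations can be appended as extra
# "cohorts" to anchor the interpretation of the components.

#' Assemble the cohorts x SNPs allele-frequency matrix
#'
#' Restricts to SNPs present with a non-missing frequency in every input
#' (complete-case columns; the dropped count is reported), harmonizes all
#' cohorts to the first input's allele orientation (frequency complemented
#' on swapped or strand-flipped pairs; palindromic and irreconcilable SNPs
#' dropped), and applies a pooled minor-allele-frequency filter.
#'
#' @param cohorts list of [cohort_summary()] objects (>= 3 rows including
#'   any references are needed downstream).
#' @param refs optional [ref_panel()]; its populations are appended as
#'   extra rows.
#' @param min_maf pooled MAF threshold (default 0.01).
#' @return object of class `freq_matrix`: numeric matrix with cohort rows
#'   and SNP columns; attributes `n_dropped_missing` (SNPs absent or
#'   missing in some input), `n_dropped_maf`, and `snps` (keys in the
#'   retained orientation).
#' @export
build_freq_matrix <- function(cohorts, refs = NULL, min_maf = 0.01) {
  stopifnot(length(cohorts) >= 1)
  master <- cohorts[[1]]$records[!is.na(freq), .(snp, chr, bp, a1, a2)]
  total_universe <- length(unique(unlist(c(
    lapply(cohorts, function(ch) ch$records$snp),
    if (!is.null(refs)) list(refs$snps$snp)))))

  align_freqs <- function(rec) {
    m <- merge(master, rec, by = "snp", suffixes = c("", ".x"))
    same <- m$a1.x == m$a1 & m$a2.x == m$a2
    swap <- m$a1.x == m$a2 & m$a2.x == m$a1
    flip_same <- m$a1.x == dna_complement(m$a1) & m$a2.x == dna_complement(m$a2)
    flip_swap <- m$a1.x == dna_complement(m$a2) & m$a2.x == dna_complement(m$a1)
    keep <- (same | swap | flip_same | flip_swap) & !is_palindromic(m$a1, m$a2)
    p <- ifelse(swap | flip_swap, 1 - m$freq, m$freq)
    p[!keep] <- NA_real_
    stats::setNames(p, m$snp)
  }

  rows <- lapply(cohorts, function(ch)
    align_freqs(ch$records[!is.na(freq), .(snp, a1 = a1, a2 = a2, freq)]))
  ids <- vapply(cohorts, `[[`, character(1), "cohort_id")
  if (!is.null(refs)) {
    for (pop in colnames(refs$freqs)) {
      rec <- data.table::data.table(snp = refs$snps$snp, a1 = refs$snps$a1,
                                    a2 = refs$snps$a2,
                                    freq = refs$freqs[, pop])
      rows <- c(rows, list(align_freqs(rec[!is.na(freq)])))
      ids <- c(ids, pop)
    }
  }

  shared <- Reduce(intersect, lapply(rows, function(r) names(r)[!is.na(r)]))
  if (length(shared) == 0L)
    stopf("build_freq_matrix: no SNP is present in all inputs")
  mat <- do.call(rbind, lapply(rows, function(r) r[shared]))
  rownames(mat) <- ids
  n_dropped_missing <- total_universe - length(shared)

  pooled <- colMeans(mat)
  maf <- pmin(pooled, 1 - pooled)
  keep_maf <- maf >= min_maf
  n_dropped_maf <- sum(!keep_maf)
  mat <- mat[, keep_maf, drop = FALSE]
  keys <- master[match(colnames(mat), master$snp)]

  structure(mat, class = c("freq_matrix", "matrix"),
            n_dropped_missing = n_dropped_missing,
            n_dropped_maf = n_dropped_maf, snps = keys)
}

#' Principal components over cohorts from reported allele frequencies
#'
#' Conventional PCA with cohorts as observations: columns are centered
#' (`scale_mode = "center_scale"`, the default, additionally divides each
#' column by \eqn{\sqrt{\bar p (1-\bar p)}} with \eqn{\bar p} the column
#' mean, the analogue of genotype standardization), the centered matrix is
#' decomposed by SVD, and cohort coordinates are the left singular vectors
#' scaled by the singular values. The sign of each component is fixed so
#' that its largest-magnitude SNP loading is positive, making results
#' reproducible across platforms.
#'
#' @param m a [build_freq_matrix()] result (or plain cohorts x SNPs
#'   matrix).
#' @param k number of components (default 2); requires nrow >= k + 1.
#' @param scale_mode `"center_scale"` or `"center"`.
#' @return object of class `meta_pca_result`: `coords` (cohorts x k),
#'   `eigenvalues` (all, non-increasing), `prop_var`, `scale_mode`,
#'   `loadings` (SNPs x k).
#' @export
run_meta_pca <- function(m, k = 2, scale_mode = c("center_scale", "center")) {
  scale_mode <- match.arg(scale_mode)
  X <- unclass(m)
  stopifnot(is.matrix(X), nrow(X) >= k + 1)
  X <- X[, colSums(is.na(X)) == 0L, drop = FALSE]
  ctr <- colMeans(X)
  X <- sweep(X, 2, ctr)
  if (scale_mode == "center_scale") {
    s <- sqrt(ctr * (1 - ctr))
    keep <- s > 0
    X <- sweep(X[, keep, drop = FALSE], 2, s[keep], "/")
  }
  if (all(abs(X) < .Machine$double.eps * 100))
    stopf("run_meta_pca: frequency matrix has zero variance")
  sv <- svd(X)
  eig <- sv$d^2 / (nrow(X) - 1)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k)
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("mPC", seq_len(k))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(X)
  structure(list(coords = coords, eigenvalues = eig,
                 prop_var = eig / sum(eig), scale_mode = scale_mode,
                 loadings = loadings),
            class = "meta_pca_result")
}

#' @export
print.meta_pca_result <- function(x, ...) {
  k <- ncol(x$coords)
  cat(sprintf("<meta_pca_result> %d cohorts, %d components (%s)\n",
              nrow(x$coords), k, x$scale_mode))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("mPC%d %.1f%%", seq_len(k),
                            100 * x$prop_var[seq_len(k)]), collapse = ", ")))
  print(round(head(x$coords, 10), 4))
  if (nrow(x$coords) > 10) cat("  ...\n")
  invisible(x)
}
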