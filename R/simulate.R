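# Synthetic multi-cohort GWAS experiments with known truth. Populations
# follow the Balding-Nichols model (Beta-distributed population allele
# frequencies around an ancestral frequency, parameterized by Fst);
# genotypes are unlinked Binomial(2, p) draws; phenotypes are polygenic
# with a chosen heritability on a chosen number of QTLs; sample overlap,
# first-degree relatives and shared control pools are planted explicitly
# and recorded in a truth object so every detection metric can be scored.

#' Simulated SNP map
#'
#' `m_snps` markers spread over `n_chr` chromosomes at a fixed spacing so
#' that every marker pair satisfies the default independence gap of
#' [prune_independent()]; allele pairs are drawn from the eight
#' non-palindromic ordered pairs.
#'
#' @param m_snps number of SNPs.
#' @param n_chr chromosomes to spread over (default 22).
#' @param spacing_bp distance between adjacent simulated SNPs (default
#'   1e5).
#' @return data.table (snp, chr, bp, a1, a2).
#' @export
sim_snp_map <- function(m_snps, n_chr = 22L, spacing_bp = 1e5) {
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pick <- pairs[sample.int(nrow(pairs), m_snps, replace = TRUE), ,
                drop = FALSE]
  chr <- rep(seq_len(n_chr), length.out = m_snps)
  idx_in_chr <- stats::ave(seq_len(m_snps), chr, FUN = seq_along)
  data.table::data.table(snp = sprintf("rs%07d", seq_len(m_snps)),
                         chr = as.character(chr),
                         bp = as.integer(idx_in_chr * spacing_bp),
                         a1 = pick[, 1], a2 = pick[, 2])
}

#' Balding-Nichols population allele frequencies
#'
#' Ancestral frequencies are uniform on `maf_range`; each population draws
#' its frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and
#' variance F p(1-p). Two independent populations simulated at the same F
#' have pairwise Fst = F in expectation. F = 0 copies the ancestral
#' frequencies exactly.
#'
#' @param m_snps number of SNPs.
#' @param pops named numeric vector of per-population F values in \[0,1).
#' @param maf_range ancestral frequency range (default 0.05-0.95).
#' @param seed optional seed.
#' @return list: `ancestral` (length m), `pops` (m x npop matrix).
#' @export
sim_ref_freqs <- function(m_snps, pops = c(POP1 = 0.01, POP2 = 0.01),
                          maf_range = c(0.05, 0.95), seed = NULL) {
  stopifnot(all(pops >= 0), all(pops < 1))
  if (!is.null(seed)) set.seed(seed)
  p0 <- runif(m_snps, maf_range[1], maf_range[2])
  pm <- vapply(pops, function(f) {
    if (f == 0) p0
    else rbeta(m_snps, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  }, numeric(m_snps))
  list(ancestral = p0, pops = pm)
}

#' Observed sample allele frequencies from a population
#'
#' Binomial sampling of 2n allele draws per SNP.
#'
#' @param p population frequencies.
#' @param n diploid sample size.
#' @return frequency vector.
#' @export
sample_freqs <- function(p, n) {
  rbinom(length(p), 2L * n, p) / (2 * n)
}

#' Unlinked genotypes from population allele frequencies
#'
#' @param p frequency vector (one per SNP).
#' @param n individuals.
#' @return n x m integer dosage matrix, Binomial(2, p) per column.
#' @export
sim_genotypes <- function(p, n) {
  m <- length(p)
  G <- matrix(0L, n, m)
  for (j in seq_len(m)) G[, j] <- rbinom(n, 2L, p[j])
  G
}

#' Gene-drop one offspring per parent row
#'
#' One allele is transmitted from the parent (probability g/2 of passing
#' the counted allele) and one drawn from the population, so each
#' offspring has expected standardized relationship 0.5 with its parent.
#'
#' @param G_parents parent dosage matrix (rows = parents).
#' @param p population allele frequencies (one per column).
#' @return integer dosage matrix of the same shape.
#' @export
sim_offspring <- function(G_parents, p) {
  n <- nrow(G_parents); m <- ncol(G_parents)
  transmitted <- matrix(rbinom(n * m, 1L, as.vector(G_parents) / 2), n, m)
  pop_allele <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
  transmitted + pop_allele
}

#' Polygenic phenotype with a target heritability
#'
#' QTL effects are i.i.d. normal on `n_qtl` randomly chosen SNPs and are
#' rescaled so the realized genetic variance is exactly `h2` of a unit
#' total variance; the residual is N(0, 1 - h2). With `h2 = 0` the
#' phenotype is pure noise.
#'
#' @param G n x m dosage matrix.
#' @param h2 narrow-sense heritability in \[0,1\].
#' @param n_qtl number of causal SNPs.
#' @param qtl_idx,effects optionally reuse a previous draw (e.g. to extend
#'   a phenotype to appended individuals).
#' @return list: `y`, `gv` (genetic values), `qtl_idx`, `effects`
#'   (post-scaling, per QTL allele).
#' @export
sim_phenotype <- function(G, h2, n_qtl, qtl_idx = NULL, effects = NULL) {
  stopifnot(h2 >= 0, h2 <= 1, n_qtl <= ncol(G))
  n <- nrow(G)
  if (h2 == 0) {
    return(list(y = rnorm(n), gv = rep(0, n),
                qtl_idx = integer(0), effects = numeric(0)))
  }
  if (is.null(qtl_idx)) qtl_idx <- sort(sample.int(ncol(G), n_qtl))
  if (is.null(effects)) effects <- rnorm(length(qtl_idx))
  gv <- as.vector(G[, qtl_idx, drop = FALSE] %*% effects)
  sc <- sqrt(h2 / stats::var(gv))
  gv <- gv * sc
  effects <- effects * sc
  y <- gv + rnorm(n, 0, sqrt(1 - h2))
  list(y = y, gv = gv, qtl_idx = qtl_idx, effects = effects)
}

#' Per-SNP least-squares GWAS producing a cohort_summary
#'
#' Simple linear regression of the phenotype on each SNP dosage,
#' vectorized over SNPs in column chunks (equal to a per-SNP `lm()` loop
#' to numerical precision). Monomorphic SNPs get missing beta/se and are
#' excluded by downstream metrics.
#'
#' @param G n x m dosage matrix (may be the whole simulation pool).
#' @param y phenotype vector for the rows of `G`.
#' @param snps SNP map from [sim_snp_map()].
#' @param rows optional row indices: the cohort's individuals within `G`.
#' @param cohort_id,trait metadata for the resulting summary.
#' @param chunk columns processed per block (memory/speed trade-off).
#' @return a [cohort_summary()].
#' @export
sim_gwas <- function(G, y, snps, rows = NULL, cohort_id = "cohort",
                     trait = "trait", chunk = 2000L) {
  if (is.null(rows)) rows <- seq_len(nrow(G))
  n <- length(rows)
  stopifnot(n >= 10, length(y) == nrow(G) || length(y) == n)
  yc <- if (length(y) == nrow(G)) y[rows] else y
  m <- ncol(G)
  beta <- se <- frq <- numeric(m)
  sy <- sum(yc)
  Syy <- sum((yc - sy / n)^2)
  for (s in seq(1L, m, by = chunk)) {
    cols <- s:min(s + chunk - 1L, m)
    Gc <- G[rows, cols, drop = FALSE]
    sg <- colSums(Gc)
    sg2 <- colSums(Gc * Gc)
    Sxx <- sg2 - sg^2 / n
    Sxy <- as.vector(crossprod(Gc, yc)) - sg * sy / n
    b <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
    rss <- pmax(Syy - b * Sxy, 0)
    beta[cols] <- b
    se[cols] <- ifelse(Sxx > 0, sqrt(rss / ((n - 2) * Sxx)), NA_real_)
    frq[cols] <- sg / (2 * n)
  }
  rec <- data.table::data.table(snp = snps$snp, chr = snps$chr,
                                bp = snps$bp, a1 = snps$a1, a2 = snps$a2,
                                freq = frq, beta = beta, se = se, n = n)
  cohort_summary(rec, cohort_id = cohort_id, trait = trait)
}

#' Simulate a pair of GWAS cohorts with planted overlap and relatives
#'
#' The workhorse behind the overlap-detection experiments: two cohorts
#' drawn from one population (`n_overlap` individuals present in both with
#' identical genotypes and phenotype; optional parent-offspring pairs
#' split across the cohorts), one shared polygenic trait, and a per-SNP
#' least-squares GWAS in each cohort. The true summary-statistic
#' correlation induced by pure overlap is
#' \eqn{\gamma_{1,2} = n_{1,2}/\sqrt{n_1 n_2}}.
#'
#' @param n1,n2 cohort sizes.
#' @param n_overlap individuals shared by both cohorts (<= min(n1, n2)).
#' @param n_relatives parent-offspring pairs split across the cohorts
#'   (parent in cohort 1, offspring in cohort 2).
#' @param h2 trait heritability (0-1).
#' @param n_qtl causal SNPs (default 1000).
#' @param m_snps unlinked SNPs (default 30000).
#' @param maf_range ancestral frequency range.
#' @param seed RNG seed (bit-reproducible).
#' @param keep_genotypes keep the genotype pool and row indices in the
#'   result (memory!).
#' @param cohort_ids length-2 ids.
#' @return list: `cohorts` (two [cohort_summary()]s), `truth` (list:
#'   overlap_ids, relative_pairs, gamma_true, qtl_idx, effects, freqs,
#'   snps), and with `keep_genotypes` also `G`, `rows1`, `rows2`, `y`.
#' @export
sim_pair_study <- function(n1, n2, n_overlap = 0L, n_relatives = 0L,
                           h2 = 0.25, n_qtl = 1000L, m_snps = 30000L,
                           maf_range = c(0.05, 0.95), seed = 2016L,
                           keep_genotypes = FALSE,
                           cohort_ids = c("cohort1", "cohort2")) {
  stopifnot(n_overlap <= min(n1, n2), n_relatives <= n1 - n_overlap,
            n_overlap + n_relatives <= n2)
  set.seed(seed)
  snps <- sim_snp_map(m_snps)
  p <- runif(m_snps, maf_range[1], maf_range[2])
  n_uniq <- n1 + n2 - n_overlap
  G <- sim_genotypes(p, n_uniq)
  if (n_relatives > 0) {
    off <- sim_offspring(G[seq_len(n_relatives), , drop = FALSE], p)
    G <- rbind(G, off)
  }
  ids <- sprintf("I%06d", seq_len(nrow(G)))
  ph <- sim_phenotype(G, h2 = h2, n_qtl = n_qtl)

  rows1 <- seq_len(n1)
  rows2 <- c(if (n_overlap > 0) (n1 - n_overlap + 1L):n1,
             n1 + seq_len(n2 - n_overlap - n_relatives),
             if (n_relatives > 0) n_uniq + seq_len(n_relatives))
  s1 <- sim_gwas(G, ph$y, snps, rows = rows1, cohort_id = cohort_ids[1])
  s2 <- sim_gwas(G, ph$y, snps, rows = rows2, cohort_id = cohort_ids[2])

  truth <- list(
    overlap_ids = if (n_overlap > 0) ids[(n1 - n_overlap + 1L):n1]
    else character(0),
    relative_pairs = if (n_relatives > 0)
      data.table::data.table(parent = ids[seq_len(n_relatives)],
                             offspring = ids[n_uniq + seq_len(n_relatives)])
    else NULL,
    gamma_true = n_overlap / sqrt(n1 * n2),
    qtl_idx = ph$qtl_idx, effects = ph$effects, freqs = p, snps = snps)
  out <- list(cohorts = list(s1, s2), truth = truth)
  if (keep_genotypes) {
    rownames(G) <- ids
    out$G <- G
    out$rows1 <- rows1
    out$rows2 <- rows2
    out$y <- ph$y
  }
  out
}

#' Declarative configuration for a multi-cohort simulation
#'
#' @param m_snps number of unlinked SNPs.
#' @param populations data.frame (pop_id, fst): Balding-Nichols F per
#'   population.
#' @param cohorts list of lists with fields cohort_id, pop_id, n, and
#'   optional overlap_with = list(cohort_id, n_shared) and relatives_with
#'   = list(cohort_id, n_first_degree); partners must be earlier cohorts
#'   of the same population.
#' @param h2 trait heritability shared by all cohorts of a population (one
#'   trait model per population keeps overlapping individuals' phenotypes
#'   identical in both cohorts).
#' @param n_qtl causal SNPs.
#' @param maf_range ancestral frequency range.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m_snps, populations, cohorts, h2 = 0.25,
                       n_qtl = 1000L, maf_range = c(0.05, 0.95),
                       seed = 2016L) {
  populations <- data.table::as.data.table(populations)
  stopifnot(all(c("pop_id", "fst") %in% names(populations)),
            all(populations$fst >= 0), all(populations$fst < 1),
            h2 >= 0, h2 <= 1, n_qtl <= m_snps)
  ids <- vapply(cohorts, `[[`, character(1), "cohort_id")
  stopifnot(!anyDuplicated(ids))
  for (i in seq_along(cohorts)) {
    ch <- cohorts[[i]]
    stopifnot(ch$pop_id %in% populations$pop_id, ch$n >= 1)
    for (fld in c("overlap_with", "relatives_with")) {
      if (!is.null(ch[[fld]])) {
        j <- match(ch[[fld]]$cohort_id, ids)
        if (is.na(j) || j >= i)
          stopf("sim_config: %s of '%s' must name an earlier cohort",
                fld, ch$cohort_id)
        if (cohorts[[j]]$pop_id != ch$pop_id)
          stopf("sim_config: %s partners must share a population", fld)
      }
    }
  }
  structure(list(m_snps = as.integer(m_snps), populations = populations,
                 cohorts = cohorts, h2 = h2, n_qtl = as.integer(n_qtl),
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Run a configured multi-cohort simulation
#'
#' Generates Balding-Nichols population frequencies, per-population
#' genotype pools, one polygenic trait per population, the configured
#' overlap/relative structure, and a least-squares GWAS per cohort.
#'
#' @param config a [sim_config()].
#' @param keep_genotypes keep genotype pools and cohort row maps.
#' @return list of class `sim_study`: `snps`, `freqs` (per population),
#'   `cohorts` (named list of [cohort_summary()]), `truth` (per planted
#'   pair: overlap ids, relative pairs, gamma_true), and with
#'   `keep_genotypes` the pools, row indices and individual ids.
#' @export
sim_study <- function(config, keep_genotypes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  snps <- sim_snp_map(config$m_snps)
  fr <- sim_ref_freqs(config$m_snps,
                      pops = stats::setNames(config$populations$fst,
                                             config$populations$pop_id),
                      maf_range = config$maf_range)
  ids <- vapply(config$cohorts, `[[`, character(1), "cohort_id")

  pools <- list(); pool_rows <- list()  # per population
  cohort_rows <- list()                 # per cohort: rows into its pool
  offspring_of <- list()                # pool row -> parent pool row
  for (i in seq_along(config$cohorts)) {
    ch <- config$cohorts[[i]]
    pop <- ch$pop_id
    p <- fr$pops[, pop]
    if (is.null(pools[[pop]])) pools[[pop]] <- matrix(0L, 0L, config$m_snps)
    shared_rows <- integer(0)
    if (!is.null(ch$overlap_with)) {
      partner <- cohort_rows[[ch$overlap_with$cohort_id]]
      n_shared <- ch$overlap_with$n_shared
      if (n_shared > length(partner) || n_shared > ch$n)
        stopf("sim_study: n_shared exceeds a cohort size for '%s'",
              ch$cohort_id)
      shared_rows <- utils::tail(partner, n_shared)
    }
    rel_rows <- integer(0)
    if (!is.null(ch$relatives_with)) {
      partner <- cohort_rows[[ch$relatives_with$cohort_id]]
      n_rel <- ch$relatives_with$n_first_degree
      parents <- setdiff(partner, shared_rows)[seq_len(n_rel)]
      off <- sim_offspring(pools[[pop]][parents, , drop = FALSE], p)
      rel_rows <- nrow(pools[[pop]]) + seq_len(n_rel)
      pools[[pop]] <- rbind(pools[[pop]], off)
      offspring_of[[pop]] <- c(offspring_of[[pop]],
                               stats::setNames(parents, rel_rows))
    }
    n_fresh <- ch$n - length(shared_rows) - length(rel_rows)
    stopifnot(n_fresh >= 0)
    fresh_rows <- nrow(pools[[pop]]) + seq_len(n_fresh)
    if (n_fresh > 0)
      pools[[pop]] <- rbind(pools[[pop]], sim_genotypes(p, n_fresh))
    cohort_rows[[ch$cohort_id]] <- c(fresh_rows, shared_rows, rel_rows)
  }

  # one trait model per population, shared by its cohorts
  phenos <- lapply(names(pools), function(pop) {
    sim_phenotype(pools[[pop]], h2 = config$h2, n_qtl = config$n_qtl)
  })
  names(phenos) <- names(pools)

  summaries <- lapply(config$cohorts, function(ch) {
    sim_gwas(pools[[ch$pop_id]], phenos[[ch$pop_id]]$y, snps,
             rows = cohort_rows[[ch$cohort_id]], cohort_id = ch$cohort_id)
  })
  names(summaries) <- ids

  truth <- list()
  for (ch in config$cohorts) {
    if (!is.null(ch$overlap_with)) {
      key <- paste(ch$overlap_with$cohort_id, ch$cohort_id, sep = ":")
      n1 <- ch$overlap_with$n_shared
      na <- length(cohort_rows[[ch$overlap_with$cohort_id]])
      truth[[key]] <- list(
        overlap_pool_rows = utils::tail(cohort_rows[[ch$overlap_with$cohort_id]],
                                        n1),
        gamma_true = n1 / sqrt(na * ch$n))
    }
    if (!is.null(ch$relatives_with)) {
      key <- paste(ch$relatives_with$cohort_id, ch$cohort_id, "rel",
                   sep = ":")
      truth[[key]] <- list(offspring_of = offspring_of[[ch$pop_id]])
    }
  }

  out <- list(snps = snps, freqs = fr, cohorts = summaries, truth = truth,
              config = config)
  if (keep_genotypes) {
    out$pools <- pools
    out$cohort_rows <- cohort_rows
    out$phenotypes <- phenos
  }
  structure(out, class = "sim_study")
}

#' Case-control cohorts drawing on one shared control pool
#'
#' Mirrors the classic shared-control design: every cohort reuses the
#' same control genotypes while its cases are drawn fresh, so all
#' control individuals are planted cross-cohort duplicates.
#'
#' @param n_cohorts number of case-control cohorts (>= 2).
#' @param n_controls shared control pool size.
#' @param n_cases cases drawn fresh per cohort.
#' @param m_snps SNPs.
#' @param maf_range ancestral frequency range.
#' @param seed RNG seed.
#' @return list: `snps`, `p` (population frequencies), `genotypes` (named
#'   list of (n_controls + n_cases) x m matrices, control rows first, row
#'   names carrying shared control ids), `labels` (per cohort,
#'   control/case), `shared_ids`.
#' @export
sim_shared_controls <- function(n_cohorts = 2L, n_controls = 300L,
                                n_cases = 500L, m_snps = 500L,
                                maf_range = c(0.05, 0.95), seed = 2016L) {
  stopifnot(n_cohorts >= 2)
  set.seed(seed)
  snps <- sim_snp_map(m_snps)
  p <- runif(m_snps, maf_range[1], maf_range[2])
  ctrl <- sim_genotypes(p, n_controls)
  shared_ids <- sprintf("CTRL%05d", seq_len(n_controls))
  rownames(ctrl) <- shared_ids
  genotypes <- list(); labels <- list()
  for (k in seq_len(n_cohorts)) {
    cases <- sim_genotypes(p, n_cases)
    rownames(cases) <- sprintf("D%d_CASE%05d", k, seq_len(n_cases))
    genotypes[[paste0("disease", k)]] <- rbind(ctrl, cases)
    labels[[paste0("disease", k)]] <- c(rep("control", n_controls),
                                        rep("case", n_cases))
  }
  list(snps = snps, p = p, genotypes = genotypes, labels = labels,
       shared_ids = shared_ids)
}
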