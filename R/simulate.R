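#' Simulation configuration for a bivariate GWAS pair
#'
#' Collects the generating parameters for a pair of case-control GWAS
#' z-score sets: SNP count, per-trait sample sizes, number of overlapping
#' individuals, SNP-heritabilities, genetic correlation, phenotypic
#' correlation among overlapping individuals, the LD-score distribution, and
#' optional planted pleiotropic / heterogeneous SNPs.
#'
#' @param m_snps number of SNPs.
#' @param n1,n2 GWAS sample sizes.
#' @param n_shared overlapping individuals, `<= min(n1, n2)`.
#' @param h2_1,h2_2 SNP-heritabilities in \[0,1\].
#' @param rg genetic correlation in \[-1,1\].
#' @param rho_pheno phenotypic correlation among overlapping individuals.
#' @param ld_score_mean,ld_score_shape mean (>= 1) and gamma shape of the
#'   LD-score distribution; `shape = Inf` gives constant LD scores.
#' @param m_ref number of SNPs the heritability is spread over. The default
#'   1.2e6 is a genome-wide reference-panel SNP count: the analyzed panel is
#'   treated as a thinned subset of the genome, so per-SNP chi-squared
#'   inflation sits at the levels seen in well-powered GWAS regardless of
#'   how many SNPs are simulated.
#' @param prev1,prev2 optional `c(K, P)` population/sample prevalences.
#' @param planted_hetero data frame with columns `index`, `shift1`, `shift2`
#'   (z-scale mean shifts) for heterogeneous SNPs, or `NULL`.
#' @param planted_pleio data frame with columns `index`, `shift` (shared
#'   per-allele effect on the standardized trait scale, planted on the z
#'   scale as `shift * sqrt(n_i * 2 p (1-p))`), or `NULL`.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 20000, n1 = 100000, n2 = 100000,
                       n_shared = 0, h2_1 = 0.25, h2_2 = 0.25, rg = 0,
                       rho_pheno = 0, ld_score_mean = 100,
                       ld_score_shape = 2, m_ref = 1.2e6,
                       prev1 = NULL, prev2 = NULL,
                       planted_hetero = NULL, planted_pleio = NULL,
                       seed = 1L) {
  stopifnot(abs(rg) <= 1, n_shared <= min(n1, n2),
            h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1,
            abs(rho_pheno) <= 1)
  if (!is.null(planted_hetero) && !is.null(planted_pleio) &&
      length(intersect(planted_hetero$index, planted_pleio$index)) > 0L)
    stop("planted heterogeneous and pleiotropic SNP sets must be disjoint")
  structure(list(m_snps = m_snps, n1 = n1, n2 = n2, n_shared = n_shared,
                 h2_1 = h2_1, h2_2 = h2_2, rg = rg, rho_pheno = rho_pheno,
                 ld_score_mean = ld_score_mean,
                 ld_score_shape = ld_score_shape, m_ref = m_ref,
                 prev1 = prev1, prev2 = prev2,
                 planted_hetero = planted_hetero,
                 planted_pleio = planted_pleio, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate per-SNP LD scores
#'
#' Draws LD scores as `1 + Gamma(shape, scale)` with the scale chosen so the
#' mean equals `mean`; `shape = Inf` gives the degenerate distribution at
#' `mean`. All scores are >= 1.
#'
#' @param m_snps number of SNPs.
#' @param mean target mean LD score, >= 1.
#' @param shape gamma shape parameter (> 0, possibly `Inf`).
#' @param seed integer seed.
#' @param chrom_sizes optional named vector of SNPs per chromosome; default
#'   spreads SNPs evenly over chromosomes 1..22.
#' @return Data frame `(snp_id, chrom, pos, ldscore)` sorted by position.
#' @export
simulate_ld_scores <- function(m_snps, mean = 100, shape = 2, seed = 1L,
                               chrom_sizes = NULL) {
  if (mean < 1) stop("domain error: mean LD score must be >= 1")
  set.seed(seed)
  if (is.infinite(shape)) {
    ell <- rep(mean, m_snps)
  } else {
    ell <- 1 + stats::rgamma(m_snps, shape = shape,
                             scale = (mean - 1) / shape)
  }
  if (is.null(chrom_sizes)) {
    nchr <- min(22L, m_snps)
    chrom <- sort(rep_len(seq_len(nchr), m_snps))
  } else {
    chrom <- rep(seq_along(chrom_sizes), chrom_sizes)
  }
  pos <- integer(m_snps)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    # ~1 SNP per 10 kb, jittered, strictly increasing
    pos[idx] <- cumsum(sample(5000:15000, length(idx), replace = TRUE))
  }
  data.frame(snp_id = paste0("rs", seq_len(m_snps)), chrom = chrom,
             pos = pos, ldscore = ell, stringsAsFactors = FALSE)
}

#' Simulate a pair of genetically correlated GWAS summary statistics
#'
#' Generates per-SNP z-score pairs moment-matched to the LD score regression
#' model: for SNP j with LD score `l_j`,
#' `Var(z_ij) = 1 + n_i * h2_i * l_j / M` and
#' `Cov(z_1j, z_2j) = sqrt(n1 n2) * rg * sqrt(h2_1 h2_2) * l_j / M
#'  + rho_pheno * n_shared / sqrt(n1 n2)`.
#' SNPs are independent given their LD scores. Planted SNPs receive the
#' configured mean shifts on top of the background distribution. Betas and
#' SEs are derived from allele frequencies as `se = 1/sqrt(n * 2 p (1-p))`,
#' `beta = z * se`.
#'
#' @param cfg a [sim_config()].
#' @param ld optional pre-computed LD-score table from
#'   [simulate_ld_scores()]; generated from `cfg` when `NULL`.
#' @return List with `ss1`, `ss2` (class `sumstats`), `ld` (LD-score table)
#'   and `truth` (class `sim_truth`: the config, realized LD scores, expected
#'   intercepts, and per-SNP labels `"null"`, `"pleiotropic"`,
#'   `"heterogeneous"`).
#' @export
simulate_joint_sumstats <- function(cfg, ld = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$m_snps
  if (is.null(ld)) ld <- simulate_ld_scores(m, cfg$ld_score_mean,
                                            cfg$ld_score_shape,
                                            seed = cfg$seed)
  attr(ld, "m_ref") <- cfg$m_ref
  ell <- ld$ldscore
  M <- cfg$m_ref
  v1 <- 1 + cfg$n1 * cfg$h2_1 * ell / M
  v2 <- 1 + cfg$n2 * cfg$h2_2 * ell / M
  cti <- cfg$rho_pheno * cfg$n_shared / sqrt(cfg$n1 * cfg$n2)
  cv <- sqrt(cfg$n1 * cfg$n2) * cfg$rg * sqrt(cfg$h2_1 * cfg$h2_2) *
    ell / M + cti
  bad <- cv^2 > v1 * v2 + 1e-12
  if (any(bad))
    stop("configuration error: implied per-SNP covariance not positive ",
         "semi-definite (rg/rho_pheno/n_shared combination) at ",
         sum(bad), " SNPs")
  # draw (z1, z2) ~ BVN via conditional factorization
  e1 <- stats::rnorm(m)
  e2 <- stats::rnorm(m)
  z1 <- sqrt(v1) * e1
  rho_j <- cv / sqrt(v1 * v2)
  z2 <- sqrt(v2) * (rho_j * e1 + sqrt(pmax(0, 1 - rho_j^2)) * e2)

  freq <- stats::runif(m, 0.05, 0.5)
  labels <- rep("null", m)
  if (!is.null(cfg$planted_pleio) && nrow(cfg$planted_pleio) > 0L) {
    i <- cfg$planted_pleio$index
    v_snp <- 2 * freq[i] * (1 - freq[i])
    z1[i] <- z1[i] + cfg$planted_pleio$shift * sqrt(cfg$n1 * v_snp)
    z2[i] <- z2[i] + cfg$planted_pleio$shift * sqrt(cfg$n2 * v_snp)
    labels[i] <- "pleiotropic"
  }
  if (!is.null(cfg$planted_hetero) && nrow(cfg$planted_hetero) > 0L) {
    i <- cfg$planted_hetero$index
    z1[i] <- z1[i] + cfg$planted_hetero$shift1
    z2[i] <- z2[i] + cfg$planted_hetero$shift2
    labels[i] <- "heterogeneous"
  }

  mk <- function(z, n, trait, prev) {
    se <- 1 / sqrt(n * 2 * freq * (1 - freq))
    rec <- data.frame(snp_id = ld$snp_id, chrom = ld$chrom, pos = ld$pos,
                      a1 = "A", a2 = "G", freq_a1 = freq,
                      beta = z * se, se = se, z = z,
                      n_total = n, stringsAsFactors = FALSE)
    if (!is.null(prev)) {
      rec$n_cases <- round(prev[2] * n)
      rec$n_controls <- n - rec$n_cases
    }
    sumstats(rec, trait_id = trait)
  }
  ss1 <- mk(z1, cfg$n1, "trait1", cfg$prev1)
  ss2 <- mk(z2, cfg$n2, "trait2", cfg$prev2)
  truth <- structure(list(config = cfg, ld_scores = ell,
                          expected_intercept1 = 1, expected_intercept2 = 1,
                          expected_cross_intercept = cti, labels = labels),
                     class = "sim_truth")
  list(ss1 = ss1, ss2 = ss2, ld = ld, truth = truth)
}

#' Simulate a block-structured genetic-correlation matrix
#'
#' Builds a symmetric unit-diagonal matrix with `within_rg` inside planted
#' clusters and `between_rg` across them, adds symmetric Gaussian noise to
#' the off-diagonal, and projects to the nearest valid correlation matrix
#' when the result is not positive semi-definite.
#'
#' @param k_traits number of traits.
#' @param cluster_sizes integer vector summing to the number of clustered
#'   traits (`<= k_traits`); remaining traits form singleton background.
#' @param within_rg,between_rg correlation levels, `within_rg > between_rg`.
#' @param noise_sd standard deviation of the off-diagonal noise.
#' @param seed integer seed.
#' @return `k_traits` x `k_traits` correlation matrix with trait labels and
#'   attribute `"clusters"` giving the planted assignment (0 = background).
#' @export
simulate_rg_matrix <- function(k_traits, cluster_sizes, within_rg = 0.9,
                               between_rg = 0.1, noise_sd = 0, seed = 1L) {
  stopifnot(abs(within_rg) <= 1, abs(between_rg) <= 1,
            within_rg > between_rg)
  if (sum(cluster_sizes) > k_traits)
    stop("configuration error: cluster sizes sum exceeds k_traits")
  set.seed(seed)
  assign <- c(rep(seq_along(cluster_sizes), cluster_sizes),
              rep(0L, k_traits - sum(cluster_sizes)))
  R <- matrix(between_rg, k_traits, k_traits)
  for (g in seq_along(cluster_sizes)) {
    idx <- which(assign == g)
    R[idx, idx] <- within_rg
  }
  # background traits are uncorrelated with everything
  bg <- which(assign == 0L)
  R[bg, ] <- 0; R[, bg] <- 0
  diag(R) <- 1
  if (noise_sd > 0 && k_traits > 1) {
    E <- matrix(stats::rnorm(k_traits^2, sd = noise_sd), k_traits)
    E <- (E + t(E)) / 2
    diag(E) <- 0
    R <- R + E
    R[R > 1] <- 1; R[R < -1] <- -1
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    }
  }
  labs <- paste0("trait", seq_len(k_traits))
  dimnames(R) <- list(labs, labs)
  attr(R, "clusters") <- assign
  R
}
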