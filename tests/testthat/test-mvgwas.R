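test_that("CPM closed form matches hand-evaluable cases", {
  # perfect homogeneity: b_F = c, zero misfit
  W <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  f <- fit_cpm_snp(c(0.3, 0.3), W)
  expect_equal(f$b_F, 0.3)
  expect_equal(f$chi2_cpm, 0, tolerance = 1e-12)
  # hand-evaluable GLS at W = I
  f2 <- fit_cpm_snp(c(1, 0), diag(2))
  expect_equal(f2$b_F, 0.5)
  expect_equal(f2$chi2_cpm, 0.5)
  expect_equal(f2$se, 1 / sqrt(2))
  # antisymmetric case
  f3 <- fit_cpm_snp(c(0.2, -0.2), diag(2))
  expect_equal(f3$b_F, 0)
  expect_equal(f3$chi2_cpm, 2 * 0.2^2)
  # singular W is refused with a condition diagnostic
  expect_error(fit_cpm_snp(c(1, 0), matrix(1, 2, 2)), "singular W")
})

test_that("closed form agrees with a numeric WLS oracle", {
  set.seed(101)
  for (i in 1:200) {
    c_vec <- rnorm(2)
    W <- random_spd2()
    f <- fit_cpm_snp(c_vec, W)
    o <- numeric_cpm_oracle(c_vec, W)
    expect_lt(abs(f$b_F - o$b_F), 1e-6 * max(1, abs(o$b_F)))
    expect_lt(abs(f$chi2_cpm - o$chi2), 1e-6 * max(1, abs(o$chi2)))
    expect_gte(f$chi2_cpm, -1e-8)
  }
})

test_that("IPM saturates the SNP moments and Qb reduces to chi2_cpm", {
  set.seed(102)
  for (i in 1:50) {
    c_vec <- rnorm(2)
    W <- random_spd2()
    s2 <- runif(1, 0.1, 0.5)
    ipm <- fit_ipm_snp(c_vec, W, sigma2_snp = s2)
    expect_identical(ipm$chi2_ipm, 0)
    expect_equal(c(ipm$b1, ipm$b2) * s2, c_vec)
    cpm <- fit_cpm_snp(c_vec, W)
    expect_equal(cpm$chi2_cpm - ipm$chi2_ipm, cpm$chi2_cpm)
  }
})

test_that("with W proportional to I, b_F is the mean and Qb is Cochran's Q", {
  set.seed(103)
  for (i in 1:50) {
    c_vec <- rnorm(2)
    v <- runif(1, 0.5, 2)
    f <- fit_cpm_snp(c_vec, diag(2) * v)
    expect_equal(f$b_F, mean(c_vec), tolerance = 1e-12)
    expect_equal(f$chi2_cpm, cochran_q(c_vec, c(v, v)), tolerance = 1e-9)
  }
})

test_that("snp moment expansion has the documented scale and structure", {
  # identical traits: equal c, symmetric W
  m <- expand_snp_moments(z1 = 2, z2 = 2, n1 = 1e5, n2 = 1e5, freq = 0.3,
                          cti = 0.2)
  expect_equal(m$c1, m$c2)
  expect_equal(m$w11, m$w22)
  # no overlap: diagonal W
  m0 <- expand_snp_moments(2, 1, 1e5, 1e5, 0.3, cti = 0)
  expect_equal(m0$w12, 0)
  expect_error(expand_snp_moments(2, 1, 1e5, 1e5, freq = 0), "domain error")
  expect_error(expand_snp_moments(2, 1, 1e5, 1e5, 0.3, cti = 1.5),
               "non-PSD")

  # planted standardized effect recovered on the c / sigma2_snp scale
  cfg <- sim_config(m_snps = 5000, n1 = 2e5, n2 = 2e5, h2_1 = 0, h2_2 = 0,
                    n_shared = 0,
                    planted_pleio = data.frame(index = 1:500, shift = 0.01),
                    seed = 104)
  sim <- simulate_joint_sumstats(cfg)
  r1 <- sim$ss1$records
  mm <- expand_snp_moments(r1$z[1:500], sim$ss2$records$z[1:500],
                           r1$n_total[1:500], r1$n_total[1:500],
                           r1$freq_a1[1:500], cti = 0)
  best <- mm$c1 / mm$sigma2_snp
  se_best <- sqrt(mm$w11) / mm$sigma2_snp
  expect_lt(abs(mean(best) - 0.01), 3 * mean(se_best) / sqrt(500))
})

test_that("run_mvgwas produces calibrated Qb and an LDSC-consistent factor", {
  cfg <- sim_config(m_snps = 20000, n1 = 1e5, n2 = 1e5, h2_1 = 0.25,
                    h2_2 = 0.25, rg = 1, n_shared = 0,
                    planted_pleio = data.frame(index = 1:50, shift = 0.015),
                    seed = 105)
  sim <- simulate_joint_sumstats(cfg)
  cov <- multivariable_ldsc(list(sim$ss1, sim$ss2), sim$ld)
  mv <- run_mvgwas(sim$ss1, sim$ss2, cov)
  expect_equal(mv$n_snps, 20000)
  expect_true(all(mv$fits$q_b >= -1e-8))
  expect_true(all(mv$fits$p_qb > 0 & mv$fits$p_qb <= 1))

  # GLS efficiency: the factor z exceeds both inputs at shared signals
  planted <- match(sim$ss1$records$snp_id[1:50], mv$fits$snp_id)
  h <- harmonize_sumstats(sim$ss1, sim$ss2)
  expect_gt(mean(abs(mv$fits$z_F[planted])),
            mean(abs(h$ss1$records$z[1:50])))
  expect_gt(mean(abs(mv$fits$z_F[planted])),
            mean(abs(h$ss2$records$z[1:50])))
  # planted shared SNPs do not trigger heterogeneity
  expect_lte(mean(mv$fits$p_qb[planted] < 0.05), 0.06 + 3 * sqrt(0.05 / 50))

  # the factor sumstats pass back through LDSC with positive h2
  fss <- mv$factor_ss
  fit <- ldsc_univariate(fss, sim$ld)
  expect_gt(fit$h2_obs, 0)
  expect_gt(fit$h2_obs / fit$h2_se, 3)

  # diagonal and full-W variants agree when overlap is absent
  mv_full <- run_mvgwas(sim$ss1, sim$ss2, cov, overlap_w = TRUE)
  expect_gt(cor(mv$fits$q_b, mv_full$fits$q_b), 0.99)

  # optional GC correction deflates the factor statistics
  lam <- estimate_lambda_gc(mv$factor_ss)
  mv_gc <- run_mvgwas(sim$ss1, sim$ss2, cov, gc_lambda = lam)
  expect_true(mv_gc$factor_ss$gc_applied)
  expect_equal(estimate_lambda_gc(mv_gc$factor_ss), 1, tolerance = 1e-6)
})

test_that("locus definition merges by window and tracks the lead SNP", {
  df <- data.frame(snp_id = paste0("s", 1:6), chrom = c(1, 1, 1, 2, 2, 2),
                   pos = c(1e6, 1.01e6, 2e6, 5e5, 5.1e5, 5.2e5),
                   pval = c(1e-9, 1e-12, 1e-10, 0.5, 1e-9, 1e-20))
  # nothing significant
  expect_equal(nrow(define_loci(df, p_threshold = 1e-30)), 0L)
  # 10 kb apart merge under a 250 kb window; 990 kb gap does not
  loci <- define_loci(df)
  expect_equal(nrow(loci), 3L)
  expect_equal(loci$lead_snp, c("s2", "s3", "s6"))
  expect_equal(loci$n_snps, c(2L, 1L, 2L))
  expect_true(all(loci$start < loci$end))
  # lead p is the member minimum
  expect_equal(loci$lead_p, c(1e-12, 1e-10, 1e-20))
  # constructed 3-cluster fixture recovers exactly 3 loci
  set.seed(9)
  fix <- data.frame(snp_id = paste0("x", 1:30), chrom = 3,
                    pos = c(1e6 + 1:10 * 1e3, 9e6 + 1:10 * 1e3,
                            2e7 + 1:10 * 1e3),
                    pval = 10^runif(30, -15, -9))
  expect_equal(nrow(define_loci(fix)), 3L)
})

test_that("locus intersection matches a brute-force oracle with padding", {
  # disjoint chromosomes
  a <- data.frame(chrom = 1, start = 1e6, end = 2e6)
  b <- data.frame(chrom = 2, start = 1e6, end = 2e6)
  expect_equal(nrow(intersect_loci(a, b)), 0L)
  # the +-1 Mb padding semantics
  a <- data.frame(chrom = 20, start = 30.0e6, end = 31.0e6)
  b <- data.frame(chrom = 20, start = 31.5e6, end = 32.0e6)
  expect_equal(nrow(intersect_loci(a, b, pad = 1e6)), 1L)
  expect_equal(nrow(intersect_loci(a, b, pad = 0)), 0L)

  # random interval sets against the O(n^2) oracle
  brute <- function(a, b, pad) {
    hits <- 0L
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] - pad < b$end[j] + pad &&
          b$start[j] - pad < a$end[i] + pad) hits <- hits + 1L
    }
    hits
  }
  set.seed(106)
  for (rep in 1:30) {
    mk <- function(n) {
      st <- sample.int(5e7, n)
      data.frame(chrom = sample(1:3, n, replace = TRUE), start = st,
                 end = st + sample.int(2e6, n))
    }
    a <- mk(sample(3:12, 1)); b <- mk(sample(3:12, 1))
    pad <- sample(c(0, 1e5, 1e6), 1)
    expect_equal(nrow(intersect_loci(a, b, pad = pad)), brute(a, b, pad))
    # symmetry
    expect_equal(nrow(intersect_loci(a, b, pad = pad)),
                 nrow(intersect_loci(b, a, pad = pad)))
  }
})
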