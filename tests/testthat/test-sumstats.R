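test_that("loading computes z and p, drops invalid rows, enforces schema", {
  tab <- toy_table()
  path <- write_toy_file(tab)
  ss <- load_sumstats(path)
  expect_s3_class(ss, "sumstats")
  expect_equal(ss$records$z, tab$beta / tab$se)
  # two-sided normal tail at z = 2 (independent normal-CDF evaluation)
  expect_equal(ss$records$pval[1], 0.0455002638964, tolerance = 1e-9)
  expect_equal(attr(ss, "n_dropped"), 0L)

  # same-allele row is dropped and counted
  bad <- rbind(tab, data.frame(snp_id = "rs4", chrom = 3L, pos = 1L,
                               a1 = "A", a2 = "A", freq_a1 = 0.2,
                               beta = 0.1, se = 0.1, n_total = 1000))
  ss2 <- load_sumstats(write_toy_file(bad))
  expect_equal(nrow(ss2$records), 3L)
  expect_equal(attr(ss2, "n_dropped"), 1L)
  expect_equal(unname(attr(ss2, "drop_reasons")["invalid_allele"]), 1L)

  # no effect-size column resolvable
  noeff <- tab[, c("snp_id", "chrom", "pos", "a1", "a2")]
  expect_error(load_sumstats(write_toy_file(noeff)), "schema error")
  expect_error(load_sumstats(tempfile()), "input error")

  # quality error naming the dominant failure when most rows are invalid
  mostly_bad <- tab
  mostly_bad$a2 <- mostly_bad$a1
  mostly_bad <- rbind(mostly_bad, tab[1, ])
  expect_error(load_sumstats(write_toy_file(mostly_bad)),
               "quality error.*invalid_allele")
})

test_that("write/load round trip is the identity and byte-stable", {
  set.seed(42)
  n <- 2000
  rec <- data.frame(snp_id = paste0("rs", 1:n), chrom = 1L,
                    pos = sort(sample.int(1e7, n)),
                    a1 = "A", a2 = "C",
                    freq_a1 = runif(n, 0.05, 0.95),
                    beta = rnorm(n, sd = 0.02),
                    se = runif(n, 0.005, 0.02),
                    n_total = 50000, stringsAsFactors = FALSE)
  ss <- sumstats(rec, trait_id = "sim")
  p1 <- tempfile(); p2 <- tempfile()
  write_sumstats(ss, p1)
  back <- load_sumstats(p1, trait_id = "sim")
  for (col in c("pos", "freq_a1", "beta", "se", "z", "pval", "n_total"))
    expect_equal(back$records[[col]], ss$records[[col]], tolerance = 1e-9)
  expect_identical(back$records$snp_id, ss$records$snp_id)
  write_sumstats(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  # empty sumstats: header-only file, zero records on re-load
  empty <- ss
  empty$records <- ss$records[0, , drop = FALSE]
  p3 <- tempfile()
  write_sumstats(empty, p3)
  expect_length(readLines(p3), 1L)
  expect_equal(nrow(load_sumstats(p3)$records), 0L)
})

test_that("direction flip negates beta and z, keeps p, and is an involution", {
  ss <- toy_ss()
  fl <- flip_effect_direction(ss)
  expect_equal(fl$records$beta, -ss$records$beta)
  expect_equal(fl$records$z, -ss$records$z)
  expect_equal(fl$records$pval, ss$records$pval)
  expect_equal(fl$records$se, ss$records$se)
  expect_true(fl$direction_flipped)
  back <- flip_effect_direction(fl)
  expect_equal(back$records, ss$records)
  expect_false(back$direction_flipped)
})

test_that("genomic control rescales z and se consistently", {
  ss <- toy_ss()
  expect_equal(apply_genomic_control(ss, 1)$records, ss$records)
  gc4 <- apply_genomic_control(ss, 4)
  expect_equal(gc4$records$z, ss$records$z / 2)
  expect_equal(gc4$records$se, ss$records$se * 2)
  expect_equal(gc4$records$beta, ss$records$beta)
  expect_true(gc4$gc_applied)
  expect_error(apply_genomic_control(ss, 0), "domain error")
  expect_warning(apply_genomic_control(ss, 0.5), "lambda_gc < 1")

  # median chi2 arithmetic on a generated sample; correction by
  # lambda = median chi2 / qchisq(0.5, 1) restores the null median
  set.seed(7)
  n <- 5001
  rec <- data.frame(snp_id = paste0("s", 1:n), a1 = "A", a2 = "G",
                    z = rnorm(n, sd = 1.28), se = 1)
  infl <- sumstats(rec)
  lam <- estimate_lambda_gc(infl)
  corr <- apply_genomic_control(infl, lam)
  expect_equal(median(corr$records$z^2), qchisq(0.5, 1), tolerance = 1e-9)
  # every p-value strictly increases under lambda > 1
  expect_true(all(corr$records$pval > infl$records$pval))
})

test_that("effective sample size follows the case-control formula", {
  expect_equal(effective_sample_size(500, 1000), 1000)  # balanced design
  expect_equal(effective_sample_size(51800, 1138870), 197775.781257,
               tolerance = 1e-6)
  expect_lt(effective_sample_size(1, 1e6), 4.1)         # limit n_cases -> 0
  expect_error(effective_sample_size(1000, 1000), "n_cases < n_total")
  meta <- trait_meta(n_total = 1138870, n_cases = 51800,
                     sample_prev = 0.045483, pop_prev = 0.05)
  expect_equal(meta$effective_n, effective_sample_size(51800, 1138870))
  expect_error(trait_meta(n_total = 1000, n_cases = 100, sample_prev = 0.5),
               "inconsistent")
})

test_that("allele harmonization aligns, sign-flips and drops ambiguous SNPs", {
  t1 <- toy_table()
  t2 <- toy_table()
  # reverse alleles at rs2: effect must flip
  t2$a1[2] <- "T"; t2$a2[2] <- "C"
  t2$beta[2] <- -t2$beta[2]
  # add a strand-ambiguous SNP to both
  amb <- data.frame(snp_id = "rs9", chrom = 4L, pos = 100L, a1 = "A",
                    a2 = "T", freq_a1 = 0.5, beta = 0.01, se = 0.01,
                    n_total = 1000)
  s1 <- sumstats(rbind(t1, amb)); s2 <- sumstats(rbind(t2, amb))
  h <- harmonize_sumstats(s1, s2)
  expect_equal(h$n_shared, 3L)
  expect_equal(h$n_flipped, 1L)
  expect_equal(h$n_ambiguous, 1L)
  expect_false("rs9" %in% h$ss1$records$snp_id)
  expect_equal(h$ss2$records$beta, h$ss1$records$beta)
  expect_identical(h$ss2$records$a1, h$ss1$records$a1)
})
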