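test_that("block partitions validate, read from BED, and cover SNP tables", {
  bed <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    start = c(0, 1000, 0), end = c(1000, 5000, 2000))
  path <- tempfile(fileext = ".bed")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  bp <- read_block_partition(path)
  expect_s3_class(bp, "block_partition")
  expect_equal(bp$chrom, c(1L, 1L, 2L))
  # overlap within a chromosome is refused
  expect_error(block_partition(data.frame(chrom = 1, start = c(0, 500),
                                          end = c(1000, 1500))),
               "overlapping blocks")
  # generated partition hits the requested genome-wide count
  snp <- simulate_ld_scores(30000, 50, 2, seed = 1)
  gen <- make_block_partition(snp, n_blocks = 1703)
  expect_gt(nrow(gen), 1600)
  expect_lt(nrow(gen), 1800)
})

test_that("whitelist and mask filtering keep the right SNPs", {
  rec <- data.frame(snp_id = paste0("s", 1:10), chrom = 1L,
                    pos = as.integer(1:10 * 1000), a1 = "A", a2 = "G",
                    z = rnorm(10), se = 1, n_total = 1000)
  ss <- sumstats(rec)
  # no-op filters
  same <- filter_snps(ss, whitelist = rec$snp_id,
                      mask = data.frame(chrom = integer(), start = integer(),
                                        end = integer()))
  expect_equal(same$records, ss$records)
  # 4 whitelisted, 1 of them masked -> 3 survive
  out <- filter_snps(ss, whitelist = c("s1", "s2", "s3", "s4"),
                     mask = data.frame(chrom = 1, start = 1500, end = 2500))
  expect_equal(out$records$snp_id, c("s1", "s3", "s4"))
  # mask covering everything
  expect_error(filter_snps(ss, whitelist = rec$snp_id,
                           mask = data.frame(chrom = 1, start = 0,
                                             end = 1e6)),
               "no SNPs survive")
})

test_that("block means of -log10 P match hand counts and a brute force", {
  rec <- data.frame(snp_id = c("a", "b", "c"), chrom = 1L,
                    pos = c(10L, 20L, 5000L), a1 = "A", a2 = "G",
                    z = c(1, 1, 1), se = 1, n_total = 100)
  ss <- sumstats(rec)
  ss$records$pval <- c(0.1, 0.001, 0.5)
  ss$records$z <- qnorm(ss$records$pval / 2) * -1   # keep z/p consistent
  blocks <- block_partition(data.frame(chrom = 1, start = c(0, 1000),
                                       end = c(1000, 10000)))
  bm <- block_average_neglogp(ss, blocks)
  expect_equal(bm$mean_neglogp[bm$block == 1], 2)     # (1 + 3) / 2
  expect_equal(bm$n_snps, c(2L, 1L))

  # a SNP exactly on a block boundary joins the block whose start it equals
  rec2 <- rec
  rec2$pos <- c(999L, 1000L, 1001L)   # 0-based: 998, 999, 1000
  ss2 <- sumstats(rec2)
  bm2 <- block_average_neglogp(ss2, blocks)
  expect_equal(bm2$n_snps, c(2L, 1L))   # 1000 (0-based 999) stays in block 1

  # random fixture against a per-SNP brute-force loop
  set.seed(301)
  n <- 2000
  rnd <- sumstats(data.frame(snp_id = paste0("r", 1:n),
                             chrom = sample(1:3, n, TRUE),
                             pos = sample.int(1e6, n), a1 = "A", a2 = "G",
                             z = rnorm(n), se = 1, n_total = 100))
  bl <- make_block_partition(rnd$records, n_blocks = 60)
  fast <- block_average_neglogp(rnd, bl)
  nlp <- -log10(rnd$records$pval)
  for (row in sample(seq_len(nrow(fast)), 10)) {
    b <- fast[row, ]
    inb <- rnd$records$chrom == b$chrom &
      (rnd$records$pos - 1) >= b$start & (rnd$records$pos - 1) < b$end
    expect_equal(b$mean_neglogp, mean(nlp[inb]))
    expect_equal(b$n_snps, sum(inb))
  }
})

test_that("blockwise Spearman: exact cases, bootstrap SE, rank invariance", {
  set.seed(302)
  m1 <- data.frame(block = 1:100, chrom = 1, start = 0:99, end = 1:100,
                   n_snps = 5, mean_neglogp = runif(100, 0.1, 3))
  # identical inputs
  r <- blockwise_spearman(m1, m1, n_boot = 500, seed = 1)
  expect_equal(r$rho, 1)
  expect_equal(r$se_boot, 0)
  # strictly decreasing transform
  m2 <- m1
  m2$mean_neglogp <- exp(-m1$mean_neglogp)
  expect_equal(blockwise_spearman(m1, m2, n_boot = 50, seed = 1)$rho, -1)
  # invariance under strictly increasing transforms
  m3 <- m1
  m3$mean_neglogp <- m1$mean_neglogp^3 + 1
  mB <- m1
  mB$mean_neglogp <- runif(100)
  expect_equal(blockwise_spearman(m3, mB, n_boot = 50, seed = 1)$rho,
               blockwise_spearman(m1, mB, n_boot = 50, seed = 1)$rho)
  # too few blocks
  expect_error(blockwise_spearman(m1[1:5, ], m1[1:5, ]), "10 shared")

  # bootstrap SE stabilizes between 5,000 and 10,000 resamples
  mC <- m1
  set.seed(303)
  mC$mean_neglogp <- 0.5 * m1$mean_neglogp + rnorm(100, sd = 0.4)
  se5 <- blockwise_spearman(m1, mC, n_boot = 5000, seed = 7)$se_boot
  se10 <- blockwise_spearman(m1, mC, n_boot = 10000, seed = 7)$se_boot
  expect_lt(abs(se10 - se5) / se5, 0.05)
})

test_that("shared planted signal yields a positive blockwise correlation", {
  cfg <- sim_config(m_snps = 20000, n1 = 2e5, n2 = 2e5, h2_1 = 0.4,
                    h2_2 = 0.4, rg = 0.9, n_shared = 0, seed = 304)
  sim <- simulate_joint_sumstats(cfg)
  blocks <- make_block_partition(sim$ss1$records, n_blocks = 400)
  b1 <- block_average_neglogp(sim$ss1, blocks)
  b2 <- block_average_neglogp(sim$ss2, blocks)
  r <- blockwise_spearman(b1, b2, n_boot = 2000, seed = 305)
  expect_gt(r$rho, 0)
  expect_gt(r$rho, 3 * r$se_boot)
})
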