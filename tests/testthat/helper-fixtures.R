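# Small in-code fixtures shared across test files.

# A tiny hand-written sumstats table (valid rows only unless extra added).
toy_table <- function() {
  data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    chrom = c(1L, 1L, 2L),
    pos = c(1000L, 5000L, 2000L),
    a1 = c("A", "C", "G"),
    a2 = c("G", "T", "A"),
    freq_a1 = c(0.3, 0.4, 0.2),
    beta = c(0.02, -0.01, 0.005),
    se = c(0.01, 0.02, 0.01),
    n_total = c(1000, 1000, 1000),
    stringsAsFactors = FALSE
  )
}

toy_ss <- function() sumstats(toy_table(), trait_id = "toy")

write_toy_file <- function(tab = toy_table()) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Random SPD 2x2 matrix for GLS oracle checks.
random_spd2 <- function() {
  A <- matrix(stats::rnorm(4), 2, 2)
  W <- crossprod(A) + diag(2) * 0.1
  (W + t(W)) / 2
}

# Independent numeric WLS oracle: minimize (c - b1)' W^-1 (c - b1) over b.
numeric_cpm_oracle <- function(c, W) {
  Winv <- solve(W)
  obj <- function(b) {
    r <- c - b
    as.numeric(t(r) %*% Winv %*% r)
  }
  opt <- stats::optimize(obj, interval = range(c) + c(-10, 10), tol = 1e-12)
  list(b_F = opt$minimum, chi2 = opt$objective)
}

# Cochran's Q for two studies with effect estimates x and variances v.
cochran_q <- function(x, v) {
  w <- 1 / v
  xbar <- sum(w * x) / sum(w)
  sum(w * (x - xbar)^2)
}
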