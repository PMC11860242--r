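# Cross-method validation of the common-factor results: N-weighted
# meta-analysis with sample-overlap correction, and the homogeneous-effect
# cross-phenotype statistic Shom.

#' Null-SNP z-score correlation matrix
#'
#' Estimates the correlation of z-scores across traits from SNPs where every
#' trait's |z| is below the truncation bound (default 1.96), i.e. from
#' effectively null SNPs; this correlation reflects correlated estimation
#' error from overlapping samples. Projected to the nearest valid
#' correlation matrix if numerically indefinite.
#'
#' @param ss_list list of harmonized `sumstats` objects (intersected on SNP
#'   id here; traits are aligned pairwise to the first).
#' @param z_bound truncation bound on |z| (default 1.96).
#' @return Object of class `z_corr_matrix`: `R` (k x k), `z_bound`,
#'   `n_snps` contributing.
#' @export
estimate_null_z_correlation <- function(ss_list, z_bound = 1.96) {
  k <- length(ss_list)
  stopifnot(k >= 2)
  for (i in seq(2, k))
    ss_list[[i]] <- harmonize_sumstats(ss_list[[1]], ss_list[[i]])$ss2
  ids <- Reduce(intersect, lapply(ss_list, function(s) s$records$snp_id))
  Z <- vapply(ss_list, function(s)
    s$records$z[match(ids, s$records$snp_id)], numeric(length(ids)))
  keep <- rowSums(abs(Z) < z_bound) == k
  if (sum(keep) < 1000)
    stop("fewer than 1,000 SNPs survive the |z| < ", z_bound, " truncation")
  R <- stats::cor(Z[keep, , drop = FALSE])
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  dimnames(R) <- rep(list(vapply(ss_list, function(s) s$trait_id, "")), 2)
  structure(list(R = R, z_bound = z_bound, n_snps = sum(keep)),
            class = "z_corr_matrix")
}

#' N-weighted multivariate GWAS meta-analysis
#'
#' Sample-size-weighted meta-analysis of z-scores with a sample-overlap
#' correction through the cross-trait intercept matrix: per SNP j,
#' `z_meta = sum_i w_ij z_ij / sqrt(sum_i w_ij^2 +
#'  sum_{i != k} w_ij w_kj CTI_ik)` with weights `w_ij = sqrt(h2_i * N_ij)`.
#'
#' @param ss_list list of `sumstats` objects (harmonized to the first).
#' @param h2 vector of SNP heritabilities, one per trait.
#' @param cti matrix of cross-trait intercepts (k x k, symmetric; diagonal
#'   ignored). Scalar allowed for k = 1... 2.
#' @return A `sumstats` object for the meta-analyzed trait with `z`, `pval`
#'   and combined effective `n_total = sum_i N_ij`.
#' @export
nweighted_gwama <- function(ss_list, h2, cti = NULL) {
  k <- length(ss_list)
  stopifnot(length(h2) == k)
  if (is.null(cti)) cti <- matrix(0, k, k)
  if (length(cti) == 1L && k == 2L)
    cti <- matrix(c(0, cti, cti, 0), 2, 2)
  if (!isSymmetric(unname(cti), tol = 1e-8))
    stop("cross-trait intercept matrix must be symmetric")
  if (k >= 2) for (i in seq(2, k))
    ss_list[[i]] <- harmonize_sumstats(ss_list[[1]], ss_list[[i]])$ss2
  ids <- Reduce(intersect, lapply(ss_list, function(s) s$records$snp_id))
  recs <- lapply(ss_list, function(s)
    s$records[match(ids, s$records$snp_id), , drop = FALSE])
  Z <- vapply(recs, function(r) r$z, numeric(length(ids)))
  N <- vapply(recs, function(r) r$n_total, numeric(length(ids)))
  W <- sweep(sqrt(N), 2, sqrt(pmax(h2, 0)), "*")
  num <- rowSums(W * Z)
  den2 <- rowSums(W^2)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      den2 <- den2 + 2 * W[, i] * W[, j] * cti[i, j]
  }
  if (any(den2 <= 0))
    stop("invalid cross-trait intercept matrix: non-positive meta variance")
  z_meta <- num / sqrt(den2)
  r1 <- recs[[1]]
  out <- data.frame(snp_id = r1$snp_id, chrom = r1$chrom, pos = r1$pos,
                    a1 = r1$a1, a2 = r1$a2,
                    freq_a1 = r1$freq_a1,
                    z = z_meta, n_total = rowSums(N),
                    stringsAsFactors = FALSE)
  sumstats(out, trait_id = "nweighted_meta")
}

#' Homogeneous-effect cross-phenotype statistic (Shom)
#'
#' `Shom = (e' R^-1 T)^2 / (e' R^-1 e)` with the sample-size-weighted
#' z vector `T_i = sqrt(N_i) z_i / sqrt(mean(N))`, `R` the null-SNP z-score
#' correlation matrix, `N` the (median) sample size per trait, and `e` the
#' unit vector; referred to a 1-df chi-squared. With this scaling
#' convention (recorded in the output) the statistic reduces to `z^2` for a
#' single trait and, for uncorrelated traits, to the square of the classic
#' sample-size-weighted meta-analysis z,
#' `(sum_i sqrt(N_i) z_i)^2 / sum_i N_i` -- the fixed-effect chi-squared
#' under effect homogeneity.
#'
#' @param z numeric vector (one SNP, length k) or an m x k matrix of
#'   z-scores.
#' @param n vector of per-trait (median) sample sizes.
#' @param corr a `z_corr_matrix` or a plain k x k correlation matrix.
#' @return For vector input, a list `s_hom`, `p`, `weighting`; for matrix
#'   input, a data frame with columns `s_hom`, `p`.
#' @export
s_hom_test <- function(z, n, corr) {
  R <- if (inherits(corr, "z_corr_matrix")) corr$R else corr
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, 1) else as.matrix(z)
  k <- ncol(Z)
  stopifnot(length(n) == k, all(dim(R) == c(k, k)))
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("singular Sigma in Shom: ", conditionMessage(e)))
  e <- rep(1, k)
  u <- as.numeric(Rinv %*% e)            # R^-1 e
  denom <- sum(e * u)
  T <- sweep(Z, 2, sqrt(n / mean(n)), "*")
  s <- as.numeric(T %*% u)^2 / denom
  p <- stats::pchisq(s, df = 1, lower.tail = FALSE)
  if (single)
    list(s_hom = s, p = p,
         weighting = "T_i = sqrt(N_i/mean(N)) z_i; Sigma = R")
  else data.frame(s_hom = s, p = p)
}

#' Genome-wide Shom scan
#'
#' Runs [s_hom_test()] at every shared SNP of a list of harmonized GWASs,
#' using the median per-trait sample size and a null-SNP z-score correlation
#' matrix (estimated here when not supplied).
#'
#' @param ss_list list of `sumstats` objects.
#' @param corr optional `z_corr_matrix`; estimated via
#'   [estimate_null_z_correlation()] when `NULL`.
#' @param z_bound truncation bound passed to the correlation estimate.
#' @return Data frame `snp_id, chrom, pos, s_hom, p`.
#' @export
s_hom_scan <- function(ss_list, corr = NULL, z_bound = 1.96) {
  k <- length(ss_list)
  if (k >= 2) for (i in seq(2, k))
    ss_list[[i]] <- harmonize_sumstats(ss_list[[1]], ss_list[[i]])$ss2
  if (is.null(corr))
    corr <- estimate_null_z_correlation(ss_list, z_bound = z_bound)
  ids <- Reduce(intersect, lapply(ss_list, function(s) s$records$snp_id))
  recs <- lapply(ss_list, function(s)
    s$records[match(ids, s$records$snp_id), , drop = FALSE])
  Z <- vapply(recs, function(r) r$z, numeric(length(ids)))
  n_med <- vapply(recs, function(r) stats::median(r$n_total), 1)
  res <- s_hom_test(Z, n_med, corr)
  cbind(data.frame(snp_id = recs[[1]]$snp_id, chrom = recs[[1]]$chrom,
                   pos = recs[[1]]$pos, stringsAsFactors = FALSE), res)
}
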