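# Per-SNP bivariate common-factor GWAS.
#
# With both factor loadings constrained to 1 and k = 2 traits, the SNP-free
# measurement model (factor variance + two residual variances against the
# three unique elements of S) is exactly identified, so all model misfit
# lives in the two SNP-trait covariance moments. The common pathway model
# (CPM) then reduces to a 2-moment GLS problem with a closed form, the
# independent pathway model (IPM) is saturated in the SNP moments
# (chi2_ipm = 0), and the heterogeneity statistic Qb = chi2_CPM - chi2_IPM
# is a 1-df chi-squared difference.

#' Factor model specification from a genetic covariance estimate
#'
#' Solves the exactly identified two-trait measurement model with both
#' loadings fixed to 1: factor variance `sigma2_F = S[1,2]`, residual
#' variances `u_i = S[i,i] - S[1,2]`.
#'
#' @param cov a `genetic_cov_estimate` with k = 2 (from
#'   [multivariable_ldsc()]).
#' @param use_liability use the liability-scale `S` when present (default
#'   `FALSE`: observed scale).
#' @return List of class `factor_model_spec`: `sigma2_F`, `u1`, `u2`, `S`,
#'   `V`, `intercepts`, `traits`.
#' @export
factor_model_spec <- function(cov, use_liability = FALSE) {
  stopifnot(inherits(cov, "genetic_cov_estimate"),
            length(cov$traits) == 2L)
  S <- if (use_liability) cov$S else cov$S_obs
  structure(list(sigma2_F = S[1, 2], u1 = S[1, 1] - S[1, 2],
                 u2 = S[2, 2] - S[1, 2], S = S, V = cov$V,
                 intercepts = cov$intercepts, traits = cov$traits),
            class = "factor_model_spec")
}

#' Per-SNP moments for the factor model
#'
#' Converts per-SNP z-scores to partially standardized SNP-trait genetic
#' covariances `c_i = z_i * sqrt(sigma2_SNP / N_i)` (equivalently the
#' per-allele effect on the standardized trait times the SNP variance
#' `sigma2_SNP = 2 p (1-p)`), with their 2 x 2 sampling covariance `W`:
#' diagonal `intercept_i * sigma2_SNP / N_i`, off-diagonal
#' `cti * sigma2_SNP / sqrt(N1 N2)` (the sample-overlap covariance of the
#' two estimation errors, `cti` the cross-trait intercept).
#'
#' All arguments are vectorized over SNPs.
#'
#' @param z1,z2 z-scores for the two traits.
#' @param n1,n2 per-SNP sample sizes.
#' @param freq effect-allele frequency in (0,1).
#' @param cti cross-trait intercept.
#' @param int1,int2 univariate LDSC intercepts (default 1).
#' @param overlap_w include the off-diagonal overlap term in `W`
#'   (default `TRUE`); `FALSE` gives the diagonal-W variant.
#' @return Data frame with columns `c1`, `c2`, `w11`, `w12`, `w22`,
#'   `sigma2_snp`.
#' @export
expand_snp_moments <- function(z1, z2, n1, n2, freq, cti = 0,
                               int1 = 1, int2 = 1, overlap_w = TRUE) {
  if (any(freq <= 0 | freq >= 1))
    stop("domain error: freq must lie strictly in (0,1)")
  s2 <- 2 * freq * (1 - freq)
  w11 <- int1 * s2 / n1
  w12 <- if (overlap_w) cti * s2 / sqrt(n1 * n2) else 0 * s2
  w22 <- int2 * s2 / n2
  if (any(w12^2 >= w11 * w22))
    stop("non-PSD W: |cross-trait intercept| implies correlation >= 1")
  data.frame(c1 = z1 * sqrt(s2 / n1), c2 = z2 * sqrt(s2 / n2),
             w11 = w11, w12 = w12, w22 = w22, sigma2_snp = s2)
}

# Vectorized 2x2 GLS core shared by fit_cpm_snp and run_mvgwas.
cpm_core <- function(c1, c2, w11, w12, w22) {
  det <- w11 * w22 - w12^2
  if (any(det <= 0))
    stop("singular W: condition problem, min det = ", min(det))
  # elements of W^{-1}
  a11 <- w22 / det; a22 <- w11 / det; a12 <- -w12 / det
  sw <- a11 + a22 + 2 * a12            # 1' W^-1 1
  bF <- (a11 * c1 + a22 * c2 + a12 * (c1 + c2)) / sw
  se <- 1 / sqrt(sw)
  r1 <- c1 - bF; r2 <- c2 - bF
  chi2 <- a11 * r1^2 + 2 * a12 * r1 * r2 + a22 * r2^2
  list(b_F = bF, se = se, z_F = bF / se, chi2_cpm = pmax(chi2, 0))
}

#' Fit the common pathway model at one SNP
#'
#' Closed-form GLS under the unit-loading constraint:
#' `b_F = (1' W^-1 c) / (1' W^-1 1)`, `SE = 1/sqrt(1' W^-1 1)`,
#' `chi2_cpm = (c - b_F 1)' W^-1 (c - b_F 1)`.
#'
#' @param c length-2 vector of SNP-trait covariances.
#' @param W 2 x 2 sampling covariance of `c`.
#' @return List `b_F`, `se`, `z_F`, `p_F`, `chi2_cpm`.
#' @export
fit_cpm_snp <- function(c, W) {
  stopifnot(length(c) == 2L, all(dim(W) == c(2L, 2L)))
  if (abs(W[1, 2] - W[2, 1]) > 1e-12 * max(abs(W)))
    stop("W must be symmetric")
  kappa <- tryCatch(kappa(W, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa) || det(W) <= 0)
    stop("singular W (condition number ", format(kappa), ")")
  f <- cpm_core(c[1], c[2], W[1, 1], W[1, 2], W[2, 2])
  f$p_F <- 2 * stats::pnorm(-abs(f$z_F))
  f
}

#' Fit the independent pathway model at one SNP
#'
#' The SNP paths are saturated: each trait gets its own direct path, so the
#' two SNP moments are fit exactly and `chi2_ipm = 0`; returned explicitly
#' so the heterogeneity statistic is computed by the stated subtraction.
#'
#' @param c length-2 vector of SNP-trait covariances.
#' @param W 2 x 2 sampling covariance of `c` (unused by the point fit;
#'   checked for symmetry).
#' @param sigma2_snp SNP variance `2 p (1-p)` used to return per-trait
#'   standardized path coefficients `b_i = c_i / sigma2_snp`.
#' @return List `b1`, `b2`, `chi2_ipm` (exactly 0).
#' @export
fit_ipm_snp <- function(c, W = NULL, sigma2_snp = 1) {
  stopifnot(length(c) == 2L)
  list(b1 = c[1] / sigma2_snp, b2 = c[2] / sigma2_snp, chi2_ipm = 0)
}

#' Bivariate common-factor multivariate GWAS with per-SNP heterogeneity
#'
#' For every SNP shared by the two harmonized GWASs, fits the common pathway
#' model (shared factor, loadings 1) and the saturated independent pathway
#' model, and returns the common-factor association (`b_F`, `se`, `z_F`,
#' `p_F`), the model chi-squareds, and the heterogeneity statistic
#' `Qb = chi2_CPM - chi2_IPM` with its 1-df p-value. Also assembles a new
#' `sumstats` object for the common factor, suitable for downstream LD score
#' regression, with per-SNP effective sample size `sigma2_SNP / se_F^2`.
#'
#' @param ss1,ss2 `sumstats` objects (harmonized internally).
#' @param cov `genetic_cov_estimate` for the pair, from
#'   [multivariable_ldsc()]; supplies the univariate and cross-trait
#'   intercepts.
#' @param freq_source where to take effect-allele frequencies from:
#'   `"ss1"` (default), `"ss2"`, or a data frame `(snp_id, freq_a1)` playing
#'   the role of a reference panel.
#' @param overlap_w include the sample-overlap off-diagonal
#'   `cti * se1 * se2` in `W` (the full-W variant). Default `FALSE`
#'   (diagonally weighted fit): exact when samples do not overlap, and
#'   robust to noise in the estimated cross-trait intercept; with
#'   substantial sample overlap and a precisely estimated intercept the
#'   full-W variant is better calibrated. The two agree closely in
#'   well-conditioned settings.
#' @param intercept_scale_w multiply the diagonal of `W` by the estimated
#'   univariate LDSC intercepts (absorbing residual confounding into the
#'   per-SNP error variance). Default `FALSE`: the diagonal comes from the
#'   rescaled SEs alone, which is exact when the univariate intercepts are 1.
#' @param gc_lambda optional genomic-control factor applied to the factor
#'   summary statistics (e.g. an LDSC-derived inflation index); `NULL` for
#'   none.
#' @return List of class `mvgwas_result`: `fits` (one row per SNP:
#'   `snp_id, chrom, pos, freq_a1, sigma2_snp, c1, c2, b_F, se_F, z_F, p_F,
#'   chi2_cpm, chi2_ipm, q_b, p_qb, b1_ipm, b2_ipm`), `factor_ss`
#'   (a `sumstats`), `model` (the `factor_model_spec`), `n_snps`.
#' @export
run_mvgwas <- function(ss1, ss2, cov, freq_source = "ss1",
                       overlap_w = FALSE, intercept_scale_w = FALSE,
                       gc_lambda = NULL) {
  stopifnot(inherits(cov, "genetic_cov_estimate"))
  h <- harmonize_sumstats(ss1, ss2)
  r1 <- h$ss1$records; r2 <- h$ss2$records
  if (nrow(r1) == 0L) stop("empty SNP intersection between traits")
  freq <- if (is.data.frame(freq_source)) {
    f <- freq_source$freq_a1[match(r1$snp_id, freq_source$snp_id)]
    if (anyNA(f)) stop("freq source missing ", sum(is.na(f)), " SNPs")
    f
  } else if (identical(freq_source, "ss2")) r2$freq_a1 else r1$freq_a1
  mom <- expand_snp_moments(r1$z, r2$z, r1$n_total, r2$n_total, freq,
                            cti = cov$intercepts[1, 2],
                            int1 = if (intercept_scale_w)
                              cov$intercepts[1, 1] else 1,
                            int2 = if (intercept_scale_w)
                              cov$intercepts[2, 2] else 1,
                            overlap_w = overlap_w)
  f <- cpm_core(mom$c1, mom$c2, mom$w11, mom$w12, mom$w22)
  q_b <- pmax(f$chi2_cpm - 0, 0)   # chi2_ipm = 0 (saturated SNP paths)
  fits <- data.frame(snp_id = r1$snp_id, chrom = r1$chrom, pos = r1$pos,
                     freq_a1 = freq, sigma2_snp = mom$sigma2_snp,
                     c1 = mom$c1, c2 = mom$c2,
                     b_F = f$b_F, se_F = f$se, z_F = f$z_F,
                     p_F = 2 * stats::pnorm(-abs(f$z_F)),
                     chi2_cpm = f$chi2_cpm, chi2_ipm = 0,
                     q_b = q_b,
                     p_qb = stats::pchisq(q_b, df = 1, lower.tail = FALSE),
                     b1_ipm = mom$c1 / mom$sigma2_snp,
                     b2_ipm = mom$c2 / mom$sigma2_snp,
                     stringsAsFactors = FALSE)
  n_eff <- mom$sigma2_snp / f$se^2
  frec <- data.frame(snp_id = r1$snp_id, chrom = r1$chrom, pos = r1$pos,
                     a1 = r1$a1, a2 = r1$a2, freq_a1 = freq,
                     beta = f$b_F, se = f$se, z = f$z_F,
                     n_total = n_eff, stringsAsFactors = FALSE)
  factor_ss <- sumstats(frec, trait_id = paste0("F_", h$ss1$trait_id, "_",
                                                h$ss2$trait_id))
  if (!is.null(gc_lambda))
    factor_ss <- apply_genomic_control(factor_ss, gc_lambda)
  structure(list(fits = fits, factor_ss = factor_ss,
                 model = factor_model_spec(cov), n_snps = nrow(fits)),
            class = "mvgwas_result")
}

#' @export
print.mvgwas_result <- function(x, ...) {
  cat(sprintf("mvGWAS common-factor fit: %d SNPs\n", x$n_snps))
  cat(sprintf("measurement model: sigma2_F = %.4f, u1 = %.4f, u2 = %.4f\n",
              x$model$sigma2_F, x$model$u1, x$model$u2))
  cat(sprintf("genome-wide significant (p < 5e-8): factor %d, Qb %d\n",
              sum(x$fits$p_F < 5e-8), sum(x$fits$p_qb < 5e-8)))
  invisible(x)
}

#' Define significant loci by greedy positional merging
#'
#' SNPs below the p-value threshold are merged into one locus when within
#' `merge_window` base pairs of the locus so far, per chromosome; the lead
#' SNP is the member with the smallest p-value. Intervals are half-open
#' `[start, end)`.
#'
#' @param x a `sumstats` object, or a data frame with columns `snp_id`,
#'   `chrom`, `pos` and a p-value column.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param merge_window merge distance in bp (default 250000).
#' @param p_col p-value column name for data-frame input (default `"pval"`).
#' @return Data frame of loci: `chrom`, `start`, `end`, `lead_snp`,
#'   `lead_p`, `n_snps`, plus a list column `members` of member SNP ids.
#'   Zero rows when nothing is significant.
#' @export
define_loci <- function(x, p_threshold = 5e-8, merge_window = 250000,
                        p_col = "pval") {
  df <- if (inherits(x, "sumstats")) x$records else x
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(df)),
            p_col %in% names(df))
  sig <- df[df[[p_col]] < p_threshold, , drop = FALSE]
  empty <- data.frame(chrom = integer(), start = numeric(),
                      end = numeric(), lead_snp = character(),
                      lead_p = numeric(), n_snps = integer())
  empty$members <- list()
  if (nrow(sig) == 0L) return(empty)
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  loci <- list()
  cur <- NULL
  flush <- function(cur) {
    lead <- which.min(cur$p)
    data.frame(chrom = cur$chrom, start = min(cur$pos),
               end = max(cur$pos) + 1, lead_snp = cur$id[lead],
               lead_p = cur$p[lead], n_snps = length(cur$id))
  }
  for (i in seq_len(nrow(sig))) {
    if (is.null(cur) || sig$chrom[i] != cur$chrom ||
        sig$pos[i] - max(cur$pos) > merge_window) {
      if (!is.null(cur)) loci[[length(loci) + 1L]] <- c(flush(cur),
                                                        list(members = list(cur$id)))
      cur <- list(chrom = sig$chrom[i], pos = sig$pos[i],
                  id = sig$snp_id[i], p = sig[[p_col]][i])
    } else {
      cur$pos <- c(cur$pos, sig$pos[i])
      cur$id <- c(cur$id, sig$snp_id[i])
      cur$p <- c(cur$p, sig[[p_col]][i])
    }
  }
  loci[[length(loci) + 1L]] <- c(flush(cur), list(members = list(cur$id)))
  out <- do.call(rbind, lapply(loci, function(l)
    data.frame(chrom = l$chrom, start = l$start, end = l$end,
               lead_snp = l$lead_snp, lead_p = l$lead_p,
               n_snps = l$n_snps)))
  out$members <- lapply(loci, function(l) l$members[[1]])
  rownames(out) <- NULL
  out
}

#' Intersect two locus sets with optional padding
#'
#' Reports every pair of loci (one from each set) whose intervals, each
#' expanded by `pad` base pairs on both sides, overlap in half-open interval
#' arithmetic on the same chromosome. Padding both sets keeps the operation
#' symmetric.
#'
#' @param a,b locus data frames from [define_loci()] (need `chrom`,
#'   `start`, `end`).
#' @param pad padding in bp added to both ends of every interval
#'   (default 0; the cross-method locus comparison uses 1e6).
#' @return Data frame of overlapping pairs with columns `a_idx`, `b_idx`,
#'   `chrom`, `a_start`, `a_end`, `b_start`, `b_end`.
#' @export
intersect_loci <- function(a, b, pad = 0) {
  out <- data.frame(a_idx = integer(), b_idx = integer(), chrom = integer(),
                    a_start = numeric(), a_end = numeric(),
                    b_start = numeric(), b_end = numeric())
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  res <- list()
  for (i in seq_len(nrow(a))) {
    same <- which(b$chrom == a$chrom[i])
    if (length(same) == 0L) next
    as_ <- a$start[i] - pad; ae <- a$end[i] + pad
    bs <- b$start[same] - pad; be <- b$end[same] + pad
    hit <- same[as_ < be & bs < ae]
    if (length(hit) > 0L)
      res[[length(res) + 1L]] <- data.frame(
        a_idx = i, b_idx = hit, chrom = a$chrom[i],
        a_start = a$start[i], a_end = a$end[i],
        b_start = b$start[hit], b_end = b$end[hit])
  }
  if (length(res) == 0L) return(out)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
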