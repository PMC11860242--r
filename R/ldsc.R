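# LD score regression: heritability, genetic covariance, intercepts, with
# delete-one-block jackknife (co)variances computed from per-block
# sufficient statistics so a full jackknife costs O(m + n_blocks).

# Merge a sumstats object with an LD-score table; genomic order.
merge_sumstats_ld <- function(ss, ld) {
  stopifnot(inherits(ss, "sumstats"))
  rec <- ss$records
  idx <- match(rec$snp_id, ld$snp_id)
  keep <- !is.na(idx)
  rec <- rec[keep, , drop = FALSE]
  ldm <- ld[idx[keep], , drop = FALSE]
  ord <- order(ldm$chrom, ldm$pos)
  rec <- rec[ord, , drop = FALSE]
  ldm <- ldm[ord, , drop = FALSE]
  data.frame(snp_id = rec$snp_id, chrom = ldm$chrom, pos = ldm$pos,
             z = rec$z, n = rec$n_total, ell = ldm$ldscore,
             stringsAsFactors = FALSE)
}

# Contiguous equal-count jackknife block assignment for m ordered SNPs.
make_blocks <- function(m, n_blocks) {
  if (m < n_blocks)
    stop("configuration error: fewer SNPs (", m, ") than jackknife blocks (",
         n_blocks, ")")
  as.integer(ceiling(seq_len(m) * n_blocks / m))
}

# Weighted regression y ~ a + b x with optional two-step structure:
# the intercept is estimated on `step1` rows (with slope nuisance), then the
# slope on all rows with the intercept fixed. Delete-one-block replicates are
# recovered from per-block sums. Returns intercept, slope and a B x 2
# replicate matrix (intercept, slope).
wls_block_fit <- function(y, x, w, block, step1 = NULL) {
  B <- max(block)
  two_step <- !is.null(step1)
  sums_by_block <- function(idx) {
    bw <- w[idx]; bx <- x[idx]; by <- y[idx]; bb <- factor(block[idx],
                                                          levels = seq_len(B))
    cbind(w = rowsum_safe(bw, bb),
          wx = rowsum_safe(bw * bx, bb),
          wy = rowsum_safe(bw * by, bb),
          wxx = rowsum_safe(bw * bx * bx, bb),
          wxy = rowsum_safe(bw * bx * by, bb))
  }
  solve_ab <- function(S) {
    det <- S[, "w"] * S[, "wxx"] - S[, "wx"]^2
    a <- (S[, "wxx"] * S[, "wy"] - S[, "wx"] * S[, "wxy"]) / det
    b <- (S[, "w"] * S[, "wxy"] - S[, "wx"] * S[, "wy"]) / det
    cbind(a, b)
  }
  if (two_step) {
    S1 <- sums_by_block(which(step1))
    S2 <- sums_by_block(seq_along(y))
    tot1 <- matrix(colSums(S1), 1, dimnames = list(NULL, colnames(S1)))
    tot2 <- matrix(colSums(S2), 1, dimnames = list(NULL, colnames(S2)))
    ab_full <- solve_ab(tot1)
    a_full <- ab_full[1, "a"]
    b_full <- (tot2[, "wxy"] - a_full * tot2[, "wx"]) / tot2[, "wxx"]
    # delete-one-block replicates
    D1 <- sweep(-S1, 2, tot1, "+")
    D2 <- sweep(-S2, 2, tot2, "+")
    a_rep <- solve_ab(D1)[, "a"]
    b_rep <- (D2[, "wxy"] - a_rep * D2[, "wx"]) / D2[, "wxx"]
    list(intercept = unname(a_full), slope = unname(b_full),
         reps = cbind(intercept = a_rep, slope = b_rep))
  } else {
    S2 <- sums_by_block(seq_along(y))
    tot2 <- matrix(colSums(S2), 1, dimnames = list(NULL, colnames(S2)))
    ab_full <- solve_ab(tot2)
    D2 <- sweep(-S2, 2, tot2, "+")
    ab_rep <- solve_ab(D2)
    list(intercept = unname(ab_full[1, "a"]), slope = unname(ab_full[1, "b"]),
         reps = cbind(intercept = ab_rep[, "a"], slope = ab_rep[, "b"]))
  }
}

# Per-level sums including empty levels (a block can contribute no SNPs to
# the intercept step); rowsum() drops absent groups.
rowsum_safe <- function(v, f) {
  out <- numeric(nlevels(f))
  if (length(v) > 0L) {
    rs <- rowsum(v, f)
    out[match(rownames(rs), levels(f))] <- rs[, 1]
  }
  out
}

jackknife_se <- function(reps) {
  B <- nrow(reps)
  ctr <- sweep(reps, 2, colMeans(reps))
  sqrt((B - 1) / B * colSums(ctr^2))
}

jackknife_cov <- function(reps) {
  B <- nrow(reps)
  ctr <- sweep(reps, 2, colMeans(reps))
  (B - 1) / B * crossprod(ctr)
}

# Preliminary univariate pass: expected chi2 per SNP, used only to build
# regression weights for the final fits.
ldsc_prelim <- function(z, n, ell, m_ref, block, two_step_cutoff = 30) {
  chi2 <- z^2
  x <- n * ell / m_ref
  h0 <- min(max((mean(chi2) - 1) / mean(x), 0), 1)
  w <- 1 / (pmax(ell, 1) * pmax(1 + h0 * x, 0.1)^2)
  step1 <- chi2 < two_step_cutoff
  f1 <- if (any(step1)) wls_block_fit(chi2, x, w, block, step1 = step1)
  else wls_block_fit(chi2, x, w, block)
  pmax(f1$intercept + f1$slope * x, 0.1)
}

# One fitting routine for every pair (i, j), including i = j: regression of
# y = z_i * z_j on x = sqrt(N_i N_j) * ell / M with weights
# 1 / (ell * (e_i e_j + E[y]^2)) iterated once, and two-step estimation with
# the intercept taken from SNPs with |y| < cutoff. Using one code path for
# diagonal and off-diagonal elements makes a duplicated trait give rg = 1
# exactly, and keeps the fit exactly antisymmetric under z -> -z.
ldsc_fit_pair <- function(y, x, ell, e12, block, two_step_cutoff = 30) {
  step1 <- abs(y) < two_step_cutoff
  use_two_step <- any(step1)
  fit <- function(w) {
    if (use_two_step) wls_block_fit(y, x, w, block, step1 = step1)
    else wls_block_fit(y, x, w, block)
  }
  cv0 <- mean(y) / mean(x) * x
  f1 <- fit(1 / (pmax(ell, 1) * (e12 + cv0^2)))
  cv <- f1$intercept + f1$slope * x
  f2 <- fit(1 / (pmax(ell, 1) * (e12 + cv^2)))
  if (!use_two_step)
    warning("no statistic below two-step cutoff; one-step fit used")
  f2$one_step <- !use_two_step
  f2
}

#' Univariate LD score regression
#'
#' Estimates observed-scale SNP heritability and the regression intercept
#' from per-SNP chi-squared statistics, under
#' `E[chi2_j] = intercept + N_j * h2 * l_j / M`. The fit is a weighted
#' regression with heteroskedasticity/LD weights `1/(l_j * E[chi2_j]^2)`
#' iterated once, two-step estimation (intercept from SNPs with
#' `chi2 < two_step_cutoff`, slope with the intercept fixed), and
#' delete-one-block jackknife standard errors over contiguous
#' genomically ordered SNP blocks.
#'
#' @param ss a `sumstats` object (GC-uncorrected; see `force`).
#' @param ld LD-score table: data frame `(snp_id, chrom, pos, ldscore)`,
#'   optionally with attribute `m_ref` giving the reference SNP count `M`.
#' @param n_blocks jackknife blocks (default 200, >= 20).
#' @param two_step_cutoff chi-squared cutoff for the intercept step
#'   (default 30).
#' @param pop_prev,sample_prev optional prevalences `K`, `P` for liability
#'   conversion of `h2`.
#' @param m_ref reference panel SNP count `M`; defaults to
#'   `attr(ld, "m_ref")` or `nrow(ld)`.
#' @param force fit even if `ss$gc_applied` is set (GC correction biases
#'   heritability downwards; refused by default).
#' @return Object of class `ldsc_h2`: `h2_obs`, `h2_se`, `intercept`,
#'   `intercept_se`, optional `h2_liab`, `h2_liab_se`, `lambda_gc`
#'   (median-chi2 inflation), `mean_chi2`, `m_snps`, `n_blocks`, and the
#'   jackknife replicate matrix `reps`.
#' @export
ldsc_univariate <- function(ss, ld, n_blocks = 200, two_step_cutoff = 30,
                            pop_prev = NULL, sample_prev = NULL,
                            m_ref = NULL, force = FALSE) {
  if (ss$gc_applied && !force)
    stop("summary statistics are GC-corrected; LDSC requires uncorrected ",
         "input (use force = TRUE to override)")
  if (n_blocks < 20) stop("configuration error: n_blocks must be >= 20")
  d <- merge_sumstats_ld(ss, ld)
  if (nrow(d) < 1000)
    stop("configuration error: fewer than 1,000 SNPs shared with the ",
         "LD-score table")
  m_ref <- m_ref %||% attr(ld, "m_ref") %||% nrow(ld)
  block <- make_blocks(nrow(d), n_blocks)
  e <- ldsc_prelim(d$z, d$n, d$ell, m_ref, block, two_step_cutoff)
  fit <- ldsc_fit_pair(d$z^2, d$n * d$ell / m_ref, d$ell, e^2, block,
                       two_step_cutoff)
  ses <- jackknife_se(fit$reps)
  out <- list(h2_obs = fit$slope, h2_se = unname(ses["slope"]),
              intercept = fit$intercept,
              intercept_se = unname(ses["intercept"]),
              lambda_gc = stats::median(d$z^2) / stats::qchisq(0.5, 1),
              mean_chi2 = mean(d$z^2), m_snps = nrow(d), m_ref = m_ref,
              n_blocks = n_blocks, one_step = fit$one_step,
              reps = fit$reps)
  if (!is.null(pop_prev) && !is.null(sample_prev)) {
    mult <- liability_multiplier(pop_prev, sample_prev)
    out$h2_liab <- fit$slope * mult
    out$h2_liab_se <- out$h2_se * mult
    out$liability_multiplier <- mult
  }
  class(out) <- "ldsc_h2"
  out
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat(sprintf("h2 (observed): %.4f (%.4f)\nintercept: %.4f (%.4f)\n",
              x$h2_obs, x$h2_se, x$intercept, x$intercept_se))
  if (!is.null(x$h2_liab))
    cat(sprintf("h2 (liability): %.4f (%.4f)\n", x$h2_liab, x$h2_liab_se))
  cat(sprintf("lambda_GC: %.4f; mean chi2: %.4f; %d SNPs, %d blocks\n",
              x$lambda_gc, x$mean_chi2, x$m_snps, x$n_blocks))
  invisible(x)
}

#' Bivariate LD score regression
#'
#' Estimates the genetic covariance, cross-trait intercept and genetic
#' correlation of two traits from the regression of `z1*z2` on LD scores:
#' `E[z1 z2] = sqrt(N1 N2) * rho_g * l_j / M + rho * Ns / sqrt(N1 N2)`.
#' A thin wrapper over [multivariable_ldsc()] for `k = 2`.
#'
#' @param ss1,ss2 `sumstats` objects (harmonized internally).
#' @param ld LD-score table.
#' @param n_blocks jackknife blocks.
#' @param ... passed to [multivariable_ldsc()].
#' @return A `genetic_cov_estimate` (see [multivariable_ldsc()]).
#' @export
ldsc_bivariate <- function(ss1, ss2, ld, n_blocks = 200, ...) {
  multivariable_ldsc(list(ss1, ss2), ld, n_blocks = n_blocks, ...)
}

#' Multivariable LD score regression
#'
#' Assembles the k x k genetic covariance matrix `S` (SNP heritabilities on
#' the diagonal, genetic covariances off it), the intercept matrix
#' (univariate intercepts on the diagonal, sample-overlap cross-trait
#' intercepts off it), the genetic correlation matrix with standard errors,
#' and the sampling covariance `V` of the unique elements of `S` from a
#' joint delete-one-block jackknife sharing one block partition across all
#' regressions.
#'
#' @param ss_list list of >= 2 `sumstats` objects.
#' @param ld LD-score table.
#' @param n_blocks jackknife blocks (default 200).
#' @param prevalences optional list of `c(K, P)` per trait; when supplied,
#'   `S` is rescaled to the liability scale (diagonal by the conversion
#'   multiplier, off-diagonal by the geometric mean of multipliers; `rg` is
#'   unchanged).
#' @param two_step_cutoff chi-squared cutoff for univariate intercepts.
#' @param m_ref reference SNP count `M` (default from `ld`).
#' @param force allow GC-corrected input.
#' @return Object of class `genetic_cov_estimate` with fields `traits`, `S`,
#'   `S_obs`, `V` (covariance of `vech(S)`, lower-triangle column-major),
#'   `intercepts`, `rg`, `rg_se`, `rg_out_of_bounds`, `h2_se`, `m_snps`,
#'   `n_blocks`, `reps`.
#' @export
multivariable_ldsc <- function(ss_list, ld, n_blocks = 200,
                               prevalences = NULL, two_step_cutoff = 30,
                               m_ref = NULL, force = FALSE) {
  k <- length(ss_list)
  stopifnot(k >= 2)
  for (ss in ss_list) {
    stopifnot(inherits(ss, "sumstats"))
    if (ss$gc_applied && !force)
      stop("summary statistics are GC-corrected; LDSC requires uncorrected ",
           "input (use force = TRUE to override)")
  }
  # harmonize all traits to the first's allele coding
  for (i in seq(2, k)) {
    h <- harmonize_sumstats(ss_list[[1]], ss_list[[i]])
    ss_list[[i]] <- h$ss2
  }
  ids <- Reduce(intersect, lapply(ss_list, function(s) s$records$snp_id))
  if (length(ids) < 1000)
    stop("configuration error: only ", length(ids),
         " SNPs shared across traits after harmonization")
  merged <- lapply(ss_list, function(s) {
    s$records <- s$records[match(ids, s$records$snp_id), , drop = FALSE]
    merge_sumstats_ld(s, ld)
  })
  if (length(unique(vapply(merged, nrow, 1L))) != 1L)
    stop("inconsistent SNP sets after LD merge: ",
         paste(vapply(merged, nrow, 1L), collapse = ", "))
  m <- nrow(merged[[1]])
  m_ref <- m_ref %||% attr(ld, "m_ref") %||% nrow(ld)
  block <- make_blocks(m, n_blocks)
  ell <- merged[[1]]$ell

  e_prelim <- lapply(merged, function(d)
    ldsc_prelim(d$z, d$n, ell, m_ref, block, two_step_cutoff))

  S <- diag(1, k)
  intercepts <- diag(1, k)
  # vech ordering of unique S elements (lower triangle, column-major)
  pair_idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, "col"], pair_idx[, "row"]), ,
                       drop = FALSE]
  reps <- matrix(NA_real_, n_blocks, nrow(pair_idx))
  cti_se <- matrix(0, k, k)
  uni_se <- numeric(k)
  for (q in seq_len(nrow(pair_idx))) {
    i <- pair_idx[q, "row"]; j <- pair_idx[q, "col"]
    di <- merged[[i]]; dj <- merged[[j]]
    bf <- ldsc_fit_pair(di$z * dj$z, sqrt(di$n * dj$n) * ell / m_ref,
                        ell, e_prelim[[i]] * e_prelim[[j]], block,
                        two_step_cutoff)
    S[i, j] <- S[j, i] <- bf$slope
    intercepts[i, j] <- intercepts[j, i] <- bf$intercept
    reps[, q] <- bf$reps[, "slope"]
    if (i == j) uni_se[i] <- jackknife_se(bf$reps)[["slope"]]
    else cti_se[i, j] <- cti_se[j, i] <- jackknife_se(bf$reps)["intercept"]
  }
  colnames(reps) <- paste0("s", pair_idx[, "row"], pair_idx[, "col"])
  V <- jackknife_cov(reps)
  dimnames(V) <- list(colnames(reps), colnames(reps))

  # rg and its jackknife SE from the replicate matrix
  rg <- matrix(1, k, k); rg_se <- matrix(0, k, k)
  oob <- FALSE
  diag_cols <- match(paste0("s", seq_len(k), seq_len(k)), colnames(reps))
  for (q in seq_len(nrow(pair_idx))) {
    i <- pair_idx[q, "row"]; j <- pair_idx[q, "col"]
    if (i == j) next
    denom <- S[i, i] * S[j, j]
    if (denom <= 0) {
      rg[i, j] <- rg[j, i] <- NA_real_
      rg_se[i, j] <- rg_se[j, i] <- NA_real_
      oob <- TRUE
      next
    }
    rg[i, j] <- rg[j, i] <- S[i, j] / sqrt(denom)
    rg_reps <- reps[, q] / sqrt(pmax(reps[, diag_cols[i]] *
                                       reps[, diag_cols[j]], 1e-12))
    rg_se[i, j] <- rg_se[j, i] <- jackknife_se(cbind(rg_reps))
    if (abs(rg[i, j]) > 1) oob <- TRUE
  }

  traits <- vapply(ss_list, function(s) s$trait_id, "")
  S_obs <- S
  if (!is.null(prevalences)) {
    mult <- vapply(prevalences, function(p)
      liability_multiplier(p[1], p[2]), 1)
    scale_mat <- sqrt(mult) %o% sqrt(mult)
    S <- S * scale_mat
    vech_scale <- scale_mat[cbind(pair_idx[, "row"], pair_idx[, "col"])]
    V <- V * (vech_scale %o% vech_scale)
    reps <- sweep(reps, 2, vech_scale, "*")
  }
  dimnames(S) <- dimnames(S_obs) <- dimnames(intercepts) <-
    dimnames(rg) <- list(traits, traits)
  structure(list(traits = traits, S = S, S_obs = S_obs, V = V,
                 intercepts = intercepts, cti_se = cti_se, rg = rg,
                 rg_se = rg_se, rg_out_of_bounds = oob,
                 h2_se = uni_se,
                 m_snps = m, m_ref = m_ref, n_blocks = n_blocks,
                 snp_ids = merged[[1]]$snp_id, reps = reps),
            class = "genetic_cov_estimate")
}

#' @export
print.genetic_cov_estimate <- function(x, ...) {
  k <- length(x$traits)
  cat("Genetic covariance estimate (", k, " traits, ", x$m_snps,
      " SNPs, ", x$n_blocks, " jackknife blocks)\nS:\n", sep = "")
  print(round(x$S, 4))
  cat("intercepts:\n"); print(round(x$intercepts, 4))
  cat("rg:\n"); print(round(x$rg, 4))
  invisible(x)
}

#' Liability-scale conversion multiplier
#'
#' `K^2 (1-K)^2 / (P (1-P) z^2)` with `z` the standard normal density at the
#' liability threshold `qnorm(1 - K)`; the case-control ascertainment form.
#'
#' @param K population prevalence in (0,1).
#' @param P sample prevalence in (0,1).
#' @return The multiplier taking observed-scale h2 to the liability scale.
#' @examples
#' liability_multiplier(0.5, 0.5)  # pi/2
#' @export
liability_multiplier <- function(K, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop("domain error: prevalences must lie in (0,1)")
  z <- stats::dnorm(stats::qnorm(1 - K))
  K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}

#' Convert observed-scale heritability to the liability scale
#'
#' @param h2_obs observed-scale heritability.
#' @param K population prevalence.
#' @param P sample prevalence.
#' @return Liability-scale heritability.
#' @export
observed_to_liability <- function(h2_obs, K, P) {
  h2_obs * liability_multiplier(K, P)
}

#' Median-chi-squared genomic inflation factor
#'
#' `median(z^2) / qchisq(0.5, 1)`.
#'
#' @param ss a `sumstats` object.
#' @return The inflation factor `lambda_GC`.
#' @export
estimate_lambda_gc <- function(ss) {
  stats::median(ss$records$z^2) / stats::qchisq(0.5, 1)
}
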