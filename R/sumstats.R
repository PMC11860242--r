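VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics object
#'
#' A `sumstats` object bundles one GWAS's per-SNP association records with
#' trait-level metadata. Records are stored as a data frame with columns
#' `snp_id`, `chrom`, `pos`, `a1` (effect allele), `a2` (other allele),
#' `freq_a1`, `beta`, `se`, `z`, `pval`, `n_total`, and optionally `n_cases`,
#' `n_controls`. Internal consistency (`z = beta/se`, `pval` the two-sided
#' normal tail of `z`, valid allele pairs, unique SNP ids) is enforced at
#' construction.
#'
#' @param records data frame of per-SNP records (see Details).
#' @param trait_id character label for the trait.
#' @param gc_applied logical; has genomic control been applied?
#' @param direction_flipped logical; have effect directions been flipped?
#' @param validate logical; run invariant checks (default `TRUE`).
#' @return An object of class `sumstats`.
#' @export
sumstats <- function(records, trait_id = "trait", gc_applied = FALSE,
                     direction_flipped = FALSE, validate = TRUE) {
  stopifnot(is.data.frame(records))
  req <- c("snp_id", "a1", "a2")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!("z" %in% names(records)) && !all(c("beta", "se") %in% names(records)))
    stop("records need z or beta+se")
  records <- complete_effect_columns(records)
  obj <- structure(
    list(trait_id = trait_id, records = records,
         gc_applied = isTRUE(gc_applied),
         direction_flipped = isTRUE(direction_flipped)),
    class = "sumstats")
  if (validate) validate_sumstats(obj)
  obj
}

# Fill z from beta/se, beta/se from z, and pval from z.
complete_effect_columns <- function(rec) {
  if (!("z" %in% names(rec))) rec$z <- rec$beta / rec$se
  if (!("se" %in% names(rec))) {
    # no scale info: report effects on the z scale
    rec$se <- rep(1, nrow(rec))
    rec$beta <- rec$z
  }
  if (!("beta" %in% names(rec))) rec$beta <- rec$z * rec$se
  need_z <- is.na(rec$z) & !is.na(rec$beta) & !is.na(rec$se)
  rec$z[need_z] <- rec$beta[need_z] / rec$se[need_z]
  need_b <- is.na(rec$beta) & !is.na(rec$z)
  rec$beta[need_b] <- rec$z[need_b] * rec$se[need_b]
  rec$pval <- 2 * stats::pnorm(-abs(rec$z))
  rec
}

#' Validate a sumstats object
#'
#' Checks the container invariants: `beta = z * se` to relative tolerance
#' 1e-6, `pval` equal to the two-sided normal tail probability of `z`,
#' alleles in A/C/G/T with `a1 != a2`, no duplicated SNP ids, positive SEs,
#' and `n_cases + n_controls = n_total` where counts are present.
#'
#' @param ss a `sumstats` object.
#' @return `ss`, invisibly; stops on violation.
#' @export
validate_sumstats <- function(ss) {
  stopifnot(inherits(ss, "sumstats"))
  rec <- ss$records
  if (nrow(rec) == 0L) return(invisible(ss))
  if (anyDuplicated(rec$snp_id))
    stop("duplicate snp_id in records")
  if (!all(rec$a1 %in% VALID_ALLELES) || !all(rec$a2 %in% VALID_ALLELES))
    stop("alleles must be in {A,C,G,T}")
  if (any(rec$a1 == rec$a2)) stop("a1 must differ from a2")
  if (any(rec$se <= 0)) stop("standard errors must be > 0")
  ok <- is.finite(rec$beta) & is.finite(rec$z)
  rel <- abs(rec$beta[ok] - rec$z[ok] * rec$se[ok]) /
    pmax(abs(rec$beta[ok]), abs(rec$z[ok] * rec$se[ok]), 1e-300)
  nz <- abs(rec$beta[ok]) > 0 | abs(rec$z[ok]) > 0
  if (any(rel[nz] > 1e-6)) stop("beta and z*se disagree beyond tolerance")
  pexp <- 2 * stats::pnorm(-abs(rec$z))
  prel <- abs(rec$pval - pexp) / pmax(pexp, 1e-300)
  if (any(prel > 1e-6)) stop("pval inconsistent with z")
  if (all(c("n_cases", "n_controls", "n_total") %in% names(rec))) {
    cc <- !is.na(rec$n_cases) & !is.na(rec$n_controls)
    if (any(abs(rec$n_cases[cc] + rec$n_controls[cc] - rec$n_total[cc]) >
              1e-6 * pmax(rec$n_total[cc], 1)))
      stop("n_cases + n_controls != n_total")
  }
  invisible(ss)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats '%s': %d SNPs%s%s\n", x$trait_id, nrow(x$records),
              if (x$gc_applied) " [GC corrected]" else "",
              if (x$direction_flipped) " [direction flipped]" else ""))
  invisible(x)
}

#' Trait metadata for a case-control GWAS
#'
#' Holds sample prevalence `P`, population prevalence `K`, sample counts and
#' the derived effective sample size.
#'
#' @param n_total,n_cases,n_controls sample counts (controls optional; derived
#'   when missing).
#' @param sample_prev sample prevalence `P` in (0,1); derived from counts when
#'   missing.
#' @param pop_prev population prevalence `K` in (0,1), or `NA`.
#' @return A list of class `trait_meta` with fields `P`, `K`, `n_total`,
#'   `n_cases`, `n_controls`, `effective_n`.
#' @export
trait_meta <- function(n_total, n_cases = NA, n_controls = NA,
                       sample_prev = NA, pop_prev = NA) {
  if (is.na(n_controls) && !is.na(n_cases)) n_controls <- n_total - n_cases
  if (is.na(sample_prev) && !is.na(n_cases)) sample_prev <- n_cases / n_total
  if (!is.na(sample_prev) && !is.na(n_cases)) {
    if (abs(sample_prev - n_cases / n_total) > 1e-6)
      stop("sample_prev inconsistent with n_cases/n_total")
  }
  eff <- if (!is.na(n_cases)) effective_sample_size(n_cases, n_total) else n_total
  structure(list(P = sample_prev, K = pop_prev, n_total = n_total,
                 n_cases = n_cases, n_controls = n_controls,
                 effective_n = eff),
            class = "trait_meta")
}

#' Effective sample size of a case-control GWAS
#'
#' The equivalent balanced-design sample size,
#' `4 * n_cases * (1 - n_cases / n_total)`.
#'
#' @param n_cases,n_total case and total counts, `0 < n_cases < n_total`.
#' @return Effective sample size (individuals).
#' @examples
#' effective_sample_size(51800, 1138870)
#' @export
effective_sample_size <- function(n_cases, n_total) {
  if (any(n_cases <= 0) || any(n_cases >= n_total))
    stop("need 0 < n_cases < n_total")
  4 * n_cases * (1 - n_cases / n_total)
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a header-labelled tab-delimited table, renames columns via
#' `column_map`, drops rows failing allele or numeric validity (counting
#' them), and completes missing effect columns (`z` from `beta/se` and vice
#' versa; when only `z` is available, effects are reported on the z scale).
#'
#' @param path path to a tab-delimited file with a header row.
#' @param column_map named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `freq_a1`, `beta`, `se`, `z`,
#'   `pval`, `n_total`, `n_cases`, `n_controls`) to file column names.
#'   Canonical names already present in the file need not be mapped.
#' @param trait_id trait label; defaults to the file name.
#' @param max_drop_frac error if more than this fraction of rows is dropped
#'   (default 0.5).
#' @return A `sumstats` object; the number of dropped rows is available as
#'   `attr(, "n_dropped")` with a breakdown in `attr(, "drop_reasons")`.
#' @export
load_sumstats <- function(path, column_map = NULL, trait_id = NULL,
                          max_drop_frac = 0.5) {
  if (!file.exists(path)) stop("input error: cannot read ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!(src %in% names(tab)))
        stop("schema error: mapped column '", src, "' not in file")
      names(tab)[names(tab) == src] <- canon
    }
  }
  if (!("snp_id" %in% names(tab)) || !all(c("a1", "a2") %in% names(tab)))
    stop("schema error: snp_id, a1, a2 required")
  has_beta <- all(c("beta", "se") %in% names(tab))
  if (!has_beta && !("z" %in% names(tab)))
    stop("schema error: no effect-size column (beta+se or z) resolvable")

  n0 <- nrow(tab)
  tab$a1 <- toupper(as.character(tab$a1))
  tab$a2 <- toupper(as.character(tab$a2))
  reasons <- c(invalid_allele = 0L, bad_numeric = 0L, duplicate_id = 0L)
  bad_allele <- !(tab$a1 %in% VALID_ALLELES) | !(tab$a2 %in% VALID_ALLELES) |
    tab$a1 == tab$a2
  reasons["invalid_allele"] <- sum(bad_allele)
  tab <- tab[!bad_allele, , drop = FALSE]
  numcols <- intersect(c("pos", "freq_a1", "beta", "se", "z", "pval",
                         "n_total", "n_cases", "n_controls"), names(tab))
  for (cc in numcols) tab[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))
  bad_num <- rep(FALSE, nrow(tab))
  if (has_beta) bad_num <- bad_num | !is.finite(tab$beta) |
      !is.finite(tab$se) | tab$se <= 0
  if (!has_beta) bad_num <- bad_num | !is.finite(tab$z)
  if ("freq_a1" %in% names(tab))
    bad_num <- bad_num | (!is.na(tab$freq_a1) &
                            (tab$freq_a1 < 0 | tab$freq_a1 > 1))
  reasons["bad_numeric"] <- sum(bad_num)
  tab <- tab[!bad_num, , drop = FALSE]
  dup <- duplicated(tab$snp_id)
  reasons["duplicate_id"] <- sum(dup)
  tab <- tab[!dup, , drop = FALSE]

  n_dropped <- n0 - nrow(tab)
  if (n0 > 0 && n_dropped / n0 > max_drop_frac) {
    dom <- names(reasons)[which.max(reasons)]
    stop("quality error: ", n_dropped, "/", n0,
         " rows dropped; dominant failure: ", dom)
  }
  ss <- sumstats(tab, trait_id = trait_id %||% basename(path))
  attr(ss, "n_dropped") <- n_dropped
  attr(ss, "drop_reasons") <- reasons
  ss
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write summary statistics to a tab-delimited file
#'
#' Output uses canonical column names and full double precision, so
#' `load_sumstats(write_sumstats(ss))` reproduces `ss` to relative tolerance
#' 1e-9 and repeated writes are byte-identical.
#'
#' @param ss a `sumstats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "sumstats"))
  rec <- ss$records
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("I/O error: cannot write ", path))
  on.exit(close(con))
  num <- vapply(rec, is.numeric, logical(1))
  out <- rec
  for (j in which(num)) out[[j]] <- formatC(rec[[j]], digits = 17,
                                            format = "g")
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flip the effect direction of every record
#'
#' Negates `beta` and `z` (turning, for example, a "can you keep a beat"
#' GWAS into a rhythm-impairment GWAS); `se` and `pval` are unchanged and the
#' `direction_flipped` flag is toggled. Applying the operation twice restores
#' the input.
#'
#' @param ss a `sumstats` object.
#' @return The flipped `sumstats` object.
#' @export
flip_effect_direction <- function(ss) {
  stopifnot(inherits(ss, "sumstats"))
  ss$records$beta <- -ss$records$beta
  ss$records$z <- -ss$records$z
  ss$direction_flipped <- !ss$direction_flipped
  ss
}

#' Apply genomic control to summary statistics
#'
#' Divides z-scores by `sqrt(lambda_gc)` and inflates SEs by the same factor,
#' so beta, se, z and pval stay mutually consistent; the median chi-squared
#' of the output is the input's divided by `lambda_gc`.
#'
#' @param ss a `sumstats` object.
#' @param lambda_gc genomic inflation factor, > 0. Values < 1 trigger a
#'   warning and, when `deflate_ok = FALSE`, are treated as a no-op.
#' @param deflate_ok allow deflation (`lambda_gc < 1`)? Default `FALSE`.
#' @return The corrected `sumstats` with `gc_applied` set.
#' @export
apply_genomic_control <- function(ss, lambda_gc, deflate_ok = FALSE) {
  stopifnot(inherits(ss, "sumstats"))
  if (lambda_gc <= 0) stop("domain error: lambda_gc must be > 0")
  if (lambda_gc < 1) {
    warning("lambda_gc < 1", if (!deflate_ok) "; treated as no-op")
    if (!deflate_ok) lambda_gc <- 1
  }
  s <- sqrt(lambda_gc)
  ss$records$z <- ss$records$z / s
  ss$records$se <- ss$records$se * s
  ss$records$pval <- 2 * stats::pnorm(-abs(ss$records$z))
  ss$gc_applied <- TRUE
  ss
}

#' Harmonize two summary-statistics sets to a shared SNP panel
#'
#' Intersects on `snp_id`, aligns the second trait's effect alleles to the
#' first's (swapping a1/a2 and negating beta/z where the pair is reversed),
#' drops strand-ambiguous (A/T, C/G) SNPs and SNPs whose allele pairs cannot
#' be reconciled.
#'
#' @param ss1,ss2 `sumstats` objects.
#' @param drop_ambiguous drop strand-ambiguous SNPs (default `TRUE`).
#' @return List with harmonized `ss1`, `ss2` (same SNP order) and counts
#'   `n_shared`, `n_flipped`, `n_ambiguous`, `n_mismatch`.
#' @export
harmonize_sumstats <- function(ss1, ss2, drop_ambiguous = TRUE) {
  stopifnot(inherits(ss1, "sumstats"), inherits(ss2, "sumstats"))
  r1 <- ss1$records; r2 <- ss2$records
  shared <- intersect(r1$snp_id, r2$snp_id)
  r1 <- r1[match(shared, r1$snp_id), , drop = FALSE]
  r2 <- r2[match(shared, r2$snp_id), , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- r1$a1 == comp[r1$a2]
  same <- r1$a1 == r2$a1 & r1$a2 == r2$a2
  swapped <- r1$a1 == r2$a2 & r1$a2 == r2$a1
  # allow strand-complement matches for non-ambiguous SNPs
  same_c <- r1$a1 == comp[r2$a1] & r1$a2 == comp[r2$a2]
  swap_c <- r1$a1 == comp[r2$a2] & r1$a2 == comp[r2$a1]
  keep <- (same | swapped | same_c | swap_c)
  n_mismatch <- sum(!keep)
  if (drop_ambiguous) keep <- keep & !ambiguous
  flip <- (swapped | swap_c) & keep
  r2$beta[flip] <- -r2$beta[flip]
  r2$z[flip] <- -r2$z[flip]
  if ("freq_a1" %in% names(r2)) r2$freq_a1[flip] <- 1 - r2$freq_a1[flip]
  r2$a1[keep] <- r1$a1[keep]
  r2$a2[keep] <- r1$a2[keep]
  ss1$records <- r1[keep, , drop = FALSE]
  ss2$records <- r2[keep, , drop = FALSE]
  list(ss1 = ss1, ss2 = ss2, n_shared = sum(keep), n_flipped = sum(flip),
       n_ambiguous = sum(ambiguous), n_mismatch = n_mismatch)
}
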