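# Correlation of association signal between two GWASs via Spearman
# correlation of block-averaged -log10 P over approximately independent LD
# blocks, with a block-bootstrap standard error. Useful when signed effects
# are unavailable (e.g. multivariate test statistics).

#' Read a BED-style LD-block partition
#'
#' Reads 0-based half-open intervals `(chrom, start, end)` from a
#' tab-delimited BED file (no header; a leading `chr` prefix is stripped),
#' checks they are sorted and non-overlapping within chromosome.
#'
#' @param path BED file path.
#' @return Data frame of class `block_partition`: `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_block_partition <- function(path) {
  if (!file.exists(path)) stop("input error: cannot read ", path)
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed$chrom <- as.integer(sub("^chr", "", as.character(bed$chrom)))
  block_partition(bed)
}

#' Construct / validate a block partition
#'
#' @param blocks data frame `(chrom, start, end)`, 0-based half-open.
#' @return The sorted partition with class `block_partition`; errors if
#'   intervals overlap within a chromosome.
#' @export
block_partition <- function(blocks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(blocks)))
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  if (any(blocks$end <= blocks$start)) stop("blocks need start < end")
  for (cc in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == cc, , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping blocks on chromosome ", cc)
  }
  rownames(blocks) <- NULL
  class(blocks) <- c("block_partition", "data.frame")
  blocks
}

#' Partition SNP coverage into approximately equal blocks
#'
#' Convenience generator of a genome partition covering a SNP table: splits
#' each chromosome's span into contiguous intervals so the total block count
#' is about `n_blocks` (the genome-wide LD-block partitions used in practice
#' have ~1,703 blocks).
#'
#' @param snp_table data frame with `chrom`, `pos` (1-based).
#' @param n_blocks target number of blocks (default 1703).
#' @return A `block_partition` (0-based half-open).
#' @export
make_block_partition <- function(snp_table, n_blocks = 1703) {
  chroms <- sort(unique(snp_table$chrom))
  counts <- table(factor(snp_table$chrom, levels = chroms))
  per_chr <- pmax(1L, round(n_blocks * as.numeric(counts) / nrow(snp_table)))
  out <- list()
  for (i in seq_along(chroms)) {
    p <- snp_table$pos[snp_table$chrom == chroms[i]]
    lo <- min(p) - 1L; hi <- max(p)           # 0-based half-open cover
    cuts <- unique(round(seq(lo, hi, length.out = per_chr[i] + 1)))
    if (length(cuts) < 2) cuts <- c(lo, hi)
    out[[i]] <- data.frame(chrom = chroms[i], start = cuts[-length(cuts)],
                           end = cuts[-1])
  }
  block_partition(do.call(rbind, out))
}

#' Filter SNPs by whitelist and interval mask
#'
#' Keeps SNPs whose id is in `whitelist` (e.g. a HapMap3-style reference
#' panel) and whose position falls outside every masked interval (e.g. the
#' MHC region). Mask intervals are 0-based half-open.
#'
#' @param ss a `sumstats` object.
#' @param whitelist character vector of SNP ids, or `NULL` for no id filter.
#' @param mask data frame `(chrom, start, end)` of intervals to exclude, or
#'   `NULL`.
#' @return Filtered `sumstats`; error when nothing survives.
#' @export
filter_snps <- function(ss, whitelist = NULL, mask = NULL) {
  stopifnot(inherits(ss, "sumstats"))
  rec <- ss$records
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(whitelist)) {
    if (length(whitelist) == 0L) stop("whitelist must be non-empty")
    keep <- keep & rec$snp_id %in% whitelist
  }
  if (!is.null(mask) && nrow(mask) > 0L) {
    for (i in seq_len(nrow(mask))) {
      inmask <- rec$chrom == mask$chrom[i] &
        (rec$pos - 1) >= mask$start[i] & (rec$pos - 1) < mask$end[i]
      keep <- keep & !inmask
    }
  }
  if (!any(keep)) stop("no SNPs survive whitelist/mask filtering")
  ss$records <- rec[keep, , drop = FALSE]
  ss
}

#' Per-block mean -log10 P
#'
#' Assigns each SNP to at most one block by half-open containment
#' (1-based SNP position `pos` is inside a 0-based half-open block
#' `[start, end)` when `start <= pos - 1 < end`) and averages `-log10(P)`
#' within each block. Blocks containing no SNP are dropped and reported via
#' `attr(, "n_empty")`.
#'
#' @param ss a `sumstats` object with positions.
#' @param blocks a `block_partition`.
#' @return Data frame `block` (row index into `blocks`), `chrom`, `start`,
#'   `end`, `n_snps`, `mean_neglogp`.
#' @export
block_average_neglogp <- function(ss, blocks) {
  stopifnot(inherits(ss, "sumstats"))
  rec <- ss$records
  nlp <- -log10(pmax(rec$pval, 1e-300))
  bsum <- numeric(nrow(blocks)); bn <- integer(nrow(blocks))
  for (cc in unique(blocks$chrom)) {
    bidx <- which(blocks$chrom == cc)
    sidx <- which(rec$chrom == cc)
    if (length(sidx) == 0L) next
    b <- blocks[bidx, , drop = FALSE]
    # findInterval over block starts; verify containment against end
    p0 <- rec$pos[sidx] - 1
    j <- findInterval(p0, b$start)
    ok <- j >= 1 & p0 < b$end[pmax(j, 1)]
    jj <- bidx[j[ok]]
    bsum_c <- rowsum(nlp[sidx][ok], jj)
    bn_c <- rowsum(rep(1L, sum(ok)), jj)
    rows <- as.integer(rownames(bsum_c))
    bsum[rows] <- bsum[rows] + bsum_c[, 1]
    bn[rows] <- bn[rows] + bn_c[, 1]
  }
  used <- bn > 0
  out <- data.frame(block = which(used), chrom = blocks$chrom[used],
                    start = blocks$start[used], end = blocks$end[used],
                    n_snps = bn[used],
                    mean_neglogp = bsum[used] / bn[used])
  attr(out, "n_empty") <- sum(!used)
  out
}

#' Blockwise Spearman correlation with block-bootstrap SE
#'
#' Rank-based Spearman correlation between two traits' per-block mean
#' `-log10(P)` values over their shared blocks, with a standard error from
#' resampling blocks with replacement (ties get average ranks; resamples
#' with zero rank variance are dropped).
#'
#' @param map1,map2 outputs of [block_average_neglogp()].
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed for the bootstrap.
#' @return List of class `block_corr_result`: `rho`, `se_boot`, `n_blocks`,
#'   `n_bootstrap`.
#' @export
blockwise_spearman <- function(map1, map2, n_boot = 10000, seed = 1L) {
  shared <- intersect(map1$block, map2$block)
  if (length(shared) < 10)
    stop("fewer than 10 shared non-empty blocks")
  x <- map1$mean_neglogp[match(shared, map1$block)]
  y <- map2$mean_neglogp[match(shared, map2$block)]
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  nb <- length(shared)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nb, nb, replace = TRUE)
    reps[b] <- suppressWarnings(stats::cor(x[idx], y[idx],
                                           method = "spearman"))
  }
  reps <- reps[is.finite(reps)]
  structure(list(rho = rho, se_boot = stats::sd(reps), n_blocks = nb,
                 n_bootstrap = n_boot),
            class = "block_corr_result")
}

#' @export
print.block_corr_result <- function(x, ...) {
  cat(sprintf("blockwise Spearman rho = %.4f (bootstrap SE %.4f), %d blocks, %d resamples\n",
              x$rho, x$se_boot, x$n_blocks, x$n_bootstrap))
  invisible(x)
}
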