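#' IBS sharing counts for a sample pair
#'
#' Counts SNPs at which two samples share 0, 1 or 2 alleles identical by
#' state, from alt-allele dosage vectors (0/1/2, `NA` missing). SNPs with
#' a missing genotype in either sample are excluded.
#'
#' @param g1,g2 integer dosage vectors of equal length.
#' @return Named integer vector `c(ibs0, ibs1, ibs2)`; the sum is the
#'   number of SNPs used.
#' @export
ibs_counts <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  use <- !is.na(g1) & !is.na(g2)
  if (!any(use)) stop("no SNP with both genotypes non-missing")
  a <- g1[use]; b <- g2[use]
  # IBS2: same dosage; IBS0: opposite homozygotes; IBS1: the rest
  ibs2 <- sum(a == b)
  ibs0 <- sum(abs(a - b) == 2)
  c(ibs0 = ibs0, ibs1 = sum(use) - ibs0 - ibs2, ibs2 = ibs2)
}

# Per-SNP IBS-class probabilities conditional on sharing 0 or 1 allele
# IBD, under HWE at alt frequency p (conditional on 2 IBD, IBS is always
# 2). Rows: ibs0, ibs1, ibs2.
ibs_given_ibd <- function(p) {
  q <- 1 - p
  list(ibd0 = rbind(ibs0 = 2 * p^2 * q^2,
                    ibs1 = 4 * p^3 * q + 4 * p * q^3,
                    ibs2 = p^4 + q^4 + 4 * p^2 * q^2),
       ibd1 = rbind(ibs0 = 0 * p,
                    ibs1 = 2 * p^2 * q + 2 * p * q^2,
                    ibs2 = p^3 + q^3 + p^2 * q + p * q^2))
}

#' Method-of-moments pairwise IBD estimate (PLINK-style PI_HAT)
#'
#' Estimates the probabilities `(Z0, Z1, Z2)` that a pair of samples
#' shares 0, 1 or 2 alleles identical by descent, and the summary
#' `PI_HAT = Z1/2 + Z2`, from biallelic SNP dosages and known alt-allele
#' frequencies. The moment equations are solved sequentially: `Z0` from
#' the observed IBS0 count (IBS0 is impossible given any IBD sharing at a
#' locus), `Z1` from the IBS1 count after removing the `Z0` contribution,
#' `Z2` as the remainder; estimates are clamped to `[0, 1]` and
#' renormalized. SNPs with panel MAF below `min_maf` are excluded before
#' estimation (moment estimators are unstable at rare alleles).
#'
#' @param g1,g2 integer alt-dosage vectors (0/1/2, `NA` missing).
#' @param freq alt-allele frequencies of the panel SNPs, in (0, 1).
#' @param min_maf minimum minor-allele frequency for a SNP to be used.
#' @return An object of class `ibd_estimate`: list with `z0`, `z1`, `z2`,
#'   `pi_hat`, `n_snps_used`.
#' @export
estimate_ibd <- function(g1, g2, freq, min_maf = 0.05) {
  stopifnot(length(g1) == length(freq), length(g2) == length(freq))
  maf <- pmin(freq, 1 - freq)
  keep <- !is.na(freq) & maf >= min_maf & freq > 0 & freq < 1
  if (!any(keep))
    stop("no usable SNP after MAF pruning (degenerate panel)")
  g1 <- g1[keep]; g2 <- g2[keep]; p <- freq[keep]
  use <- !is.na(g1) & !is.na(g2)
  if (!any(use)) stop("no SNP with both genotypes non-missing")
  g1 <- g1[use]; g2 <- g2[use]; p <- p[use]
  obs <- ibs_counts(g1, g2)
  cond <- ibs_given_ibd(p)
  e0 <- rowSums(cond$ibd0)          # expected IBS counts if fully IBD0
  e1 <- rowSums(cond$ibd1)          # expected IBS counts if fully IBD1
  n <- length(p)
  z0 <- obs[["ibs0"]] / e0[["ibs0"]]
  z1 <- (obs[["ibs1"]] - z0 * e0[["ibs1"]]) / e1[["ibs1"]]
  z2 <- (obs[["ibs2"]] - z0 * e0[["ibs2"]] - z1 * e1[["ibs2"]]) / n
  z <- pmax(c(z0, z1, z2), 0)
  z <- pmin(z, 1)
  z <- z / sum(z)
  structure(list(z0 = z[1], z1 = z[2], z2 = z[3],
                 pi_hat = z[2] / 2 + z[3], n_snps_used = n),
            class = "ibd_estimate")
}

#' @export
print.ibd_estimate <- function(x, ...) {
  cat(sprintf("IBD estimate (%d SNPs): Z0=%.4f Z1=%.4f Z2=%.4f PI_HAT=%.4f\n",
              x$n_snps_used, x$z0, x$z1, x$z2, x$pi_hat))
  invisible(x)
}

#' Pairwise IBD estimates from a variant set
#'
#' Convenience wrapper for QC on a multi-sample VCF: alt-allele
#' frequencies are estimated from the sample dosages themselves (a crude
#' estimate in small pedigrees — prefer a reference panel when one is
#' available), then [estimate_ibd()] is run for each requested pair.
#'
#' @param x a [variant_set()].
#' @param pairs data frame (or 2-column matrix) of sample-id pairs.
#' @param min_maf minimum panel MAF, as in [estimate_ibd()].
#' @return Data frame: `sample1`, `sample2`, `Z0`, `Z1`, `Z2`, `PI_HAT`,
#'   `NSNP`.
#' @export
estimate_ibd_pairs <- function(x, pairs, min_maf = 0.05) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(pairs) >= 2)
  bad <- setdiff(unique(c(pairs[[1]], pairs[[2]])), x$samples)
  if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  freq <- rowMeans(x$geno, na.rm = TRUE) / 2
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    est <- estimate_ibd(x$geno[, pairs[[1]][i]], x$geno[, pairs[[2]][i]],
                        freq, min_maf = min_maf)
    data.frame(sample1 = pairs[[1]][i], sample2 = pairs[[2]][i],
               Z0 = est$z0, Z1 = est$z1, Z2 = est$z2,
               PI_HAT = est$pi_hat, NSNP = est$n_snps_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
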