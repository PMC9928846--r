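#' Allele frequency from genotype counts
#'
#' Frequency of allele A2 given counts of the three genotype classes
#' (A1A1 homozygotes, heterozygotes, A2A2 homozygotes) among non-missing
#' calls.
#'
#' @param counts integer vector `c(n_hom_a1, n_het, n_hom_a2)`.
#' @return Frequency of A2 in `[0, 1]`.
#' @export
allele_frequency <- function(counts) {
  counts <- check_geno_counts(counts)
  total <- sum(counts)
  if (total == 0) stop("allele frequency undefined: all calls missing")
  (counts[2] + 2 * counts[3]) / (2 * total)
}

check_geno_counts <- function(counts) {
  if (length(counts) != 3 || any(is.na(counts)))
    stop("counts must be c(n_hom_a1, n_het, n_hom_a2)")
  if (any(counts < 0)) stop("negative genotype counts")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  as.numeric(counts)
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test conditional on the observed allele counts: over all
#' heterozygote counts compatible with the allele counts, the p-value sums
#' the probabilities of configurations whose probability does not exceed
#' that of the observed one (the standard exact test, not mid-p). The
#' per-configuration probabilities are evaluated by a ratio recurrence from
#' the observed heterozygote count, which is numerically exact for the
#' sample sizes involved in SNP QC.
#'
#' @param counts integer vector `c(n_hom_a1, n_het, n_hom_a2)`.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(counts) {
  counts <- check_geno_counts(counts)
  n <- sum(counts)
  if (n < 1) stop("HWE test needs at least one genotype")
  nA <- 2 * counts[1] + counts[2]
  nB <- counts[2] + 2 * counts[3]
  rare <- min(nA, nB)
  # heterozygote counts share the parity of the rare allele count
  hs <- seq(rare %% 2, rare, by = 2)
  if (length(hs) == 1) return(1)
  # log P(h+2) - log P(h) = log[ (nA-h)(nB-h) / ((h+2)(h+1)) ]
  h <- hs[-length(hs)]
  step <- log((nA - h) * (nB - h)) - log((h + 2) * (h + 1))
  logp <- c(0, cumsum(step))          # relative log-probabilities over hs
  logp <- logp - max(logp)
  prob <- exp(logp); prob <- prob / sum(prob)
  obs <- prob[match(counts[2], hs)]
  p <- sum(prob[prob <= obs * (1 + 1e-9)])
  min(p, 1)
}

#' Per-SNP summary statistics
#'
#' Computes, for every SNP, the genotype class counts, A2 allele frequency,
#' call rate and Hardy-Weinberg exact-test p-value on non-missing calls.
#'
#' @param geno a [genotypes()] object.
#' @return data.frame with one row per SNP: `snp_id`, `n_hom_a1`, `n_het`,
#'   `n_hom_a2`, `allele_freq_a2`, `maf`, `call_rate`, `hwe_p`.
#' @export
snp_stats <- function(geno) {
  validate_genotypes(geno)
  d <- geno$dosage
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  tot <- n0 + n1 + n2
  freq <- ifelse(tot > 0, (n1 + 2 * n2) / (2 * tot), NA_real_)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    if (tot[j] == 0) return(NA_real_)
    hwe_exact_test(c(n0[j], n1[j], n2[j]))
  }, numeric(1))
  data.frame(snp_id = geno$map$snp_id,
             n_hom_a1 = n0, n_het = n1, n_hom_a2 = n2,
             allele_freq_a2 = freq,
             maf = pmin(freq, 1 - freq),
             call_rate = tot / nrow(d),
             hwe_p = hwe,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply SNP and individual quality-control filters
#'
#' Mirrors conventional PLINK-style pre-processing: individuals with a
#' missing-genotype fraction above `ind_missing_max` are removed first;
#' per-SNP statistics are then recomputed and SNPs failing call rate, then
#' minor allele frequency, then the Hardy-Weinberg exact test are removed.
#' Because removing SNPs changes individual missingness (and vice versa),
#' the two stages are repeated until nothing more is removed, which makes
#' the filter idempotent: running it again on its own output changes
#' nothing. All comparisons are strict (a SNP with MAF exactly `maf_min`
#' is kept). Each removed item carries one primary reason tag: `mind`
#' (individual missingness), `geno` (SNP call rate), `maf`, or `hwe`.
#'
#' @param geno a [genotypes()] object.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_p_min minimum HWE exact p-value (default 1e-3).
#' @param snp_call_rate_min minimum SNP call rate (default 0.90).
#' @param ind_missing_max maximum individual missing fraction (default
#'   0.10).
#' @return A list with elements `genotypes` (the filtered [genotypes()]
#'   object) and `report` (class `"qc_report"`: in/out counts plus
#'   per-item removal tables).
#' @export
apply_qc <- function(geno, maf_min = 0.05, hwe_p_min = 1e-3,
                     snp_call_rate_min = 0.90, ind_missing_max = 0.10) {
  validate_genotypes(geno)
  n_in <- length(geno$fid); m_in <- nrow(geno$map)
  if (n_in == 0 || m_in == 0) stop("empty genotype matrix")

  keep_ind <- rep(TRUE, n_in)
  keep_snp <- rep(TRUE, m_in)
  reason_snp <- rep(NA_character_, m_in)
  repeat {
    changed <- FALSE
    miss_frac <- rowMeans(is.na(
      geno$dosage[, keep_snp, drop = FALSE]))
    drop_ind <- keep_ind & miss_frac > ind_missing_max
    if (any(drop_ind)) {
      keep_ind[drop_ind] <- FALSE
      changed <- TRUE
    }
    if (!any(keep_ind)) stop("QC removed every individual")

    cur <- which(keep_snp)
    st <- snp_stats(subset_genotypes(geno, i = which(keep_ind), j = cur))
    reason <- rep(NA_character_, length(cur))
    reason[st$call_rate < snp_call_rate_min] <- "geno"
    todo <- is.na(reason)
    reason[todo & (is.na(st$maf) | st$maf < maf_min)] <- "maf"
    todo <- is.na(reason)
    reason[todo & st$hwe_p < hwe_p_min] <- "hwe"
    if (any(!is.na(reason))) {
      bad <- cur[!is.na(reason)]
      keep_snp[bad] <- FALSE
      reason_snp[bad] <- reason[!is.na(reason)]
      changed <- TRUE
    }
    if (!any(keep_snp)) stop("QC removed every SNP")
    if (!changed) break
  }
  removed_ind <- data.frame(FID = geno$fid[!keep_ind],
                            IID = geno$iid[!keep_ind],
                            reason = rep("mind", sum(!keep_ind)),
                            stringsAsFactors = FALSE)
  removed_snp <- data.frame(snp_id = geno$map$snp_id[!keep_snp],
                            reason = reason_snp[!keep_snp],
                            stringsAsFactors = FALSE)
  out <- subset_genotypes(geno, i = which(keep_ind), j = which(keep_snp))

  report <- structure(list(
    n_snps_in = m_in, n_snps_out = sum(keep_snp),
    n_individuals_in = n_in, n_individuals_out = sum(keep_ind),
    removed_snps = removed_snp, removed_individuals = removed_ind,
    thresholds = c(maf_min = maf_min, hwe_p_min = hwe_p_min,
                   snp_call_rate_min = snp_call_rate_min,
                   ind_missing_max = ind_missing_max)),
    class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  individuals: %d -> %d (%d removed, mind)\n",
              x$n_individuals_in, x$n_individuals_out,
              nrow(x$removed_individuals)))
  tab <- table(factor(x$removed_snps$reason,
                      levels = c("geno", "maf", "hwe")))
  cat(sprintf("  SNPs: %d -> %d (geno %d, maf %d, hwe %d)\n",
              x$n_snps_in, x$n_snps_out, tab["geno"], tab["maf"],
              tab["hwe"]))
  invisible(x)
}
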