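#' @title Polygenic risk score from a published SNP panel
#' @description Hardy-Weinberg testing, quality-control filtering of GWAS
#'   candidate SNPs (minor-allele-frequency agreement with the reference
#'   population, linkage-disequilibrium pruning, imputation quality,
#'   Hardy-Weinberg equilibrium), weighted allelic scoring, and use of the
#'   resulting score as an adjustment covariate.
#' @name genetics-prs
NULL

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square of observed genotype counts against the
#' Hardy-Weinberg expectations p^2, 2pq, q^2 computed from the sample allele
#' frequency. Monomorphic samples (no minor allele or no major allele) are
#' trivially in equilibrium and return p = 1.
#'
#' @param aa,ab,bb genotype counts (major homozygote, heterozygote, minor
#'   homozygote).
#' @return List with `chisq`, `p`, `maf`.
#' @export
hwe_test <- function(aa, ab, bb) {
  n <- aa + ab + bb
  if (n <= 0) stop("all-zero genotype counts")
  if (any(c(aa, ab, bb) < 0)) stop("genotype counts must be >= 0")
  p <- (2 * aa + ab) / (2 * n)
  q <- 1 - p
  if (p <= 0 || q <= 0)
    return(list(chisq = 0, p = 1, maf = min(p, q)))
  expected <- n * c(p^2, 2 * p * q, q^2)
  chisq <- sum((c(aa, ab, bb) - expected)^2 / expected)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       maf = min(p, q))
}

#' Load the packaged SNP panel
#'
#' Transcription of the published table of GWAS-selected SNPs for the smoking
#' (cigarettes per day) and alcohol-consumption phenotypes, with signed
#' per-allele effect sizes, discovery p-values, allele codes, gene labels and
#' chromosomes as printed (including a missing chromosome entry and one indel
#' effect allele, both kept verbatim).
#'
#' @param candidates if TRUE, load the 25-row candidate fixture instead: the
#'   16 published SNPs plus 9 synthetic rejected candidates (marked
#'   `synthetic = TRUE`) carrying QC statistics, for exercising [qc_filter()].
#' @return data.frame of SNP records.
#' @export
load_snp_panel <- function(candidates = FALSE) {
  fname <- if (candidates) "snp_candidates_synthetic.tsv" else "snp_panel.tsv"
  path <- system.file("extdata", fname, package = "brainrisk", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Quality-control filtering of candidate SNPs
#'
#' Retains candidates passing all four conditions: absolute minor-allele
#' frequency difference between cohort and reference population at most
#' `maf_diff_max`; imputation info score at least `info_min`; Hardy-Weinberg
#' p-value above `hwe_min`; and no strong linkage disequilibrium (r^2 >=
#' `ld_max`) with another retained SNP of the same trait. LD pruning keeps,
#' within a correlated pair, the SNP with the smaller discovery p-value
#' (`p_overall`). SNPs with a missing statistic are excluded with reason
#' `"missing_stat"`.
#'
#' @param candidates data.frame with columns `trait`, `rsid`, `effect_size`,
#'   `p_overall`, `maf_ref`, `maf_cohort`, `info`, `hwe_p`, and optionally
#'   `ld_partner` / `ld_r2` (strongest within-trait LD).
#' @param maf_diff_max maximum MAF difference (default 0.03).
#' @param ld_max LD r^2 pruning threshold (default 0.8).
#' @param hwe_min minimum Hardy-Weinberg p (default 0.05).
#' @param info_min minimum imputation info score (default 0.9).
#' @return The retained rows, with attribute `excluded`: data.frame of
#'   `rsid`, `trait`, `reason`.
#' @export
qc_filter <- function(candidates, maf_diff_max = 0.03, ld_max = 0.8,
                      hwe_min = 0.05, info_min = 0.9) {
  need <- c("trait", "rsid", "p_overall", "maf_ref", "maf_cohort", "info", "hwe_p")
  if (!all(need %in% names(candidates)))
    stop("candidates must contain: ", paste(need, collapse = ", "))
  cand <- as.data.frame(candidates)
  reason <- rep(NA_character_, nrow(cand))
  stats_na <- !stats::complete.cases(cand[c("maf_ref", "maf_cohort", "info", "hwe_p")])
  reason[stats_na] <- "missing_stat"
  maf_bad <- !stats_na & abs(cand$maf_cohort - cand$maf_ref) > maf_diff_max
  reason[maf_bad] <- "maf_diff"
  info_bad <- is.na(reason) & cand$info < info_min
  reason[info_bad] <- "low_info"
  hwe_bad <- is.na(reason) & cand$hwe_p <= hwe_min
  reason[hwe_bad] <- "hwe"

  # LD pruning among survivors, per trait; keep the smaller discovery p
  if (all(c("ld_partner", "ld_r2") %in% names(cand))) {
    partner_row <- vapply(seq_len(nrow(cand)), function(i) {
      if (is.na(cand$ld_partner[i]) || cand$ld_partner[i] == "") return(NA_integer_)
      j <- which(cand$rsid == cand$ld_partner[i] & cand$trait == cand$trait[i])
      if (length(j)) j[[1L]] else NA_integer_
    }, integer(1))
    repeat {
      alive <- is.na(reason)
      offenders <- which(alive & !is.na(cand$ld_r2) & cand$ld_r2 >= ld_max &
                           !is.na(partner_row) & alive[pmax(partner_row, 1L)])
      if (!length(offenders)) break
      i <- offenders[[1L]]
      j <- partner_row[i]
      drop <- if (cand$p_overall[i] > cand$p_overall[j]) i else j
      reason[drop] <- "ld"
    }
  }
  keep <- is.na(reason)
  out <- cand[keep, , drop = FALSE]
  attr(out, "excluded") <- data.frame(rsid = cand$rsid[!keep],
                                      trait = cand$trait[!keep],
                                      reason = reason[!keep])
  out
}

#' Weighted allelic polygenic risk score
#'
#' For each trait set, a participant's set mean is the sum of effect-allele
#' dosages multiplied by the published per-allele effect sizes, divided by the
#' participant's number of non-missing SNPs in that set. The combined score is
#' the sum of the per-trait set means. Scaling all effect sizes by a constant
#' scales every score by the same constant.
#'
#' @param dosages numeric matrix, participants x SNPs (values in \[0, 2\],
#'   NA for missing), with rsids as column names.
#' @param panel SNP panel data.frame with `rsid`, `trait`, `effect_size`.
#' @return data.frame with one row per participant: per-trait set means and
#'   `prs` (their sum, NA and flagged when a set has no non-missing SNP).
#' @export
weighted_score <- function(dosages, panel) {
  D <- as.matrix(dosages)
  if (is.null(colnames(D))) stop("'dosages' needs rsid column names")
  missing_snps <- setdiff(panel$rsid, colnames(D))
  if (length(missing_snps))
    stop("dosage columns missing for: ", paste(missing_snps, collapse = ", "))
  if (any(D < 0 | D > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  traits <- unique(panel$trait)
  out <- data.frame(row.names = seq_len(nrow(D)))
  for (tr in traits) {
    snps <- panel$rsid[panel$trait == tr]
    eff <- panel$effect_size[panel$trait == tr]
    Dt <- D[, snps, drop = FALSE]
    weighted <- sweep(Dt, 2L, eff, `*`)
    m <- rowSums(!is.na(Dt))
    s <- rowSums(weighted, na.rm = TRUE)
    out[[paste0("set_mean_", tolower(tr))]] <- ifelse(m > 0, s / m, NA_real_)
  }
  out$prs <- rowSums(as.matrix(out))
  out$all_missing <- !stats::complete.cases(out)
  out
}

#' Append the PRS as a covariate to an analysis design
#'
#' Participants without a defined PRS are dropped listwise (as when genotype
#' data are available only for a subsample) and the number removed is recorded.
#'
#' @param design data.frame of covariates (rows = participants).
#' @param prs numeric PRS per participant (NA where undefined), aligned with
#'   `design` rows.
#' @return The design with a `prs` column, restricted to rows with a defined
#'   PRS; attribute `n_dropped` records the removals.
#' @export
adjust_for_prs <- function(design, prs) {
  design <- as.data.frame(design)
  if (length(prs) != nrow(design)) stop("'prs' must align with design rows")
  keep <- !is.na(prs)
  out <- design[keep, , drop = FALSE]
  out$prs <- prs[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
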