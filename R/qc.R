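#' Quality-control parameters
#'
#' Defaults follow common SNP-panel preprocessing for livestock genotypes:
#' SNP call rate >= 90\%, minor allele frequency >= 5\%, absolute deviation of
#' the observed heterozygote frequency from its Hardy--Weinberg expectation
#' 2p(1-p) at most 15\%, animal call rate >= 90\% (flagged, not removed), and
#' phenotype outliers beyond 3 SD discarded. All boundary comparisons are
#' strict: exactly meeting a threshold passes.
#'
#' @param min_snp_call_rate,min_maf,max_het_deviation,min_animal_call_rate
#'   fractions in (0, 1].
#' @param phenotype_sd_clip positive number of standard deviations.
#' @return list of class \code{qc_params}.
#' @export
qc_params <- function(min_snp_call_rate = 0.90, min_maf = 0.05,
                      max_het_deviation = 0.15, min_animal_call_rate = 0.90,
                      phenotype_sd_clip = 3.0) {
  stopifnot(min_snp_call_rate > 0, min_snp_call_rate <= 1,
            min_maf > 0, min_maf <= 1,
            max_het_deviation > 0, max_het_deviation <= 1,
            min_animal_call_rate > 0, min_animal_call_rate <= 1,
            phenotype_sd_clip > 0)
  structure(list(min_snp_call_rate = min_snp_call_rate, min_maf = min_maf,
                 max_het_deviation = max_het_deviation,
                 min_animal_call_rate = min_animal_call_rate,
                 phenotype_sd_clip = phenotype_sd_clip),
            class = "qc_params")
}

#' Filter SNPs on call rate, MAF and Hardy--Weinberg heterozygote deviation
#'
#' Filters are applied in a fixed order -- call rate, then MAF, then HWE --
#' with allele frequencies computed on the SNPs surviving the previous step
#' (non-missing calls only), so the per-criterion counts in the report are
#' reproducible. The HWE criterion removes SNPs whose observed heterozygote
#' frequency differs from 2p(1-p) by more than \code{max_het_deviation}.
#'
#' @param gm a [genotype_matrix()].
#' @param map the matching [snp_map()].
#' @param qc a [qc_params()].
#' @return list with filtered \code{genotypes}, \code{map} and a
#'   \code{report} (counts removed per criterion; serializable with
#'   [write_qc_report()]).
#' @export
filter_snps <- function(gm, map, qc = qc_params()) {
  calls <- gm$calls
  if (ncol(calls) == 0L) stop("empty genotype matrix")
  stopifnot(ncol(calls) == nrow(map))
  n <- nrow(calls)
  n_in <- ncol(calls)

  call_rate <- colMeans(!is.na(calls))
  drop_cr <- call_rate < qc$min_snp_call_rate
  keep <- !drop_cr

  p_alt <- colSums(calls[, keep, drop = FALSE], na.rm = TRUE) /
    (2 * colSums(!is.na(calls[, keep, drop = FALSE])))
  maf <- pmin(p_alt, 1 - p_alt)
  drop_maf_sub <- maf < qc$min_maf
  keep2 <- keep
  keep2[keep][drop_maf_sub] <- FALSE

  sub <- calls[, keep2, drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  p <- colSums(sub, na.rm = TRUE) / (2 * n_obs)
  het_obs <- colSums(sub == 1L, na.rm = TRUE) / n_obs
  het_exp <- 2 * p * (1 - p)
  drop_hwe_sub <- abs(het_obs - het_exp) > qc$max_het_deviation
  keep3 <- keep2
  keep3[keep2][drop_hwe_sub] <- FALSE

  if (!any(keep3)) stop("all SNPs removed by quality control")
  report <- list(
    n_snps_in = n_in,
    removed_call_rate = sum(drop_cr),
    removed_maf = sum(drop_maf_sub),
    removed_hwe = sum(drop_hwe_sub),
    n_snps_out = sum(keep3))
  map_out <- map[keep3, , drop = FALSE]
  rownames(map_out) <- NULL
  class(map_out) <- class(map)
  list(genotypes = genotype_matrix(calls[, keep3, drop = FALSE],
                                   gm$animal_ids, map_out),
       map = map_out, report = report)
}

#' Filter phenotypes and flag low-call-rate animals
#'
#' Zero phenotypes are treated as missing and removed. Remaining raw values
#' outside mean +/- \code{phenotype_sd_clip} SD (mean and SD computed on the
#' nonzero raw values) are removed; values exactly on the boundary are kept.
#' Animals whose genotype call rate falls below \code{min_animal_call_rate}
#' are reported in the QC report but kept, the convention being that low
#' animal call rates warrant investigation rather than silent removal.
#' Phenotyped animals without a genotype record are reported and dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param phenos phenotype data.frame (see [read_phenotypes()]).
#' @param qc a [qc_params()].
#' @return list with \code{genotypes} (unchanged), filtered \code{phenos} and
#'   a \code{report}.
#' @export
filter_animals_and_phenotypes <- function(gm, phenos, qc = qc_params()) {
  not_genotyped <- setdiff(phenos$animal, gm$animal_ids)
  phenos2 <- phenos[phenos$animal %in% gm$animal_ids, , drop = FALSE]
  zero <- phenos2$adg_raw == 0
  phenos2 <- phenos2[!zero, , drop = FALSE]
  m <- mean(phenos2$adg_raw)
  s <- stats::sd(phenos2$adg_raw)
  out_lo <- m - qc$phenotype_sd_clip * s
  out_hi <- m + qc$phenotype_sd_clip * s
  outlier <- phenos2$adg_raw < out_lo | phenos2$adg_raw > out_hi
  phenos3 <- phenos2[!outlier, , drop = FALSE]
  if (nrow(phenos3) < 2) stop("fewer than 2 phenotypes remain after filtering")
  rownames(phenos3) <- NULL
  cr <- rowMeans(!is.na(gm$calls))
  flagged <- gm$animal_ids[cr < qc$min_animal_call_rate]
  report <- list(
    n_phenotypes_in = nrow(phenos),
    dropped_not_genotyped = length(not_genotyped),
    not_genotyped_ids = not_genotyped,
    removed_zero = sum(zero),
    removed_outlier = sum(outlier),
    n_phenotypes_out = nrow(phenos3),
    flagged_low_call_rate_animals = flagged)
  list(genotypes = gm, phenos = phenos3, report = report)
}

#' Write a QC report as JSON
#' @param report a report list from [filter_snps()] or
#'   [filter_animals_and_phenotypes()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
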