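#' Quality-control thresholds
#'
#' Bundles the pre-association QC thresholds: variant call rate (< 0.9
#' removed), sample call rate (< 0.75 removed), per-sample heterozygosity
#' (> `het_sd` SD from the mean, two-sided), relatedness (PI_HAT > 0.2),
#' Hardy-Weinberg equilibrium (P < 1e-6), imputation quality (INFO r2 <
#' 0.7) and principal-component outliers on the top `pca_k` components.
#'
#' @param variant_call_rate_min,sample_call_rate_min Minimum call rates.
#' @param het_sd SD multiplier for heterozygosity outliers.
#' @param pi_hat_max Maximum tolerated PI_HAT.
#' @param hwe_p_min Minimum HWE P-value.
#' @param info_min Minimum imputation INFO r2.
#' @param pca_k Number of leading components screened.
#' @param pca_outlier_sd SD multiplier for PCA outliers.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(variant_call_rate_min = 0.9,
                          sample_call_rate_min = 0.75,
                          het_sd = 3, pi_hat_max = 0.2, hwe_p_min = 1e-6,
                          info_min = 0.7, pca_k = 8, pca_outlier_sd = 6) {
  stopifnot(variant_call_rate_min >= 0, variant_call_rate_min <= 1,
            sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            het_sd > 0, pi_hat_max >= 0, pi_hat_max <= 1,
            hwe_p_min > 0, hwe_p_min < 1, info_min >= 0, info_min <= 1,
            pca_k >= 1, pca_outlier_sd > 0)
  structure(list(variant_call_rate_min = variant_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min,
                 het_sd = het_sd, pi_hat_max = pi_hat_max,
                 hwe_p_min = hwe_p_min, info_min = info_min,
                 pca_k = pca_k, pca_outlier_sd = pca_outlier_sd),
            class = "qc_thresholds")
}

qc_report <- function(stage, unit, id, statistic) {
  tibble::tibble(stage = stage, unit = unit,
                 id = as.character(id), statistic = as.numeric(statistic))
}

empty_report <- function() {
  qc_report(character(), character(), character(), numeric())
}

#' Per-variant and per-sample genotype call rates
#'
#' @param panel A [haplotype_panel()].
#' @return Numeric vector of non-missing genotype fractions.
#' @export
variant_call_rate <- function(panel) {
  d <- dosages(panel)
  colMeans(!is.na(d))
}

#' @rdname variant_call_rate
#' @export
sample_call_rate <- function(panel) {
  d <- dosages(panel)
  rowMeans(!is.na(d))
}

#' Remove variants with low genotype call rate
#'
#' Variants whose fraction of non-missing genotypes is strictly below
#' `min_rate` are removed; a variant exactly at the threshold is retained.
#'
#' @param panel A [haplotype_panel()].
#' @param min_rate Minimum call rate (default 0.9).
#' @return A list with the filtered `panel` and a `report` tibble.
#' @export
filter_variant_call_rate <- function(panel, min_rate = 0.9) {
  cr <- variant_call_rate(panel)
  drop <- cr < min_rate
  list(panel = subset_variants(panel, !drop),
       report = qc_report("variant_call_rate", "variant",
                          panel$variants$id[drop], cr[drop]))
}

#' Remove samples with low genotype call rate
#'
#' @param panel A [haplotype_panel()].
#' @param min_rate Minimum call rate (default 0.75).
#' @return A list with the filtered `panel` and a `report` tibble.
#' @export
filter_sample_call_rate <- function(panel, min_rate = 0.75) {
  cr <- sample_call_rate(panel)
  drop <- cr < min_rate
  list(panel = subset_samples(panel, !drop),
       report = qc_report("sample_call_rate", "sample",
                          panel$samples$sample[drop], cr[drop]))
}

#' Per-sample heterozygosity
#'
#' Fraction of heterozygous genotypes among non-missing genotypes.
#'
#' @param panel A [haplotype_panel()].
#' @return Named numeric vector, one value per sample.
#' @export
sample_het <- function(panel) {
  d <- dosages(panel)
  rowMeans(d == 1L, na.rm = TRUE)
}

#' Remove heterozygosity outliers
#'
#' Samples whose heterozygosity deviates from the panel mean by more than
#' `sd_mult` standard deviations (either direction; excess heterozygosity
#' signals contamination, deficit signals inbreeding or genotyping failure)
#' are removed. With fewer than three samples, or zero SD, nothing is
#' removed.
#'
#' @param panel A [haplotype_panel()].
#' @param sd_mult SD multiplier (default 3).
#' @return A list with the filtered `panel` and a `report` tibble.
#' @export
filter_sample_het <- function(panel, sd_mult = 3) {
  het <- sample_het(panel)
  if (n_samples(panel) < 3) {
    message("fewer than 3 samples: heterozygosity filter skipped")
    return(list(panel = panel, report = empty_report()))
  }
  s <- stats::sd(het)
  drop <- if (is.na(s) || s == 0) rep(FALSE, length(het)) else
    abs(het - mean(het)) > sd_mult * s
  list(panel = subset_samples(panel, !drop),
       report = qc_report("heterozygosity", "sample",
                          panel$samples$sample[drop], het[drop]))
}

#' Method-of-moments relatedness (PI_HAT) between two samples
#'
#' PLINK-style estimator: identity-by-state counts between the two genotype
#' vectors are compared with their expectations under IBD states 0/1/2
#' given the panel allele frequencies; the moment estimates of
#' `P(IBD = k)` are clamped at zero and renormalised, and
#' `PI_HAT = P(IBD=2) + P(IBD=1)/2`.
#'
#' @param panel A [haplotype_panel()].
#' @param sample_i,sample_j Sample ids or indices.
#' @return PI_HAT in `[0, 1]`.
#' @export
estimate_pi_hat <- function(panel, sample_i, sample_j) {
  d <- dosages(panel)
  idx <- function(s) if (is.character(s)) match(s, panel$samples$sample) else s
  d1 <- d[idx(sample_i), ]
  d2 <- d[idx(sample_j), ]
  p <- colMeans(d, na.rm = TRUE) / 2
  ok <- !is.na(d1) & !is.na(d2) & !is.na(p) & p > 0 & p < 1
  if (!any(ok)) {
    stop("no polymorphic variants with genotypes in both samples",
         call. = FALSE)
  }
  d1 <- d1[ok]; d2 <- d2[ok]; p <- p[ok]; q <- 1 - p
  ibs <- 2L - abs(d1 - d2)
  n_ibs <- tabulate(ibs + 1L, nbins = 3L)
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibd1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_ibd1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  p0 <- n_ibs[1] / e0_ibd0
  p1 <- (n_ibs[2] - p0 * e1_ibd0) / e1_ibd1
  p2 <- (n_ibs[3] - p0 * e2_ibd0 - p1 * e2_ibd1) / length(p)
  pr <- pmax(c(p0, p1, p2), 0)
  pr <- pr / sum(pr)
  min(1, max(0, pr[3] + pr[2] / 2))
}

#' Remove one member of each related sample pair
#'
#' All pairs with PI_HAT above `max_pi_hat` are flagged (highest first);
#' from each flagged pair still intact, the member with the lower call rate
#' is removed.
#'
#' @param panel A [haplotype_panel()].
#' @param max_pi_hat Threshold (default 0.2).
#' @return A list with the filtered `panel` and a `report` tibble.
#' @export
filter_relatedness <- function(panel, max_pi_hat = 0.2) {
  n <- n_samples(panel)
  if (n < 2) return(list(panel = panel, report = empty_report()))
  pairs <- utils::combn(n, 2)
  ph <- apply(pairs, 2, function(ij)
    estimate_pi_hat(panel, ij[1], ij[2]))
  flagged <- which(ph > max_pi_hat)
  flagged <- flagged[order(-ph[flagged])]
  cr <- sample_call_rate(panel)
  removed <- integer(0)
  stat <- numeric(0)
  for (k in flagged) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (i %in% removed || j %in% removed) next
    worse <- if (cr[i] < cr[j]) i else j
    removed <- c(removed, worse)
    stat <- c(stat, ph[k])
  }
  keep <- setdiff(seq_len(n), removed)
  list(panel = subset_samples(panel, keep),
       report = qc_report("relatedness", "sample",
                          panel$samples$sample[removed], stat))
}

#' Hardy-Weinberg equilibrium Pearson chi-square test
#'
#' Expected genotype counts are derived from the observed allele
#' frequencies; the Pearson chi-square statistic has one degree of freedom.
#' Monomorphic tables return `P = 1` by convention.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (vectorised).
#' @return A tibble with columns `chi2` and `p`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (any(n < 1)) stop("each table needs at least one genotype", call. = FALSE)
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  mono <- p == 0 | p == 1
  e_aa <- n * p^2
  e_ab <- 2 * n * p * q
  e_bb <- n * q^2
  chi2 <- ifelse(mono, 0,
                 (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab +
                   (n_bb - e_bb)^2 / e_bb)
  pval <- ifelse(mono, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  tibble::tibble(chi2 = chi2, p = pval)
}

#' Remove variants departing from Hardy-Weinberg equilibrium
#'
#' When `controls` is supplied the test uses control samples only, so true
#' case-enriched association signals are not discarded.
#'
#' @param panel A [haplotype_panel()].
#' @param p_min Minimum HWE P-value (default 1e-6).
#' @param controls Optional character vector of control sample ids.
#' @return A list with the filtered `panel` and a `report` tibble.
#' @export
filter_hwe <- function(panel, p_min = 1e-6, controls = NULL) {
  d <- dosages(panel)
  if (!is.null(controls)) d <- d[panel$samples$sample %in% controls, ,
                                 drop = FALSE]
  n_bb <- colSums(d == 2L, na.rm = TRUE)  # alt homozygotes
  n_ab <- colSums(d == 1L, na.rm = TRUE)
  n_aa <- colSums(d == 0L, na.rm = TRUE)
  res <- hwe_test(n_aa, n_ab, n_bb)
  drop <- res$p < p_min
  list(panel = subset_variants(panel, !drop),
       report = qc_report("hwe", "variant",
                          panel$variants$id[drop], res$p[drop]))
}

#' Remove variants with low imputation quality
#'
#' Variants with `info_score` strictly below `min_info` are removed;
#' variants lacking an INFO value are retained with a message.
#'
#' @param panel A [haplotype_panel()].
#' @param min_info Minimum INFO r2 (default 0.7).
#' @return A list with the filtered `panel` and a `report` tibble.
#' @export
filter_info <- function(panel, min_info = 0.7) {
  info <- panel$variants$info_score
  if (all(is.na(info))) {
    message("no INFO scores present: imputation-quality filter skipped")
    return(list(panel = panel, report = empty_report()))
  }
  drop <- !is.na(info) & info < min_info
  if (any(is.na(info))) {
    message(sum(is.na(info)), " variant(s) lack an INFO score and were kept")
  }
  list(panel = subset_variants(panel, !drop),
       report = qc_report("info", "variant",
                          panel$variants$id[drop], info[drop]))
}

#' Principal components of the genotype matrix
#'
#' Dosages are mean-imputed, centred at twice the allele frequency and
#' scaled by `sqrt(2 p (1 - p))`; components come from the singular value
#' decomposition of the standardised matrix and are ordered by decreasing
#' variance explained.
#'
#' @param panel A [haplotype_panel()].
#' @param k Number of leading components to return (default 8, the usual
#'   covariate set for association); truncated with a warning when it
#'   exceeds the matrix rank.
#' @return A list with `scores` (tibble: `sample`, `PC1` ... `PCk`) and
#'   `sdev` (component standard deviations).
#' @export
pca_genotypes <- function(panel, k = 8) {
  d <- dosages(panel)
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- 2 * p[j]
  x <- sweep(d, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(d))
  rank_max <- min(nrow(x) - 1L, ncol(x))
  if (k > rank_max) {
    warning("k truncated to matrix rank (", rank_max, ")")
    k <- rank_max
  }
  s <- svd(x, nu = k, nv = 0)
  scores <- s$u %*% diag(s$d[seq_len(k)], nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = dplyr::bind_cols(
         tibble::tibble(sample = panel$samples$sample),
         tibble::as_tibble(scores)),
       sdev = s$d / sqrt(max(1, nrow(x) - 1)))
}

#' Flag principal-component outliers
#'
#' A sample is an outlier when any of its leading component scores lies
#' more than `sd_mult` standard deviations from the component mean. The
#' screen is iterated once: means and SDs are recomputed without the
#' first-pass outliers before the final flags are set.
#'
#' @param scores Score tibble from [pca_genotypes()].
#' @param sd_mult SD multiplier (default 6).
#' @return A tibble with columns `sample` and `outlier`.
#' @export
flag_pca_outliers <- function(scores, sd_mult = 6) {
  m <- as.matrix(scores[, grep("^PC", names(scores)), drop = FALSE])
  flag_pass <- function(m, ref) {
    mu <- colMeans(m[ref, , drop = FALSE])
    s <- apply(m[ref, , drop = FALSE], 2, stats::sd)
    s[is.na(s) | s == 0] <- Inf
    rowSums(abs(sweep(m, 2, mu)) > sd_mult * rep(s, each = nrow(m))) > 0
  }
  out1 <- flag_pass(m, seq_len(nrow(m)))
  ref <- if (all(out1)) seq_len(nrow(m)) else which(!out1)
  tibble::tibble(sample = scores$sample, outlier = flag_pass(m, ref))
}

#' Remove principal-component outlier samples
#'
#' @param panel A [haplotype_panel()].
#' @param k Components screened.
#' @param sd_mult SD multiplier.
#' @return A list with the filtered `panel` and a `report` tibble.
#' @export
filter_pca_outliers <- function(panel, k = 8, sd_mult = 6) {
  pca <- pca_genotypes(panel, k = k)
  fl <- flag_pca_outliers(pca$scores, sd_mult = sd_mult)
  list(panel = subset_samples(panel, !fl$outlier),
       report = qc_report("pca_outlier", "sample",
                          fl$sample[fl$outlier], NA_real_))
}

#' Run the full pre-association QC sequence
#'
#' Filters are applied in a fixed order: variant call rate, sample call
#' rate, heterozygosity, relatedness, PCA outliers, Hardy-Weinberg,
#' imputation INFO.
#'
#' @param panel A [haplotype_panel()].
#' @param thresholds A [qc_thresholds()] object.
#' @param controls Optional control sample ids for the HWE stage.
#' @return A list with the filtered `panel`, the combined `report` tibble
#'   and a `counts` tibble of per-stage variant and sample counts.
#' @export
run_qc <- function(panel, thresholds = qc_thresholds(), controls = NULL) {
  th <- thresholds
  stages <- list(
    variant_call_rate = function(p)
      filter_variant_call_rate(p, th$variant_call_rate_min),
    sample_call_rate = function(p)
      filter_sample_call_rate(p, th$sample_call_rate_min),
    heterozygosity = function(p) filter_sample_het(p, th$het_sd),
    relatedness = function(p) filter_relatedness(p, th$pi_hat_max),
    pca_outlier = function(p)
      filter_pca_outliers(p, th$pca_k, th$pca_outlier_sd),
    hwe = function(p) filter_hwe(p, th$hwe_p_min, controls),
    info = function(p) filter_info(p, th$info_min)
  )
  report <- list()
  counts <- list(tibble::tibble(stage = "input",
                                n_variants = n_variants(panel),
                                n_samples = n_samples(panel)))
  for (nm in names(stages)) {
    res <- stages[[nm]](panel)
    panel <- res$panel
    report[[length(report) + 1L]] <- res$report
    counts[[length(counts) + 1L]] <- tibble::tibble(
      stage = nm, n_variants = n_variants(panel),
      n_samples = n_samples(panel))
  }
  list(panel = panel, report = dplyr::bind_rows(report),
       counts = dplyr::bind_rows(counts))
}
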