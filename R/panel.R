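#' Construct a phased haplotype panel
#'
#' A `haplotype_panel` holds biallelic single-nucleotide variants on one
#' chromosome together with the phased alleles of a set of modern samples and,
#' optionally, the (unphased) diploid genotypes of one archaic individual
#' aligned to the same sites. Positions are stored 0-based internally; all
#' intervals elsewhere in the package are 0-based half-open. Conversion to and
#' from the 1-based VCF convention happens only in [read_vcf()] / [write_vcf()].
#'
#' @param variants A data frame with one row per variant and columns `chrom`,
#'   `pos` (0-based base-pair coordinate, strictly increasing), `id`, `ref`,
#'   `alt` and optionally `info_score` (imputation quality in `[0, 1]`, `NA`
#'   when not available).
#' @param haplotypes Integer matrix with `nrow(variants)` rows and two columns
#'   per sample (sample `i` occupies columns `2i - 1` and `2i`). Entries are
#'   allele indices: 0 (ref), 1 (alt) or `NA` (missing).
#' @param samples A data frame with columns `sample` and `population`, one row
#'   per diploid sample, in the column order of `haplotypes`.
#' @param archaic Optional integer matrix (`nrow(variants)` x 2) of archaic
#'   allele indices, unordered, `NA` for missing sites.
#' @param outgroup Optional population label designating the African outgroup;
#'   functions that need one (e.g. [apply_site_criteria()]) fall back to it.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, haplotypes, samples, archaic = NULL,
                            outgroup = NULL) {
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  required <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("`variants` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"info_score" %in% names(variants)) variants$info_score <- NA_real_
  if (!all(c("sample", "population") %in% names(samples))) {
    stop("`samples` must have columns `sample` and `population`", call. = FALSE)
  }
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != nrow(variants)) {
    stop("`haplotypes` must have one row per variant", call. = FALSE)
  }
  if (ncol(haplotypes) != 2L * nrow(samples)) {
    stop("`haplotypes` must have two columns per sample", call. = FALSE)
  }
  if (nrow(variants) > 1 && any(diff(variants$pos) <= 0)) {
    stop("variant positions must be strictly increasing", call. = FALSE)
  }
  bad <- haplotypes[!is.na(haplotypes)]
  if (length(bad) > 0 && !all(bad %in% c(0L, 1L))) {
    stop("haplotype allele indices must be 0, 1 or NA", call. = FALSE)
  }
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  if (!is.null(archaic)) {
    archaic <- as.matrix(archaic)
    storage.mode(archaic) <- "integer"
    if (nrow(archaic) != nrow(variants) || ncol(archaic) != 2L) {
      stop("`archaic` must be an n_variants x 2 matrix", call. = FALSE)
    }
  }
  structure(
    list(variants = variants, haplotypes = haplotypes, samples = samples,
         archaic = archaic, outgroup = outgroup),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  pops <- table(x$samples$population)
  cat("<haplotype_panel> ", nrow(x$variants), " variants, ",
      nrow(x$samples), " samples (",
      paste(names(pops), pops, sep = ": ", collapse = ", "), ")",
      if (!is.null(x$archaic)) " + archaic genome", "\n", sep = "")
  if (!is.null(x$outgroup)) cat("  outgroup: ", x$outgroup, "\n", sep = "")
  invisible(x)
}

#' Numbers of variants and samples in a panel
#' @param panel A [haplotype_panel()].
#' @return An integer count.
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' @rdname n_variants
#' @export
n_samples <- function(panel) nrow(panel$samples)

# column indices of the two haplotypes of sample i
hap_cols <- function(i) c(2L * i - 1L, 2L * i)

# label for each haplotype column: "<sample>|<side>"
hap_ids <- function(panel) {
  paste(rep(panel$samples$sample, each = 2), rep(0:1, n_samples(panel)),
        sep = "|")
}

# population label for each haplotype column
hap_pops <- function(panel) rep(panel$samples$population, each = 2)

#' Per-sample alternate-allele dosages
#'
#' @param panel A [haplotype_panel()].
#' @return An `n_samples x n_variants` integer matrix of 0/1/2 dosages
#'   (`NA` when either allele is missing), rows named by sample id and
#'   columns by variant id.
#' @export
dosages <- function(panel) {
  h <- panel$haplotypes
  odd <- seq(1L, ncol(h), by = 2L)
  d <- t(h[, odd, drop = FALSE] + h[, odd + 1L, drop = FALSE])
  dimnames(d) <- list(panel$samples$sample, panel$variants$id)
  d
}

#' Alternate-allele frequency per variant within populations
#'
#' Frequencies are computed over non-missing haplotypes of the samples whose
#' population label is in `pops` (all samples when `NULL`).
#'
#' @param panel A [haplotype_panel()].
#' @param pops Character vector of population labels, or `NULL` for all.
#' @return Numeric vector, one frequency per variant (`NaN` where every
#'   haplotype is missing).
#' @export
allele_freq <- function(panel, pops = NULL) {
  keep <- if (is.null(pops)) rep(TRUE, 2L * n_samples(panel)) else
    hap_pops(panel) %in% pops
  h <- panel$haplotypes[, keep, drop = FALSE]
  rowMeans(h, na.rm = TRUE)
}

# subset a panel by variant index, keeping all parallel structures aligned
subset_variants <- function(panel, keep) {
  haplotype_panel(
    variants = panel$variants[keep, , drop = FALSE],
    haplotypes = panel$haplotypes[keep, , drop = FALSE],
    samples = panel$samples,
    archaic = if (is.null(panel$archaic)) NULL else
      panel$archaic[keep, , drop = FALSE],
    outgroup = panel$outgroup
  )
}

# subset a panel by sample index
subset_samples <- function(panel, keep) {
  keep <- if (is.logical(keep)) which(keep) else as.integer(keep)
  cols <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  haplotype_panel(
    variants = panel$variants,
    haplotypes = panel$haplotypes[, cols, drop = FALSE],
    samples = panel$samples[keep, , drop = FALSE],
    archaic = panel$archaic,
    outgroup = panel$outgroup
  )
}

#' Variant table of a panel
#'
#' @param x A [haplotype_panel()].
#' @param ... Unused.
#' @return The `variants` tibble (0-based positions).
#' @importFrom tibble as_tibble
#' @export
as_tibble.haplotype_panel <- function(x, ...) x$variants
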