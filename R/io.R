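#' Read a VCF into a haplotype panel
#'
#' Parses a VCF v4.x with per-sample GT fields into a [haplotype_panel()].
#' Only biallelic single-nucleotide variants are analysable downstream;
#' multiallelic sites and indels are dropped when `filter_biallelic_snv` is
#' `TRUE`. VCF positions (1-based) are converted to the package's internal
#' 0-based convention. An imputation-quality value is read from the `INFO=`
#' key of the INFO column when present.
#'
#' @param path Path to a VCF (plain or gzip).
#' @param populations Sample-to-population mapping: either a named character
#'   vector (names are sample ids) or a data frame with columns `sample` and
#'   `population`. Every modern sample in the VCF must be mapped.
#' @param archaic_sample Optional sample id to treat as the archaic
#'   individual; its genotypes populate the panel's `archaic` slot and it is
#'   excluded from the modern sample set.
#' @param filter_biallelic_snv Drop indels and multiallelic sites (default
#'   `TRUE`).
#' @param outgroup Optional population label designating the African outgroup.
#' @return A [haplotype_panel()].
#' @export
read_vcf <- function(path, populations, archaic_sample = NULL,
                     filter_biallelic_snv = TRUE, outgroup = NULL) {
  if (is.data.frame(populations)) {
    pop_map <- stats::setNames(populations$population, populations$sample)
  } else {
    pop_map <- populations
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (nrow(fix) == 0) {
    sample_ids <- setdiff(colnames(gt)[-1], archaic_sample)
    return(empty_panel(sample_ids, pop_map, archaic_sample, outgroup))
  }
  keep <- rep(TRUE, nrow(fix))
  if (filter_biallelic_snv) {
    nucs <- c("A", "C", "G", "T")
    keep <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
      fix[, "REF"] %in% nucs & fix[, "ALT"] %in% nucs
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  sample_ids <- colnames(gt)[-1]
  modern <- setdiff(sample_ids, archaic_sample)
  unmapped <- setdiff(modern, names(pop_map))
  if (length(unmapped) > 0) {
    stop("sample(s) not in population map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(archaic_sample) && !archaic_sample %in% sample_ids) {
    stop("archaic sample `", archaic_sample, "` not found in VCF",
         call. = FALSE)
  }

  info_col <- fix[, "INFO"]
  info_col[is.na(info_col)] <- "."
  info_score <- rep(NA_real_, length(info_col))
  hit <- grepl("(^|;)INFO=", info_col)
  info_score[hit] <- suppressWarnings(as.numeric(
    sub(".*?(^|;)INFO=([^;]*).*", "\\2", info_col[hit])
  ))
  variants <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    info_score = info_score
  )

  parse_gt <- function(cols) {
    g <- sub(":.*", "", gt[, cols, drop = FALSE])
    a1 <- substr(g, 1L, 1L)
    a2 <- substr(g, 3L, 3L)
    a2[nchar(g) == 1L] <- "."   # haploid-style missing "."
    to_idx <- function(a) {
      out <- suppressWarnings(as.integer(a))
      bad <- is.na(out) & !is.na(a) & a != "." & a != ""
      if (any(bad)) {
        stop("unparseable GT at variant row(s): ",
             paste(utils::head(which(rowSums(matrix(bad, nrow = nrow(g))) > 0)),
                   collapse = ", "), call. = FALSE)
      }
      out
    }
    list(a1 = matrix(to_idx(a1), nrow = nrow(g)),
         a2 = matrix(to_idx(a2), nrow = nrow(g)))
  }

  mod <- parse_gt(modern)
  haps <- matrix(NA_integer_, nrow = nrow(variants), ncol = 2L * length(modern))
  haps[, seq(1L, ncol(haps), 2L)] <- mod$a1
  haps[, seq(2L, ncol(haps), 2L)] <- mod$a2

  archaic <- NULL
  if (!is.null(archaic_sample)) {
    arc <- parse_gt(archaic_sample)
    archaic <- cbind(arc$a1[, 1], arc$a2[, 1])
  }
  samples <- tibble::tibble(sample = modern,
                            population = unname(pop_map[modern]))
  haplotype_panel(variants, haps, samples, archaic = archaic,
                  outgroup = outgroup)
}

# zero-variant panel with a valid shape
empty_panel <- function(sample_ids, pop_map, archaic_sample, outgroup) {
  unmapped <- setdiff(sample_ids, names(pop_map))
  if (length(unmapped) > 0) {
    stop("sample(s) not in population map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  haplotype_panel(
    variants = tibble::tibble(chrom = character(), pos = integer(),
                              id = character(), ref = character(),
                              alt = character(), info_score = numeric()),
    haplotypes = matrix(integer(), nrow = 0, ncol = 2L * length(sample_ids)),
    samples = tibble::tibble(sample = sample_ids,
                             population = unname(pop_map[sample_ids])),
    archaic = if (is.null(archaic_sample)) NULL else
      matrix(integer(), nrow = 0, ncol = 2L),
    outgroup = outgroup
  )
}

#' Write a haplotype panel to VCF
#'
#' Modern samples are written phased (`|`); the archaic individual, when
#' present, is appended as an unphased (`/`) sample. Internal 0-based
#' positions are converted back to 1-based VCF coordinates. Output is
#' gzip-compressed (readable by [read_vcf()]).
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path (conventionally `.vcf.gz`).
#' @param archaic_sample Name used for the archaic column (default
#'   `"archaic"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, archaic_sample = "archaic") {
  va <- panel$variants
  info <- ifelse(is.na(va$info_score), ".",
                 paste0("INFO=", format(va$info_score, trim = TRUE)))
  fix <- cbind(CHROM = va$chrom, POS = as.character(va$pos + 1L),
               ID = va$id, REF = va$ref, ALT = va$alt,
               QUAL = ".", FILTER = ".", INFO = info)
  fmt <- function(a1, a2, sep) {
    out <- paste(ifelse(is.na(a1), ".", a1), ifelse(is.na(a2), ".", a2),
                 sep = sep)
    matrix(out, nrow = nrow(va))
  }
  h <- panel$haplotypes
  odd <- seq(1L, ncol(h), by = 2L)
  gt_body <- fmt(h[, odd, drop = FALSE], h[, odd + 1L, drop = FALSE], "|")
  colnames(gt_body) <- panel$samples$sample
  if (!is.null(panel$archaic)) {
    arc <- fmt(panel$archaic[, 1, drop = FALSE],
               panel$archaic[, 2, drop = FALSE], "/")
    colnames(arc) <- archaic_sample
    gt_body <- cbind(gt_body, arc)
  }
  gt <- cbind(FORMAT = rep("GT", nrow(va)), gt_body)
  meta <- c("##fileformat=VCFv4.2",
            "##source=introgressr",
            "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality r2\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  obj <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read per-study association summary statistics
#'
#' Expects a TSV with header columns `snp`, `effect_allele`, `p`, `study`
#' and at least one of `beta` (log odds ratio) or `or`; `se` is optional.
#' Whichever of `beta`/`or` is absent is filled in via the natural-log
#' relation `beta = ln(OR)`.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `snp`, `effect_allele`, `beta`, `se`, `or`,
#'   `p`, `study`.
#' @export
read_summary_stats <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("snp", "effect_allele", "p", "study")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("summary statistics lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"beta" %in% names(x) && !"or" %in% names(x)) {
    stop("summary statistics need a `beta` or `or` column", call. = FALSE)
  }
  if (!"beta" %in% names(x)) x$beta <- log(x$or)
  if (!"or" %in% names(x)) x$or <- exp(x$beta)
  if (!"se" %in% names(x)) x$se <- NA_real_
  if (any(x$p <= 0 | x$p > 1, na.rm = TRUE)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  if (any(x$se <= 0, na.rm = TRUE)) stop("SE must be positive", call. = FALSE)
  if (any(x$or <= 0, na.rm = TRUE)) {
    stop("odds ratios must be positive", call. = FALSE)
  }
  dplyr::select(x, "snp", "effect_allele", "beta", "se", "or", "p", "study")
}

#' @rdname read_summary_stats
#' @param x Tibble of summary statistics.
#' @export
write_summary_stats <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read and write ground-truth tract BED files
#'
#' Truth tracts are stored as BED5-style lines: chrom, start, end (0-based
#' half-open), haplotype id (`sample|side`), origin (`introgressed` or
#' `ILS`).
#'
#' @param path File path.
#' @return `read_truth_bed()` returns a tibble with columns `chrom`, `start`,
#'   `end`, `hap`, `origin`.
#' @export
read_truth_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "hap", "origin"),
                  col_types = "ciicc")
}

#' @rdname read_truth_bed
#' @param truth Tibble of truth tracts as produced by [simulate_panel()].
#' @export
write_truth_bed <- function(truth, path) {
  readr::write_tsv(truth[, c("chrom", "start", "end", "hap", "origin")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Thin wrapper that writes any tidy result table (segments, aSNP calls,
#' association results, QC reports) with a stable column order.
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_results <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
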