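#' Assemble a pipeline configuration
#'
#' Two modes mirror the two analysis paths: `"genotype"` runs QC, aSNP
#' calling and covariate-adjusted association on individual-level data;
#' `"summary"` looks candidate aSNPs up in per-study summary statistics and
#' applies the effect-direction concordance rule (the path used when only
#' GWAS summary data are available).
#'
#' @param mode `"genotype"` or `"summary"`.
#' @param panel A [haplotype_panel()], or `NULL` to read/simulate one.
#' @param vcf,populations,archaic_sample VCF path plus sample metadata used
#'   when `panel` is `NULL`.
#' @param sim Optional [sim_params()]; when given the panel is simulated.
#' @param afr_pop African outgroup label.
#' @param map,map2 [genetic_map()] objects (or paths) for the length test.
#' @param pheno Phenotype tibble (or TSV path) with `sample`, `status` and
#'   covariate columns.
#' @param covariates Covariate column names used in association.
#' @param n_pcs Number of genotype principal components appended to the
#'   covariates (0 disables).
#' @param summary_stats Summary-statistics tibble (or TSV path) for
#'   summary mode.
#' @param asnp_ids Optional aSNP id vector restricting summary mode.
#' @param ils An [ils_config()].
#' @param qc A [qc_thresholds()], or `NULL` to skip sample/variant QC.
#' @param alpha Significance level used for calling and per-study filters.
#' @param prune_r2 LD-pruning threshold (default 0.5).
#' @param independence_r2 Independent-count threshold (default 0.8).
#' @param seed RNG seed applied at the start of the run.
#' @param outdir Optional output directory for TSV artefacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("genotype", "summary"), panel = NULL,
                            vcf = NULL, populations = NULL,
                            archaic_sample = NULL, sim = NULL,
                            afr_pop = NULL, map = NULL, map2 = NULL,
                            pheno = NULL, covariates = c("age", "sex"),
                            n_pcs = 0, summary_stats = NULL,
                            asnp_ids = NULL, ils = ils_config(),
                            qc = qc_thresholds(), alpha = 0.05,
                            prune_r2 = 0.5, independence_r2 = 0.8,
                            seed = NULL, outdir = NULL) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_count <- function(stage, n_in, n_out) {
  tibble::tibble(stage = stage, n_in = n_in, n_out = n_out)
}

#' Run the full analysis pipeline
#'
#' Genotype mode: acquire panel (simulate or read) -> sample/variant QC ->
#' aSNP calling (site criteria + segment-length test) -> covariate-adjusted
#' logistic association of the called aSNPs -> LD pruning -> independent
#' test count, Bonferroni threshold and inflation factor. Summary mode:
#' restrict per-study summary statistics to candidate aSNPs and apply the
#' cross-study concordance rule. The same configuration and seed always
#' reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list with a `manifest` (per-stage record counts and the
#'   configuration hash) and the stage outputs (`panel`, `qc`, `asnps`,
#'   `segments`, `assoc`, `pruned`, `m_independent`, `threshold`,
#'   `lambda`, `n_significant` in genotype mode; `stats` and `concordance`
#'   in summary mode).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  t0 <- Sys.time()
  manifest <- list()
  log_stage <- function(stage, n_in, n_out) {
    manifest[[length(manifest) + 1L]] <<- stage_count(stage, n_in, n_out)
    message(sprintf("[%s] %s -> %s", stage, n_in, n_out))
  }
  out <- list()

  if (config$mode == "summary") {
    stats_tbl <- config$summary_stats
    if (is.character(stats_tbl)) stats_tbl <- read_summary_stats(stats_tbl)
    n0 <- length(unique(stats_tbl$snp))
    if (!is.null(config$asnp_ids)) {
      stats_tbl <- stats_tbl[stats_tbl$snp %in% config$asnp_ids, ,
                             drop = FALSE]
    }
    log_stage("summary_lookup", n0, length(unique(stats_tbl$snp)))
    conc <- concordance_filter(stats_tbl, alpha = config$alpha)
    log_stage("concordance", nrow(conc), sum(conc$pass))
    out$stats <- stats_tbl
    out$concordance <- conc
    out$candidates <- conc$snp[conc$pass]
  } else {
    panel <- config$panel
    if (is.null(panel) && !is.null(config$sim)) {
      simulated <- simulate_panel(config$sim)
      panel <- simulated$panel
      out$truth <- simulated$truth
    }
    if (is.null(panel) && !is.null(config$vcf)) {
      panel <- read_vcf(config$vcf, config$populations,
                        archaic_sample = config$archaic_sample,
                        outgroup = config$afr_pop)
    }
    if (is.null(panel)) stop("no panel source configured", call. = FALSE)
    map <- config$map
    if (is.character(map)) map <- read_genetic_map(map)
    if (is.null(map)) stop("genotype mode needs a genetic map", call. = FALSE)
    map2 <- config$map2
    if (is.character(map2)) map2 <- read_genetic_map(map2)

    if (!is.null(config$qc)) {
      nv <- n_variants(panel); ns <- n_samples(panel)
      qc_res <- run_qc(panel, config$qc)
      panel <- qc_res$panel
      out$qc <- qc_res
      log_stage("qc_variants", nv, n_variants(panel))
      log_stage("qc_samples", ns, n_samples(panel))
    }

    calls <- find_asnps(panel, map, cfg = config$ils, alpha = config$alpha,
                        afr_pop = config$afr_pop, map2 = map2)
    log_stage("site_criteria", n_variants(panel),
              sum(calls$candidates$candidate))
    log_stage("segment_test", sum(calls$candidates$candidate),
              nrow(calls$asnps))
    out$panel <- panel
    out$candidates <- calls$candidates
    out$segments <- calls$segments
    out$asnps <- calls$asnps

    if (!is.null(config$pheno) && nrow(calls$asnps) > 0) {
      pheno <- config$pheno
      if (is.character(pheno)) {
        pheno <- readr::read_tsv(pheno, show_col_types = FALSE)
      }
      pheno <- pheno[pheno$sample %in% panel$samples$sample, , drop = FALSE]
      covars <- config$covariates
      if (config$n_pcs > 0) {
        sub <- subset_samples(panel,
                              match(pheno$sample, panel$samples$sample))
        pcs <- pca_genotypes(sub, k = config$n_pcs)$scores
        pheno <- dplyr::left_join(pheno, pcs, by = "sample")
        covars <- c(covars, setdiff(names(pcs), "sample"))
      }
      assoc <- assoc_scan(panel, pheno, snps = calls$asnps$id,
                          covariates = covars)
      log_stage("association", nrow(calls$asnps), nrow(assoc))
      d <- dosages(panel)[pheno$sample, calls$asnps$id, drop = FALSE]
      ld <- ld_matrix(d)
      pruned <- greedy_prune(assoc, ld, r2_threshold = config$prune_r2)
      log_stage("ld_prune", nrow(assoc), nrow(pruned))
      m <- count_independent(calls$asnps$id, ld,
                             r2_threshold = config$independence_r2)
      thr <- bonferroni_threshold(m, config$alpha)
      lam <- genomic_lambda(p = assoc$wald_p)
      n_sig <- sum(assoc$wald_p < thr)
      log_stage("bonferroni", m, n_sig)
      out$assoc <- assoc
      out$pruned <- pruned
      out$m_independent <- m
      out$threshold <- thr
      out$lambda <- lam
      out$n_significant <- n_sig
    }
  }

  out$manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    seed = config$seed,
    counts = dplyr::bind_rows(manifest),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) if (!is.null(x) && is.data.frame(x)) {
      write_results(x, file.path(config$outdir, f))
    }
    w(out$candidates, "candidates.tsv")
    w(out$segments, "segments.tsv")
    w(out$asnps, "asnps.tsv")
    w(out$assoc, "association.tsv")
    w(out$pruned, "pruned.tsv")
    w(out$concordance, "concordance.tsv")
    w(out$manifest$counts, "manifest_counts.tsv")
  }
  out
}
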