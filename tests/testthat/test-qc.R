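# panel with controllable missingness: n_var x n_samples pattern matrix of
# missing-genotype indicators
panel_with_missing <- function(miss, freqs = NULL, seed = 1) {
  set.seed(seed)
  n_var <- nrow(miss)
  n_s <- ncol(miss)
  if (is.null(freqs)) freqs <- runif(n_var, 0.2, 0.8)
  haps <- matrix(rbinom(n_var * 2 * n_s, 1, rep(freqs, 2 * n_s)),
                 n_var, 2 * n_s)
  for (j in seq_len(n_s)) {
    haps[miss[, j], (2 * j - 1):(2 * j)] <- NA_integer_
  }
  haplotype_panel(
    tibble::tibble(chrom = "1", pos = seq_len(n_var) * 100L,
                   id = paste0("v", seq_len(n_var)),
                   ref = "A", alt = "G", info_score = NA_real_),
    haps,
    tibble::tibble(sample = paste0("S", seq_len(n_s)),
                   population = "EUR")
  )
}

test_that("variant call-rate filter removes below 0.9 and keeps the boundary", {
  miss <- matrix(FALSE, 3, 10)
  miss[1, 1:2] <- TRUE   # call rate 0.8 -> removed
  miss[2, 1] <- TRUE     # call rate 0.9 -> retained (strict <)
  panel <- panel_with_missing(miss)
  res <- filter_variant_call_rate(panel, 0.9)
  expect_equal(res$panel$variants$id, c("v2", "v3"))
  expect_equal(res$report$id, "v1")
  expect_equal(res$report$statistic, 0.8)
  # no missingness: unchanged
  clean <- panel_with_missing(matrix(FALSE, 3, 10))
  expect_equal(n_variants(filter_variant_call_rate(clean)$panel), 3)
})

test_that("sample call-rate filter removes samples under 75%", {
  miss <- matrix(FALSE, 20, 5)
  miss[1:6, 3] <- TRUE   # sample 3 call rate 0.7
  panel <- panel_with_missing(miss)
  res <- filter_sample_call_rate(panel, 0.75)
  expect_equal(res$report$id, "S3")
  expect_equal(n_samples(res$panel), 4)
})

test_that("heterozygosity outliers are removed two-sidedly", {
  set.seed(4)
  n_var <- 200
  haps <- matrix(rbinom(n_var * 2 * 21, 1, 0.5), n_var, 42)
  # plant sample 21 heterozygous everywhere: alternate 0|1
  haps[, 41] <- 0L
  haps[, 42] <- 1L
  panel <- haplotype_panel(
    tibble::tibble(chrom = "1", pos = seq_len(n_var) * 10L,
                   id = paste0("v", seq_len(n_var)), ref = "A", alt = "C",
                   info_score = NA_real_),
    haps,
    tibble::tibble(sample = paste0("S", 1:21), population = "EUR"))
  res <- filter_sample_het(panel, 3)
  expect_equal(res$report$id, "S21")
  expect_equal(n_samples(res$panel), 20)
  # identical heterozygosity everywhere: nothing removed
  flat <- haplotype_panel(
    panel$variants,
    matrix(rep(c(0L, 1L), n_var * 3), n_var, 6, byrow = TRUE),
    tibble::tibble(sample = paste0("S", 1:3), population = "EUR"))
  expect_equal(n_samples(filter_sample_het(flat)$panel), 3)
  # two samples: degenerate, skipped with a message
  two <- haplotype_panel(
    panel$variants, haps[, 1:4],
    tibble::tibble(sample = c("S1", "S2"), population = "EUR"))
  expect_message(res2 <- filter_sample_het(two), "fewer than 3")
  expect_equal(n_samples(res2$panel), 2)
})

test_that("PI_HAT separates duplicates, relatives and unrelated pairs", {
  set.seed(12)
  n_var <- 1000
  freqs <- runif(n_var, 0.05, 0.5)
  hap_draw <- function() rbinom(n_var, 1, freqs)
  # S1/S2 duplicates; S3 unrelated; S4 = child of S1 and an unrelated parent
  h1a <- hap_draw(); h1b <- hap_draw()
  transmitted <- ifelse(rbinom(n_var, 1, 0.5) == 1, h1a, h1b)
  haps <- cbind(h1a, h1b, h1a, h1b, hap_draw(), hap_draw(),
                transmitted, hap_draw())
  # background unrelated samples stabilise the plug-in allele frequencies
  for (i in 5:20) haps <- cbind(haps, hap_draw(), hap_draw())
  panel <- haplotype_panel(
    tibble::tibble(chrom = "1", pos = seq_len(n_var) * 50L,
                   id = paste0("v", seq_len(n_var)), ref = "A", alt = "G",
                   info_score = NA_real_),
    haps,
    tibble::tibble(sample = paste0("S", 1:20), population = "EUR"))
  expect_gte(estimate_pi_hat(panel, "S1", "S2"), 0.95)
  expect_lt(abs(estimate_pi_hat(panel, "S1", "S3")), 0.05)
  expect_equal(estimate_pi_hat(panel, "S1", "S4"), 0.5, tolerance = 0.1)

  res <- filter_relatedness(panel, 0.2)
  expect_true(any(c("S1", "S2") %in% res$report$id))
  expect_true("S3" %in% res$panel$samples$sample)
})

test_that("PI_HAT requires polymorphic sites", {
  haps <- matrix(0L, 10, 4)
  panel <- haplotype_panel(
    tibble::tibble(chrom = "1", pos = 1:10 * 10L, id = paste0("v", 1:10),
                   ref = "A", alt = "G", info_score = NA_real_),
    haps,
    tibble::tibble(sample = c("S1", "S2"), population = "EUR"))
  expect_error(estimate_pi_hat(panel, "S1", "S2"), "polymorphic")
})

test_that("HWE chi-square matches hand arithmetic and conventions", {
  res <- hwe_test(25, 50, 25)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  res2 <- hwe_test(50, 0, 50)
  expect_equal(res2$chi2, 100)
  expect_lt(res2$p, 1e-20)
  expect_equal(hwe_test(0, 0, 80)$p, 1)  # monomorphic convention
})

test_that("HWE test agrees with the chi-square from multinomial expectations", {
  set.seed(8)
  for (i in 1:100) {
    counts <- as.vector(stats::rmultinom(1, sample(50:500, 1),
                                         prob = runif(3, 0.05, 1)))
    got <- hwe_test(counts[1], counts[2], counts[3])
    n <- sum(counts)
    p <- (2 * counts[1] + counts[2]) / (2 * n)
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((counts - expected)^2 / expected)
    expect_equal(got$chi2, chi2, tolerance = 1e-8)
    expect_equal(got$p, stats::pchisq(chi2, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("INFO filter removes below 0.7, keeps the boundary and missing", {
  panel <- panel_with_missing(matrix(FALSE, 5, 4))
  panel$variants$info_score <- c(0.69, 0.70, NA, 0.95, 0.2)
  expect_message(res <- filter_info(panel, 0.7), "kept")
  expect_equal(res$panel$variants$info_score, c(0.70, NA, 0.95))
  expect_equal(res$report$id, c("v1", "v5"))
  # all missing: untouched with a message
  none <- panel_with_missing(matrix(FALSE, 3, 4))
  expect_message(res2 <- filter_info(none), "skipped")
  expect_equal(n_variants(res2$panel), 3)
})

test_that("PCA separates diverged populations and flags planted outliers", {
  set.seed(19)
  n_var <- 300
  n_per <- 40
  f1 <- runif(n_var, 0.05, 0.35)
  f2 <- pmin(f1 + 0.4, 0.95)
  g <- rbind(random_dosages(n_per, f1), random_dosages(n_per, f2))
  haps <- matrix(0L, n_var, 4 * n_per)
  haps[, seq(1, 4 * n_per - 1, 2)] <- t(pmin(g, 1))
  haps[, seq(2, 4 * n_per, 2)] <- t(pmax(g - 1, 0))
  panel <- haplotype_panel(
    tibble::tibble(chrom = "1", pos = seq_len(n_var) * 10L,
                   id = paste0("v", seq_len(n_var)), ref = "A", alt = "G",
                   info_score = NA_real_),
    haps,
    tibble::tibble(sample = paste0("S", seq_len(2 * n_per)),
                   population = rep(c("P1", "P2"), each = n_per)))
  pca <- pca_genotypes(panel, k = 2)
  r <- cor(pca$scores$PC1, as.numeric(panel$samples$population == "P2"))
  expect_gt(abs(r), 0.9)
  # two balanced clusters: neither is an outlier at 6 SD
  expect_false(any(flag_pca_outliers(pca$scores, 6)$outlier))
  # plant one sample from a very divergent population into an otherwise
  # homogeneous panel: it must be the only flagged outlier
  n_var3 <- 500
  n3 <- 60
  fb <- runif(n_var3, 0.2, 0.8)
  g3 <- random_dosages(n3, fb)
  g3[n3, ] <- random_dosages(1, ifelse(fb < 0.5, 0.99, 0.01))
  haps3 <- matrix(0L, n_var3, 2 * n3)
  haps3[, seq(1, 2 * n3 - 1, 2)] <- t(pmin(g3, 1))
  haps3[, seq(2, 2 * n3, 2)] <- t(pmax(g3 - 1, 0))
  panel3 <- haplotype_panel(
    tibble::tibble(chrom = "1", pos = seq_len(n_var3) * 10L,
                   id = paste0("v", seq_len(n_var3)), ref = "A", alt = "G",
                   info_score = NA_real_),
    haps3,
    tibble::tibble(sample = paste0("S", seq_len(n3)), population = "P1"))
  fl <- flag_pca_outliers(pca_genotypes(panel3, k = 4)$scores, 6)
  expect_equal(which(fl$outlier), n3)
  res3 <- filter_pca_outliers(panel3, k = 4, sd_mult = 6)
  expect_equal(res3$report$id, paste0("S", n3))
})

test_that("k larger than the matrix rank is truncated with a warning", {
  panel <- panel_with_missing(matrix(FALSE, 30, 4))
  expect_warning(pca <- pca_genotypes(panel, k = 10), "rank")
  expect_lte(sum(grepl("^PC", names(pca$scores))), 3)
})

test_that("stable QC filters are idempotent", {
  miss <- matrix(FALSE, 30, 8)
  miss[1:2, 1:4] <- TRUE
  miss[3, 1] <- TRUE
  panel <- panel_with_missing(miss, seed = 6)
  panel$variants$info_score <- runif(30)
  once <- filter_variant_call_rate(panel)$panel
  twice <- filter_variant_call_rate(once)$panel
  expect_identical(once$variants$id, twice$variants$id)
  suppressMessages({
    once_i <- filter_info(panel, 0.5)$panel
    twice_i <- filter_info(once_i, 0.5)$panel
  })
  expect_identical(once_i$variants$id, twice_i$variants$id)
  once_h <- filter_hwe(panel, 1e-6)$panel
  expect_identical(once_h$variants$id,
                   filter_hwe(once_h, 1e-6)$panel$variants$id)
})

test_that("run_qc applies the fixed stage order with consistent counts", {
  miss <- matrix(FALSE, 40, 10)
  miss[1:6, 1] <- TRUE
  panel <- panel_with_missing(miss, seed = 13)
  suppressMessages(res <- run_qc(panel, qc_thresholds(pca_k = 3)))
  expect_equal(res$counts$stage,
               c("input", "variant_call_rate", "sample_call_rate",
                 "heterozygosity", "relatedness", "pca_outlier", "hwe",
                 "info"))
  expect_true(all(diff(res$counts$n_variants) <= 0))
  expect_true(all(diff(res$counts$n_samples) <= 0))
  # every removal is accounted for in the report
  expect_equal(res$counts$n_variants[1] - dplyr::last(res$counts$n_variants),
               sum(res$report$unit == "variant"))
})
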