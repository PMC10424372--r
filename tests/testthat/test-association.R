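test_that("logistic fit on a 2x2 table equals the closed-form odds ratio", {
  d <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  st <- c(rep(1, 100), rep(0, 100))
  res <- tidy(fit_logistic(d, st))
  expect_equal(res$or, 27 / 7, tolerance = 1e-6)
  expect_equal(res$beta, log(27 / 7), tolerance = 1e-6)
  expect_equal(res$se, sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90),
               tolerance = 1e-6)
  expect_equal(res$n_cases, 100L)
  gl <- glance(fit_logistic(d, st))
  expect_true(gl$converged)
})

test_that("logistic fit matches closed-form 2x2 log-OR on random tables", {
  set.seed(44)
  for (i in 1:50) {
    cells <- sample(5:60, 4, replace = TRUE)  # a,b,c,d
    d <- c(rep(1, cells[1]), rep(0, cells[2]),
           rep(1, cells[3]), rep(0, cells[4]))
    st <- rep(c(1, 0), c(cells[1] + cells[2], cells[3] + cells[4]))
    res <- tidy(fit_logistic(d, st))
    expect_equal(res$beta, log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-6)
    expect_equal(res$se, sqrt(sum(1 / cells)), tolerance = 1e-6)
  }
})

test_that("separation and rank deficiency are surfaced, not silent", {
  st <- rep(c(1, 0), each = 25)
  d_sep <- as.numeric(st)  # perfect separation
  expect_warning(fit_logistic(d_sep, st), "separation")
  covar <- data.frame(x1 = rnorm(50))
  covar$x2 <- covar$x1 * 2
  expect_error(
    fit_logistic(rbinom(50, 2, 0.3), st, covariates = covar),
    "rank deficient")
  expect_error(fit_logistic(rbinom(10, 2, .3), rep(1, 10)), "control")
})

test_that("a huge effect at a rare allele propagates a separation warning", {
  set.seed(2)
  sim <- simulate_panel(sim_params(seq_length = 5e5, n_afr = 5,
                                   n_nonafr = 40, seed = 14))
  id <- sim$panel$variants$id[which(allele_freq(sim$panel) > 0.01)[1]]
  pp <- pheno_params(beta0 = -8, causal = stats::setNames(30, id), seed = 3)
  ph <- simulate_phenotypes(sim$panel, pp)
  expect_warning(
    fit_logistic(dosages(sim$panel)[ph$sample, id], ph$status, snp = id),
    "separation")
})

test_that("the vectorised scan agrees with per-variant glm fits", {
  set.seed(10)
  n <- 300
  G <- random_dosages(n, runif(12, 0.1, 0.5))
  age <- rnorm(n, 55, 8)
  sex <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.3 + 0.4 * G[, 3] + 0.02 * (age - 55)))
  sc <- logistic_scan(G, y, covariates = cbind(age = age, sex = sex))
  for (j in c(1, 3, 7, 12)) {
    f <- glm(y ~ G[, j] + age + sex, family = binomial())
    expect_equal(sc$beta[j], unname(coef(f)[2]), tolerance = 1e-6)
    expect_equal(sc$se[j], unname(summary(f)$coefficients[2, 2]),
                 tolerance = 1e-6)
  }
  expect_true(all(sc$converged))
})

test_that("null genotypes stay within two standard errors most of the time", {
  set.seed(55)
  G <- random_dosages(2000, runif(200, 0.1, 0.5))
  y <- rbinom(2000, 1, 0.5)
  sc <- logistic_scan(G, y)
  expect_gte(mean(abs(sc$beta) < 2 * sc$se), 0.93)
})

test_that("r2 and D' reproduce hand-computed haplotype LD", {
  g <- random_dosages(50, c(0.3, 0.3))
  expect_equal(ld_r2(g[, 1], g[, 1]), 1)
  # perfectly complementary haplotypes
  h1 <- rep(c(1, 0), 50)
  h2 <- 1 - h1
  expect_equal(ld_r2(h1, h2), 1)
  expect_equal(ld_dprime(h1, h2), 1)
  # counts AB=40, Ab=10, aB=10, ab=40
  h1 <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  h2 <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  expect_equal(ld_r2(h1, h2), 0.36)
  expect_equal(ld_dprime(h1, h2), 0.6)
  expect_message(r0 <- ld_r2(rep(0, 50), g[, 1]), "monomorphic")
  expect_equal(r0, 0)
})

test_that("ld_matrix matches pairwise ld_r2 and handles monomorphics", {
  set.seed(9)
  G <- random_dosages(80, c(0.2, 0.4, 0.5))
  G <- cbind(G, mono = 0L)
  ld <- ld_matrix(G)
  expect_equal(dim(ld), c(4, 4))
  expect_equal(diag(ld), rep(1, 4), ignore_attr = TRUE)
  expect_equal(ld[1, 2], ld_r2(G[, 1], G[, 2]))
  expect_equal(ld[1, 4], 0)
})

test_that("greedy pruning keeps the lowest-P variant per LD block", {
  res <- tibble::tibble(snp = c("A", "B", "C"),
                        wald_p = c(1e-5, 1e-3, 1e-4),
                        pos = c(100, 200, 300))
  ld <- matrix(c(1, 0.6, 0.1,
                 0.6, 1, 0.6,
                 0.1, 0.6, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  kept <- greedy_prune(res, ld, 0.5)
  expect_equal(sort(kept$snp), c("A", "C"))
  # pair: keep only the smaller P
  kept2 <- greedy_prune(res[1:2, ], ld[1:2, 1:2], 0.5)
  expect_equal(kept2$snp, "A")
  # single variant trivially kept
  expect_equal(nrow(greedy_prune(res[1, ], ld, 0.5)), 1)
  expect_error(greedy_prune(tibble::tibble(snp = "Z", wald_p = 0.1), ld),
               "lacks")
})

test_that("pruned output never contains a pair above the r2 threshold", {
  set.seed(23)
  sim <- simulate_panel(sim_params(seq_length = 2e6, n_afr = 10,
                                   n_nonafr = 30, seed = 88))
  calls <- find_asnps(sim$panel, constant_rate_map(1, 2e6),
                      cfg = ils_config(g_div = 37900))
  eur <- sim$panel$samples$sample[sim$panel$samples$population == "EUR"]
  d <- dosages(sim$panel)[eur, calls$asnps$id, drop = FALSE]
  ld <- ld_matrix(d)
  res <- tibble::tibble(snp = calls$asnps$id, wald_p = runif(nrow(calls$asnps)),
                        pos = calls$asnps$pos)
  kept <- greedy_prune(res, ld, 0.5)
  off <- ld[kept$snp, kept$snp]
  diag(off) <- 0
  expect_lte(max(off), 0.5)
})

test_that("independent-test counting follows the greedy construction", {
  ids <- paste0("s", 1:10)
  ld_lo <- matrix(0.1, 10, 10, dimnames = list(ids, ids)); diag(ld_lo) <- 1
  expect_equal(count_independent(ids, ld_lo, 0.8), 10)
  ld_hi <- matrix(0.9, 10, 10, dimnames = list(ids, ids)); diag(ld_hi) <- 1
  expect_equal(count_independent(ids, ld_hi, 0.8), 1)
  # hand-traced 6-variant case: keep s1, s3, s5
  ids6 <- paste0("s", 1:6)
  m <- matrix(0.1, 6, 6, dimnames = list(ids6, ids6))
  m["s1", "s2"] <- m["s2", "s1"] <- 0.9
  m["s2", "s3"] <- m["s3", "s2"] <- 0.85
  m["s3", "s4"] <- m["s4", "s3"] <- 0.9
  m["s5", "s6"] <- m["s6", "s5"] <- 0.9
  diag(m) <- 1
  expect_equal(count_independent(ids6, m, 0.8), 3)
})

test_that("Bonferroni thresholds reproduce the published arithmetic", {
  expect_equal(signif(bonferroni_threshold(19623), 3), 2.55e-6)
  expect_equal(signif(bonferroni_threshold(21780), 3), 2.30e-6)
  expect_equal(signif(bonferroni_threshold(21965), 3), 2.28e-6)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(200, 0.05) * 200, 0.05)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("the genomic inflation factor is anchored at the null median", {
  p <- seq(0.001, 0.999, length.out = 101)  # median exactly 0.5
  expect_equal(genomic_lambda(p = p), 1.0)
  chisq <- stats::rchisq(5000, 1)
  expect_equal(genomic_lambda(chisq = 3 * chisq),
               3 * genomic_lambda(chisq = chisq))
  expect_warning(genomic_lambda(p = runif(10)), "unstable")
  expect_error(genomic_lambda(), "supply")
})

test_that("lambda is near one for null Wald statistics", {
  set.seed(70)
  G <- random_dosages(800, runif(1500, 0.1, 0.5))
  y <- rbinom(800, 1, 0.5)
  sc <- logistic_scan(G, y)
  lam <- genomic_lambda(p = sc$wald_p)
  expect_gt(lam, 0.9)
  expect_lt(lam, 1.1)
})

test_that("concordance requires agreement of direction and significance", {
  base <- tibble::tibble(snp = "rs1", study = c("g1", "g2", "g3"),
                         beta = c(0.3, 0.2, 0.25),
                         p = c(0.01, 0.03, 0.001), effect_allele = "T")
  expect_true(concordance_filter(base)$pass)
  flip <- base; flip$beta[3] <- -0.1
  expect_false(concordance_filter(flip)$pass)
  weak <- base; weak$p[2] <- 0.06
  expect_false(concordance_filter(weak)$pass)
  bad <- base; bad$effect_allele <- c("T", "T", "A")
  expect_error(concordance_filter(bad), "allele")
})

test_that("assoc_scan recovers a planted effect through the panel interface", {
  set.seed(61)
  sim <- simulate_panel(sim_params(seq_length = 1e6, n_afr = 5,
                                   n_nonafr = 250, seed = 51))
  freq <- allele_freq(sim$panel, "EUR")
  id <- sim$panel$variants$id[which(freq > 0.2 & freq < 0.6)[1]]
  pp <- pheno_params(beta0 = -0.4, causal = stats::setNames(log(2), id),
                     beta_age = 0.01, seed = 8)
  eur <- sim$panel$samples$sample[sim$panel$samples$population == "EUR"]
  ph <- simulate_phenotypes(sim$panel, pp, samples = eur)
  res <- assoc_scan(sim$panel, ph, snps = id,
                    covariates = c("age", "sex"), engine = "glm")
  expect_gt(res$ci_upper, 2)   # true OR = 2 inside the 95% CI
  expect_lt(res$ci_lower, 2)
  expect_lt(res$wald_p, 0.05)
  res2 <- assoc_scan(sim$panel, ph, snps = id, covariates = c("age", "sex"),
                     engine = "scan")
  expect_equal(res2$beta, res$beta, tolerance = 1e-6)
})
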