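#' Parameters for the admixed-panel simulator
#'
#' The simulator produces a phased panel for one African outgroup population
#' and one or two non-African target populations, an archaic pseudo-genome,
#' and per-haplotype ground-truth tracts. Archaic-origin sequence enters
#' non-African haplotypes through two routes with distinct length scales:
#'
#' * introgressed tracts, broken down by recombination over `g_adm`
#'   generations since admixture, so lengths are exponential with mean
#'   `1/(r_bp * g_adm)` bp (`r_bp` = rate in cM/Mb times 1e-8);
#' * incomplete-lineage-sorting (ILS) tracts, shared segments surviving from
#'   the common ancestral population and therefore broken down over the much
#'   larger `g_div` generations, with mean length `1/(r_bp * g_div)`.
#'
#' ILS tracts are genome-level entities carried by random haplotypes in all
#' populations; with probability `pi_afr_loss` an ILS tract has drifted out
#' of the African outgroup entirely, which is the case the segment-length
#' test (rather than outgroup sharing) must catch.
#'
#' Defaults mirror genome-wide observations for Neandertal admixture: ~2%
#' archaic ancestry in non-Africans from an admixture pulse ~55 thousand
#' years ago (1900 generations at 29 years), and an archaic-modern
#' divergence of ~550 thousand years on each branch (37 900 total branch
#' generations).
#'
#' @param seq_length Simulated chromosome length in bp.
#' @param n_afr,n_nonafr,n_nonafr2 Diploid sample counts for the African
#'   outgroup and the non-African population(s); `n_nonafr2 = 0` disables the
#'   second target population.
#' @param p_adm Expected introgressed genome fraction per non-African
#'   haplotype.
#' @param p_adm2 Introgressed fraction for the second target population
#'   (defaults to `1.15 * p_adm`, reflecting elevated archaic ancestry in
#'   East Asians).
#' @param g_adm Generations since admixture.
#' @param g_div Total branch generations separating archaic and modern
#'   lineages.
#' @param mu_arch Density (per bp) of archaic-marker sites; positions are
#'   drawn once genome-wide so sites are shared across haplotypes, and a
#'   site segregates only where covered by an archaic-origin tract.
#' @param mu_bg Density (per bp) of neutral background SNPs.
#' @param q_ils Genome fraction covered by ILS tract entities.
#' @param pi_afr_loss Probability an ILS tract is absent from every African
#'   haplotype.
#' @param ils_carrier_p Probability that any given haplotype carries a given
#'   ILS tract entity.
#' @param rate Constant recombination rate in cM/Mb (ignored when `map`
#'   given).
#' @param map Optional [genetic_map()]; tract lengths are drawn in genetic
#'   distance and mapped back to bp, so rate heterogeneity is honoured.
#' @param missing_rate,genotype_error_rate Per-allele probabilities of
#'   missingness and allele flips applied to the modern panel.
#' @param afr_label,nonafr_labels Population labels.
#' @param seed Optional RNG seed for bit-reproducibility.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(seq_length = 1e7, n_afr = 50, n_nonafr = 50,
                       n_nonafr2 = 0, p_adm = 0.02, p_adm2 = NULL,
                       g_adm = 1900, g_div = 37900,
                       mu_arch = 1e-3, mu_bg = 1e-3,
                       q_ils = 0.01, pi_afr_loss = 0.3, ils_carrier_p = 0.25,
                       rate = 1, map = NULL,
                       missing_rate = 0, genotype_error_rate = 0,
                       afr_label = "AFR",
                       nonafr_labels = c("EUR", "EAS"), seed = NULL) {
  if (is.null(p_adm2)) p_adm2 <- 1.15 * p_adm
  stopifnot(seq_length > 0, n_afr >= 1, n_nonafr >= 1, n_nonafr2 >= 0,
            p_adm >= 0, p_adm <= 1, q_ils >= 0, q_ils <= 1,
            pi_afr_loss >= 0, pi_afr_loss <= 1,
            ils_carrier_p > 0, ils_carrier_p <= 1,
            mu_arch > 0, mu_bg > 0, g_adm > 0)
  if (g_adm >= g_div) {
    stop("`g_adm` must be smaller than `g_div`", call. = FALSE)
  }
  if (p_adm + q_ils >= 1) {
    stop("`p_adm` + `q_ils` must be < 1", call. = FALSE)
  }
  structure(
    list(seq_length = seq_length, n_afr = n_afr, n_nonafr = n_nonafr,
         n_nonafr2 = n_nonafr2, p_adm = p_adm, p_adm2 = p_adm2,
         g_adm = g_adm, g_div = g_div, mu_arch = mu_arch, mu_bg = mu_bg,
         q_ils = q_ils, pi_afr_loss = pi_afr_loss,
         ils_carrier_p = ils_carrier_p, rate = rate, map = map,
         missing_rate = missing_rate,
         genotype_error_rate = genotype_error_rate,
         afr_label = afr_label, nonafr_labels = nonafr_labels, seed = seed),
    class = "sim_params"
  )
}

# renewal process of alternating gaps and tracts over [0, total), both
# exponential; stationary coverage equals `fraction`
draw_tracts <- function(total, mean_len, fraction) {
  if (fraction <= 0 || total <= 0) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  mean_gap <- mean_len * (1 - fraction) / fraction
  n_guess <- ceiling(total / (mean_len + mean_gap) * 1.6) + 20L
  starts <- ends <- numeric(0)
  cursor <- 0
  while (cursor < total) {
    gaps <- stats::rexp(n_guess, 1 / mean_gap)
    lens <- stats::rexp(n_guess, 1 / mean_len)
    s <- cursor + cumsum(gaps) + c(0, cumsum(lens)[-n_guess])
    e <- s + lens
    starts <- c(starts, s)
    ends <- c(ends, e)
    cursor <- ends[length(ends)]
  }
  keep <- starts < total
  starts <- starts[keep]
  ends <- pmin(ends[keep], total)
  tibble::tibble(start = starts, end = ends)
}

# map an interval table drawn in cumulative-cM space back to bp
cm_to_bp <- function(map, tr) {
  if (nrow(tr) == 0) return(tibble::tibble(start = numeric(), end = numeric()))
  inv <- function(cmv) {
    stats::approx(map$cm, map$pos, xout = cmv, rule = 2,
                  ties = "ordered")$y
  }
  out <- tibble::tibble(start = inv(tr$start), end = inv(tr$end))
  out[out$end - out$start >= 1, , drop = FALSE]
}

# TRUE for each x covered by one of the disjoint intervals (sorted by start)
covered_by <- function(x, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(x)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  i <- findInterval(x, starts)
  i > 0 & x < ends[pmax(i, 1L)]
}

#' Simulate an admixed haplotype panel with ground truth
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `panel` (a [haplotype_panel()] whose archaic
#'   slot is homozygous derived at every archaic-marker site), `truth`
#'   (tibble of per-haplotype tracts: `chrom`, `start`, `end`, `hap`,
#'   `origin`), and `sites` (tibble flagging each panel variant as
#'   `archaic` or `background`).
#' @export
simulate_panel <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  L <- params$seq_length
  map <- if (is.null(params$map)) constant_rate_map(params$rate, L) else
    params$map
  total_cm <- interp_cm(map, L) - interp_cm(map, 0)
  mean_cm_adm <- 100 / params$g_adm   # Morgans = cM / 100
  mean_cm_ils <- 100 / params$g_div
  mean_rate <- total_cm / (L / 1e6)
  mean_bp_adm <- 1 / (mean_rate * 1e-8 * params$g_adm)
  if (L < mean_bp_adm) {
    warning("sequence shorter than one mean introgressed tract; ",
            "tract statistics will be unstable")
  }

  pops <- c(rep(params$afr_label, params$n_afr),
            rep(params$nonafr_labels[1], params$n_nonafr),
            if (params$n_nonafr2 > 0)
              rep(params$nonafr_labels[2], params$n_nonafr2))
  n_dip <- length(pops)
  samples <- tibble::tibble(
    sample = paste0(pops, "_", stats::ave(seq_along(pops), pops,
                                          FUN = seq_along)),
    population = pops
  )
  n_hap <- 2L * n_dip
  hpop <- rep(pops, each = 2)
  hid <- paste(rep(samples$sample, each = 2), rep(0:1, n_dip), sep = "|")
  is_afr_hap <- hpop == params$afr_label

  # per-haplotype introgressed tracts (non-African haplotypes only)
  hap_tracts <- vector("list", n_hap)
  truth <- vector("list", n_hap)
  for (h in seq_len(n_hap)) {
    if (is_afr_hap[h]) {
      hap_tracts[[h]] <- tibble::tibble(start = numeric(), end = numeric())
      next
    }
    p_h <- if (hpop[h] == params$nonafr_labels[1]) params$p_adm else
      params$p_adm2
    tr <- cm_to_bp(map, draw_tracts(total_cm, mean_cm_adm, p_h))
    hap_tracts[[h]] <- tr
    if (nrow(tr) > 0) {
      truth[[h]] <- tibble::tibble(chrom = "1", start = tr$start,
                                   end = tr$end, hap = hid[h],
                                   origin = "introgressed")
    }
  }

  # genome-level ILS tract entities, assigned to random carrier haplotypes
  ils <- cm_to_bp(map, draw_tracts(total_cm, mean_cm_ils, params$q_ils))
  ils_truth <- list()
  if (nrow(ils) > 0) {
    afr_lost <- stats::runif(nrow(ils)) < params$pi_afr_loss
    for (k in seq_len(nrow(ils))) {
      carrier <- stats::runif(n_hap) < params$ils_carrier_p
      if (afr_lost[k]) carrier[is_afr_hap] <- FALSE
      for (h in which(carrier)) {
        tr <- hap_tracts[[h]]
        # keep per-haplotype tracts disjoint: skip carriers where the ILS
        # entity would overlap an introgressed tract
        if (nrow(tr) > 0 &&
            any(tr$start < ils$end[k] & ils$start[k] < tr$end)) next
        hap_tracts[[h]] <- dplyr::bind_rows(
          tr, tibble::tibble(start = ils$start[k], end = ils$end[k]))
        ils_truth[[length(ils_truth) + 1L]] <- tibble::tibble(
          chrom = "1", start = ils$start[k], end = ils$end[k],
          hap = hid[h], origin = "ILS")
      }
    }
  }
  truth <- dplyr::bind_rows(c(truth, ils_truth))
  if (nrow(truth) > 0) {
    truth <- dplyr::arrange(truth, .data$hap, .data$start)
  } else {
    truth <- tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric(), hap = character(),
                            origin = character())
  }

  # candidate archaic-marker positions, shared across the panel
  arch_pos <- sort(unique(floor(
    stats::runif(stats::rpois(1, params$mu_arch * L), 0, L))))
  bg_pos <- sort(unique(floor(
    stats::runif(stats::rpois(1, params$mu_bg * L), 0, L))))
  bg_pos <- setdiff(bg_pos, arch_pos)

  arch_carry <- matrix(FALSE, nrow = length(arch_pos), ncol = n_hap)
  for (h in seq_len(n_hap)) {
    tr <- hap_tracts[[h]]
    if (nrow(tr) > 0) {
      arch_carry[, h] <- covered_by(arch_pos, tr$start, tr$end)
    }
  }
  seg_sites <- rowSums(arch_carry) > 0
  arch_pos <- arch_pos[seg_sites]
  arch_carry <- arch_carry[seg_sites, , drop = FALSE]

  bg_freq <- stats::runif(length(bg_pos))
  bg_alleles <- matrix(
    stats::runif(length(bg_pos) * n_hap) < bg_freq,
    nrow = length(bg_pos), ncol = n_hap)
  # the African outgroup retains ancestral diversity at neutral sites: a
  # background derived allele never fixes in the outgroup panel
  afr_cols <- which(is_afr_hap)
  lost <- which(rowSums(bg_alleles[, afr_cols, drop = FALSE]) ==
                  length(afr_cols))
  if (length(lost) > 0) {
    flip <- afr_cols[sample.int(length(afr_cols), length(lost),
                                replace = TRUE)]
    bg_alleles[cbind(lost, flip)] <- FALSE
  }
  bg_poly <- rowSums(bg_alleles) > 0 & rowSums(bg_alleles) < n_hap
  bg_pos <- bg_pos[bg_poly]
  bg_alleles <- bg_alleles[bg_poly, , drop = FALSE]

  pos <- c(arch_pos, bg_pos)
  origin <- rep(c("archaic", "background"),
                c(length(arch_pos), length(bg_pos)))
  o <- order(pos)
  pos <- pos[o]; origin <- origin[o]
  haps <- rbind(arch_carry, bg_alleles)[o, , drop = FALSE]
  storage.mode(haps) <- "integer"

  if (params$genotype_error_rate > 0 && length(haps) > 0) {
    flip <- stats::runif(length(haps)) < params$genotype_error_rate
    haps[flip] <- 1L - haps[flip]
  }
  if (params$missing_rate > 0 && length(haps) > 0) {
    haps[stats::runif(length(haps)) < params$missing_rate] <- NA_integer_
  }

  nucs <- c("A", "C", "G", "T")
  ref <- sample(nucs, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), character(1))
  variants <- tibble::tibble(
    chrom = "1", pos = as.integer(pos),
    id = paste0("snv_", pos + 1L), ref = ref, alt = unname(alt),
    info_score = NA_real_
  )
  archaic <- cbind(as.integer(origin == "archaic"),
                   as.integer(origin == "archaic"))

  panel <- haplotype_panel(variants, haps, samples, archaic = archaic,
                           outgroup = params$afr_label)
  sites <- tibble::tibble(id = variants$id, pos = variants$pos,
                          origin = origin)
  list(panel = panel, truth = truth, sites = sites)
}

#' Parameters for case-control phenotype simulation
#'
#' @param beta0 Intercept on the log-odds scale (sets baseline prevalence).
#' @param causal Named numeric vector of per-allele log odds ratios, named
#'   by variant id (`NULL` for a null phenotype).
#' @param beta_age,beta_sex Covariate effects on the log-odds scale.
#' @param age_mean,age_sd Normal age distribution (years).
#' @param sex_p Probability of sex code 1.
#' @param seed Optional RNG seed.
#' @return A list of class `pheno_params`.
#' @export
pheno_params <- function(beta0 = 0, causal = NULL, beta_age = 0,
                         beta_sex = 0, age_mean = 60, age_sd = 10,
                         sex_p = 0.5, seed = NULL) {
  structure(list(beta0 = beta0, causal = causal, beta_age = beta_age,
                 beta_sex = beta_sex, age_mean = age_mean, age_sd = age_sd,
                 sex_p = sex_p, seed = seed),
            class = "pheno_params")
}

#' Simulate case-control status and covariates under a logistic model
#'
#' Disease status is Bernoulli with
#' `logit(P) = beta0 + sum(beta_g * dosage) + beta_age * age + beta_sex * sex`,
#' the generative mirror of the logistic model fitted by [fit_logistic()].
#'
#' @param panel A [haplotype_panel()].
#' @param pp A [pheno_params()] object.
#' @param samples Optional character vector restricting to a subset of
#'   samples (e.g. the non-African populations).
#' @return A tibble with columns `sample`, `status` (0/1), `age`, `sex`.
#' @export
simulate_phenotypes <- function(panel, pp, samples = NULL) {
  stopifnot(inherits(pp, "pheno_params"))
  if (!is.null(pp$seed)) set.seed(pp$seed)
  ids <- if (is.null(samples)) panel$samples$sample else samples
  n <- length(ids)
  age <- stats::rnorm(n, pp$age_mean, pp$age_sd)
  sex <- as.integer(stats::runif(n) < pp$sex_p)
  lin <- pp$beta0 + pp$beta_age * age + pp$beta_sex * sex
  if (!is.null(pp$causal) && length(pp$causal) > 0) {
    missing_ids <- setdiff(names(pp$causal), panel$variants$id)
    if (length(missing_ids) > 0) {
      stop("causal variant(s) absent from panel: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    d <- dosages(panel)[ids, names(pp$causal), drop = FALSE]
    d[is.na(d)] <- 0
    lin <- lin + as.vector(d %*% pp$causal)
  }
  prob <- stats::plogis(lin)
  tibble::tibble(sample = ids,
                 status = as.integer(stats::runif(n) < prob),
                 age = age, sex = sex)
}

#' Sample a retrospective case-control genotype study
#'
#' Draws genotype dosages for a fixed number of cases and controls at a
#' single biallelic SNP under Hardy-Weinberg genotype frequencies and a
#' per-allele odds ratio: control genotypes follow `Binomial(2, maf)` (rare
#' disease approximation) and case genotype probabilities are proportional
#' to `HWE(g) * OR^g`.
#'
#' @param n_cases,n_controls Group sizes.
#' @param maf Effect-allele frequency in the source population.
#' @param or Per-allele odds ratio.
#' @return A tibble with columns `status` (1 = case) and `dosage`.
#' @export
simulate_case_control <- function(n_cases, n_controls, maf, or) {
  hwe <- stats::dbinom(0:2, 2, maf)
  case_p <- hwe * or^(0:2)
  case_p <- case_p / sum(case_p)
  tibble::tibble(
    status = rep(c(1L, 0L), c(n_cases, n_controls)),
    dosage = c(sample(0:2, n_cases, replace = TRUE, prob = case_p),
               stats::rbinom(n_controls, 2, maf))
  )
}
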