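# Shared fixture builders. Everything is generated in code; no binary files.

# Hand-built panel: 2 AFR samples (all ref), 2 EUR samples, archaic genome
# homozygous alt everywhere. EUR_1 haplotype 0 carries the alt allele at the
# first three sites; site 4 is carried only by EUR_2 haplotype 0.
toy_candidate_panel <- function(pos = c(10000, 20000, 30000, 40000)) {
  n_var <- length(pos)
  variants <- tibble::tibble(
    chrom = "1", pos = as.integer(pos),
    id = paste0("v", seq_len(n_var)),
    ref = "A", alt = "G", info_score = NA_real_
  )
  haps <- matrix(0L, n_var, 8)  # AFR_1, AFR_2, EUR_1, EUR_2 (2 cols each)
  haps[1:3, 5] <- 1L            # EUR_1 side 0
  haps[4, 7] <- 1L              # EUR_2 side 0
  samples <- tibble::tibble(
    sample = c("AFR_1", "AFR_2", "EUR_1", "EUR_2"),
    population = c("AFR", "AFR", "EUR", "EUR")
  )
  archaic <- matrix(1L, n_var, 2)
  haplotype_panel(variants, haps, samples, archaic = archaic,
                  outgroup = "AFR")
}

# random panel for round-trip tests, with missingness and INFO scores
random_panel <- function(n_var = 20, n_samples = 6, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(1e5, n_var))
  nucs <- c("A", "C", "G", "T")
  ref <- sample(nucs, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), character(1))
  variants <- tibble::tibble(
    chrom = "1", pos = pos, id = paste0("rs", seq_len(n_var)),
    ref = ref, alt = unname(alt),
    info_score = round(stats::runif(n_var), 3)
  )
  haps <- matrix(sample(c(0L, 1L, NA), n_var * 2 * n_samples,
                        replace = TRUE, prob = c(.6, .3, .1)),
                 n_var, 2 * n_samples)
  samples <- tibble::tibble(
    sample = paste0("S", seq_len(n_samples)),
    population = rep(c("AFR", "EUR"), length.out = n_samples)
  )
  archaic <- matrix(sample(c(0L, 1L, NA), n_var * 2, replace = TRUE),
                    n_var, 2)
  haplotype_panel(variants, haps, samples, archaic = archaic,
                  outgroup = "AFR")
}

# write VCF text lines directly (independent of write_vcf)
write_raw_vcf <- function(path, body_lines,
                          samples = c("S1", "S2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body_lines), path)
  path
}

# dosage matrix with given per-column allele frequencies
random_dosages <- function(n, freqs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(freqs)
  g <- matrix(stats::rbinom(n * m, 2, rep(freqs, each = n)), n, m)
  colnames(g) <- paste0("snp", seq_len(m))
  g
}

# independent brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  cur <- 1
  for (k in seq_along(o)) {
    i <- o[k]
    r <- m - k + 1
    cur <- min(cur, m * p[i] / r)
    adj[i] <- cur
  }
  adj
}
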