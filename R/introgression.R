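#' Configuration of the lineage-sorting segment-length model
#'
#' A shared segment surviving by incomplete lineage sorting (ILS) has been
#' exposed to recombination along both branches since the archaic-modern
#' divergence, so its expected length is `1/(r_bp * g_div)` bp, where
#' `r_bp` is the local per-bp recombination probability per generation and
#' `g_div` the total branch generations. By default `g_div` is derived from
#' a divergence of 550 thousand years per branch and a 29-year generation
#' time.
#'
#' @param t_div_years Divergence time per branch in years.
#' @param gen_years Generation time in years.
#' @param g_div Total branch generations; overrides the time-based default
#'   `2 * t_div_years / gen_years` when given.
#' @param min_markers Minimum markers per tested segment (default 2; a
#'   single marker spans zero length and is untestable).
#' @param conservative_two_maps When two maps are supplied to
#'   [score_segments()], use for each segment the larger of the two
#'   expected ILS lengths, making ILS harder to reject.
#' @return A list of class `ils_config`.
#' @export
ils_config <- function(t_div_years = 550000, gen_years = 29, g_div = NULL,
                       min_markers = 2, conservative_two_maps = FALSE) {
  if (is.null(g_div)) g_div <- 2 * t_div_years / gen_years
  stopifnot(g_div > 0, min_markers >= 1)
  structure(list(t_div_years = t_div_years, gen_years = gen_years,
                 g_div = g_div, min_markers = min_markers,
                 conservative_two_maps = conservative_two_maps),
            class = "ils_config")
}

#' Apply the archaic allele-sharing site criteria
#'
#' A variant is a candidate archaic SNP when (a) one of its alleles is
#' shared between the archaic genome and at least one non-African
#' population, (b) that allele is absent from the African outgroup, and
#' (c) the archaic individual carries it in homozygous state. Sites with a
#' missing archaic genotype are ineligible.
#'
#' @param panel A [haplotype_panel()] with an archaic genome, already
#'   restricted to biallelic SNVs.
#' @param afr_pop African outgroup population label; defaults to the
#'   panel's `outgroup` attribute.
#' @return A tibble with one row per variant: `idx`, `id`, `pos`,
#'   `archaic_allele` (0 = ref, 1 = alt, `NA` when undefined), per-criterion
#'   logical flags `crit_a`, `crit_b`, `crit_c`, the archaic-allele
#'   frequencies `afr_freq` and `nonafr_freq` (maximum over non-African
#'   populations), and `candidate`.
#' @export
apply_site_criteria <- function(panel, afr_pop = NULL) {
  if (is.null(afr_pop)) afr_pop <- panel$outgroup
  pops <- unique(panel$samples$population)
  if (is.null(afr_pop) || !afr_pop %in% pops) {
    stop("African outgroup population not present in panel", call. = FALSE)
  }
  nonafr <- setdiff(pops, afr_pop)
  if (length(nonafr) == 0) {
    stop("panel has no non-African population", call. = FALSE)
  }
  if (is.null(panel$archaic)) {
    stop("panel carries no archaic genome", call. = FALSE)
  }
  arc <- panel$archaic
  hom <- !is.na(arc[, 1]) & !is.na(arc[, 2]) & arc[, 1] == arc[, 2]
  allele <- ifelse(hom, arc[, 1], NA_integer_)

  alt_afr <- allele_freq(panel, afr_pop)
  alt_non <- vapply(nonafr, function(p) allele_freq(panel, p),
                    numeric(n_variants(panel)))
  alt_non <- matrix(alt_non, nrow = n_variants(panel))
  # frequency of the archaic allele (ref-coded sites flip)
  freq_of <- function(altf) ifelse(is.na(allele), NA_real_,
                                   ifelse(allele == 1L, altf, 1 - altf))
  afr_freq <- freq_of(alt_afr)
  nonafr_freq <- if (length(nonafr) == 1) freq_of(alt_non[, 1]) else
    do.call(pmax, c(lapply(seq_along(nonafr),
                           function(j) freq_of(alt_non[, j])),
                    list(na.rm = TRUE)))
  crit_c <- hom
  crit_b <- !is.na(afr_freq) & afr_freq == 0
  crit_a <- !is.na(nonafr_freq) & nonafr_freq > 0
  tibble::tibble(
    idx = seq_len(n_variants(panel)),
    id = panel$variants$id,
    pos = panel$variants$pos,
    archaic_allele = allele,
    afr_freq = afr_freq,
    nonafr_freq = nonafr_freq,
    crit_a = crit_a, crit_b = crit_b, crit_c = crit_c,
    candidate = crit_a & crit_b & crit_c
  )
}

#' Build per-haplotype candidate marker segments
#'
#' On each non-African haplotype, maximal runs of consecutive candidate
#' sites at which the haplotype carries the archaic allele form a segment;
#' a run is broken by any candidate site where the haplotype carries the
#' non-archaic allele (missing alleles neither extend nor break a run).
#' Runs with fewer than `min_markers` markers are discarded. The segment
#' interval spans the first to the last marker, so its length is the
#' distance between them.
#'
#' @param panel A [haplotype_panel()].
#' @param candidates Output of [apply_site_criteria()].
#' @param min_markers Minimum markers per segment (default 2).
#' @param afr_pop African outgroup label (haplotypes of this population are
#'   not segment substrates); defaults to the panel's `outgroup`.
#' @return A tibble with columns `hap`, `sample`, `side`, `start`, `end`,
#'   `n_markers`, `length`.
#' @export
build_segments <- function(panel, candidates, min_markers = 2,
                           afr_pop = NULL) {
  if (is.null(afr_pop)) afr_pop <- panel$outgroup
  cand <- candidates[candidates$candidate, , drop = FALSE]
  empty <- tibble::tibble(hap = character(), sample = character(),
                          side = integer(), start = numeric(),
                          end = numeric(), n_markers = integer(),
                          length = numeric())
  if (nrow(cand) == 0) return(empty)
  h <- panel$haplotypes[cand$idx, , drop = FALSE]
  carrier <- h == rep(cand$archaic_allele, times = ncol(h))
  pops <- hap_pops(panel)
  ids <- hap_ids(panel)
  out <- vector("list", ncol(h))
  for (col in seq_len(ncol(h))) {
    if (!is.null(afr_pop) && pops[col] == afr_pop) next
    v <- carrier[, col]
    obs <- which(!is.na(v))
    if (length(obs) == 0) next
    r <- rle(v[obs])
    ends_at <- cumsum(r$lengths)
    starts_at <- ends_at - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_markers)
    if (length(runs) == 0) next
    first_idx <- obs[starts_at[runs]]
    last_idx <- obs[ends_at[runs]]
    out[[col]] <- tibble::tibble(
      hap = ids[col],
      sample = panel$samples$sample[(col + 1L) %/% 2L],
      side = (col + 1L) %% 2L,
      start = cand$pos[first_idx],
      end = cand$pos[last_idx],
      n_markers = r$lengths[runs],
      length = cand$pos[last_idx] - cand$pos[first_idx]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Expected ILS segment length at a local recombination rate
#'
#' @param rate Mean local recombination rate in cM/Mb (vectorised).
#' @param cfg An [ils_config()] (or a bare `g_div` via `cfg = NULL` is not
#'   supported; pass a config).
#' @return Expected length in bp; `Inf` at rate 0 (segment untestable, its
#'   p-value is 1).
#' @export
expected_ils_length <- function(rate, cfg = ils_config()) {
  if (any(rate < 0)) stop("recombination rate must be >= 0", call. = FALSE)
  ifelse(rate == 0, Inf, 1 / (rate * 1e-8 * cfg$g_div))
}

#' Tail probability of a segment length under lineage sorting
#'
#' Tract lengths under recombination breakdown are modelled as exponential
#' (memoryless), so the probability that an ILS segment is at least `len`
#' long is `exp(-len / e_len)`. An infinite `e_len` (zero recombination)
#' yields p = 1: such segments can never reject ILS.
#'
#' @param len Observed segment length in bp.
#' @param e_len Expected ILS length from [expected_ils_length()].
#' @return p-value in `(0, 1]`, strictly decreasing in `len`.
#' @export
ils_pvalue <- function(len, e_len) {
  if (any(!is.finite(len)) || any(len < 0)) {
    stop("segment length must be finite and >= 0", call. = FALSE)
  }
  if (any(is.nan(e_len)) || any(e_len <= 0)) {
    stop("expected length must be positive (Inf allowed)", call. = FALSE)
  }
  exp(-len / e_len)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Score segments against the ILS length model
#'
#' Adds to each segment its mean local recombination rate, expected ILS
#' length, raw exponential-tail p-value and BH-adjusted p-value (the BH
#' family is all tested segments in the call). With
#' `cfg$conservative_two_maps` and a second map, each segment uses the
#' larger of the two expected lengths.
#'
#' @param segments Output of [build_segments()].
#' @param map A [genetic_map()].
#' @param cfg An [ils_config()].
#' @param map2 Optional second [genetic_map()].
#' @return The segment tibble with columns `rate`, `e_len`, `p_raw`,
#'   `p_adj` appended.
#' @export
score_segments <- function(segments, map, cfg = ils_config(), map2 = NULL) {
  if (nrow(segments) == 0) {
    return(dplyr::mutate(segments, rate = numeric(0), e_len = numeric(0),
                         p_raw = numeric(0), p_adj = numeric(0)))
  }
  qstart <- segments$start
  qend <- pmax(segments$end, segments$start + 1)  # zero-length guard
  rate <- local_rate(map, qstart, qend)
  e_len <- expected_ils_length(rate, cfg)
  if (!is.null(map2) && isTRUE(cfg$conservative_two_maps)) {
    e2 <- expected_ils_length(local_rate(map2, qstart, qend), cfg)
    e_len <- pmax(e_len, e2)
  }
  p_raw <- ils_pvalue(segments$length, e_len)
  dplyr::mutate(segments, rate = rate, e_len = e_len, p_raw = p_raw,
                p_adj = bh_adjust(p_raw))
}

#' Call archaic SNPs from significant segments
#'
#' A candidate site is called an aSNP when it lies on at least one segment
#' whose BH-adjusted ILS p-value is below `alpha` (segments with adjusted
#' p >= alpha are consistent with lineage sorting and contribute nothing).
#'
#' @param candidates Output of [apply_site_criteria()].
#' @param segments Scored segments from [score_segments()].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return The candidate rows that were called, sorted by position, with a
#'   `n_support` column counting supporting significant segments.
#' @export
call_asnps <- function(candidates, segments, alpha = 0.05) {
  cand <- candidates[candidates$candidate, , drop = FALSE]
  sig <- segments[segments$p_adj < alpha, , drop = FALSE]
  if (nrow(cand) == 0 || nrow(sig) == 0) {
    return(dplyr::mutate(cand[0, ], n_support = integer(0)))
  }
  n_support <- vapply(cand$pos, function(x)
    sum(sig$start <= x & x <= sig$end), integer(1))
  out <- dplyr::mutate(cand, n_support = n_support)
  out <- out[out$n_support > 0, , drop = FALSE]
  dplyr::arrange(out, .data$pos)
}

#' Full archaic-SNP calling pass
#'
#' Applies the site criteria, builds and scores per-haplotype segments, and
#' calls aSNPs at the given significance level.
#'
#' @inheritParams apply_site_criteria
#' @inheritParams score_segments
#' @param alpha Significance level on the adjusted p-value.
#' @return A list with `candidates`, `segments` and `asnps` tibbles.
#' @export
find_asnps <- function(panel, map, cfg = ils_config(), alpha = 0.05,
                       afr_pop = NULL, map2 = NULL) {
  candidates <- apply_site_criteria(panel, afr_pop = afr_pop)
  segments <- build_segments(panel, candidates,
                             min_markers = cfg$min_markers,
                             afr_pop = afr_pop)
  segments <- score_segments(segments, map, cfg = cfg, map2 = map2)
  asnps <- call_asnps(candidates, segments, alpha = alpha)
  list(candidates = candidates, segments = segments, asnps = asnps)
}

#' Compare aSNP calls with simulator ground truth
#'
#' Truth is taken at the site level: an archaic-marker site (homozygous
#' derived in the archaic genome) is truly introgressed when it falls
#' inside at least one introgressed truth tract. Precision is the fraction
#' of called aSNPs that are truly introgressed; sensitivity is the fraction
#' of truly introgressed marker sites that were called.
#'
#' @param asnps Called aSNPs from [call_asnps()] / [find_asnps()].
#' @param truth Truth-tract tibble from [simulate_panel()].
#' @param panel The simulated [haplotype_panel()].
#' @return A one-row tibble: `n_called`, `n_true`, `tp`, `precision`,
#'   `sensitivity`.
#' @export
evaluate_asnp_calls <- function(asnps, truth, panel) {
  intro <- truth[truth$origin == "introgressed", , drop = FALSE]
  marker <- !is.na(panel$archaic[, 1]) & panel$archaic[, 1] == 1L &
    panel$archaic[, 2] == 1L
  marker_pos <- panel$variants$pos[marker]
  in_intro <- rep(FALSE, length(marker_pos))
  # tract intervals may overlap across haplotypes; merge before testing
  if (nrow(intro) > 0) {
    o <- order(intro$start)
    s <- intro$start[o]; e <- intro$end[o]
    merged_s <- s[1]; merged_e <- e[1]
    for (k in seq_along(s)[-1]) {
      m <- length(merged_s)
      if (s[k] <= merged_e[m]) merged_e[m] <- max(merged_e[m], e[k]) else {
        merged_s <- c(merged_s, s[k]); merged_e <- c(merged_e, e[k])
      }
    }
    in_intro <- covered_by(marker_pos, merged_s, merged_e)
  }
  true_pos <- marker_pos[in_intro]
  called_pos <- asnps$pos
  tp <- sum(called_pos %in% true_pos)
  tibble::tibble(
    n_called = length(called_pos),
    n_true = length(true_pos),
    tp = tp,
    precision = if (length(called_pos) > 0) tp / length(called_pos) else NA_real_,
    sensitivity = if (length(true_pos) > 0)
      sum(true_pos %in% called_pos) / length(true_pos) else NA_real_
  )
}
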