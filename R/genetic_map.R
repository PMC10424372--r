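#' Construct a genetic (recombination) map
#'
#' A genetic map is an ordered set of points `(pos, rate, cm)` giving the
#' local recombination rate (cM/Mb) and cumulative genetic distance (cM)
#' along one chromosome. 1 cM/Mb corresponds to a crossover probability of
#' 1e-8 per base pair per generation.
#'
#' @param pos Base-pair positions, strictly increasing.
#' @param rate Local rates in cM/Mb, non-negative.
#' @param cm Cumulative genetic distance in cM, non-decreasing.
#' @param chrom Optional chromosome label.
#' @return An object of class `genetic_map` (a tibble with attributes).
#' @export
genetic_map <- function(pos, rate, cm, chrom = NA_character_) {
  if (length(pos) < 1) stop("map needs at least one point", call. = FALSE)
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("map positions must be strictly increasing", call. = FALSE)
  }
  if (any(rate < 0)) stop("recombination rates must be >= 0", call. = FALSE)
  if (is.unsorted(cm)) {
    stop("cumulative cM must be non-decreasing", call. = FALSE)
  }
  out <- tibble::tibble(pos = as.numeric(pos), rate = as.numeric(rate),
                        cm = as.numeric(cm))
  attr(out, "chrom") <- chrom
  class(out) <- c("genetic_map", class(out))
  out
}

#' Build a constant-rate genetic map
#'
#' @param rate Rate in cM/Mb.
#' @param length_bp Chromosome length covered.
#' @param chrom Optional chromosome label.
#' @return A [genetic_map()] with two points spanning `[0, length_bp]`.
#' @export
constant_rate_map <- function(rate, length_bp, chrom = NA_character_) {
  genetic_map(pos = c(0, length_bp), rate = c(rate, rate),
              cm = c(0, rate * length_bp / 1e6), chrom = chrom)
}

#' Read a HapMap-format genetic map
#'
#' Accepts whitespace- or tab-delimited files with columns
#' (chrom, position, rate cM/Mb, cumulative cM) or (position, rate,
#' cumulative cM); a header row is detected and skipped.
#'
#' @param path Path to the map file.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(
    fields[-1]  # first column may legitimately be a chromosome label
  ))))
  x <- utils::read.table(path, header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("genetic map needs >= 3 columns", call. = FALSE)
  if (ncol(x) >= 4) {
    genetic_map(pos = x[[2]], rate = x[[3]], cm = x[[4]],
                chrom = as.character(x[[1]][1]))
  } else {
    genetic_map(pos = x[[1]], rate = x[[2]], cm = x[[3]])
  }
}

# cumulative cM at arbitrary positions: piecewise-linear interpolation,
# constant (zero-rate) extension beyond the mapped range
interp_cm <- function(map, at) {
  if (nrow(map) == 1) return(rep(map$cm[1], length(at)))
  stats::approx(map$pos, map$cm, xout = at, rule = 2)$y
}

#' Mean local recombination rate over an interval
#'
#' The rate over `[start, end)` is the difference in interpolated cumulative
#' cM divided by the interval length in Mb. Queries beyond the mapped range
#' use the boundary cumulative value, i.e. the map is extended with rate 0.
#'
#' @param map A [genetic_map()].
#' @param start,end Interval bounds in bp (0-based half-open); vectorised.
#' @return Mean rate(s) in cM/Mb.
#' @export
local_rate <- function(map, start, end) {
  if (any(start >= end)) stop("`start` must be < `end`", call. = FALSE)
  (interp_cm(map, end) - interp_cm(map, start)) / ((end - start) / 1e6)
}
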