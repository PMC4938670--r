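#' Simulate one meiosis on one chromosome
#'
#' Crossovers are drawn as a Poisson process with no interference: the count
#' is Poisson with mean equal to the chromosome's genetic length in Morgans
#' for the given sex, and positions are drawn proportional to the local
#' crossover intensity of the landscape. The gamete starts from a random
#' parental haplotype and switches at each crossover.
#'
#' @param haplotypes 2 x m matrix of phased parental alleles (0/1), one row
#'   per haplotype, columns ordered by physical position.
#' @param positions marker positions, 0-based bp, non-decreasing.
#' @param landscape a [recomb_landscape()].
#' @param chrom chromosome name (must exist in the landscape).
#' @param sex "male" or "female" (selects the intensity track).
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @return list with `gamete` (length-m 0/1 vector) and `crossovers`
#'   (bp positions, possibly empty).
#' @examples
#' g <- generate_genome(1, c(1e6, 1e6), 0, seed = 1)
#' ls <- recomb_landscape(g)
#' hap <- rbind(rep(0L, 10), rep(1L, 10))
#' simulate_meiosis(hap, seq(0, 9e5, length.out = 10), ls, "chr1", "female", seed = 2)
#' @export
simulate_meiosis <- function(haplotypes, positions, landscape, chrom,
                             sex = c("male", "female"), seed = NULL) {
  sex <- match.arg(sex)
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) == 2,
            ncol(haplotypes) == length(positions))
  seg <- landscape[landscape$chrom == chrom, , drop = FALSE]
  if (nrow(seg) == 0) stopf("landscape undefined for chromosome %s", chrom)
  if (max(seg$end) <= 0) stopf("zero-length chromosome %s", chrom)
  rate <- if (sex == "male") seg$male_rate else seg$female_rate
  run <- function() meiosis_gamete(haplotypes[1, ], haplotypes[2, ], positions,
                                   seg$start, seg$end, rate)
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Internal fast path: draws from the current RNG stream.
meiosis_gamete <- function(hapA, hapB, positions, seg_start, seg_end, rate) {
  w <- rate * (seg_end - seg_start) / 1e6  # cM per segment
  morgans <- sum(w) / 100
  n_xo <- if (morgans > 0) rpois(1, morgans) else 0L
  xo <- numeric(0)
  if (n_xo > 0) {
    si <- sample.int(length(w), n_xo, replace = TRUE, prob = w)
    xo <- sort(seg_start[si] + runif(n_xo) * (seg_end[si] - seg_start[si]))
  }
  start_hap <- sample.int(2L, 1L)
  parity <- (start_hap - 1L + findInterval(positions, xo)) %% 2L
  gamete <- ifelse(parity == 0L, hapA, hapB)
  list(gamete = as.integer(gamete), crossovers = xo)
}
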