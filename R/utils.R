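#' Map functions: recombination fraction to genetic distance
#'
#' Convert a recombination fraction \eqn{\theta} to a map distance in
#' centimorgans. The Haldane function, \eqn{d = -50 \ln(1 - 2\theta)}, assumes
#' crossovers occur without interference; the Kosambi function,
#' \eqn{d = 25 \ln\{(1 + 2\theta)/(1 - 2\theta)\}}, allows partial
#' interference. Distances are capped at `max_cM` (with `theta >= 0.5` mapping
#' to the cap) so that a handful of effectively unlinked adjacent pairs cannot
#' blow up a map.
#'
#' @param theta recombination fraction(s) in `[0, 0.5]`.
#' @param max_cM cap on the returned distance (default 50 cM).
#' @return distance(s) in cM.
#' @examples
#' haldane_cM(0.2) # 25.54
#' kosambi_cM(0.2)
#' @export
haldane_cM <- function(theta, max_cM = 50) {
  d <- ifelse(theta >= 0.5, Inf, -50 * log(1 - 2 * theta))
  pmin(d, max_cM)
}

#' @rdname haldane_cM
#' @export
kosambi_cM <- function(theta, max_cM = 50) {
  d <- ifelse(theta >= 0.5, Inf, 25 * log((1 + 2 * theta) / (1 - 2 * theta)))
  pmin(d, max_cM)
}

map_distance_fun <- function(map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (map_function == "haldane") haldane_cM else kosambi_cM
}

# Run code with a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a reproducible sub-seed (kept within 32-bit integer range).
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12289L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
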