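#' Simulate a reference genome with chromosome-assigned and unplaced sequence
#'
#' Generates random chromosome sequences and logically excises a set of
#' windows from them to act as "unplaced contigs", emulating an assembly in
#' which part of the sequence is not yet assigned to chromosomes. Excised
#' windows are masked (`N`) in the chromosome records of the emitted assembly
#' so that placed and unplaced sequence are disjoint and exact flank matches
#' are unique; internally the full chromosome sequence is retained so that
#' meiosis simulation and flank extraction see the true coordinates.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param length_range two-element vector, min/max chromosome length in bp.
#' @param unplaced_fraction fraction of total sequence to excise as unplaced
#'   contigs (`0 <= f < 1`).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param contigs_per_chrom number of contig windows excised per chromosome
#'   (ignored when `unplaced_fraction = 0`).
#' @return an object of class `sim_genome`: chromosome sequences
#'   ([Biostrings::DNAStringSet]), chromosome lengths, and a `contig_info`
#'   table (name, source chromosome, 0-based offset, length).
#' @examples
#' g <- generate_genome(2, c(2e5, 3e5), unplaced_fraction = 0.2, seed = 1)
#' summary(g$contig_info$length / sum(g$chrom_lengths))
#' @export
generate_genome <- function(n_chrom = 5, length_range = c(2e7, 2e7),
                            unplaced_fraction = 0.22, seed = 1,
                            contigs_per_chrom = 2) {
  stopifnot(n_chrom >= 1, length(length_range) == 2,
            unplaced_fraction >= 0, unplaced_fraction < 1)
  with_seed(seed, {
    lens <- as.integer(round(runif(n_chrom, length_range[1], length_range[2])))
    if (any(lens <= 0)) stopf("chromosome lengths must be positive")
    names(lens) <- sprintf("chr%d", seq_len(n_chrom))
    seqs <- vapply(lens, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    chromosomes <- Biostrings::DNAStringSet(seqs)
    names(chromosomes) <- names(lens)

    ci <- NULL
    if (unplaced_fraction > 0) {
      rows <- vector("list", n_chrom * contigs_per_chrom)
      k <- 0L
      for (ch in seq_len(n_chrom)) {
        L <- lens[ch]
        base_len <- unplaced_fraction * L / contigs_per_chrom
        clens <- as.integer(round(base_len * runif(contigs_per_chrom, 0.7, 1.3)))
        margin <- 1000L; gap <- 500L
        need <- sum(clens) + 2L * margin + (contigs_per_chrom + 1L) * gap
        if (need >= L)
          stopf("chromosome %s (%d bp) too small to host %d contigs totalling %d bp",
                names(lens)[ch], L, contigs_per_chrom, sum(clens))
        # place windows left to right with random gaps
        free <- L - 2L * margin - sum(clens)
        cuts <- sort(runif(contigs_per_chrom, 0, 1))
        starts0 <- margin + as.integer(floor(cuts * (free - contigs_per_chrom * gap))) +
          gap * seq_len(contigs_per_chrom) + c(0L, cumsum(clens)[-contigs_per_chrom])
        for (j in seq_len(contigs_per_chrom)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            name = sprintf("contig%04d", k),
            source_chrom = names(lens)[ch],
            start0 = starts0[j],
            length = clens[j],
            stringsAsFactors = FALSE)
        }
      }
      ci <- do.call(rbind, rows[seq_len(k)])
      tot <- sum(ci$length) / sum(as.numeric(lens))
      if (abs(tot - unplaced_fraction) > 0.1 * max(unplaced_fraction, 1e-9))
        stopf("excised fraction %.3f deviates from requested %.3f", tot,
              unplaced_fraction)
    } else {
      ci <- data.frame(name = character(), source_chrom = character(),
                       start0 = integer(), length = integer(),
                       stringsAsFactors = FALSE)
    }

    structure(list(chromosomes = chromosomes,
                   chrom_lengths = lens,
                   contig_info = ci,
                   seed = seed),
              class = "sim_genome")
  })
}

#' @method print sim_genome
#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("Simulated genome: %d chromosomes (%.1f Mb), %d unplaced contigs (%.1f Mb, %.1f%%)\n",
              length(x$chrom_lengths), sum(as.numeric(x$chrom_lengths)) / 1e6,
              nrow(x$contig_info), sum(x$contig_info$length) / 1e6,
              100 * sum(x$contig_info$length) / sum(as.numeric(x$chrom_lengths))))
  invisible(x)
}

# Mask intervals (0-based half-open) excised from a chromosome.
mask_windows <- function(genome, chrom) {
  ci <- genome$contig_info
  ci[ci$source_chrom == chrom, , drop = FALSE]
}

#' Assembly view of a simulated genome
#'
#' Returns the sequences as a mapping pipeline would see them: chromosome
#' records with excised contig windows hard-masked to `N`, followed by the
#' unplaced contig records carrying the excised sequence.
#'
#' @param genome a `sim_genome`.
#' @return a [Biostrings::DNAStringSet] of chromosomes then contigs.
#' @export
assembly_seqs <- function(genome) {
  chroms <- genome$chromosomes
  ci <- genome$contig_info
  out_chr <- chroms
  if (nrow(ci) > 0) {
    for (ch in unique(ci$source_chrom)) {
      w <- ci[ci$source_chrom == ch, ]
      at <- IRanges::IRanges(start = w$start0 + 1L, width = w$length)
      out_chr[[ch]] <- Biostrings::replaceAt(
        chroms[[ch]], at,
        Biostrings::DNAStringSet(strrep("N", w$length)))
    }
    ctg <- Biostrings::DNAStringSet(lapply(seq_len(nrow(ci)), function(i) {
      Biostrings::subseq(chroms[[ci$source_chrom[i]]],
                         start = ci$start0[i] + 1L, width = ci$length[i])
    }))
    names(ctg) <- ci$name
    c(out_chr, ctg)
  } else {
    out_chr
  }
}

#' Write the assembly FASTA for a simulated genome
#'
#' @param genome a `sim_genome`.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(assembly_seqs(genome), path)
  invisible(path)
}

#' Sex-specific crossover landscape
#'
#' Defines a piecewise-constant crossover intensity (cM/Mb) over physical
#' position for each chromosome and sex. The male landscape has an elevated
#' rate in the subtelomeric fraction at each chromosome end
#' (`male_subtel_factor` times the interior rate over the outer
#' `subtel_fraction` of the chromosome length at each end); the female
#' landscape is flat. The female rate is derived from `target_length_ratio`
#' so that total female genetic length equals `target_length_ratio` times the
#' male total, unless `female_base_rate` is given explicitly.
#'
#' @param genome a `sim_genome`.
#' @param male_interior_rate male interior intensity, cM/Mb.
#' @param male_subtel_factor fold elevation of the male subtelomeric rate.
#' @param subtel_fraction fraction of chromosome length at each end that is
#'   subtelomeric (default outer 10 percent of each end).
#' @param target_length_ratio female:male total genetic length ratio.
#' @param female_base_rate optional explicit flat female rate, cM/Mb.
#' @return object of class `recomb_landscape`: a segment table
#'   (chrom, start, end in bp, male_rate, female_rate) with the parameters as
#'   attributes.
#' @examples
#' g <- generate_genome(1, c(1e6, 1e6), 0, seed = 1)
#' ls <- recomb_landscape(g)
#' landscape_lengths(ls)
#' @export
recomb_landscape <- function(genome, male_interior_rate = 1.25,
                             male_subtel_factor = 10, subtel_fraction = 0.1,
                             target_length_ratio = 1.5,
                             female_base_rate = NULL) {
  stopifnot(male_interior_rate >= 0, male_subtel_factor >= 0,
            subtel_fraction >= 0, subtel_fraction < 0.5)
  male_mean <- male_interior_rate *
    (2 * subtel_fraction * male_subtel_factor + (1 - 2 * subtel_fraction))
  frate <- female_base_rate %||% (target_length_ratio * male_mean)
  segs <- do.call(rbind, lapply(names(genome$chrom_lengths), function(ch) {
    L <- as.numeric(genome$chrom_lengths[[ch]])
    b <- c(0, round(subtel_fraction * L), round((1 - subtel_fraction) * L), L)
    mr <- male_interior_rate * c(male_subtel_factor, 1, male_subtel_factor)
    keep <- diff(b) > 0
    data.frame(chrom = ch, start = b[-4][keep], end = b[-1][keep],
               male_rate = mr[keep], female_rate = frate,
               stringsAsFactors = FALSE)
  }))
  structure(segs, class = c("recomb_landscape", "data.frame"),
            params = list(male_interior_rate = male_interior_rate,
                          male_subtel_factor = male_subtel_factor,
                          subtel_fraction = subtel_fraction,
                          target_length_ratio = target_length_ratio,
                          female_base_rate = frate))
}

#' True genetic lengths of a crossover landscape
#'
#' Integrates the landscape intensity over each chromosome.
#'
#' @param landscape a `recomb_landscape`.
#' @return data frame with chrom, male_cM, female_cM.
#' @export
landscape_lengths <- function(landscape) {
  sp <- split(seq_len(nrow(landscape)), landscape$chrom)
  out <- do.call(rbind, lapply(names(sp), function(ch) {
    s <- landscape[sp[[ch]], ]
    mb <- (s$end - s$start) / 1e6
    data.frame(chrom = ch, male_cM = sum(s$male_rate * mb),
               female_cM = sum(s$female_rate * mb), stringsAsFactors = FALSE)
  }))
  out[match(unique(landscape$chrom), out$chrom), , drop = FALSE]
}

# Cumulative genetic position (cM) at physical positions `pos` (0-based bp)
# on one chromosome, for one sex.
landscape_cum_cM <- function(landscape, chrom, pos, sex = c("male", "female")) {
  sex <- match.arg(sex)
  s <- landscape[landscape$chrom == chrom, , drop = FALSE]
  if (nrow(s) == 0) stopf("no landscape for chromosome %s", chrom)
  rate <- if (sex == "male") s$male_rate else s$female_rate
  cum0 <- c(0, cumsum(rate * (s$end - s$start) / 1e6))
  i <- findInterval(pos, s$start, rightmost.closed = TRUE)
  i[i < 1] <- 1L
  i[i > nrow(s)] <- nrow(s)
  cum0[i] + rate[i] * (pmin(pos, s$end[i]) - s$start[i]) / 1e6
}
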