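#' Construct a genotype matrix with pedigree links
#'
#' The central genotype container: biallelic calls coded 0 (hom ref),
#' 1 (het), 2 (hom alt), `NA` (missing) for markers (rows) by individuals
#' (columns), together with marker metadata and the pedigree.
#'
#' @param G integer matrix, markers x individuals.
#' @param markers data frame with at least `id`, `ref`, `alt`; optional
#'   assembly columns `target` and `pos` (1-based) used when writing VCF.
#' @param individuals data frame with `id`, `sire`, `dam`, `sex`, `role`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, markers, individuals) {
  stopifnot(is.matrix(G), nrow(G) == nrow(markers), ncol(G) == nrow(individuals))
  off <- individuals[individuals$role == "offspring", ]
  miss <- setdiff(unique(c(off$sire, off$dam)), individuals$id)
  if (length(miss) > 0)
    stopf("offspring reference parent(s) absent from individuals: %s",
          paste(miss, collapse = ", "))
  rownames(G) <- markers$id
  colnames(G) <- individuals$id
  structure(list(G = G, markers = markers, individuals = individuals),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d individuals (%d founders, %d offspring); %.2f%% missing\n",
              nrow(x$G), ncol(x$G),
              sum(x$individuals$role == "founder"),
              sum(x$individuals$role == "offspring"),
              100 * mean(is.na(x$G))))
  invisible(x)
}

#' @method dim genotype_matrix
#' @export
dim.genotype_matrix <- function(x) dim(x$G)

# Subset markers (i, logical or index over rows) and/or individuals (j).
subset_gm <- function(gm, i = NULL, j = NULL) {
  if (!is.null(i)) {
    gm$G <- gm$G[i, , drop = FALSE]
    gm$markers <- gm$markers[i, , drop = FALSE]
  }
  if (!is.null(j)) {
    gm$G <- gm$G[, j, drop = FALSE]
    gm$individuals <- gm$individuals[j, , drop = FALSE]
  }
  gm
}

#' Simulate pedigree genotypes with known truth
#'
#' Places biallelic SNPs uniformly at random on the simulated genome (both on
#' chromosome-assigned sequence and inside the excised windows that form the
#' unplaced contigs), draws founder genotypes from the marker allele
#' frequencies, generates offspring genotypes through simulated meioses under
#' the sex-specific crossover landscape, and finally applies symmetric
#' genotyping errors and missingness. Marker flanking sequences (35 bp either
#' side of the SNP, 71-mers) are read from the genome; markers whose full
#' flank does not fit inside a single assembly target are rejected and
#' resampled.
#'
#' @param genome a [generate_genome()] result (after any gene models have
#'   been written into it).
#' @param pedigree a [make_pedigree()] data frame.
#' @param n_markers number of SNPs to simulate.
#' @param landscape a [recomb_landscape()].
#' @param maf_distribution function of `n` returning alt-allele frequencies
#'   (the alt allele is the minor allele when frequencies are below 0.5).
#' @param genotyping_error_rate per-call probability that a genotype is
#'   replaced by one of the other two states (symmetric flip).
#' @param missing_rate per-call missing probability.
#' @param seed integer seed; fixes every downstream file byte-for-byte.
#' @param gene_models optional [generate_gene_models()] result; when given,
#'   each SNP's true effect category is recorded in the truth set.
#' @param flank_bp flank length either side of the SNP (default 35).
#' @return list with `gm` (a [genotype_matrix()]), `flanks` (marker_id,
#'   flank, offset), and `truth` (never consulted by pipeline stages): marker
#'   truth table (true chromosome, position, per-sex cM, assembly target,
#'   effect category) and per-meiosis crossover positions.
#' @export
simulate_genotypes <- function(genome, pedigree, n_markers = 2000,
                               landscape = recomb_landscape(genome),
                               maf_distribution = function(n) runif(n, 0.1, 0.5),
                               genotyping_error_rate = 0.005,
                               missing_rate = 0.01, seed = 1,
                               gene_models = NULL, flank_bp = 35) {
  validate_pedigree(pedigree)
  with_seed(seed, {
    mk <- sample_marker_positions(genome, n_markers, flank_bp)
    chrs <- names(genome$chrom_lengths)

    ## alleles
    refs <- character(n_markers)
    for (ch in chrs) {
      idx <- which(mk$chrom == ch)
      if (length(idx) == 0) next
      at <- IRanges::IRanges(start = mk$pos0[idx] + 1L, width = 1L)
      refs[idx] <- as.character(Biostrings::extractAt(genome$chromosomes[[ch]], at))
    }
    alts <- vapply(refs, function(r) sample(setdiff(DNA_BASES, r), 1), character(1))
    p_alt <- maf_distribution(n_markers)

    founders <- pedigree[pedigree$role == "founder", ]
    off <- pedigree[pedigree$role == "offspring", ]
    nf <- nrow(founders); no <- nrow(off)

    ## founder haplotypes: n_markers x (2 * nf), phased
    H <- matrix(rbinom(n_markers * 2L * nf, 1L, rep(p_alt, times = 2L * nf)),
                nrow = n_markers)
    hap_col <- function(ind_idx, h) 2L * (ind_idx - 1L) + h
    fidx <- setNames(seq_len(nf), founders$id)

    ## offspring gametes, chromosome by chromosome
    P <- matrix(0L, n_markers, no)  # paternal gamete alleles
    M <- matrix(0L, n_markers, no)  # maternal
    xo_log <- vector("list", 2L * no)
    kx <- 0L
    for (ch in chrs) {
      rows <- which(mk$chrom == ch)
      if (length(rows) == 0) next
      seg <- landscape[landscape$chrom == ch, , drop = FALSE]
      pos <- mk$pos0[rows]
      for (o in seq_len(no)) {
        si <- fidx[[off$sire[o]]]; di <- fidx[[off$dam[o]]]
        gp <- meiosis_gamete(H[rows, hap_col(si, 1L)], H[rows, hap_col(si, 2L)],
                             pos, seg$start, seg$end, seg$male_rate)
        gmat <- meiosis_gamete(H[rows, hap_col(di, 1L)], H[rows, hap_col(di, 2L)],
                               pos, seg$start, seg$end, seg$female_rate)
        P[rows, o] <- gp$gamete
        M[rows, o] <- gmat$gamete
        nx <- length(gp$crossovers) + length(gmat$crossovers)
        if (nx > 0) {
          kx <- kx + 1L
          xo_log[[kx]] <- data.frame(
            offspring = rep(off$id[o], nx), chrom = rep(ch, nx),
            parent = c(rep(off$sire[o], length(gp$crossovers)),
                       rep(off$dam[o], length(gmat$crossovers))),
            sex = c(rep("male", length(gp$crossovers)),
                    rep("female", length(gmat$crossovers))),
            pos = c(gp$crossovers, gmat$crossovers), stringsAsFactors = FALSE)
        }
      }
    }
    crossovers <- do.call(rbind, xo_log[seq_len(kx)])

    ## genotype matrix: founders then offspring, order as pedigree
    Gf <- H[, hap_col(seq_len(nf), 1L), drop = FALSE] +
      H[, hap_col(seq_len(nf), 2L), drop = FALSE]
    Go <- P + M
    G <- matrix(0L, n_markers, nrow(pedigree))
    G[, match(founders$id, pedigree$id)] <- Gf
    G[, match(off$id, pedigree$id)] <- Go

    ## genotyping error: symmetric flip to one of the other two states
    if (genotyping_error_rate > 0) {
      flip <- which(runif(length(G)) < genotyping_error_rate)
      if (length(flip) > 0)
        G[flip] <- (G[flip] + sample(1:2, length(flip), replace = TRUE)) %% 3L
    }
    if (missing_rate > 0) {
      G[runif(length(G)) < missing_rate] <- NA_integer_
    }

    ## flanks (71-mers centred on the SNP), read from the true sequence
    flank <- character(n_markers)
    for (ch in chrs) {
      idx <- which(mk$chrom == ch)
      if (length(idx) == 0) next
      at <- IRanges::IRanges(start = mk$pos0[idx] - flank_bp + 1L,
                             width = 2L * flank_bp + 1L)
      flank[idx] <- as.character(Biostrings::extractAt(genome$chromosomes[[ch]], at))
    }
    flanks <- data.frame(marker_id = mk$id, flank = flank,
                         offset = as.integer(flank_bp),
                         stringsAsFactors = FALSE)

    markers <- data.frame(id = mk$id, ref = refs, alt = alts,
                          target = mk$target, pos = mk$target_pos0 + 1L,
                          stringsAsFactors = FALSE)
    gm <- genotype_matrix(G, markers, as.data.frame(pedigree))

    eff <- if (!is.null(gene_models)) {
      truth_effects(gene_models, genome, transform(mk, ref = refs, alt = alts))
    } else {
      data.frame(effect = rep("intergenic", n_markers),
                 gene = NA_character_, stringsAsFactors = FALSE)
    }
    truth_markers <- data.frame(
      id = mk$id, chrom = mk$chrom, pos0 = mk$pos0,
      cM_male = NA_real_,
      cM_female = NA_real_, target = mk$target, target_pos0 = mk$target_pos0,
      ref = refs, alt = alts, effect = eff$effect, gene = eff$gene,
      stringsAsFactors = FALSE)
    for (ch in chrs) {
      i <- which(mk$chrom == ch)
      truth_markers$cM_male[i] <- landscape_cum_cM(landscape, ch, mk$pos0[i], "male")
      truth_markers$cM_female[i] <- landscape_cum_cM(landscape, ch, mk$pos0[i], "female")
    }

    list(gm = gm, flanks = flanks,
         truth = list(markers = truth_markers, crossovers = crossovers,
                      landscape = landscape, pedigree = as.data.frame(pedigree),
                      params = list(n_markers = n_markers,
                                    genotyping_error_rate = genotyping_error_rate,
                                    missing_rate = missing_rate, seed = seed)))
  })
}

# Uniform marker placement with full-flank rejection. A marker whose flank
# lies wholly inside an excised window belongs to that contig on the
# assembly; flanks straddling a window boundary are rejected and resampled.
sample_marker_positions <- function(genome, n_markers, flank_bp) {
  lens <- genome$chrom_lengths
  chrs <- names(lens)
  ci <- genome$contig_info
  acc_chrom <- character(0); acc_pos <- integer(0)
  tries <- 0L
  while (length(acc_pos) < n_markers) {
    tries <- tries + 1L
    if (tries > 200L) stopf("unable to place %d markers with full flanks", n_markers)
    need <- n_markers - length(acc_pos)
    draw <- 2L * need + 50L
    ch <- sample(chrs, draw, replace = TRUE, prob = as.numeric(lens))
    pos <- as.integer(floor(runif(draw) * (as.numeric(lens[ch]) - 2 * flank_bp))) + flank_bp
    ok <- rep(TRUE, draw)
    if (nrow(ci) > 0) {
      for (k in seq_len(nrow(ci))) {
        s <- ci$start0[k]; e <- ci$start0[k] + ci$length[k]
        on_ch <- ch == ci$source_chrom[k]
        inside <- on_ch & (pos - flank_bp >= s) & (pos + flank_bp < e)
        outside <- !on_ch | (pos + flank_bp < s) | (pos - flank_bp >= e)
        ok <- ok & (inside | outside)
      }
    }
    acc_chrom <- c(acc_chrom, ch[ok]); acc_pos <- c(acc_pos, pos[ok])
    dup <- duplicated(paste(acc_chrom, acc_pos))
    acc_chrom <- acc_chrom[!dup]; acc_pos <- acc_pos[!dup]
  }
  acc_chrom <- acc_chrom[seq_len(n_markers)]
  acc_pos <- acc_pos[seq_len(n_markers)]
  o <- order(match(acc_chrom, chrs), acc_pos)
  chrom <- acc_chrom[o]; pos0 <- acc_pos[o]
  target <- chrom; target_pos0 <- pos0
  if (nrow(ci) > 0) {
    for (k in seq_len(nrow(ci))) {
      s <- ci$start0[k]; e <- ci$start0[k] + ci$length[k]
      i <- chrom == ci$source_chrom[k] & pos0 >= s & pos0 < e
      target[i] <- ci$name[k]
      target_pos0[i] <- pos0[i] - s
    }
  }
  data.frame(id = sprintf("M%05d", seq_len(n_markers)), chrom = chrom,
             pos0 = pos0, target = target, target_pos0 = target_pos0,
             stringsAsFactors = FALSE)
}
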