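SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate toy gene models and write them into a simulated genome
#'
#' Places non-overlapping protein-coding genes on the chromosome-assigned
#' (non-excised) parts of the genome. Each gene carries 1-3 transcript
#' variants sharing a CDS (alternative transcripts differ in 3' UTR extent),
#' each with an expression value. Exonic sequence (5' UTR, a CDS with a valid
#' start and stop and no internal stop codons, 3' UTR) and random intronic
#' sequence are written into the chromosome at the gene locus, reverse-
#' complemented for minus-strand genes, so that downstream ORF prediction on
#' the spliced transcript recovers exactly the constructed CDS.
#'
#' @param genome a `sim_genome`.
#' @param n_genes number of genes to place.
#' @param seed integer seed.
#' @param aa_range range of protein lengths (amino acids, incl. Met).
#' @param n_exon_range range of exon counts per transcript.
#' @return list with `models` (class `gene_models`) and `genome` (the genome
#'   with gene sequence written in; use this downstream).
#' @export
generate_gene_models <- function(genome, n_genes = 150, seed = 1,
                                 aa_range = c(110, 250),
                                 n_exon_range = c(2, 5)) {
  if (n_genes == 0)
    return(list(models = structure(list(genes = list()), class = "gene_models"),
                genome = genome))
  with_seed(seed, {
    chrs <- names(genome$chrom_lengths)
    occupied <- setNames(vector("list", length(chrs)), chrs)
    genes <- vector("list", n_genes)
    placed <- 0L
    for (g in seq_len(n_genes)) {
      built <- build_gene_structure(aa_range, n_exon_range)
      loc <- place_gene(genome, occupied, built$span, margin = 500L, gap = 200L)
      if (is.null(loc))
        stopf("could not place gene %d of %d without overlap (placed %d)",
              g, n_genes, placed)
      ch <- loc$chrom; start0 <- loc$start0
      occupied[[ch]] <- rbind(occupied[[ch]], c(start0, start0 + built$span))
      strand <- sample(c("+", "-"), 1)
      gseq <- built$genomic_seq
      if (strand == "-") gseq <- revcomp_chr(gseq)
      genome$chromosomes[[ch]] <- Biostrings::replaceAt(
        genome$chromosomes[[ch]],
        IRanges::IRanges(start = start0 + 1L, width = built$span),
        Biostrings::DNAStringSet(gseq))

      n_tr <- sample(1:3, 1)
      exprs <- round(stats::rlnorm(n_tr, meanlog = 1, sdlog = 1), 3)
      transcripts <- vector("list", n_tr)
      for (t in seq_len(n_tr)) {
        trim <- if (t == 1) 0L else
          sample.int(max(built$utr3_len - 30L, 1L), 1)
        tr <- layout_transcript(built, start0, strand, trim)
        tr$id <- sprintf("G%04d.t%d", g, t)
        tr$expression <- exprs[t]
        transcripts[[t]] <- tr
      }
      genes[[g]] <- list(id = sprintf("G%04d", g), chrom = ch, strand = strand,
                         start0 = start0, end0 = start0 + built$span,
                         transcripts = transcripts)
      placed <- placed + 1L
    }
    list(models = structure(list(genes = genes), class = "gene_models"),
         genome = genome)
  })
}

#' @method print gene_models
#' @export
print.gene_models <- function(x, ...) {
  ntr <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat(sprintf("gene_models: %d genes, %d transcripts\n", length(x$genes), ntr))
  invisible(x)
}

# Draw a gene's mRNA structure and sequence (sense strand, transcript
# orientation). Retries the UTR draw until the longest qualifying ORF of the
# mRNA is exactly the constructed CDS.
build_gene_structure <- function(aa_range, n_exon_range) {
  n_aa <- sample(aa_range[1]:aa_range[2], 1)
  cds_nt <- 3L * n_aa + 3L
  cds <- paste0("ATG",
                paste(sample(SENSE_CODONS, n_aa - 1L, replace = TRUE), collapse = ""),
                sample(STOP_CODONS, 1))
  repeat {
    utr5_len <- sample(50:200, 1)
    utr3_len <- sample(100:250, 1)
    utr5 <- paste(sample(DNA_BASES, utr5_len, replace = TRUE), collapse = "")
    utr3 <- paste(sample(DNA_BASES, utr3_len, replace = TRUE), collapse = "")
    mrna <- paste0(utr5, cds, utr3)
    orf <- find_orf(mrna, min_aa = 100)
    if (!is.null(orf) && orf$start == utr5_len + 1L && orf$end == utr5_len + cds_nt)
      break
  }
  mlen <- nchar(mrna)
  n_ex <- sample(n_exon_range[1]:n_exon_range[2], 1)
  cuts <- integer(0)
  if (n_ex > 1) {
    repeat {
      cuts <- sort(sample(30:(mlen - 30L), n_ex - 1L))
      if (all(diff(c(0L, cuts, mlen)) >= 30L)) break
    }
  }
  ex_bounds <- cbind(c(0L, cuts), c(cuts, mlen))  # transcript coords, half-open
  introns <- if (n_ex > 1) sample(80:400, n_ex - 1L, replace = TRUE) else integer(0)
  intron_seq <- vapply(introns, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), character(1))
  pieces <- character(2L * n_ex - 1L)
  for (i in seq_len(n_ex)) {
    pieces[2L * i - 1L] <- substr(mrna, ex_bounds[i, 1] + 1L, ex_bounds[i, 2])
    if (i < n_ex) pieces[2L * i] <- intron_seq[i]
  }
  list(mrna = mrna, utr5_len = utr5_len, cds_nt = cds_nt, utr3_len = utr3_len,
       ex_bounds = ex_bounds, introns = introns,
       genomic_seq = paste(pieces, collapse = ""),
       span = mlen + sum(introns))
}

place_gene <- function(genome, occupied, span, margin, gap, max_try = 500L) {
  lens <- genome$chrom_lengths
  chrs <- names(lens)
  ci <- genome$contig_info
  for (k in seq_len(max_try)) {
    ch <- sample(chrs, 1, prob = as.numeric(lens))
    L <- lens[[ch]]
    if (L < span + 2L * margin) next
    s <- sample.int(L - span - 2L * margin, 1) + margin
    e <- s + span
    occ <- occupied[[ch]]
    if (!is.null(occ) && nrow(occ) > 0 &&
        any(s < occ[, 2] + gap & e > occ[, 1] - gap)) next
    w <- ci[ci$source_chrom == ch, , drop = FALSE]
    if (nrow(w) > 0 &&
        any(s < w$start0 + w$length + gap & e > w$start0 - gap)) next
    return(list(chrom = ch, start0 = s))
  }
  NULL
}

# Exon/CDS/UTR genome intervals for one transcript variant. `trim3` shortens
# the 3' UTR by that many transcript bases.
layout_transcript <- function(built, start0, strand, trim3 = 0L) {
  # genomic exon intervals (sense construction orientation)
  n_ex <- nrow(built$ex_bounds)
  gpos <- integer(n_ex + 1L)
  g <- 0L
  ex_g <- matrix(0L, n_ex, 2)
  for (i in seq_len(n_ex)) {
    w <- built$ex_bounds[i, 2] - built$ex_bounds[i, 1]
    ex_g[i, ] <- c(g, g + w)
    g <- g + w + (if (i < n_ex) built$introns[i] else 0L)
  }
  span <- built$span
  mlen <- nchar(built$mrna)
  t_end <- mlen - trim3
  # transcript-coordinate features, half-open
  feats <- list(
    exon = cbind(0L, t_end),
    utr5 = if (built$utr5_len > 0) cbind(0L, built$utr5_len) else NULL,
    cds = cbind(built$utr5_len, built$utr5_len + built$cds_nt),
    utr3 = if (t_end > built$utr5_len + built$cds_nt)
      cbind(built$utr5_len + built$cds_nt, t_end) else NULL)
  # exon pieces in transcript coords (clipped at t_end)
  ex_t <- built$ex_bounds
  ex_t[, 2] <- pmin(ex_t[, 2], t_end)
  keep <- ex_t[, 1] < ex_t[, 2]
  ex_t <- ex_t[keep, , drop = FALSE]
  ex_g <- ex_g[keep, , drop = FALSE]

  map_feature <- function(fr) {
    if (is.null(fr)) return(matrix(integer(0), 0, 2))
    out <- NULL
    for (i in seq_len(nrow(ex_t))) {
      a <- max(fr[1], ex_t[i, 1]); b <- min(fr[2], ex_t[i, 2])
      if (a >= b) next
      o1 <- a - ex_t[i, 1]; o2 <- b - ex_t[i, 1]
      gi <- if (strand == "+")
        c(start0 + ex_g[i, 1] + o1, start0 + ex_g[i, 1] + o2)
      else
        c(start0 + span - (ex_g[i, 1] + o2), start0 + span - (ex_g[i, 1] + o1))
      out <- rbind(out, gi)
    }
    out <- out[order(out[, 1]), , drop = FALSE]
    dimnames(out) <- NULL
    out
  }
  list(exons = map_feature(feats$exon),
       cds = map_feature(feats$cds[1, ]),
       utr5 = if (is.null(feats$utr5)) matrix(integer(0), 0, 2)
              else map_feature(feats$utr5[1, ]),
       utr3 = if (is.null(feats$utr3)) matrix(integer(0), 0, 2)
              else map_feature(feats$utr3[1, ]))
}

# Spliced sequence of a transcript (5'->3'), from genome-ascending exon
# intervals (0-based half-open) and strand.
transcript_seq <- function(genome, chrom, exons, strand) {
  at <- IRanges::IRanges(start = exons[, 1] + 1L, end = exons[, 2])
  parts <- as.character(Biostrings::extractAt(genome$chromosomes[[chrom]], at))
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp_chr(s) else s
}

# Highest-expression transcript, used by the truth labeller; deliberately a
# separate (enumeration-style) code path from the annotation module.
truth_canonical <- function(gene) {
  ex <- vapply(gene$transcripts, function(t) t$expression, numeric(1))
  cand <- which(ex == max(ex))
  if (length(cand) > 1) {
    ol <- vapply(gene$transcripts[cand],
                 function(t) sum(t$cds[, 2] - t$cds[, 1]), numeric(1))
    cand <- cand[ol == max(ol)]
    if (length(cand) > 1) {
      ids <- vapply(gene$transcripts[cand], function(t) t$id, character(1))
      cand <- cand[order(ids)[1]]
    }
  }
  gene$transcripts[[cand[1]]]
}

# Truth-set effect labelling, computed at generation time from the gene
# structures by explicit position-set membership and whole-protein
# translation of the mutated CDS.
truth_effects <- function(models, genome, mk) {
  n <- nrow(mk)
  effect <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  for (gene in models$genes) {
    tr <- truth_canonical(gene)
    span <- range(tr$exons)
    idx <- which(mk$chrom == gene$chrom & mk$pos0 >= span[1] & mk$pos0 < span[2])
    if (length(idx) == 0) next
    cds_pos <- unlist(lapply(seq_len(nrow(tr$cds)),
                             function(i) seq(tr$cds[i, 1], tr$cds[i, 2] - 1L)))
    if (gene$strand == "-") cds_pos <- rev(cds_pos)
    exon_pos <- unlist(lapply(seq_len(nrow(tr$exons)),
                              function(i) seq(tr$exons[i, 1], tr$exons[i, 2] - 1L)))
    utr5_pos <- if (nrow(tr$utr5) > 0)
      unlist(lapply(seq_len(nrow(tr$utr5)),
                    function(i) seq(tr$utr5[i, 1], tr$utr5[i, 2] - 1L))) else integer(0)
    utr3_pos <- if (nrow(tr$utr3) > 0)
      unlist(lapply(seq_len(nrow(tr$utr3)),
                    function(i) seq(tr$utr3[i, 1], tr$utr3[i, 2] - 1L))) else integer(0)
    ref_cds <- transcript_cds_seq(genome, gene$chrom, tr, gene$strand)
    for (m in idx) {
      p <- mk$pos0[m]
      gene_id[m] <- gene$id
      if (p %in% cds_pos) {
        t_idx <- match(p, cds_pos)  # 1-based position in spliced CDS
        alt_t <- if (gene$strand == "+") mk$alt[m] else comp_base(mk$alt[m])
        alt_cds <- ref_cds
        substr(alt_cds, t_idx, t_idx) <- alt_t
        effect[m] <- compare_cds(ref_cds, alt_cds, t_idx)
      } else if (p %in% utr5_pos) {
        effect[m] <- "utr5"
      } else if (p %in% utr3_pos) {
        effect[m] <- "utr3"
      } else if (!(p %in% exon_pos)) {
        d <- min(abs(p - setdiff(unique(c(tr$exons[, 1] - 1L, tr$exons[, 2])),
                                 c(span[1] - 1L, span[2]))))
        effect[m] <- if (d <= 7L) "splice_region" else "intron"
      } else {
        effect[m] <- "utr3"  # exon base outside CDS/UTR tables cannot occur
      }
    }
  }
  data.frame(effect = effect, gene = gene_id, stringsAsFactors = FALSE)
}

transcript_cds_seq <- function(genome, chrom, tr, strand) {
  at <- IRanges::IRanges(start = tr$cds[, 1] + 1L, end = tr$cds[, 2])
  parts <- as.character(Biostrings::extractAt(genome$chromosomes[[chrom]], at))
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp_chr(s) else s
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

translate_chr <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

# Brute-force categorisation of a CDS substitution: whole-protein comparison,
# with explicit start/stop rules.
compare_cds <- function(ref_cds, alt_cds, t_idx) {
  codon_i <- (t_idx - 1L) %/% 3L + 1L
  n_codon <- nchar(ref_cds) %/% 3L
  if (codon_i == 1L) return("start_stop_change")
  ref_p <- translate_chr(ref_cds)
  alt_p <- translate_chr(alt_cds)
  stops_ref <- gregexpr("\\*", ref_p)[[1]]
  stops_alt <- gregexpr("\\*", alt_p)[[1]]
  if (!identical(as.integer(stops_ref), as.integer(stops_alt)))
    return("start_stop_change")
  if (!identical(ref_p, alt_p)) return("nonsynonymous")
  "synonymous"
}
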