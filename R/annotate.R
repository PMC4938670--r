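EFFECT_CATEGORIES <- c("intergenic", "intron", "splice_region", "utr5",
                       "utr3", "synonymous", "nonsynonymous",
                       "start_stop_change")
GENIC_CATEGORIES <- setdiff(EFFECT_CATEGORIES, "intergenic")
EXONIC_CATEGORIES <- c("synonymous", "nonsynonymous", "start_stop_change")

#' Find the longest qualifying open reading frame of a transcript
#'
#' Scans the three forward frames of the spliced transcript sequence for
#' ATG-initiated, stop-terminated reading frames with at least `min_aa`
#' codons before the stop; returns the longest (ties broken by the 5'-most
#' start), or `NULL` if none qualifies.
#'
#' @param seq spliced transcript sequence (character, 5'->3').
#' @param min_aa minimum protein length in amino acids (default 100).
#' @return `NULL`, or list with `start`, `end` (1-based inclusive transcript
#'   coordinates, stop codon included) and `aa` (protein length).
#' @examples
#' s <- paste0("CC", "ATG", strrep("GCT", 120), "TAA", "GG")
#' find_orf(s)$aa
#' @export
find_orf <- function(seq, min_aa = 100) {
  n <- nchar(seq)
  if (n < 3 * (min_aa + 1)) return(NULL)
  best <- NULL
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    prev_stop <- 0L
    for (s in which(is_stop)) {
      cand <- which(is_atg[(prev_stop + 1L):(s - 1L)])
      if (length(cand) > 0) {
        a <- prev_stop + cand[1]          # first ATG in the segment
        aa <- s - a                        # codons before the stop
        if (aa >= min_aa &&
            (is.null(best) || aa > best$aa ||
             (aa == best$aa && starts[a] < best$start))) {
          best <- list(start = starts[a], end = starts[s] + 2L, aa = aa)
        }
      }
      prev_stop <- s
    }
  }
  best
}

#' Select the canonical transcript of a gene
#'
#' The most highly expressed transcript variant; ties are broken by the
#' longest ORF, then by lexicographic transcript id.
#'
#' @param gene one gene of a `gene_models` object.
#' @param genome optional `sim_genome`, used to compute ORF lengths for
#'   tie-breaking (falls back to annotated CDS width when absent).
#' @param min_aa ORF threshold for the tie-break.
#' @return the selected transcript (list).
#' @export
select_canonical_transcript <- function(gene, genome = NULL, min_aa = 100) {
  ex <- vapply(gene$transcripts, function(t) t$expression, numeric(1))
  cand <- which(ex == max(ex))
  if (length(cand) > 1) {
    ol <- vapply(gene$transcripts[cand], function(t) {
      if (!is.null(genome)) {
        orf <- find_orf(transcript_seq(genome, gene$chrom, t$exons,
                                       gene$strand), min_aa)
        if (is.null(orf)) 0 else orf$aa
      } else sum(t$cds[, 2] - t$cds[, 1]) / 3
    }, numeric(1))
    cand <- cand[ol == max(ol)]
    if (length(cand) > 1) {
      ids <- vapply(gene$transcripts[cand], function(t) t$id, character(1))
      cand <- cand[order(ids)]
    }
  }
  gene$transcripts[[cand[1]]]
}

# Per-gene annotation index: canonical transcript, exon intervals with
# transcript coordinates, and the ORF re-derived from the spliced sequence.
build_gene_index <- function(models, genome, min_aa = 100, splice_bp = 8) {
  idx <- lapply(models$genes, function(gene) {
    tr <- select_canonical_transcript(gene, genome, min_aa)
    sseq <- transcript_seq(genome, gene$chrom, tr$exons, gene$strand)
    orf <- find_orf(sseq, min_aa)
    ex <- tr$exons  # genome-ascending, 0-based half-open
    w <- ex[, 2] - ex[, 1]
    # transcript coordinate (0-based) of each exon's genome-ascending start
    toff <- if (gene$strand == "+") cumsum(c(0, w))[seq_len(nrow(ex))]
            else rev(cumsum(c(0, rev(w)))[seq_len(nrow(ex))])
    list(gene_id = gene$id, chrom = gene$chrom, strand = gene$strand,
         span = range(ex), exons = ex, toff = toff, seq = sseq, orf = orf)
  })
  keep <- vapply(idx, function(g) !is.null(g$orf), logical(1))
  idx[keep]  # genes without a qualifying ORF are dropped from annotation
}

# transcript coordinate (1-based) of genome position p (0-based) within an
# indexed gene, or NA when p is intronic
genome_to_transcript <- function(g, p) {
  for (i in seq_len(nrow(g$exons))) {
    if (p >= g$exons[i, 1] && p < g$exons[i, 2]) {
      o <- if (g$strand == "+") p - g$exons[i, 1]
           else g$exons[i, 2] - 1L - p
      return(g$toff[i] + o + 1L)
    }
  }
  NA_integer_
}

classify_one <- function(g, p, ref, alt, splice_bp) {
  t <- genome_to_transcript(g, p)
  orf <- g$orf
  if (is.na(t)) {
    edges <- setdiff(unique(c(g$exons[, 1] - 1L, g$exons[, 2])),
                     c(g$span[1] - 1L, g$span[2]))
    d <- min(abs(p - edges))
    return(list(category = if (d <= splice_bp - 1L) "splice_region" else "intron",
                detail = NULL))
  }
  if (t >= orf$start && t <= orf$end) {
    idx <- t - orf$start + 1L
    codon_i <- (idx - 1L) %/% 3L + 1L
    within <- (idx - 1L) %% 3L
    n_codons <- (orf$end - orf$start + 1L) %/% 3L
    cstart <- orf$start + 3L * (codon_i - 1L)
    ref_codon <- substr(g$seq, cstart, cstart + 2L)
    alt_t <- if (g$strand == "+") alt else comp_base(alt)
    alt_codon <- ref_codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_t
    aa <- function(cod) {
      x <- Biostrings::GENETIC_CODE[[cod]]
      if (is.null(x)) "X" else x
    }
    cat <- if (codon_i == 1L) "start_stop_change"
      else if (codon_i == n_codons) {
        if (alt_codon %in% STOP_CODONS) "synonymous" else "start_stop_change"
      } else if (alt_codon %in% STOP_CODONS) "start_stop_change"
      else if (aa(ref_codon) != aa(alt_codon)) "nonsynonymous"
      else "synonymous"
    return(list(category = cat,
                detail = list(ref_codon = ref_codon, alt_codon = alt_codon,
                              aa_change = paste0(aa(ref_codon), codon_i,
                                                 aa(alt_codon)))))
  }
  list(category = if (t < orf$start) "utr5" else "utr3", detail = NULL)
}

#' Classify uniquely placed SNPs by positional effect
#'
#' Positional/functional classification of each uniquely placed SNP against
#' the canonical transcript of each gene, by precedence: CDS (translated
#' strand-aware with the standard genetic code into start/stop changes,
#' nonsynonymous or synonymous) > UTR (5'/3' relative to the ORF) > splice
#' region (intronic bases within `splice_bp` of an exon boundary) > intron >
#' intergenic. The ORF is re-derived from the spliced transcript sequence
#' with [find_orf()]; genes with no qualifying ORF are treated as
#' non-annotated. SNPs overlapping several genes take the highest-precedence
#' category. Placements on unanchored contigs are classified (necessarily
#' intergenic with chromosome-hosted gene models) and flagged off-chromosome.
#'
#' @param placements resolved placements; only `unique`/`resolved_by_linkage`
#'   rows are classified.
#' @param models a `gene_models` object.
#' @param genome a `sim_genome`.
#' @param alleles data frame with `marker_id` (or `id`), `ref`, `alt`.
#' @param chromosomes chromosome names (targets not listed are flagged
#'   `off_chromosome`).
#' @param splice_bp splice-region extent into the intron (default 8).
#' @param min_aa ORF threshold (default 100 aa).
#' @return data frame of class `variant_effects`: marker_id, target, pos,
#'   gene, category, ref_codon, alt_codon, aa_change, off_chromosome.
#' @export
classify_variants <- function(placements, models, genome, alleles,
                              chromosomes = names(genome$chrom_lengths),
                              splice_bp = 8, min_aa = 100) {
  if ("id" %in% names(alleles) && !("marker_id" %in% names(alleles)))
    names(alleles)[names(alleles) == "id"] <- "marker_id"
  pl <- placements[placements$status %in% c("unique", "resolved_by_linkage"), ]
  idx <- build_gene_index(models, genome, min_aa, splice_bp)
  by_chrom <- split(seq_along(idx), vapply(idx, function(g) g$chrom, character(1)))
  al <- alleles[match(pl$marker_id, alleles$marker_id), ]
  prec <- c(start_stop_change = 1, nonsynonymous = 1, synonymous = 1,
            utr5 = 2, utr3 = 2, splice_region = 3, intron = 4)
  n <- nrow(pl)
  category <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  refc <- altc <- aach <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ch <- pl$target[i]
    gl <- by_chrom[[ch]]
    if (is.null(gl)) next
    p0 <- pl$pos[i] - 1L
    best <- NULL
    for (k in gl) {
      g <- idx[[k]]
      if (p0 < g$span[1] || p0 >= g$span[2]) next
      res <- classify_one(g, p0, al$ref[i], al$alt[i], splice_bp)
      res$gene <- g$gene_id
      if (is.null(best) || prec[[res$category]] < prec[[best$category]])
        best <- res
    }
    if (!is.null(best)) {
      category[i] <- best$category
      gene[i] <- best$gene
      if (!is.null(best$detail)) {
        refc[i] <- best$detail$ref_codon
        altc[i] <- best$detail$alt_codon
        aach[i] <- best$detail$aa_change
      }
    }
  }
  structure(data.frame(marker_id = pl$marker_id, target = pl$target,
                       pos = pl$pos, gene = gene, category = category,
                       ref_codon = refc, alt_codon = altc, aa_change = aach,
                       off_chromosome = !(pl$target %in% chromosomes),
                       stringsAsFactors = FALSE),
            class = c("variant_effects", "data.frame"))
}

#' Summarise variant-effect categories
#'
#' Totals per category, the genic percentage, and the intronic share of genic
#' SNPs (splice-region SNPs are intronic). When `by_chrom` is `TRUE`,
#' per-chromosome rows in the classic column scheme are included (exonic =
#' synonymous + nonsynonymous + start/stop changes; intronic includes splice
#' regions; UTR = 5' + 3'), off-chromosome SNPs excluded from those rows.
#'
#' @param effects a [classify_variants()] result, or a named vector of
#'   category counts.
#' @param by_chrom include the per-chromosome breakdown.
#' @return list of class `effect_summary`: `counts` (all categories),
#'   `n_classified`, `genic`, `genic_pct`, `intronic`, `intronic_pct_of_genic`,
#'   and optionally `per_chrom`.
#' @examples
#' counts <- c(intergenic = 5, intron = 3, splice_region = 1, utr5 = 1,
#'             utr3 = 2, synonymous = 2, nonsynonymous = 1,
#'             start_stop_change = 0)
#' summarize_effects(counts)$genic_pct
#' @export
summarize_effects <- function(effects, by_chrom = FALSE) {
  if (is.data.frame(effects)) {
    counts <- table(factor(effects$category, levels = EFFECT_CATEGORIES))
    counts <- setNames(as.numeric(counts), EFFECT_CATEGORIES)
  } else {
    counts <- setNames(rep(0, length(EFFECT_CATEGORIES)), EFFECT_CATEGORIES)
    counts[names(effects)] <- as.numeric(effects)
  }
  n <- sum(counts)
  genic <- sum(counts[GENIC_CATEGORIES])
  intronic <- sum(counts[c("intron", "splice_region")])
  out <- list(counts = counts, n_classified = n, genic = genic,
              genic_pct = if (n > 0) 100 * genic / n else 0,
              intronic = intronic,
              intronic_pct_of_genic = if (genic > 0) 100 * intronic / genic
                                      else 0)
  if (by_chrom && is.data.frame(effects)) {
    on <- effects[!effects$off_chromosome, ]
    out$per_chrom <- do.call(rbind, lapply(split(on, on$target), function(d) {
      data.frame(chrom = d$target[1],
                 snps = nrow(d),
                 exonic = sum(d$category %in% EXONIC_CATEGORIES),
                 intronic = sum(d$category %in% c("intron", "splice_region")),
                 utr = sum(d$category %in% c("utr5", "utr3")),
                 intergenic = sum(d$category == "intergenic"),
                 stringsAsFactors = FALSE)
    }))
    rownames(out$per_chrom) <- NULL
  }
  class(out) <- "effect_summary"
  out
}

#' @method print effect_summary
#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%d classified SNPs: %.0f genic (%.1f%%), of which %.0f intronic (%.1f%%)\n",
              x$n_classified, x$genic, x$genic_pct, x$intronic,
              x$intronic_pct_of_genic))
  print(x$counts)
  invisible(x)
}
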