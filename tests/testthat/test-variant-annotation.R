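test_that("find_orf honours the minimum length, longest rule and 5'-most tie-break", {
  orf_seq <- function(n_codons, utr5 = "CCCC", utr3 = "GGGG") {
    paste0(utr5, "ATG", strrep("GCT", n_codons - 1), "TAA", utr3)
  }
  s <- orf_seq(120)
  orf <- find_orf(s)
  expect_identical(orf$aa, 120L)
  expect_identical(orf$start, 5L)
  expect_identical(substr(s, orf$start, orf$start + 2), "ATG")
  expect_identical(substr(s, orf$end - 2, orf$end), "TAA")

  expect_null(find_orf(orf_seq(99)))          # below 100 aa
  expect_identical(find_orf(orf_seq(100))$aa, 100L)

  # two qualifying ORFs 150 and 120 aa -> the longest wins
  s2 <- paste0(orf_seq(120), "TT", orf_seq(150))
  expect_identical(find_orf(s2)$aa, 150L)
})

test_that("canonical transcript selection uses expression then ORF length", {
  mk_tr <- function(id, expr, cds_nt) {
    list(id = id, expression = expr,
         exons = cbind(0L, 10000L), cds = cbind(0L, as.integer(cds_nt)),
         utr5 = matrix(integer(0), 0, 2), utr3 = matrix(integer(0), 0, 2))
  }
  gene <- list(id = "G1", chrom = "chr1", strand = "+",
               transcripts = list(mk_tr("t1", 5, 360), mk_tr("t2", 9, 360)))
  expect_identical(select_canonical_transcript(gene)$id, "t2")
  gene2 <- list(id = "G2", chrom = "chr1", strand = "+",
                transcripts = list(mk_tr("t1", 5, 360), mk_tr("t2", 5, 900)))
  expect_identical(select_canonical_transcript(gene2)$id, "t2")
  gene3 <- list(id = "G3", chrom = "chr1", strand = "+",
                transcripts = list(mk_tr("t1", 5, 360)))
  expect_identical(select_canonical_transcript(gene3)$id, "t1")
})

test_that("classifier agrees with the generation-time truth labels on every SNP", {
  sim <- fx_genes()
  pl <- truth_placements(sim)
  eff <- classify_variants(pl, sim$models, sim$genome,
                           sim$gm$markers[, c("id", "ref", "alt")])
  tm <- sim$truth$markers
  m <- merge(eff, tm[, c("id", "effect")], by.x = "marker_id", by.y = "id")
  expect_identical(nrow(m), nrow(tm))
  expect_identical(m$category, m$effect)
  # fixture exercises the interesting categories
  expect_true(all(c("intron", "utr5", "utr3", "synonymous", "nonsynonymous")
                  %in% m$category))
})

test_that("codon-level decisions agree with brute-force translation of the mutant CDS", {
  sim <- fx_genes()
  pl <- truth_placements(sim)
  eff <- classify_variants(pl, sim$models, sim$genome,
                           sim$gm$markers[, c("id", "ref", "alt")])
  exonic <- eff[eff$category %in% c("synonymous", "nonsynonymous",
                                    "start_stop_change"), ]
  expect_gt(nrow(exonic), 5)
  tm <- sim$truth$markers
  genes <- setNames(sim$models$genes,
                    vapply(sim$models$genes, `[[`, "", "id"))
  for (i in seq_len(nrow(exonic))) {
    g <- genes[[exonic$gene[i]]]
    tr <- salmap:::truth_canonical(g)
    ref_cds <- salmap:::transcript_cds_seq(sim$genome, g$chrom, tr, g$strand)
    row <- tm[tm$id == exonic$marker_id[i], ]
    cds_pos <- unlist(lapply(seq_len(nrow(tr$cds)), function(k)
      seq(tr$cds[k, 1], tr$cds[k, 2] - 1L)))
    if (g$strand == "-") cds_pos <- rev(cds_pos)
    t_idx <- match(row$pos0, cds_pos)
    alt_t <- if (g$strand == "+") row$alt else
      c(A = "T", C = "G", G = "C", T = "A")[[row$alt]]
    alt_cds <- ref_cds
    substr(alt_cds, t_idx, t_idx) <- alt_t
    expect_identical(exonic$category[i],
                     salmap:::compare_cds(ref_cds, alt_cds, t_idx),
                     info = exonic$marker_id[i])
  }
})

test_that("canonical classification examples behave as specified", {
  sim <- fx_genes()
  # build a gene index and poke specific positions of a plus-strand gene
  idx <- salmap:::build_gene_index(sim$models, sim$genome)
  gp <- NULL
  for (g in idx) if (g$strand == "+") { gp <- g; break }
  expect_false(is.null(gp))
  # splice region: 5 bp inside the first intron vs 20 bp inside
  ex_end0 <- gp$exons[1, 2]            # first intron starts here (0-based)
  intron_len <- gp$exons[2, 1] - ex_end0
  expect_gt(intron_len, 30)
  r5 <- salmap:::classify_one(gp, ex_end0 + 4L, "A", "C", 8)
  expect_identical(r5$category, "splice_region")
  r20 <- salmap:::classify_one(gp, ex_end0 + 19L, "A", "C", 8)
  expect_identical(r20$category, "intron")
  # start codon change
  t_start <- gp$orf$start
  # genome position of the first ORF base (plus strand)
  gpos <- NULL
  off <- t_start - 1L
  for (k in seq_len(nrow(gp$exons))) {
    w <- gp$exons[k, 2] - gp$exons[k, 1]
    if (off < w) { gpos <- gp$exons[k, 1] + off; break }
    off <- off - w
  }
  ref <- substr(gp$seq, t_start, t_start)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_identical(salmap:::classify_one(gp, gpos, ref, alt, 8)$category,
                   "start_stop_change")
  # a synonymous third-position change: GAA -> GAG (both Glu)
  cds <- substr(gp$seq, gp$orf$start, gp$orf$end)
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  k <- which(codons == "GAA")
  k <- k[k > 1 & k < length(codons)][1]
  skip_if(is.na(k), "no internal GAA codon in this gene")
  tpos <- gp$orf$start + 3L * (k - 1L) + 2L  # third base of the codon
  off <- tpos - 1L
  for (j in seq_len(nrow(gp$exons))) {
    w <- gp$exons[j, 2] - gp$exons[j, 1]
    if (off < w) { gpos2 <- gp$exons[j, 1] + off; break }
    off <- off - w
  }
  expect_identical(salmap:::classify_one(gp, gpos2, "A", "G", 8)$category,
                   "synonymous")
})

test_that("classification is invariant under genome reverse complementation", {
  sim <- fx_genes()
  pl <- truth_placements(sim)
  al <- sim$gm$markers[, c("id", "ref", "alt")]
  eff1 <- classify_variants(pl, sim$models, sim$genome, al)

  L <- sim$genome$chrom_lengths[["chr1"]]
  g2 <- sim$genome
  g2$chromosomes <- Biostrings::reverseComplement(g2$chromosomes)
  names(g2$chromosomes) <- names(sim$genome$chromosomes)
  flip <- function(m) {
    if (nrow(m) == 0) return(m)
    out <- cbind(L - m[, 2], L - m[, 1])
    out[order(out[, 1]), , drop = FALSE]
  }
  models2 <- sim$models
  models2$genes <- lapply(sim$models$genes, function(g) {
    g$strand <- if (g$strand == "+") "-" else "+"
    s0 <- g$start0
    g$start0 <- L - g$end0
    g$end0 <- L - s0
    g$transcripts <- lapply(g$transcripts, function(t) {
      t$exons <- flip(t$exons); t$cds <- flip(t$cds)
      t$utr5 <- flip(t$utr5); t$utr3 <- flip(t$utr3)
      t
    })
    g
  })
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pl2 <- pl
  pl2$pos <- L - (pl$pos - 1L)  # 0-based p -> L-1-p, then +1
  al2 <- al
  al2$ref <- comp[al$ref]
  al2$alt <- comp[al$alt]
  eff2 <- classify_variants(pl2, models2, g2, al2)
  m <- merge(eff1, eff2, by = "marker_id")
  expect_identical(m$category.x, m$category.y)
})

test_that("effect summaries are exhaustive, exclusive and match printed-count arithmetic", {
  sim <- fx_genes()
  pl <- truth_placements(sim)
  eff <- classify_variants(pl, sim$models, sim$genome,
                           sim$gm$markers[, c("id", "ref", "alt")])
  s <- summarize_effects(eff, by_chrom = TRUE)
  expect_equal(sum(s$counts), nrow(eff))
  expect_equal(sum(s$per_chrom$exonic + s$per_chrom$intronic +
                     s$per_chrom$utr + s$per_chrom$intergenic),
               sum(!eff$off_chromosome))
  # count-vector interface
  s0 <- summarize_effects(c(intergenic = 0))
  expect_equal(s0$n_classified, 0)
  expect_equal(s0$genic_pct, 0)
})
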