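test_that("genome generation is deterministic and honours the unplaced fraction", {
  g1 <- generate_genome(2, c(3e5, 4e5), unplaced_fraction = 0.22, seed = 9)
  g2 <- generate_genome(2, c(3e5, 4e5), unplaced_fraction = 0.22, seed = 9)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  frac <- sum(g1$contig_info$length) / sum(as.numeric(g1$chrom_lengths))
  expect_lt(abs(frac - 0.22), 0.1 * 0.22)

  g0 <- generate_genome(2, c(3e5, 4e5), unplaced_fraction = 0, seed = 9)
  expect_identical(nrow(g0$contig_info), 0L)
  # contig names disjoint from chromosome names, sequences are excised copies
  expect_length(intersect(g1$contig_info$name, names(g1$chrom_lengths)), 0)
  asm <- assembly_seqs(g1)
  ci <- g1$contig_info[1, ]
  expect_identical(
    as.character(asm[[ci$name]]),
    as.character(Biostrings::subseq(g1$chromosomes[[ci$source_chrom]],
                                    ci$start0 + 1, width = ci$length)))
  # excised window is masked in the assembly chromosome record
  masked <- Biostrings::subseq(asm[[ci$source_chrom]], ci$start0 + 1,
                               width = ci$length)
  expect_identical(as.character(masked), strrep("N", ci$length))
})

test_that("genome generation fails when chromosomes cannot host the contigs", {
  expect_error(generate_genome(1, c(5e3, 5e3), unplaced_fraction = 0.9,
                               seed = 1, contigs_per_chrom = 3))
})

test_that("meiosis crossover counts are Poisson with mean equal to Morgan length", {
  g <- generate_genome(1, c(1e7, 1e7), 0, seed = 4)
  # flat 10 cM/Mb female landscape on 10 Mb -> 100 cM = 1 Morgan
  ls <- recomb_landscape(g, male_interior_rate = 10, male_subtel_factor = 1,
                         subtel_fraction = 0, female_base_rate = 10)
  hap <- rbind(rep(0L, 5), rep(1L, 5))
  pos <- seq(0, 9e6, length.out = 5)
  n <- withr::with_seed(11, {
    replicate(4000, {
      seg <- ls[ls$chrom == "chr1", ]
      length(salmap:::meiosis_gamete(hap[1, ], hap[2, ], pos, seg$start,
                                     seg$end, seg$female_rate)$crossovers)
    })
  })
  expect_lt(abs(mean(n) - 1), 3 * sqrt(1 / 4000) + 0.02)  # Poisson(1) mean
  expect_lt(abs(var(n) - 1), 0.15)                        # Poisson variance
})

test_that("zero intensity gives a gamete identical to one parental haplotype", {
  g <- generate_genome(1, c(1e5, 1e5), 0, seed = 4)
  ls <- recomb_landscape(g, male_interior_rate = 0, male_subtel_factor = 1,
                         subtel_fraction = 0, female_base_rate = 0)
  hapA <- rep(0L, 20); hapB <- rep(1L, 20)
  res <- simulate_meiosis(rbind(hapA, hapB), seq(0, 9e4, length.out = 20),
                          ls, "chr1", "male", seed = 5)
  expect_length(res$crossovers, 0)
  expect_true(identical(res$gamete, hapA) || identical(res$gamete, hapB))
})

test_that("male subtelomeric elevation is recovered from simulated crossovers", {
  g <- generate_genome(1, c(1e7, 1e7), 0, seed = 4)
  ls <- recomb_landscape(g)  # defaults: 10x over outer 10% of each end
  seg <- ls[ls$chrom == "chr1", ]
  L <- 1e7
  xo <- withr::with_seed(12, {
    unlist(replicate(12000, salmap:::meiosis_gamete(
      0L, 1L, 5e6, seg$start, seg$end, seg$male_rate)$crossovers,
      simplify = FALSE))
  })
  sub <- mean(xo < 0.1 * L | xo > 0.9 * L)
  # per-Mb density ratio: (sub/2Mb) / ((1-sub)/8Mb)
  ratio <- (sub / 2) / ((1 - sub) / 8)
  expect_lt(abs(ratio - 10), 1.5)
})

test_that("landscape integral matches the configured female:male ratio", {
  g <- generate_genome(3, c(5e6, 9e6), 0, seed = 21)
  ls <- recomb_landscape(g)
  len <- landscape_lengths(ls)
  expect_true(all(abs(len$female_cM / len$male_cM - 1.5) < 0.015))
})

test_that("founder allele frequencies follow the MAF distribution", {
  g <- generate_genome(1, c(2e5, 2e5), 0, seed = 31)
  ped <- make_pedigree(250, 250, 1, seed = 1)  # 500 founders
  sg <- simulate_genotypes(g, ped, n_markers = 40,
                           landscape = recomb_landscape(g),
                           maf_distribution = function(n) rep(0.3, n),
                           genotyping_error_rate = 0, missing_rate = 0,
                           seed = 5)
  founders <- sg$gm$individuals$role == "founder"
  p <- rowMeans(sg$gm$G[, founders]) / 2
  # 1000 founder haplotypes per marker: binomial se ~ 0.0145
  expect_true(all(abs(p - 0.3) < 5 * sqrt(0.3 * 0.7 / 1000)))
})

test_that("error-free genotypes contain no Mendelian-inconsistent trios and flanks round-trip", {
  sim <- fx_clean()
  rates <- mendelian_error_rates(sim$gm)
  expect_true(all(rates$marker$errors == 0))
  expect_true(all(rates$individual$errors == 0))
  # every flank is an exact 71-mer found at its true assembly position
  expect_true(all(nchar(sim$flanks$flank) == 71))
  pl <- place_markers_by_flank(sim$flanks, sim$genome)
  expect_true(all(pl$status == "unique"))
  tm <- sim$truth$markers
  m <- merge(pl, tm[, c("id", "target", "target_pos0")],
             by.x = "marker_id", by.y = "id")
  expect_true(all(m$target.x == m$target.y))
  expect_true(all(m$pos == m$target_pos0 + 1))
})

test_that("truth cM positions reproduce the configured length ratio exactly", {
  sim <- fx_small()
  tm <- sim$truth$markers
  len <- landscape_lengths(sim$landscape)
  for (ch in unique(tm$chrom)) {
    i <- tm$chrom == ch
    expect_equal(max(tm$cM_female[i]) / max(tm$cM_male[i]),
                 len$female_cM[len$chrom == ch] / len$male_cM[len$chrom == ch],
                 tolerance = 0.05)
  }
})

test_that("fixed seed fixes every emitted file byte-for-byte", {
  d1 <- tempfile(); d2 <- tempfile()
  args <- list(seed = 5, n_chrom = 1, length_range = c(3e5, 3e5),
               unplaced_fraction = 0.2, n_genes = 5, n_markers = 60,
               n_sires = 2, n_dams = 4, offspring_per_family = 4)
  do.call(simulate_study, c(args, dir = d1))
  do.call(simulate_study, c(args, dir = d2))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generated gene models have valid codon structure on both strands", {
  sim <- fx_genes()
  for (gene in sim$models$genes) {
    for (tr in gene$transcripts) {
      cds_len <- sum(tr$cds[, 2] - tr$cds[, 1])
      expect_identical(cds_len %% 3L, 0L)
      cds <- salmap:::transcript_cds_seq(sim$genome, gene$chrom, tr,
                                         gene$strand)
      expect_identical(substr(cds, 1, 3), "ATG")
      expect_true(substr(cds, cds_len - 2, cds_len) %in%
                    c("TAA", "TAG", "TGA"))
      prot <- salmap:::translate_chr(substr(cds, 1, cds_len - 3))
      expect_false(grepl("\\*", prot))  # no internal stop codons
    }
  }
  expect_true(any(vapply(sim$models$genes, function(g) g$strand == "-",
                         logical(1))))
})

test_that("with no genes every simulated SNP is truth-labelled intergenic", {
  sim <- fx_small()
  expect_true(all(sim$truth$markers$effect == "intergenic"))
})
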