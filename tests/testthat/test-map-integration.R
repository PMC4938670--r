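toy_genome <- function() {
  # two deterministic 3 kb chromosomes
  withr::with_seed(5, {
    seqs <- Biostrings::DNAStringSet(c(
      chr1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""),
      chr2 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")))
    seqs
  })
}

flank_at <- function(seqs, chrom, pos0) {
  as.character(Biostrings::subseq(seqs[[chrom]], pos0 - 35 + 1, pos0 + 36))
}

test_that("flank placement finds exact hits on both strands with the SNP centred", {
  seqs <- toy_genome()
  fl <- data.frame(
    marker_id = c("fwd", "rev"),
    flank = c(flank_at(seqs, "chr2", 1000),
              revcomp <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(flank_at(seqs, "chr1", 500))))),
    offset = 35L, stringsAsFactors = FALSE)
  pl <- place_markers_by_flank(fl, seqs)
  f <- pl[pl$marker_id == "fwd", ]
  expect_identical(f$target, "chr2")
  expect_identical(f$pos, 1001L)  # 0-based 1000 -> 1-based 1001
  expect_identical(f$strand, "+")
  r <- pl[pl$marker_id == "rev", ]
  expect_identical(r$target, "chr1")
  expect_identical(r$pos, 501L)   # same SNP coordinate, minus strand
  expect_identical(r$strand, "-")
})

test_that("the central base is a wildcard and bad flanks are skipped", {
  seqs <- toy_genome()
  fl35 <- flank_at(seqs, "chr1", 700)
  mutated <- fl35
  base <- substr(mutated, 36, 36)
  substr(mutated, 36, 36) <- setdiff(c("A", "C", "G", "T"), base)[1]
  bad <- fl35
  substr(bad, 10, 10) <- "N"
  fl <- data.frame(marker_id = c("mut", "bad"),
                   flank = c(mutated, bad), offset = 35L,
                   stringsAsFactors = FALSE)
  pl <- place_markers_by_flank(fl, seqs)
  expect_identical(pl$pos[pl$marker_id == "mut"], 701L)
  expect_false("bad" %in% pl$marker_id)
  expect_identical(attr(pl, "skipped"), "bad")
})

test_that("multi-hit flanks are recorded and resolved by linkage", {
  seqs <- toy_genome()
  # duplicate a 71-mer from chr1 into chr2 -> two exact hits
  dup <- flank_at(seqs, "chr1", 1500)
  seqs2 <- seqs
  seqs2[["chr2"]] <- Biostrings::replaceAt(
    seqs2[["chr2"]], IRanges::IRanges(2001, 2071), Biostrings::DNAString(dup))
  fl <- data.frame(marker_id = "dup", flank = dup, offset = 35L,
                   stringsAsFactors = FALSE)
  pl <- place_markers_by_flank(fl, seqs2)
  expect_identical(nrow(pl), 2L)
  expect_true(all(pl$status == "multi"))
  expect_identical(pl$n_exact_hits, c(2L, 2L))

  fake_map <- list(groups = list(LG1 = "dup"))
  lg2 <- data.frame(linkage_group = "LG1", chrom = "chr1", n_support = 5L)
  res <- resolve_multihit(pl, fake_map, lg2)
  expect_identical(nrow(res), 1L)
  expect_identical(res$status, "resolved_by_linkage")
  expect_identical(res$target, "chr1")

  # marker not in any group -> unresolved, all candidates listed
  fake_map0 <- list(groups = list(LG1 = "other"))
  res0 <- resolve_multihit(pl, fake_map0, lg2)
  expect_identical(nrow(res0), 2L)
  expect_true(all(res0$status == "unresolved"))
})

test_that("Pearson concordance matches the textbook formula and orientation invariance", {
  # constructed placements/map: cM = (0,1,2,3,4), bp = (0,10,20,40,30)
  fake_map <- list(
    groups = list(LG1 = sprintf("m%d", 1:5)),
    maps = list(LG1 = data.frame(marker_id = sprintf("m%d", 1:5),
                                 order_index = 1:5,
                                 male_cM = 0:4, female_cM = (0:4) * 2)))
  pl <- data.frame(marker_id = sprintf("m%d", 1:5), target = "chr1",
                   pos = c(0, 10, 20, 40, 30) + 1L, strand = "+",
                   n_exact_hits = 1L, status = "unique",
                   stringsAsFactors = FALSE)
  lg2 <- data.frame(linkage_group = "LG1", chrom = "chr1", n_support = 5L)
  r <- per_chrom_correlation(fake_map, pl, lg2)
  expect_equal(r$r_male, 0.9)
  expect_equal(r$r_female, 0.9)
  # reversed genetic order: |r| unchanged
  fake_map$maps$LG1$male_cM <- rev(fake_map$maps$LG1$male_cM)
  fake_map$maps$LG1$order_index <- 5:1
  r2 <- per_chrom_correlation(fake_map, pl, lg2)
  expect_equal(r2$r_male, 0.9)
})

test_that("contig anchoring follows the strict-plurality rule", {
  fake_map <- list(groups = list(LG1 = c("a1", "a2", "a3", "t1", "t2"),
                                 LG2 = c("b1", "t3", "t4")))
  lg2 <- data.frame(linkage_group = c("LG1", "LG2"),
                    chrom = c("chr5", "chr7"), n_support = c(3L, 1L))
  pl <- data.frame(
    marker_id = c("a1", "a2", "a3", "t1", "t2", "t3", "t4"),
    target = c("ctgA", "ctgA", "ctgA", "ctgT", "ctgT", "ctgT", "ctgT"),
    pos = 1L, strand = "+", n_exact_hits = 1L, status = "unique",
    stringsAsFactors = FALSE)
  contigs <- data.frame(name = c("ctgA", "ctgT", "ctgZ"),
                        length = c(1000L, 2000L, 500L),
                        stringsAsFactors = FALSE)
  rep <- anchor_contigs(pl, fake_map, contigs, lg2)
  ct <- rep$contigs
  expect_identical(ct$chrom[ct$contig == "ctgA"], "chr5")  # unanimity
  expect_true(is.na(ct$chrom[ct$contig == "ctgT"]))        # 2 vs 2 tie
  expect_true(is.na(ct$chrom[ct$contig == "ctgZ"]))        # zero support
  expect_identical(rep$totals$n_anchored, 1L)
  expect_identical(rep$totals$bp_anchored, 1000L)
  # conservation: anchored bp equals sum of assigned contig lengths
  expect_identical(rep$totals$bp_anchored,
                   sum(ct$length[!is.na(ct$chrom)]))
})

test_that("discordance detection flags translocated blocks and respects the run gate", {
  mkmap <- function(order_index) list(
    groups = list(LG1 = sprintf("m%d", seq_along(order_index))),
    maps = list(LG1 = data.frame(marker_id = sprintf("m%d", seq_along(order_index)),
                                 order_index = order_index,
                                 male_cM = order_index, female_cM = order_index)))
  mkpl <- function(n) data.frame(marker_id = sprintf("m%d", 1:n),
                                 target = "chr1", pos = (1:n) * 100L,
                                 strand = "+", n_exact_hits = 1L,
                                 status = "unique", stringsAsFactors = FALSE)
  lg2 <- data.frame(linkage_group = "LG1", chrom = "chr1", n_support = 20L)
  # fully concordant
  d0 <- detect_discordance(mkmap(1:20), mkpl(20), lg2)
  expect_identical(nrow(d0$segments), 0L)
  # block of 5 translocated in genetic order
  oi <- c(1:5, 16:20, 6:15)     # physical 6..10 carry genetic 16..20
  d1 <- detect_discordance(mkmap(oi), mkpl(20), lg2)
  expect_identical(nrow(d1$segments), 1L)
  expect_identical(d1$segments$n_markers, 5L)
  expect_identical(d1$segments$start_bp, 600L)
  expect_identical(d1$segments$end_bp, 1000L)
  # two isolated discordant markers below the run gate
  oi2 <- 1:20
  oi2[c(5, 6)] <- oi2[c(6, 5)]
  oi2[c(14, 15)] <- oi2[c(15, 14)]
  d2 <- detect_discordance(mkmap(oi2), mkpl(20), lg2, min_run = 3)
  expect_identical(nrow(d2$segments), 0L)
})

test_that("error-free end-to-end integration places, anchors and stays concordant", {
  sim <- fx_clean()
  qc <- genotype_qc(sim$gm)$gm
  lm <- linkage_map(qc, seed = 1)
  int <- integrate_map(lm, sim$flanks[sim$flanks$marker_id %in% qc$markers$id, ],
                       sim$genome)
  # 100% unique placement at true coordinates
  pl <- int$placements
  expect_true(all(pl$status == "unique"))
  tm <- sim$truth$markers
  m <- merge(pl, tm[, c("id", "target", "target_pos0")],
             by.x = "marker_id", by.y = "id")
  expect_true(all(m$pos == m$target_pos0 + 1))
  # genetic-physical concordance: the female track is tight; the male track
  # is limited by order information at the subtelomeric ends, where most of
  # the male map lives (see the methods vignette on ordering limits)
  expect_true(all(int$correlations$r_female >= 0.95))
  expect_true(all(int$correlations$r_male >= 0.85))
  # discordance stays a minority phenomenon on error-free data
  disc_markers <- sum(int$discordance$segments$n_markers)
  expect_lt(disc_markers, 0.25 * sum(int$placements$status == "unique"))
  # every contig with placed markers anchors to its true source chromosome
  ct <- int$anchors$contigs
  ci <- sim$genome$contig_info
  anchored <- ct[!is.na(ct$chrom), ]
  expect_gt(nrow(anchored), 0)
  expect_true(all(anchored$chrom ==
                    ci$source_chrom[match(anchored$contig, ci$name)]))
})

test_that("placement is strand-consistent under genome reverse complementation", {
  sim <- fx_clean()
  fl <- head(sim$flanks, 40)
  pl1 <- place_markers_by_flank(fl, sim$genome)
  seqs <- assembly_seqs(sim$genome)
  rc <- Biostrings::reverseComplement(seqs)
  names(rc) <- names(seqs)
  pl2 <- place_markers_by_flank(fl, rc)
  m <- merge(pl1, pl2, by = "marker_id")
  # coordinate reflects: pos' = len - pos + 1; strand flips
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  expect_true(all(m$target.x == m$target.y))
  expect_true(all(m$pos.y == lens[m$target.x] - m$pos.x + 1))
  expect_true(all(m$strand.x != m$strand.y))
})
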