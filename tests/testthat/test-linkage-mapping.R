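# hand-built pedigree genotypes for controlled two-point scenarios:
# `sire_pat` gives the sire's transmitted allele per offspring per marker.
phase_known_gm <- function(sire_pat) {
  # sire het at both markers, dam hom ref: offspring genotype = sire allele
  n_off <- ncol(sire_pat)
  G <- cbind(matrix(1L, nrow(sire_pat), 1),      # sire het
             matrix(0L, nrow(sire_pat), 1),      # dam hom ref
             sire_pat)                           # offspring 0/1
  ind <- data.frame(
    id = c("S1", "D1", sprintf("O%02d", seq_len(n_off))),
    sire = c(NA, NA, rep("S1", n_off)), dam = c(NA, NA, rep("D1", n_off)),
    sex = c("M", "F", rep("F", n_off)),
    role = c("founder", "founder", rep("offspring", n_off)),
    stringsAsFactors = FALSE)
  genotype_matrix(G, data.frame(id = sprintf("M%d", seq_len(nrow(sire_pat))),
                                ref = "A", alt = "C",
                                stringsAsFactors = FALSE), ind)
}

test_that("two-point estimate recovers theta from a phase-known cross", {
  # 10 offspring, 2 paternal recombinants -> theta_male = 0.2
  pat <- rbind(c(rep(0L, 5), rep(1L, 5)),
               c(rep(0L, 4), 1L, rep(1L, 4), 0L))  # recombinant at 5 and 10
  gm <- phase_known_gm(pat)
  tp <- two_point_estimate(gm, "M1", "M2")
  expect_equal(tp$theta_male, 0.2, tolerance = 1e-3)
  expect_identical(tp$n_informative[["male"]], 10L)
  expect_identical(tp$n_informative[["female"]], 0L)

  # LOD equals the exhaustive likelihood-grid maximum
  gr <- two_point_grid(gm, "M1", "M2", grid = seq(0, 0.5, by = 0.001),
                       sex = "male")
  expect_equal(gr$theta_hat, 0.2, tolerance = 1e-3)
  grp <- two_point_grid(gm, "M1", "M2", grid = seq(0, 0.5, by = 0.001))
  expect_equal(tp$lod, grp$lod, tolerance = 1e-4)
})

test_that("duplicated marker columns give theta 0 and unlinked markers theta ~0.5", {
  sim <- fx_small()
  qc <- genotype_qc(sim$gm)$gm
  tm <- sim$truth$markers
  ids <- qc$markers$id
  # duplicate: a marker against itself
  tp <- two_point_estimate(qc, ids[1], ids[1])
  expect_equal(tp$theta_pooled, 0, tolerance = 1e-6)
  # markers on different chromosomes
  ch <- tm$chrom[match(ids, tm$id)]
  i <- which(ch == "chr1")[1]; j <- which(ch == "chr2")[1]
  tp2 <- two_point_estimate(qc, ids[i], ids[j])
  expect_gt(tp2$theta_pooled, 0.35)
  expect_lt(tp2$lod, 3)
})

test_that("EM theta matches the grid oracle across random informative pairs", {
  sim <- fx_small()
  qc <- genotype_qc(sim$gm)$gm
  ids <- qc$markers$id
  set.seed(99)
  pairs <- cbind(sample(length(ids), 25), sample(length(ids), 25))
  for (k in seq_len(nrow(pairs))) {
    tp <- two_point_estimate(qc, ids[pairs[k, 1]], ids[pairs[k, 2]])
    gr <- two_point_grid(qc, ids[pairs[k, 1]], ids[pairs[k, 2]],
                         grid = seq(0, 0.5, by = 0.005))
    if (is.na(tp$theta_pooled)) next
    expect_lt(abs(tp$theta_pooled - gr$theta_hat), 0.005 + 1e-9)
    expect_lt(abs(tp$lod - gr$lod), 0.02 + 0.01 * gr$lod)
  }
})

test_that("clustering respects degenerate thresholds and monotonicity", {
  sim <- fx_clean()
  qc <- genotype_qc(sim$gm)$gm
  tr <- salmap:::build_transmissions(qc)
  pairs <- salmap:::pairwise_lod(tr)
  cl0 <- cluster_groups(pairs, 0)
  # threshold 0: all markers with any informative pair in one group
  expect_identical(length(cl0$groups), 1L)
  clI <- cluster_groups(pairs, Inf)
  expect_identical(length(clI$groups), 0L)
  expect_identical(length(clI$unassigned), nrow(qc$G))
  # group count monotone non-decreasing in threshold
  counts <- vapply(c(2, 5, 10, 20, 40),
                   function(t) length(cluster_groups(pairs, t)$groups) +
                     length(cluster_groups(pairs, t)$unassigned), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the plateau threshold recovers the simulated chromosome partition", {
  sim <- fx_clean()
  qc <- genotype_qc(sim$gm)$gm
  lm <- linkage_map(qc, seed = 1)
  expect_identical(length(lm$maps), 2L)
  tm <- sim$truth$markers
  for (g in names(lm$groups)) {
    chs <- unique(tm$chrom[match(lm$groups[[g]], tm$id)])
    expect_identical(length(chs), 1L)
  }
})

test_that("join_singles applies the limit and margin rules", {
  # synthetic pairwise matrices: 5 markers, groups {1,2} and {3,4}, single 5
  lod <- matrix(0, 5, 5, dimnames = list(sprintf("M%d", 1:5),
                                         sprintf("M%d", 1:5)))
  lod[1, 2] <- lod[2, 1] <- 50
  lod[3, 4] <- lod[4, 3] <- 50
  ni <- matrix(10L, 5, 5)
  cl <- list(groups = list(LG1 = c("M1", "M2"), LG2 = c("M3", "M4")),
             unassigned = "M5")
  with_lod <- function(a, b) {
    l <- lod
    l["M5", "M1"] <- l["M1", "M5"] <- a
    l["M5", "M3"] <- l["M3", "M5"] <- b
    list(lod = l, n_inf = ni)
  }
  j1 <- join_singles(cl, with_lod(40, 2), lod_limit = 20)
  expect_true("M5" %in% j1$groups$LG1)
  j2 <- join_singles(cl, with_lod(10, 2), lod_limit = 20)
  expect_identical(j2$unassigned, "M5")
  j3 <- join_singles(cl, with_lod(25, 24.5), lod_limit = 20)
  expect_identical(j3$unassigned, "M5")  # ambiguous margin
})

test_that("ordering recovers collinear noise-free orders and exhaustive optima", {
  # 10 markers with theta from true collinear positions, noise-free
  pos_cM <- c(0, 4, 9, 15, 22, 30, 39, 49, 60, 72)
  th <- (1 - exp(-2 * abs(outer(pos_cM, pos_cM, "-")) / 100)) / 2  # Haldane inverse
  ids <- sprintf("M%02d", 1:10)
  dimnames(th) <- list(ids, ids)
  lodm <- 50 - 49 * th / 0.5
  dimnames(lodm) <- dimnames(th)
  pairs <- list(theta = th, lod = lodm, n_inf = matrix(100L, 10, 10))
  om <- order_markers(sample(ids), pairs, seed = 3)
  expect_true(identical(om$order, ids) || identical(om$order, rev(ids)))

  # n <= 8: heuristic equals exhaustive-permutation minimum by construction;
  # compare against an independent brute force over all orders
  set.seed(7)
  n <- 7
  th7 <- matrix(runif(n * n, 0.05, 0.45), n, n)
  th7 <- (th7 + t(th7)) / 2
  diag(th7) <- 0
  ids7 <- sprintf("A%d", seq_len(n))
  dimnames(th7) <- list(ids7, ids7)
  pairs7 <- list(theta = th7, lod = th7 * 0 + 10, n_inf = matrix(10L, n, n))
  om7 <- order_markers(ids7, pairs7, seed = 1)
  D <- haldane_cM(th7, 50)
  best <- Inf
  perm <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm(v[-i]), function(p) c(v[i], p))))
  for (p in perm(seq_len(n))) {
    len <- sum(D[cbind(p[-n], p[-1])])
    if (len < best) best <- len
  }
  expect_equal(om7$length, best, tolerance = 1e-9)
})

test_that("map length is invariant under order reversal", {
  sim <- fx_clean()
  qc <- genotype_qc(sim$gm)$gm
  tm <- sim$truth$markers
  ids <- qc$markers$id
  sel <- tm[tm$id %in% ids & tm$chrom == "chr1", ]
  ord <- sel$id[order(sel$pos0)]
  d1 <- sex_specific_distances(qc, ord, bin_size = 1)
  d2 <- sex_specific_distances(qc, rev(ord), bin_size = 1)
  expect_equal(max(d1$male_cM), max(d2$male_cM), tolerance = 1e-9)
  expect_equal(max(d1$female_cM), max(d2$female_cM), tolerance = 1e-9)
})

test_that("map function distances are correct and capped", {
  expect_equal(haldane_cM(0), 0)
  expect_equal(haldane_cM(0.2), -50 * log(0.6))
  expect_equal(haldane_cM(0.2), 25.54, tolerance = 1e-3)
  expect_equal(haldane_cM(0.5), 50)
  expect_equal(kosambi_cM(0.2), 25 * log(1.4 / 0.6))
})

test_that("sex-specific distances recover the simulated female map length", {
  sim <- fx_clean()
  qc <- genotype_qc(sim$gm)$gm
  tm <- sim$truth$markers
  ids <- qc$markers$id
  tot_f <- tot_m <- 0
  for (ch in unique(tm$chrom)) {
    sel <- tm[tm$id %in% ids & tm$chrom == ch, ]
    ord <- sel$id[order(sel$pos0)]
    d <- sex_specific_distances(qc, ord, bin_size = 1)
    tot_f <- tot_f + max(d$female_cM)
    tot_m <- tot_m + max(d$male_cM)
  }
  truth_f <- sum(vapply(unique(tm$chrom), function(ch) {
    i <- tm$chrom == ch & tm$id %in% ids
    max(tm$cM_female[i]) - min(tm$cM_female[i])
  }, numeric(1)))
  expect_lt(abs(tot_f - truth_f) / truth_f, 0.12)
  # recovered heterochiasmy close to the configured 1.5 (sampling slack)
  expect_lt(abs(tot_f / tot_m - 1.5), 0.25)
})
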