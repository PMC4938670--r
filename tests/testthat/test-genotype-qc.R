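# brute-force legality oracle: enumerate parental allele transmissions
legal_oracle <- function(o, s, d) {
  A <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  any(outer(A[[as.character(s)]], A[[as.character(d)]], `+`) == o)
}

gm_from_calls <- function(G, sires, dams, n_off_parents = NULL) {
  # founders first two columns (sire S1, dam D1), offspring after
  nm <- nrow(G)
  n_ind <- ncol(G)
  ind <- data.frame(
    id = c("S1", "D1", sprintf("O%02d", seq_len(n_ind - 2))),
    sire = c(NA, NA, rep("S1", n_ind - 2)),
    dam = c(NA, NA, rep("D1", n_ind - 2)),
    sex = c("M", "F", rep("M", n_ind - 2)),
    role = c("founder", "founder", rep("offspring", n_ind - 2)),
    stringsAsFactors = FALSE)
  genotype_matrix(G, data.frame(id = sprintf("M%02d", seq_len(nm)),
                                ref = "A", alt = "C",
                                stringsAsFactors = FALSE), ind)
}

test_that("Mendelian error calls agree with the 27-state enumeration", {
  # single trio, all 27 genotype combinations, one marker each
  combos <- expand.grid(o = 0:2, s = 0:2, d = 0:2)
  # 27 markers x 3 individuals (S1, D1, O01), one combination per marker
  G <- matrix(as.integer(cbind(combos$s, combos$d, combos$o)), ncol = 3)
  gm <- gm_from_calls(G, "S1", "D1")
  r <- mendelian_error_rates(gm)
  expected <- !mapply(legal_oracle, combos$o, combos$s, combos$d)
  expect_identical(r$marker$errors, as.numeric(expected))
  # canonical cases
  expect_true(expected[combos$o == 1 & combos$s == 0 & combos$d == 0])
  expect_false(expected[combos$o == 1 & combos$s == 0 & combos$d == 2])
  expect_true(expected[combos$o == 0 & combos$s == 0 & combos$d == 2])
})

test_that("Mendelian filtering applies the strict >1% rule", {
  # marker 1: 2 errors in 150 trios (1.33%) -> removed;
  # marker 2: 1 error in 150 (0.67%) -> retained
  n_off <- 150
  G <- rbind(c(0L, 0L, rep(0L, n_off)),
             c(0L, 0L, rep(0L, n_off)))
  G[1, 2 + 1:2] <- 1L   # two impossible hets
  G[2, 2 + 1] <- 1L     # one impossible het
  gm <- gm_from_calls(G, "S1", "D1")
  # offspring error rates: 2 markers checked each, 1 error = 50% for two
  # offspring; disable individual filtering by checking marker stage only
  r <- mendelian_error_rates(gm)
  expect_equal(r$marker$rate, c(2 / 150, 1 / 150))
  f <- filter_mendelian(gm, threshold = 1)  # degenerate: nothing removed
  expect_identical(nrow(f$gm$G), 2L)
  expect_identical(ncol(f$gm$G), ncol(gm$G))
})

test_that("MAF filter computes allele frequency over all calls with strict <", {
  # calls {0: 50, 1: 40, 2: 10} -> p_alt = (40 + 20)/200 = 0.30
  G <- matrix(c(rep(0L, 50), rep(1L, 40), rep(2L, 10)), nrow = 1)
  ind <- data.frame(id = sprintf("I%03d", 1:100), sire = NA, dam = NA,
                    sex = "M", role = "founder", stringsAsFactors = FALSE)
  gm <- genotype_matrix(G, data.frame(id = "M1", ref = "A", alt = "C"), ind)
  r <- maf_filter(gm)
  expect_equal(r$maf$maf, 0.30)
  expect_identical(nrow(r$gm$G), 1L)

  # monomorphic -> MAF 0 -> removed
  gm0 <- genotype_matrix(matrix(0L, 1, 100),
                         data.frame(id = "M1", ref = "A", alt = "C"), ind)
  expect_identical(nrow(maf_filter(gm0)$gm$G), 0L)

  # MAF exactly at the limit is retained
  G5 <- matrix(c(rep(1L, 10), rep(0L, 90)), nrow = 1)  # p = 0.05
  gm5 <- genotype_matrix(G5, data.frame(id = "M1", ref = "A", alt = "C"), ind)
  expect_identical(nrow(maf_filter(gm5, maf_limit = 0.05)$gm$G), 1L)
})

test_that("segregation distortion sums family chi-squares with correct df", {
  # family of 40: het x hom_ref, offspring 20 het / 20 hom -> chisq 0, p 1
  mk <- function(counts01) {
    G <- matrix(c(1L, 0L, rep(0L, counts01[1]), rep(1L, counts01[2])), nrow = 1)
    gm_from_calls(G, "S1", "D1")
  }
  r <- segregation_distortion(mk(c(20, 20)))
  expect_equal(r$test$chisq, 0)
  expect_equal(r$test$p, 1)
  expect_identical(nrow(r$gm$G), 1L)

  # 40 het / 0 hom -> chisq 40, 1 df, p < 0.001 -> removed
  r2 <- segregation_distortion(mk(c(0, 40)))
  expect_equal(r2$test$chisq, 40)
  expect_equal(r2$test$df, 1)
  expect_equal(r2$test$p, pchisq(40, 1, lower.tail = FALSE))
  expect_identical(nrow(r2$gm$G), 0L)

  # het x het 10:20:10 -> perfect 1:2:1
  G <- matrix(c(1L, 1L, rep(0L, 10), rep(1L, 20), rep(2L, 10)), nrow = 1)
  r3 <- segregation_distortion(gm_from_calls(G, "S1", "D1"))
  expect_equal(r3$test$chisq, 0)
  expect_equal(r3$test$df, 2)
})

test_that("QC preserves the marker/individual partition at every stage", {
  sim <- fx_small()
  qc <- genotype_qc(sim$gm)
  n_mk <- nrow(sim$gm$G)
  removed_mk <- sum(qc$removed$type == "marker")
  expect_identical(nrow(qc$gm$G) + removed_mk, n_mk)
  removed_in <- sum(qc$removed$type == "individual")
  expect_identical(ncol(qc$gm$G) + removed_in, ncol(sim$gm$G))
  # one primary reason per removal
  expect_false(any(duplicated(qc$removed$id[qc$removed$type == "marker"])))
})

test_that("error-free fixtures pass QC nearly untouched", {
  sim <- fx_clean()
  qc <- genotype_qc(sim$gm)
  expect_identical(ncol(qc$gm$G), ncol(sim$gm$G))
  # no Mendelian removals without errors; distortion false positives
  # bounded by tolerance x markers (binomial slack); the MAF filter may
  # clip markers whose realised frequency drifted below the limit
  expect_identical(sum(qc$removed$reason == "mendel"), 0L)
  n_dist <- sum(qc$removed$reason == "distortion")
  expect_lte(n_dist, qbinom(0.999, nrow(sim$gm$G), 0.001) + 1)
  expect_lte(nrow(sim$gm$G) - nrow(qc$gm$G), 0.03 * nrow(sim$gm$G))
})
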