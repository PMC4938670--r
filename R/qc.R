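# Legality of an offspring genotype given its parents' genotypes under
# Mendelian transmission. 3x3x3 lookup over (offspring, sire, dam) in {0,1,2}.
mendel_legal_table <- function() {
  trans <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)  # transmissible alleles
  arr <- array(FALSE, dim = c(3, 3, 3))
  for (s in 0:2) for (d in 0:2) {
    poss <- unique(outer(trans[[as.character(s)]], trans[[as.character(d)]], `+`))
    for (o in 0:2) arr[o + 1, s + 1, d + 1] <- o %in% poss
  }
  arr
}

#' Mendelian error rates per marker and per individual
#'
#' A trio (offspring, sire, dam) at a marker is "checked" iff all three calls
#' are non-missing, and is an "error" iff the offspring genotype is impossible
#' under Mendelian transmission from the parental genotypes. Rates are
#' errors/checked; markers or individuals with zero checked trios get rate 0
#' and are flagged. Trio errors are attributed to all three members, as in
#' trio-based Mendel checks.
#'
#' @param gm a [genotype_matrix()].
#' @return list with `marker` (id, checked, errors, rate, no_trios flag) and
#'   `individual` (id, checked, errors, rate, no_trios flag) data frames.
#' @export
mendelian_error_rates <- function(gm) {
  ind <- gm$individuals
  off <- which(ind$role == "offspring")
  legal <- mendel_legal_table()
  nm <- nrow(gm$G)
  mk_err <- mk_chk <- numeric(nm)
  in_err <- in_chk <- setNames(numeric(nrow(ind)), ind$id)
  for (o in off) {
    si <- match(ind$sire[o], ind$id)
    di <- match(ind$dam[o], ind$id)
    if (is.na(si) || is.na(di))
      stopf("offspring %s has a missing parent record", ind$id[o])
    go <- gm$G[, o]; gs <- gm$G[, si]; gd <- gm$G[, di]
    chk <- !is.na(go) & !is.na(gs) & !is.na(gd)
    err <- logical(nm)
    err[chk] <- !legal[cbind(go[chk] + 1L, gs[chk] + 1L, gd[chk] + 1L)]
    mk_chk <- mk_chk + chk
    mk_err <- mk_err + err
    ne <- sum(err); nc <- sum(chk)
    for (w in c(o, si, di)) {
      in_chk[w] <- in_chk[w] + nc
      in_err[w] <- in_err[w] + ne
    }
  }
  marker <- data.frame(id = gm$markers$id, checked = mk_chk, errors = mk_err,
                       rate = ifelse(mk_chk > 0, mk_err / mk_chk, 0),
                       no_trios = mk_chk == 0, stringsAsFactors = FALSE)
  individual <- data.frame(id = ind$id, checked = as.numeric(in_chk),
                           errors = as.numeric(in_err),
                           rate = ifelse(in_chk > 0, in_err / in_chk, 0),
                           no_trios = in_chk == 0, stringsAsFactors = FALSE)
  list(marker = marker, individual = individual)
}

#' Filter individuals and markers by Mendelian error rate
#'
#' Individuals with error rate strictly above `threshold` are removed first;
#' marker rates are then recomputed on the remaining individuals and markers
#' strictly above `threshold` removed.
#'
#' @param gm a [genotype_matrix()].
#' @param threshold maximum tolerated Mendelian error rate (default 0.01,
#'   i.e. the classic "more than 1 percent" exclusion).
#' @return list with `gm` (filtered), `removed_markers`, `removed_individuals`
#'   (with reason), and the final `rates`.
#' @export
filter_mendelian <- function(gm, threshold = 0.01) {
  r1 <- mendelian_error_rates(gm)
  bad_ind <- r1$individual$id[r1$individual$rate > threshold]
  gm2 <- if (length(bad_ind) > 0) {
    # removing a parent also drops its offsprings' trios from checking, but
    # the individuals themselves are retained unless over threshold
    keep <- !(gm$individuals$id %in% bad_ind)
    g <- subset_gm(gm, j = keep)
    g$individuals$sire[!(g$individuals$sire %in% g$individuals$id)] <- NA
    g$individuals$dam[!(g$individuals$dam %in% g$individuals$id)] <- NA
    g$individuals$role[g$individuals$role == "offspring" &
                         (is.na(g$individuals$sire) | is.na(g$individuals$dam))] <- "founder"
    g
  } else gm
  r2 <- mendelian_error_rates(gm2)
  bad_mk <- r2$marker$id[r2$marker$rate > threshold]
  gm3 <- subset_gm(gm2, i = !(gm2$markers$id %in% bad_mk))
  list(gm = gm3,
       removed_markers = data.frame(id = bad_mk, reason = rep("mendel", length(bad_mk)),
                                    stringsAsFactors = FALSE),
       removed_individuals = data.frame(id = bad_ind, reason = rep("mendel", length(bad_ind)),
                                        stringsAsFactors = FALSE),
       rates = r2)
}

#' Minor allele frequency filter
#'
#' MAF is computed over all non-missing calls of all genotyped individuals as
#' `min(p, 1-p)` with `p` the alt-allele frequency; markers with MAF strictly
#' below `maf_limit` (including monomorphic markers, MAF 0) are removed.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_limit threshold (default 0.05); a marker at exactly the limit
#'   is retained.
#' @return list with `gm`, `removed_markers`, and per-marker `maf`.
#' @export
maf_filter <- function(gm, maf_limit = 0.05) {
  n_called <- rowSums(!is.na(gm$G))
  p <- rowSums(gm$G, na.rm = TRUE) / (2 * pmax(n_called, 1))
  maf <- pmin(p, 1 - p)
  maf[n_called == 0] <- 0
  drop <- maf < maf_limit
  list(gm = subset_gm(gm, i = !drop),
       removed_markers = data.frame(id = gm$markers$id[drop],
                                    reason = rep("maf", sum(drop)),
                                    stringsAsFactors = FALSE),
       maf = data.frame(id = gm$markers$id, maf = maf, stringsAsFactors = FALSE))
}

#' Segregation distortion test
#'
#' Within each family where at least one parent is heterozygous at the marker,
#' offspring genotype counts are tested against the expected Mendelian
#' proportions: 1:1 over the two possible offspring genotypes for
#' backcross-type matings (one het parent, one homozygous parent) and 1:2:1
#' for intercross-type (het x het). The per-marker statistic sums the family
#' chi-squares (df summed likewise); families contributing fewer than two
#' informative offspring are skipped. Markers with `p < tolerance` are
#' removed.
#'
#' @param gm a [genotype_matrix()].
#' @param tolerance p-value threshold (default 0.001).
#' @return list with `gm`, `removed_markers`, and a per-marker `test` table
#'   (chisq, df, p).
#' @export
segregation_distortion <- function(gm, tolerance = 0.001) {
  ind <- gm$individuals
  off <- ind[ind$role == "offspring", ]
  fams <- split(match(off$id, ind$id), paste(off$sire, off$dam))
  fam_par <- lapply(strsplit(names(fams), " "), function(x) match(x, ind$id))
  nm <- nrow(gm$G)
  chisq <- df <- numeric(nm)
  for (f in seq_along(fams)) {
    oi <- fams[[f]]
    si <- fam_par[[f]][1]; di <- fam_par[[f]][2]
    if (is.na(si) || is.na(di)) next
    gs <- gm$G[, si]; gd <- gm$G[, di]
    Go <- gm$G[, oi, drop = FALSE]
    n0 <- rowSums(Go == 0L, na.rm = TRUE)
    n1 <- rowSums(Go == 1L, na.rm = TRUE)
    n2 <- rowSums(Go == 2L, na.rm = TRUE)
    par_ok <- !is.na(gs) & !is.na(gd)
    het_one <- par_ok & ((gs == 1L) != (gd == 1L))
    # backcross-type: het x hom; expected 1:1 over the two legal offspring
    # classes (illegal calls are the Mendel filter's business, not counted)
    bc01 <- het_one & (gs %in% c(0L, 1L) & gd %in% c(0L, 1L))
    bc12 <- het_one & (gs %in% c(1L, 2L) & gd %in% c(1L, 2L))
    nt <- n0 + n1
    ok <- bc01 & nt >= 2
    chisq[ok] <- chisq[ok] + ((n0 - n1)^2 / nt)[ok]
    df[ok] <- df[ok] + 1
    nt <- n1 + n2
    ok <- bc12 & nt >= 2
    chisq[ok] <- chisq[ok] + ((n1 - n2)^2 / nt)[ok]
    df[ok] <- df[ok] + 1
    # intercross-type: het x het, 1:2:1
    nt <- n0 + n1 + n2
    inter <- par_ok & gs == 1L & gd == 1L & nt >= 2
    x <- (n0 - nt / 4)^2 / (nt / 4) + (n1 - nt / 2)^2 / (nt / 2) +
      (n2 - nt / 4)^2 / (nt / 4)
    chisq[inter] <- chisq[inter] + x[inter]
    df[inter] <- df[inter] + 2
  }
  p <- ifelse(df > 0, pchisq(chisq, df, lower.tail = FALSE), 1)
  drop <- p < tolerance
  list(gm = subset_gm(gm, i = !drop),
       removed_markers = data.frame(id = gm$markers$id[drop],
                                    reason = rep("distortion", sum(drop)),
                                    stringsAsFactors = FALSE),
       test = data.frame(id = gm$markers$id, chisq = chisq, df = df, p = p,
                         stringsAsFactors = FALSE))
}

#' Run the full pre-mapping QC pipeline
#'
#' Applies, in order: Mendelian-error exclusion of individuals then markers
#' (rate > `mendel_threshold`), the MAF filter (MAF < `maf_limit`), and the
#' segregation-distortion filter (p < `distortion_p`).
#'
#' @param gm a [genotype_matrix()].
#' @param mendel_threshold,maf_limit,distortion_p stage thresholds.
#' @return object of class `qc_report`: the filtered `gm`, a `removed` table
#'   (id, type, reason; one primary reason per removal), per-stage `counts`,
#'   and the per-marker statistics of each stage.
#' @examples
#' \donttest{
#' sim <- simulate_study(seed = 1, n_chrom = 2, length_range = c(2e6, 2e6),
#'                       n_markers = 200, n_genes = 0)
#' qc <- genotype_qc(sim$gm)
#' qc$counts
#' }
#' @export
genotype_qc <- function(gm, mendel_threshold = 0.01, maf_limit = 0.05,
                        distortion_p = 0.001) {
  n_mk0 <- nrow(gm$G); n_in0 <- ncol(gm$G)
  s1 <- filter_mendelian(gm, mendel_threshold)
  s2 <- maf_filter(s1$gm, maf_limit)
  s3 <- segregation_distortion(s2$gm, distortion_p)
  tag <- function(d, type) {
    d$type <- rep(type, nrow(d))
    d
  }
  removed <- rbind(
    tag(s1$removed_individuals, "individual"),
    tag(s1$removed_markers, "marker"),
    tag(s2$removed_markers, "marker"),
    tag(s3$removed_markers, "marker"))
  counts <- data.frame(
    stage = c("input", "mendel", "maf", "distortion"),
    markers = c(n_mk0, nrow(s1$gm$G), nrow(s2$gm$G), nrow(s3$gm$G)),
    individuals = c(n_in0, ncol(s1$gm$G), ncol(s2$gm$G), ncol(s3$gm$G)))
  structure(list(gm = s3$gm, removed = removed, counts = counts,
                 mendel = s1$rates, maf = s2$maf, distortion = s3$test),
            class = "qc_report")
}

#' @method print qc_report
#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$removed) > 0) {
    cat("removals by reason:\n")
    print(table(x$removed$type, x$removed$reason))
  }
  invisible(x)
}
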