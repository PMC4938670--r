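BIG_DIST <- 1e10  # stands for "no informative meioses" in the -LOD metric

# Single linkage on -LOD: components at threshold t are exactly the
# transitive closure of pairs with LOD >= t.
lod_hclust <- function(lod, n_inf) {
  D <- -lod
  D[n_inf == 0] <- BIG_DIST
  stats::hclust(stats::as.dist(D), method = "single")
}

#' Cluster markers into linkage groups by two-point LOD
#'
#' Single-linkage transitive closure: markers i and j share a group iff a
#' path of pairs with LOD >= `threshold` connects them. Pairs with no
#' informative meioses never connect. Markers left in singleton components
#' are reported as unassigned.
#'
#' @param pairs pairwise estimates as produced inside [linkage_map()]: a list
#'   with `lod` and `n_inf` matrices (see [two_point_estimate()] for the
#'   underlying model).
#' @param threshold LOD threshold.
#' @return list with `membership` (integer per marker, groups numbered by
#'   decreasing size), `groups` (list of marker-id vectors, size >= 2),
#'   `unassigned` (marker ids), and `threshold`.
#' @export
cluster_groups <- function(pairs, threshold) {
  n <- nrow(pairs$lod)
  ids <- rownames(pairs$lod)
  if (is.infinite(threshold)) {
    memb <- seq_len(n)
  } else {
    hc <- lod_hclust(pairs$lod, pairs$n_inf)
    memb <- stats::cutree(hc, h = -threshold)
  }
  sizes <- tabulate(memb)
  ord <- order(sizes, decreasing = TRUE)
  renum <- match(seq_along(sizes), ord)
  memb <- renum[memb]
  sizes <- sizes[ord]
  keep <- which(sizes >= 2)
  groups <- lapply(keep, function(g) ids[memb == g])
  names(groups) <- sprintf("LG%d", seq_along(groups))
  list(membership = memb, groups = groups,
       unassigned = ids[memb %in% which(sizes < 2)], threshold = threshold)
}

#' Choose the clustering LOD threshold by the plateau criterion
#'
#' Sweeps the threshold over the single-linkage merge spectrum and returns
#' the midpoint of the widest threshold interval (in LOD units) over which
#' the number of linkage groups is constant, restricted to thresholds where
#' at least `min_assigned` of the markers fall in groups of size >= 2 (so
#' that degenerate regimes at the extremes of the sweep do not count as
#' plateaus). This follows the logic of picking the threshold at which the
#' expected karyotype emerges.
#'
#' @param pairs pairwise estimate matrices (as in [cluster_groups()]).
#' @param min_assigned minimum assigned-marker fraction for a candidate
#'   threshold (default 0.5).
#' @param min_size clusters below this size do not count as groups (nor as
#'   assigned markers) during the sweep, so stray fragments cannot mask a
#'   plateau (default 5).
#' @return list with `threshold`, `n_groups` at the plateau, and the
#'   coalesced `sweep` table (lo, hi, n_groups, frac_assigned, width).
#' @export
choose_lod_threshold <- function(pairs, min_assigned = 0.5, min_size = 5) {
  hc <- lod_hclust(pairs$lod, pairs$n_inf)
  n <- nrow(pairs$lod)
  hs <- sort(unique(hc$height))
  hs <- hs[hs < -1e-9]  # genuine linkage merges only (LOD > 0)
  if (length(hs) < 2) stopf("no linkage merge spectrum to sweep")
  mids <- (hs[-1] + hs[-length(hs)]) / 2
  cuts <- stats::cutree(hc, h = mids)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
  stat <- t(apply(cuts, 2, function(m) {
    sz <- tabulate(m)
    c(sum(sz >= min_size), sum(sz[sz >= min_size]) / n)
  }))
  sweep <- data.frame(lo = -hs[-1], hi = -hs[-length(hs)],
                      n_groups = stat[, 1], frac_assigned = stat[, 2])
  # coalesce consecutive intervals with the same group count: a plateau is
  # the full threshold range over which the count is constant
  run <- cumsum(c(TRUE, diff(sweep$n_groups) != 0))
  plat <- do.call(rbind, lapply(split(seq_len(nrow(sweep)), run), function(i) {
    data.frame(lo = min(sweep$lo[i]), hi = max(sweep$hi[i]),
               n_groups = sweep$n_groups[i[1]],
               frac_assigned = max(sweep$frac_assigned[i]))
  }))
  plat$width <- plat$hi - plat$lo
  cand <- plat[plat$frac_assigned >= min_assigned & plat$n_groups >= 2, ]
  if (nrow(cand) == 0)
    stopf("no plateau with assigned fraction >= %.2f", min_assigned)
  best <- cand[which.max(cand$width), ]
  list(threshold = (best$lo + best$hi) / 2, n_groups = best$n_groups,
       sweep = plat)
}

# Order markers along the second eigenvector of the normalised Laplacian of
# the pairwise-LOD similarity matrix.
spectral_order <- function(W) {
  n <- nrow(W)
  if (n < 3) return(NULL)
  W[is.na(W)] <- 0
  diag(W) <- 0
  d <- rowSums(W)
  if (any(d <= 0)) d[d <= 0] <- min(d[d > 0], 1e-6)
  s <- 1 / sqrt(d)
  L <- diag(n) - (s * W) * rep(s, each = n)
  ev <- eigen(L, symmetric = TRUE)
  fiedler <- ev$vectors[, n - 1L] * s
  order(fiedler)
}

#' Assign leftover single markers to existing linkage groups
#'
#' An unassigned marker joins the group holding its best-LOD partner if that
#' LOD is at least `lod_limit` and exceeds the best LOD to any other group by
#' at least `margin` LOD units; otherwise it remains unassigned.
#'
#' @param clustering a [cluster_groups()] result.
#' @param pairs pairwise estimate matrices.
#' @param lod_limit minimum LOD to join.
#' @param margin required lead over the runner-up group (default 1).
#' @return updated clustering with `joined` (ids added per group).
#' @export
join_singles <- function(clustering, pairs, lod_limit, margin = 1) {
  ids <- rownames(pairs$lod)
  joined <- character(0)
  for (m in clustering$unassigned) {
    best <- vapply(clustering$groups, function(g)
      max(pairs$lod[m, g], na.rm = TRUE), numeric(1))
    o <- order(best, decreasing = TRUE)
    if (best[o[1]] >= lod_limit &&
        (length(best) == 1 || best[o[1]] - best[o[2]] >= margin)) {
      gname <- names(clustering$groups)[o[1]]
      clustering$groups[[gname]] <- c(clustering$groups[[gname]], m)
      joined <- c(joined, m)
    }
  }
  clustering$unassigned <- setdiff(clustering$unassigned, joined)
  clustering$joined <- joined
  clustering
}

# Iteratively re-rank each marker toward the LOD-weighted mean rank of its
# strongest partners; smooths local noise left by the global seriation.
rank_refine <- function(W, ord, iters = 30, k = 15) {
  n <- nrow(W)
  if (n <= k + 1) return(ord)
  W[is.na(W)] <- 0
  diag(W) <- 0
  p <- as.numeric(match(seq_len(n), ord))
  for (it in seq_len(iters)) {
    np <- vapply(seq_len(n), function(i) {
      w <- W[i, ]
      top <- order(w, decreasing = TRUE)[seq_len(k)]
      sum(w[top] * p[top]) / max(sum(w[top]), 1e-12)
    }, numeric(1))
    p <- rank((p + np) / 2, ties.method = "first")
  }
  order(p)
}

# Consensus-block refinement. Markers are sliced into consecutive blocks of
# `B` along the current order; each parent's resolved transmissions are
# phased along the order, a per-meiosis consensus haplotype is taken per
# block, blocks are ordered by 2-opt on their pairwise consensus
# recombination rates (nearly every meiosis is informative at block level,
# so these distances are far less noisy than marker-pair estimates), and
# every marker is then re-localised against the ordered block consensuses.
block_refine <- function(tr, ord, B = 8, n_pass = 4) {
  for (pass in seq_len(n_pass)) {
    M <- length(ord)
    ridx <- match(ord, tr$marker_ids)
    nb <- ceiling(M / B)
    if (nb < 4) return(ord)
    bin_of <- rep(seq_len(nb), each = B)[seq_len(M)]
    nmei <- ncol(tr$T)
    Hall <- phased_transmissions(tr, ridx, mode = 2L)
    C <- matrix(NA_integer_, nb, nmei)
    for (b in seq_len(nb)) {
      sub <- Hall[bin_of == b, , drop = FALSE]
      s <- colSums(sub == 1L, na.rm = TRUE)
      nn <- colSums(!is.na(sub))
      C[b, ] <- ifelse(nn == 0 | 2 * s == nn, NA_integer_,
                       as.integer(2 * s > nn))
    }
    Db <- matrix(0.5, nb, nb)
    diag(Db) <- 0
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
      ok <- !is.na(C[i, ]) & !is.na(C[j, ])
      if (any(ok))
        Db[i, j] <- Db[j, i] <- sum(C[i, ok] != C[j, ok]) / sum(ok)
    }
    bo <- .order_polish_cpp(Db, seq_len(nb) - 1L)$order + 1L
    if (cor(bo, seq_len(nb), method = "spearman") < 0) bo <- rev(bo)
    pos_new <- numeric(M)
    for (mi in seq_len(M)) {
      v <- Hall[mi, ]
      dmb <- vapply(seq_len(nb), function(b) {
        ok <- !is.na(v) & !is.na(C[b, ])
        if (sum(ok) < 10) return(NA_real_)
        sum(v[ok] != C[b, ok]) / sum(ok)
      }, numeric(1))
      db <- dmb[bo]
      if (all(is.na(db))) {
        pos_new[mi] <- match(bin_of[mi], bo)
        next
      }
      bmin <- which.min(db)
      lo <- max(1, bmin - 2)
      hi <- min(nb, bmin + 2)
      w <- 1 / (db[lo:hi] + 0.02)^2
      w[is.na(w)] <- 0
      pos_new[mi] <- sum((lo:hi) * w) / sum(w)
    }
    ord <- ord[order(pos_new)]
  }
  ord
}

# exhaustive open-path minimisation for tiny groups (n! / 2 orders)
order_exhaustive <- function(D) {
  n <- nrow(D)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL
  best_len <- Inf
  for (p in perms(seq_len(n))) {
    if (p[1] > p[n]) next  # each path equals its reversal
    len <- sum(D[cbind(p[-n], p[-1])])
    if (len < best_len) {
      best_len <- len
      best <- p
    }
  }
  list(order = best, length = best_len)
}

#' Order markers within a linkage group
#'
#' Finds a marker order minimising total map length. Tiny groups (up to 8
#' markers) are solved exactly by exhaustive enumeration of all orders.
#' Small groups use greedy nearest-neighbour construction from `n_restarts`
#' random starts followed by 2-opt and single-marker reinsertion. Large
#' groups are ordered by spectral seriation of the pairwise-LOD matrix
#' (Fiedler vector), followed by LOD-weighted rank refinement and
#' consensus-block refinement against phased transmissions — at high marker
#' density the two-point length objective alone cannot discriminate local
#' order, so the global seriation backbone is kept and only consensus-level
#' evidence rearranges it. The orientation is normalised so the marker with
#' the smallest identifier lies in the first half. Per-restart/stage lengths
#' are returned so order consistency across replicates can be assessed.
#'
#' @param group character vector of marker ids.
#' @param pairs pairwise estimate matrices (theta, lod, n_inf).
#' @param tr transmission set (from the fit); enables consensus-block
#'   refinement for large groups when supplied.
#' @param n_restarts random restarts (default 5).
#' @param seed integer seed (deterministic given seed).
#' @param map_function "haldane" or "kosambi".
#' @param max_cM distance cap for unlinked/uninformative pairs.
#' @param exact_max exhaustive enumeration for groups up to this size (8).
#' @param large_min spectral/consensus path for groups of at least this
#'   size (40).
#' @return list with `order` (marker ids), `length` (cM), `restart_lengths`.
#' @export
order_markers <- function(group, pairs, tr = NULL, n_restarts = 5, seed = 1,
                          map_function = "haldane", max_cM = 50,
                          exact_max = 8, large_min = 40) {
  if (length(group) == 1)
    return(list(order = group, length = 0, restart_lengths = 0))
  th <- pairs$theta[group, group]
  mf <- map_distance_fun(map_function)
  D <- mf(th, max_cM)
  D[is.na(D)] <- max_cM
  diag(D) <- 0
  n <- length(group)
  path_cM <- function(o) sum(D[cbind(o[-n], o[-1])])
  if (n <= exact_max) {
    ex <- order_exhaustive(D)
    o <- ex$order
    lens <- ex$length
  } else if (n < large_min || is.null(tr)) {
    res <- .order_tsp_cpp(D, as.integer(n_restarts), as.integer(seed))
    sp <- spectral_order(pairs$lod[group, group])
    if (!is.null(sp)) {
      pol <- .order_polish_cpp(D, sp - 1L)
      if (pol$length < res$length) {
        res$order <- pol$order
        res$length <- pol$length
      }
      res$restart_lengths <- c(res$restart_lengths, pol$length)
    }
    o <- res$order + 1L
    lens <- res$restart_lengths
  } else {
    L <- pairs$lod[group, group]
    o0 <- rank_refine(L, spectral_order(L))
    ord1 <- block_refine(tr, group[o0])
    o <- match(ord1, group)
    lens <- path_cM(o)
  }
  ord <- group[o]
  anchor <- which(ord == min(group))
  if (anchor > length(ord) / 2) ord <- rev(ord)
  list(order = ord, length = path_cM(match(ord, group)),
       restart_lengths = lens)
}

#' Sex-specific map distances along a fixed marker order
#'
#' Re-estimates adjacent-interval recombination per sex on the fixed order
#' and converts it to cM with the chosen map function, increments capped at
#' `max_cM` and flagged. Two estimators are available. `"crossover"` (the
#' default) phases each parent's resolved transmissions along the order by
#' majority vote, optionally removes isolated single-marker flips (the
#' signature genotyping errors leave in dense maps: a lone discordant call
#' flanked by concordant ones, which would otherwise inflate the map as a
#' spurious double crossover), detects crossovers between consecutive
#' resolved markers, and distributes each crossover uniformly over the
#' intervals it may have occurred in; interval theta is then events over
#' observations. `"pairwise"` applies the two-point phase-mixture EM of
#' [two_point_estimate()] to each adjacent pair, per sex, with no error
#' handling.
#'
#' @param gm a [genotype_matrix()] or prebuilt transmissions.
#' @param order character vector of marker ids in map order.
#' @param method "crossover" or "pairwise".
#' @param correct_errors apply genotyping-error handling in the crossover
#'   method: parent-marker masking of spurious heterozygous calls and
#'   removal of single-marker reverting blips (see Details).
#' @param bin_size consensus block size for the crossover method: "auto"
#'   (8 when the order has at least 100 markers, else marker-level), or an
#'   integer.
#' @param map_function "haldane" or "kosambi".
#' @param max_cM cap per interval (default 50).
#' @return data frame: marker_id, male_cM, female_cM (cumulative, first
#'   marker at 0), and per-interval flags `male_flag`/`female_flag`
#'   ("ok", "uninformative", "capped"; first row "origin").
#' @export
sex_specific_distances <- function(gm, order,
                                   method = c("crossover", "pairwise"),
                                   correct_errors = TRUE, bin_size = "auto",
                                   map_function = "haldane", max_cM = 50) {
  method <- match.arg(method)
  tr <- if (inherits(gm, "genotype_matrix")) build_transmissions(gm) else gm
  ridx <- match(order, tr$marker_ids)
  if (anyNA(ridx)) stopf("order contains unknown markers")
  if (identical(bin_size, "auto"))
    bin_size <- if (length(order) >= 100) 8L else 1L
  mf <- map_distance_fun(map_function)
  res <- list()
  for (sex in c("male", "female")) {
    mode <- if (sex == "male") 0L else 1L
    if (method == "crossover") {
      # symmetrise over direction: phasing and masking scan along the
      # order, so estimates from the two directions are pooled to make the
      # result invariant under order reversal
      e1 <- interval_theta_crossover(tr, ridx, mode, correct_errors,
                                     bin_size)
      e2 <- interval_theta_crossover(tr, rev(ridx), mode, correct_errors,
                                     bin_size)
      ev <- ifelse(e1$n > 0, e1$theta * e1$n, 0) +
        rev(ifelse(e2$n > 0, e2$theta * e2$n, 0))
      nn <- e1$n + rev(e2$n)
      est <- list(theta = ifelse(nn > 0, ev / nn, NA_real_), n = nn)
    } else {
      est <- interval_theta_pairwise(tr, ridx, mode)
    }
    theta <- est$theta
    flag <- rep("ok", length(theta))
    flag[est$n == 0] <- "uninformative"
    theta[est$n == 0] <- 0
    d <- mf(pmin(theta, 0.499999), max_cM)
    capped <- theta >= 0.5 | d >= max_cM - 1e-9
    d[theta >= 0.5] <- max_cM
    flag[capped & flag == "ok"] <- "capped"
    res[[sex]] <- list(cM = cumsum(c(0, d)), flag = c("origin", flag))
  }
  data.frame(marker_id = order,
             male_cM = res$male$cM, female_cM = res$female$cM,
             male_flag = res$male$flag, female_flag = res$female$flag,
             stringsAsFactors = FALSE)
}

# Phase every parent's resolved transmissions along a fixed order by
# majority vote against each offspring's last resolved value. Returns the
# markers x meioses matrix of phase-aligned haplotype indicators (NA where
# unresolved); restricted to parents of one sex unless mode = 2.
phased_transmissions <- function(tr, ridx, mode = 2L, Tm = NULL) {
  M <- length(ridx)
  Tm <- Tm %||% tr$T
  Hall <- matrix(NA_integer_, M, ncol(Tm))
  cols_by_unit <- split(seq_len(ncol(Tm)), tr$unit)
  for (u in names(cols_by_unit)) {
    ui <- as.integer(u) + 1L
    if (mode != 2L && tr$unit_sex[ui] != mode) next
    cols <- cols_by_unit[[u]]
    H <- Tm[ridx, cols, drop = FALSE]
    H[H < 0L] <- NA_integer_
    # per-offspring reference = majority of the last three resolved values;
    # a single corrupted marker then cannot poison the next phase vote
    nc <- length(cols)
    l1 <- l2 <- l3 <- rep(NA_integer_, nc)
    for (m in seq_len(M)) {
      v <- H[m, ]
      s <- (!is.na(l1)) + (!is.na(l2)) + (!is.na(l3))
      tot <- ifelse(is.na(l1), 0L, l1) + ifelse(is.na(l2), 0L, l2) +
        ifelse(is.na(l3), 0L, l3)
      ref <- ifelse(s == 0L, NA_integer_,
                    ifelse(2L * tot > s, 1L, ifelse(2L * tot < s, 0L, l1)))
      cmp <- !is.na(v) & !is.na(ref)
      if (any(cmp) && 2L * sum(v[cmp] != ref[cmp]) > sum(cmp)) {
        v <- 1L - v
        H[m, ] <- v
      }
      res <- !is.na(v)
      l3[res] <- l2[res]
      l2[res] <- l1[res]
      l1[res] <- v[res]
    }
    Hall[, cols] <- H
  }
  Hall
}

# remove reverting runs of length <= kmax from a resolved 0/1 sequence
drop_blips <- function(x, kmax) {
  r <- rle(x)
  if (length(r$lengths) < 3) return(rep(FALSE, length(x)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  drop <- rep(FALSE, length(x))
  for (j in 2:(length(r$lengths) - 1L))
    if (r$lengths[j] <= kmax && r$values[j - 1] == r$values[j + 1])
      drop[starts[j]:ends[j]] <- TRUE
  drop
}

# Adjacent-interval theta by phased crossover counting. With
# correct_errors: (i) markers at which >= 3 of one parent's offspring show
# isolated flips are masked for that parent (the signature of a spurious
# heterozygous call in the parent, which would otherwise fabricate
# simultaneous "recombinants" in half its offspring); (ii) per-meiosis
# reverting runs of one marker are dropped (genotyping errors masquerading
# as immediate double crossovers). With bin_size > 1, transitions are
# counted between per-meiosis consensus haplotypes of consecutive
# `bin_size`-marker blocks, which makes the counts robust to residual
# fine-order noise; each crossover is spread uniformly over the intervals
# it may have occurred in, and interval theta is events over observations.
interval_theta_crossover <- function(tr, ridx, mode, correct_errors = TRUE,
                                     bin_size = 1) {
  M <- length(ridx)
  ev <- obs <- numeric(M - 1)
  nb <- ceiling(M / bin_size)
  bin_of <- rep(seq_len(nb), each = bin_size)[seq_len(M)]
  bmid <- as.integer(round(tapply(seq_len(M), bin_of, stats::median)))
  if (bin_size > 1 && nb >= 2) {
    # anchor terminal bins at the order ends so subtelomeric events in the
    # outer half-bins are not truncated away
    bmid[1] <- 1L
    bmid[nb] <- M
  }
  Hall <- phased_transmissions(tr, ridx, mode)
  use_mei <- if (mode == 2L) rep(TRUE, ncol(Hall)) else
    tr$unit_sex[tr$unit + 1L] == mode
  # marker positions sitting in reverting runs of <= 2 resolved calls: at
  # marker spacing these are never genuine double crossovers
  iso_flags <- function(v) {
    nz <- which(!is.na(v))
    if (length(nz) < 3) return(integer(0))
    nz[drop_blips(v[nz], 2L)]
  }
  if (correct_errors) {
    # (i) per-family mask: several blips among one family's offspring at
    # the same marker betray a genotype error in one of the two parents
    # (a spurious het in the focal parent, or a miscalled other parent
    # corrupting the transmission resolution of the whole family)
    Tm <- tr$T
    masked <- FALSE
    fam <- if (!is.null(tr$meioses))
      paste(tr$unit, tr$meioses$other) else as.character(tr$unit)
    for (cols in split(which(use_mei), fam[use_mei])) {
      iso_count <- integer(M)
      for (o in cols) {
        at <- iso_flags(Hall[, o])
        iso_count[at] <- iso_count[at] + 1L
      }
      bad <- which(iso_count >= 3L)
      if (length(bad) > 0) {
        Tm[ridx[bad], cols] <- -1L
        masked <- TRUE
      }
    }
    # (ii) displaced-marker mask: a marker flipping in isolation across
    # many meioses of many parents sits at the wrong place in the order
    # (its calls reflect a different locus); genuine double crossovers do
    # not recur at one marker, so such markers are removed from the
    # distance estimate altogether
    iso_count <- integer(M)
    for (o in which(use_mei)) {
      at <- iso_flags(Hall[, o])
      iso_count[at] <- iso_count[at] + 1L
    }
    bad <- which(iso_count >= 4L)
    if (length(bad) > 0) {
      Tm[ridx[bad], use_mei] <- -1L
      masked <- TRUE
    }
    # re-phase on the cleaned calls so that corrupted markers cannot have
    # seeded a false phase flip in the first pass
    if (masked) Hall <- phased_transmissions(tr, ridx, mode, Tm = Tm)
  }
  consensus_calls <- function(vm) {
    bc <- rep(NA_integer_, nb)
    supp <- integer(nb)
    for (b in seq_len(nb)) {
      x <- vm[bin_of == b]
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      s <- sum(x)
      if (2L * s != length(x)) {
        bc[b] <- as.integer(2L * s > length(x))
        supp[b] <- length(x)
      }
    }
    list(bc = bc, supp = supp)
  }
  bin_iso_count <- integer(nb)
  if (correct_errors && bin_size > 1) {
    # (iii) recurrence scan: an isolated consensus flip recurring at the
    # same block across meioses marks residual mis-ordered block content,
    # not independent double crossovers
    for (o in which(use_mei)) {
      cc <- consensus_calls(Hall[, o])
      nzb <- which(!is.na(cc$bc))
      if (length(nzb) < 3) next
      xb <- cc$bc[nzb]
      iso <- c(FALSE, xb[2:(length(xb) - 1)] != xb[1:(length(xb) - 2)] &
                 xb[2:(length(xb) - 1)] != xb[3:length(xb)], FALSE)
      bin_iso_count[nzb[iso]] <- bin_iso_count[nzb[iso]] + 1L
    }
  }
  for (o in which(use_mei)) {
    vm <- Hall[, o]
    supp <- NULL
    if (bin_size > 1) {
      cc <- consensus_calls(vm)
      v <- cc$bc
      supp <- cc$supp
      at <- bmid
    } else {
      v <- vm
      at <- seq_len(M)
    }
    nz <- which(!is.na(v))
    if (length(nz) < 2) next
    x <- v[nz]
    if (correct_errors) {
      drop <- drop_blips(x, 1L)
      # genotyping errors are already handled at marker level before the
      # consensus step, so an isolated consensus flip is usually a genuine
      # double crossover; it is removed only when it recurs at the same
      # block across meioses (residual mis-ordered block content)
      if (bin_size > 1) drop <- drop & bin_iso_count[nz] >= 4L
      if (any(drop)) {
        v[nz[drop]] <- NA_integer_
        nz <- which(!is.na(v))
        if (length(nz) < 2) next
        x <- v[nz]
      }
    }
    lo <- at[nz[1]]
    hi <- at[nz[length(nz)]]
    if (hi > lo) obs[lo:(hi - 1L)] <- obs[lo:(hi - 1L)] + 1
    ch <- which(x[-1] != x[-length(x)])
    for (c0 in ch) {
      a <- at[nz[c0]]
      b <- at[nz[c0 + 1L]]
      if (bin_size > 1 && b > a + 1L) {
        # localise the crossover at marker resolution: choose the split of
        # the resolved marker calls between the two block midpoints that
        # best separates the flanking block states
        rr <- a:b
        ri <- rr[!is.na(vm[rr])]
        K <- length(ri)
        if (K > 0) {
          vals <- vm[ri]
          mis_l <- cumsum(vals != x[c0])
          mis_r <- rev(cumsum(rev(vals != x[c0 + 1L])))
          cost <- c(mis_r[1], ifelse(seq_len(K) < K,
                                     mis_l[seq_len(K)] + c(mis_r[-1], 0),
                                     mis_l[K]))
          kbest <- which.min(cost) - 1L
          a2 <- if (kbest >= 1L) ri[kbest] else a
          b2 <- if (kbest < K) ri[kbest + 1L] else b
          if (b2 > a2) { a <- a2; b <- b2 }
        }
      }
      if (b > a) ev[a:(b - 1L)] <- ev[a:(b - 1L)] + 1 / (b - a)
    }
  }
  list(theta = ifelse(obs > 0, ev / obs, NA_real_), n = obs)
}

# Adjacent-interval theta by per-pair two-point EM.
interval_theta_pairwise <- function(tr, ridx, mode) {
  M <- length(ridx)
  res <- .tp_pairs_cpp(tr$T, tr$unit, tr$n_units, tr$unit_sex,
                       ridx[-M] - 1L, ridx[-1] - 1L, mode)
  list(theta = res$theta, n = res$n_inf)
}

#' Fit a sex-specific linkage map
#'
#' The package's central fit: clusters QC-passed markers into linkage groups
#' by pairwise LOD (threshold chosen by the plateau criterion unless given),
#' rescues leftover singles, orders each group by map-length minimisation,
#' and computes male and female centimorgan tracks along the fixed orders.
#'
#' @param gm a [genotype_matrix()] (after QC).
#' @param lod "auto" for the plateau criterion, or a numeric LOD threshold.
#' @param join_lod LOD limit for assigning leftover singles (default: half
#'   the clustering threshold).
#' @param n_restarts ordering restarts per group.
#' @param seed integer seed for the ordering heuristic.
#' @param map_function "haldane" (default; no interference, matching the
#'   meiosis model) or "kosambi".
#' @param distance_method see [sex_specific_distances()].
#' @param correct_errors,bin_size see [sex_specific_distances()].
#' @param max_cM per-interval distance cap.
#' @param min_assigned plateau search constraint, see [choose_lod_threshold()].
#' @param min_size minimum linkage-group size: used in the plateau sweep and
#'   to dissolve smaller fragments back into the single pool (default 5).
#' @return object of class `linkage_map`: `maps` (one data frame per linkage
#'   group: marker_id, order_index, male_cM, female_cM, flags), `groups`,
#'   `unassigned`, `lod_threshold`, `sweep`, `restart_lengths`, and the
#'   transmission set used (for reuse by downstream two-point queries).
#' @examples
#' \donttest{
#' sim <- simulate_study(seed = 1, n_chrom = 2, length_range = c(2e6, 2e6),
#'                       n_markers = 150, n_genes = 0)
#' lm <- linkage_map(genotype_qc(sim$gm)$gm, seed = 1)
#' summary(lm)
#' }
#' @export
linkage_map <- function(gm, lod = "auto", join_lod = NULL, n_restarts = 5,
                        seed = 1, map_function = c("haldane", "kosambi"),
                        distance_method = c("crossover", "pairwise"),
                        correct_errors = TRUE, bin_size = "auto",
                        max_cM = 50, min_assigned = 0.5, min_size = 5) {
  map_function <- match.arg(map_function)
  distance_method <- match.arg(distance_method)
  stopifnot(inherits(gm, "genotype_matrix"))
  tr <- build_transmissions(gm)
  pairs <- pairwise_lod(tr)
  sweep <- NULL
  if (identical(lod, "auto")) {
    ch <- choose_lod_threshold(pairs, min_assigned = min_assigned,
                               min_size = min_size)
    lod_threshold <- ch$threshold
    sweep <- ch$sweep
  } else {
    lod_threshold <- as.numeric(lod)
  }
  cl <- cluster_groups(pairs, lod_threshold)
  # dissolve fragments below the size limit; their markers go back to the
  # single pool and can be rescued by the join step
  small <- names(cl$groups)[vapply(cl$groups, length, integer(1)) < min_size]
  if (length(small) > 0) {
    cl$unassigned <- c(cl$unassigned, unlist(cl$groups[small], use.names = FALSE))
    cl$groups <- cl$groups[setdiff(names(cl$groups), small)]
    names(cl$groups) <- sprintf("LG%d", seq_along(cl$groups))
  }
  cl <- join_singles(cl, pairs, lod_limit = join_lod %||% (lod_threshold / 2))
  maps <- list()
  restart_lengths <- list()
  for (g in names(cl$groups)) {
    om <- order_markers(cl$groups[[g]], pairs, tr = tr,
                        n_restarts = n_restarts,
                        seed = sub_seed(seed, match(g, names(cl$groups))),
                        map_function = map_function, max_cM = max_cM)
    dd <- sex_specific_distances(tr, om$order, method = distance_method,
                                 correct_errors = correct_errors,
                                 bin_size = bin_size,
                                 map_function = map_function, max_cM = max_cM)
    dd$order_index <- seq_len(nrow(dd))
    dd$linkage_group <- g
    maps[[g]] <- dd
    restart_lengths[[g]] <- om$restart_lengths
  }
  structure(list(maps = maps, groups = cl$groups, unassigned = cl$unassigned,
                 lod_threshold = lod_threshold, sweep = sweep,
                 restart_lengths = restart_lengths, pairs = pairs, tr = tr,
                 map_function = map_function,
                 distance_method = distance_method,
                 call = match.call()),
            class = "linkage_map")
}

#' @method print linkage_map
#' @export
print.linkage_map <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Sex-specific linkage map: %d groups, %d mapped SNPs (%d unassigned), LOD threshold %.1f\n",
              length(x$maps), sum(s$table$snps), length(x$unassigned),
              x$lod_threshold))
  cat(sprintf("total map length: male %.1f cM, female %.1f cM (F:M ratio %.2f)\n",
              s$male_total, s$female_total, s$ratio))
  invisible(x)
}

#' Summarise a fitted linkage map
#'
#' @param object a `linkage_map`.
#' @param ... unused.
#' @return list of class `summary.linkage_map`: per-group table (snps,
#'   male/female max cM), totals and the female:male length ratio.
#' @method summary linkage_map
#' @export
summary.linkage_map <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$maps), function(g) {
    m <- object$maps[[g]]
    data.frame(linkage_group = g, snps = nrow(m),
               male_max_cM = max(m$male_cM), female_max_cM = max(m$female_cM),
               stringsAsFactors = FALSE)
  }))
  out <- list(table = tab, male_total = sum(tab$male_max_cM),
              female_total = sum(tab$female_max_cM),
              ratio = sum(tab$female_max_cM) / sum(tab$male_max_cM),
              n_unassigned = length(object$unassigned))
  class(out) <- "summary.linkage_map"
  out
}

#' @method print summary.linkage_map
#' @export
print.summary.linkage_map <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Total: male %.1f cM, female %.1f cM, ratio %.2f; %d unassigned\n",
              x$male_total, x$female_total, x$ratio, x$n_unassigned))
  invisible(x)
}

#' Combined map table of a fitted linkage map
#'
#' @param x a `linkage_map`.
#' @return one data frame over all groups: marker_id, linkage_group,
#'   order_index, male_cM, female_cM.
#' @export
map_table <- function(x) {
  stopifnot(inherits(x, "linkage_map"))
  out <- do.call(rbind, x$maps)
  rownames(out) <- NULL
  out[, c("marker_id", "linkage_group", "order_index", "male_cM", "female_cM",
          "male_flag", "female_flag")]
}

#' Plot a fitted linkage map
#'
#' Plots male against female cumulative positions per linkage group,
#' visualising heterochiasmy (points below the diagonal indicate reduced
#' male recombination).
#'
#' @param x a `linkage_map`.
#' @param ... passed to [plot()].
#' @method plot linkage_map
#' @export
plot.linkage_map <- function(x, ...) {
  tab <- map_table(x)
  lgs <- unique(tab$linkage_group)
  cols <- grDevices::hcl.colors(max(3, length(lgs)), "Dark 3")
  plot(tab$female_cM, tab$male_cM, col = cols[match(tab$linkage_group, lgs)],
       pch = 16, cex = 0.5, xlab = "female position (cM)",
       ylab = "male position (cM)", ...)
  abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}
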