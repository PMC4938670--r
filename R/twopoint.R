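# Resolve, for every meiosis (offspring x focal parent), which allele the
# focal parent transmitted at each marker. Only meioses from a parent
# heterozygous at the marker are informative; the other parent's genotype
# resolves het offspring where possible. Unresolvable or Mendelian-impossible
# configurations give NA (-1).
build_transmissions <- function(gm) {
  ind <- gm$individuals
  off <- which(ind$role == "offspring")
  n_mk <- nrow(gm$G)
  n_mei <- 2L * length(off)
  T <- matrix(-1L, n_mk, n_mei)
  unit_ids <- character(n_mei)
  mei <- data.frame(offspring = character(n_mei), parent = character(n_mei),
                    other = character(n_mei), sex = character(n_mei),
                    stringsAsFactors = FALSE)
  k <- 0L
  for (o in off) {
    for (side in c("sire", "dam")) {
      k <- k + 1L
      pid <- ind[[side]][o]
      qid <- ind[[if (side == "sire") "dam" else "sire"]][o]
      pi_ <- match(pid, ind$id); qi <- match(qid, ind$id)
      go <- gm$G[, o]; gp <- gm$G[, pi_]
      gq <- if (is.na(qi)) rep(NA_integer_, n_mk) else gm$G[, qi]
      t <- rep(-1L, n_mk)
      use <- !is.na(go) & !is.na(gp) & gp == 1L
      t[use & go == 0L & (is.na(gq) | gq != 2L)] <- 0L
      t[use & go == 2L & (is.na(gq) | gq != 0L)] <- 1L
      t[use & go == 1L & !is.na(gq) & gq == 0L] <- 1L
      t[use & go == 1L & !is.na(gq) & gq == 2L] <- 0L
      T[, k] <- t
      unit_ids[k] <- pid
      mei$offspring[k] <- ind$id[o]; mei$parent[k] <- pid
      mei$other[k] <- if (is.na(qid)) "" else qid
      mei$sex[k] <- if (side == "sire") "male" else "female"
    }
  }
  units <- unique(unit_ids)
  unit <- match(unit_ids, units) - 1L
  unit_sex <- integer(length(units))
  for (u in seq_along(units)) {
    sx <- ind$sex[match(units[u], ind$id)]
    unit_sex[u] <- if (identical(sx, "M")) 0L else 1L
  }
  list(T = T, unit = unit, n_units = length(units), unit_sex = unit_sex,
       unit_ids = units, meioses = mei, marker_ids = gm$markers$id)
}

#' Two-point linkage estimate for a marker pair
#'
#' Estimates the recombination fraction between two markers from resolved
#' parental transmissions, with each doubly-heterozygous parent's linkage
#' phase unknown: the likelihood sums the two phase configurations of each
#' parent with equal prior, offspring meioses conditionally independent given
#' phase, and theta is obtained by EM on the phase mixture (folded into
#' `[0, 0.5]`; the mixture likelihood is symmetric about 0.5). Sex-specific
#' estimates use only meioses from heterozygous parents of that sex. LOD is
#' the log10 likelihood ratio of the pooled estimate against free
#' recombination (theta = 0.5).
#'
#' @param gm a [genotype_matrix()], or a prebuilt transmission set from the
#'   internal builder (as stored in a fitted [linkage_map()]).
#' @param marker_i,marker_j marker ids or row indices.
#' @return list of class `two_point`: `theta_male`, `theta_female`,
#'   `theta_pooled` (NA when no informative meioses), `lod` (pooled, >= 0),
#'   and `n_informative` per sex.
#' @export
two_point_estimate <- function(gm, marker_i, marker_j) {
  tr <- if (inherits(gm, "genotype_matrix")) build_transmissions(gm) else gm
  ix <- function(m) if (is.character(m)) match(m, tr$marker_ids) else as.integer(m)
  i <- ix(marker_i); j <- ix(marker_j)
  if (is.na(i) || is.na(j)) stopf("unknown marker")
  one <- function(mode) .tp_pairs_cpp(tr$T, tr$unit, tr$n_units, tr$unit_sex,
                                      i - 1L, j - 1L, mode)
  m <- one(0L); f <- one(1L); p <- one(2L)
  structure(list(marker_i = tr$marker_ids[i], marker_j = tr$marker_ids[j],
                 theta_male = m$theta[1], theta_female = f$theta[1],
                 theta_pooled = p$theta[1], lod = p$lod[1],
                 n_informative = c(male = m$n_inf[1], female = f$n_inf[1],
                                   pooled = p$n_inf[1])),
            class = "two_point")
}

#' @method print two_point
#' @export
print.two_point <- function(x, ...) {
  cat(sprintf("two-point %s - %s: theta male %.3f / female %.3f / pooled %.3f, LOD %.2f (n = %d)\n",
              x$marker_i, x$marker_j, x$theta_male, x$theta_female,
              x$theta_pooled, x$lod, x$n_informative[["pooled"]]))
  invisible(x)
}

# All-pairs pooled two-point estimates; returns symmetric matrices.
pairwise_lod <- function(tr, sex_mode = 2L) {
  n <- nrow(tr$T)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- .tp_pairs_cpp(tr$T, tr$unit, tr$n_units, tr$unit_sex,
                       idx[, 1] - 1L, idx[, 2] - 1L, as.integer(sex_mode))
  LOD <- matrix(0, n, n); TH <- matrix(NA_real_, n, n); NI <- matrix(0L, n, n)
  LOD[idx] <- res$lod; TH[idx] <- res$theta; NI[idx] <- res$n_inf
  LOD[idx[, 2:1]] <- res$lod; TH[idx[, 2:1]] <- res$theta
  NI[idx[, 2:1]] <- res$n_inf
  dimnames(LOD) <- dimnames(TH) <- dimnames(NI) <-
    list(tr$marker_ids, tr$marker_ids)
  list(lod = LOD, theta = TH, n_inf = NI)
}

#' Exhaustive likelihood-grid oracle for a marker pair
#'
#' Profiles the same phase-mixture log10 likelihood as [two_point_estimate()]
#' on an explicit theta grid and returns the grid maximiser and its LOD.
#' Intended as an independent check of the EM maximiser.
#'
#' @param gm a [genotype_matrix()].
#' @param marker_i,marker_j marker ids or indices.
#' @param grid theta grid (default `seq(0, 0.5, by = 0.01)`).
#' @param sex "male", "female" or "pooled".
#' @return list with `grid`, `log10L`, `theta_hat`, `lod`.
#' @export
two_point_grid <- function(gm, marker_i, marker_j,
                           grid = seq(0, 0.5, by = 0.01),
                           sex = c("pooled", "male", "female")) {
  sex <- match.arg(sex)
  mode <- c(pooled = 2L, male = 0L, female = 1L)[[sex]]
  tr <- if (inherits(gm, "genotype_matrix")) build_transmissions(gm) else gm
  ix <- function(m) if (is.character(m)) match(m, tr$marker_ids) else as.integer(m)
  i <- ix(marker_i); j <- ix(marker_j)
  # per-parent (n, r) counts under an arbitrary reference phase
  keep <- if (mode == 2L) rep(TRUE, ncol(tr$T)) else tr$unit_sex[tr$unit + 1L] == mode
  ti <- tr$T[i, ]; tj <- tr$T[j, ]
  ok <- keep & ti >= 0L & tj >= 0L
  if (!any(ok)) return(list(grid = grid, log10L = rep(0, length(grid)),
                            theta_hat = NA_real_, lod = 0))
  u <- tr$unit[ok]
  n <- as.integer(table(factor(u, levels = unique(u))))
  r <- as.integer(tapply((ti != tj)[ok], factor(u, levels = unique(u)), sum))
  ll <- .tp_grid_cpp(n, r, grid)
  l0 <- .tp_grid_cpp(n, r, 0.5)
  best <- which.max(ll)
  list(grid = grid, log10L = ll, theta_hat = grid[best],
       lod = max(ll[best] - l0[1], 0), n = n, r = r)
}
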