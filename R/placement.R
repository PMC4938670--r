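#' Place markers on an assembly by exact flank matching
#'
#' Searches each marker's 71-mer flanking sequence, and its reverse
#' complement, for complete exact matches over all assembly sequences
#' (chromosomes and unplaced contigs), treating the central SNP base as a
#' one-base wildcard: the array flank carries one allele and the reference
#' the other, so equality is not required at the SNP site itself. Every hit
#' is recorded; the SNP coordinate is the match start plus the flank offset
#' (the wildcard stays central under reverse complementation). Flanks
#' containing non-ACGT bases outside the SNP site are skipped and logged.
#'
#' @param flanks data frame with `marker_id`, `flank` (odd-length string),
#'   `offset` (0-based SNP offset, 35 for 71-mers).
#' @param genome a `sim_genome` or a named [Biostrings::DNAStringSet] of
#'   assembly sequences.
#' @return data frame of class `physical_placement`: one row per hit (plus
#'   one `unplaced` row per hitless marker) with marker_id, target, pos
#'   (1-based SNP base), strand, n_exact_hits and status
#'   (`unique`/`multi`/`unplaced`); skipped markers are in
#'   `attr(, "skipped")`.
#' @export
place_markers_by_flank <- function(flanks, genome) {
  seqs <- if (inherits(genome, "sim_genome")) assembly_seqs(genome) else genome
  stopifnot(inherits(seqs, "DNAStringSet"))
  w <- unique(nchar(flanks$flank))
  if (length(w) != 1) stopf("flanks must share a single length")
  off <- unique(flanks$offset)
  if (length(off) != 1 || off != (w - 1) / 2)
    stopf("flank offset must put the SNP at the centre")
  off <- off[1]

  core <- flanks$flank
  substr(core, off + 1L, off + 1L) <- "A"  # neutralise the wildcard site
  valid <- grepl("^[ACGT]+$", core)
  skipped <- flanks$marker_id[!valid]
  fl <- flanks[valid, , drop = FALSE]
  n <- nrow(fl)
  hits <- list()
  if (n > 0) {
    # wildcard handled by allowing one mismatch outside the exact suffix band,
    # then verifying that the mismatch can only sit at the SNP site
    fwd_raw <- fl$flank
    rev_raw <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fl$flank)))
    search_one <- function(patterns, strand) {
      pd <- Biostrings::PDict(patterns, tb.start = off + 2L, tb.end = w)
      out <- list()
      for (s in names(seqs)) {
        m <- Biostrings::matchPDict(pd, seqs[[s]], max.mismatch = 1)
        cnt <- S4Vectors::elementNROWS(m)
        which_mk <- rep(seq_len(n), cnt)
        if (length(which_mk) == 0) next
        st <- unlist(lapply(m, IRanges::start), use.names = FALSE)
        # verify the allowed mismatch sits at the SNP site only
        subj <- as.character(Biostrings::extractAt(
          seqs[[s]], IRanges::IRanges(start = st, width = off)))
        pref <- substr(patterns[which_mk], 1L, off)
        ok <- subj == pref
        if (!any(ok)) next
        out[[s]] <- data.frame(marker_id = fl$marker_id[which_mk[ok]],
                               target = s, pos = st[ok] + off,
                               strand = strand, stringsAsFactors = FALSE)
      }
      out
    }
    hits <- c(search_one(fwd_raw, "+"), search_one(rev_raw, "-"))
  }
  hits <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(marker_id = character(), target = character(), pos = integer(),
               strand = character(), stringsAsFactors = FALSE)
  # a palindromic flank can register the same site twice; keep the + copy
  key <- paste(hits$marker_id, hits$target, hits$pos)
  hits <- hits[order(key, hits$strand), ]
  hits <- hits[!duplicated(paste(hits$marker_id, hits$target, hits$pos)), ]
  rownames(hits) <- NULL

  nh <- table(hits$marker_id)
  hits$n_exact_hits <- as.integer(nh[hits$marker_id])
  hits$status <- ifelse(hits$n_exact_hits == 1L, "unique", "multi")
  missing <- setdiff(fl$marker_id, hits$marker_id)
  if (length(missing) > 0) {
    hits <- rbind(hits, data.frame(marker_id = missing, target = NA_character_,
                                   pos = NA_integer_, strand = NA_character_,
                                   n_exact_hits = 0L, status = "unplaced",
                                   stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$marker_id, hits$target, hits$pos), ]
  rownames(hits) <- NULL
  structure(hits, class = c("physical_placement", "data.frame"),
            skipped = skipped)
}

#' Linkage group to chromosome correspondence
#'
#' Majority vote of uniquely placed markers: each linkage group is matched to
#' the chromosome carrying the plurality of its unique placements.
#'
#' @param map a fitted [linkage_map()].
#' @param placements a [place_markers_by_flank()] result.
#' @param chromosomes character vector of target names that are chromosomes
#'   (other targets are treated as unplaced contigs).
#' @return data frame: linkage_group, chrom (NA on tie/zero support),
#'   n_support.
#' @export
lg_chromosome_table <- function(map, placements, chromosomes) {
  uniq <- placements[placements$status == "unique" &
                       placements$target %in% chromosomes, ]
  do.call(rbind, lapply(names(map$groups), function(g) {
    tg <- uniq$target[uniq$marker_id %in% map$groups[[g]]]
    if (length(tg) == 0)
      return(data.frame(linkage_group = g, chrom = NA_character_,
                        n_support = 0L, stringsAsFactors = FALSE))
    tab <- sort(table(tg), decreasing = TRUE)
    chrom <- if (length(tab) > 1 && tab[1] == tab[2]) NA_character_
             else names(tab)[1]
    data.frame(linkage_group = g, chrom = chrom,
               n_support = as.integer(tab[1]), stringsAsFactors = FALSE)
  }))
}

#' Resolve multi-hit placements using the linkage map
#'
#' A marker whose flank matches more than one location keeps the hit on the
#' chromosome its linkage group corresponds to, provided exactly one of its
#' hits lies there; otherwise it becomes `unresolved` (all candidate
#' positions retained, excluded from downstream positional statistics).
#'
#' @param placements a [place_markers_by_flank()] result.
#' @param map a fitted [linkage_map()].
#' @param lg2chrom a [lg_chromosome_table()] result.
#' @return placements with multi-hit rows resolved (`resolved_by_linkage`)
#'   or marked `unresolved`.
#' @export
resolve_multihit <- function(placements, map, lg2chrom) {
  memb <- rep(names(map$groups), vapply(map$groups, length, integer(1)))
  names(memb) <- unlist(map$groups, use.names = FALSE)
  multi <- unique(placements$marker_id[placements$status == "multi"])
  keep <- rep(TRUE, nrow(placements))
  for (m in multi) {
    rows <- which(placements$marker_id == m)
    g <- memb[m]
    chrom <- if (!is.na(g)) lg2chrom$chrom[lg2chrom$linkage_group == g] else NA
    on_chrom <- which(!is.na(chrom) & placements$target[rows] == chrom)
    if (length(chrom) == 1 && !is.na(chrom) && length(on_chrom) == 1) {
      placements$status[rows[on_chrom]] <- "resolved_by_linkage"
      keep[rows[-on_chrom]] <- FALSE
    } else {
      placements$status[rows] <- "unresolved"
    }
  }
  out <- placements[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# markers usable for positional statistics on one chromosome
placed_on_chrom <- function(map, placements, lg2chrom, chrom) {
  g <- lg2chrom$linkage_group[!is.na(lg2chrom$chrom) & lg2chrom$chrom == chrom]
  if (length(g) == 0) return(NULL)
  mt <- do.call(rbind, map$maps[g])
  pl <- placements[placements$status %in% c("unique", "resolved_by_linkage") &
                     placements$target == chrom &
                     placements$marker_id %in% mt$marker_id, ]
  if (nrow(pl) == 0) return(NULL)
  d <- merge(pl[, c("marker_id", "pos")],
             mt[, c("marker_id", "order_index", "male_cM", "female_cM")],
             by = "marker_id")
  d <- d[order(d$pos, d$order_index), ]
  rownames(d) <- NULL
  d
}

#' Genetic-physical concordance per chromosome
#'
#' Pearson correlation between map position (cM) and assembly position (bp)
#' over markers with resolved placement on the chromosome, per sex; the
#' absolute value is reported since group orientation is arbitrary.
#'
#' @param map a fitted [linkage_map()].
#' @param placements resolved placements.
#' @param lg2chrom a [lg_chromosome_table()] result.
#' @param method "pearson" (default) or "spearman".
#' @return data frame: chrom, n, r_male, r_female (absolute; NA with < 3
#'   markers, flagged in `defined`).
#' @export
per_chrom_correlation <- function(map, placements, lg2chrom,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  chroms <- lg2chrom$chrom[!is.na(lg2chrom$chrom)]
  do.call(rbind, lapply(chroms, function(ch) {
    d <- placed_on_chrom(map, placements, lg2chrom, ch)
    n <- if (is.null(d)) 0L else nrow(d)
    if (n < 3)
      return(data.frame(chrom = ch, n = n, r_male = NA_real_,
                        r_female = NA_real_, defined = FALSE,
                        stringsAsFactors = FALSE))
    data.frame(chrom = ch, n = n,
               r_male = abs(cor(d$pos, d$male_cM, method = method)),
               r_female = abs(cor(d$pos, d$female_cM, method = method)),
               defined = TRUE, stringsAsFactors = FALSE)
  }))
}

#' Anchor unplaced contigs to chromosomes via the linkage map
#'
#' A contig is assigned to the chromosome whose linkage group claims a
#' strict plurality of the contig's placed markers, provided that count is
#' at least `min_support`; ties or zero support leave it unassigned.
#'
#' @param placements resolved placements.
#' @param map a fitted [linkage_map()].
#' @param contigs data frame with `name` and `length` of the unplaced
#'   contigs (e.g. `genome$contig_info`).
#' @param lg2chrom a [lg_chromosome_table()] result.
#' @param min_support minimum supporting markers (default 1, matching the
#'   permissive "tentatively mapped" convention).
#' @return list of class `anchor_report`: `contigs` (per-contig assignment
#'   with supporting counts) and `totals` (n_anchored, bp_anchored,
#'   bp_unplaced, pct_of_unplaced).
#' @export
anchor_contigs <- function(placements, map, contigs, lg2chrom,
                           min_support = 1) {
  memb <- rep(names(map$groups), vapply(map$groups, length, integer(1)))
  names(memb) <- unlist(map$groups, use.names = FALSE)
  pl <- placements[placements$status %in% c("unique", "resolved_by_linkage") &
                     placements$target %in% contigs$name, ]
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    nm <- contigs$name[i]
    mk <- pl$marker_id[pl$target == nm]
    gs <- memb[mk]
    gs <- gs[!is.na(gs)]
    if (length(gs) == 0)
      return(data.frame(contig = nm, length = contigs$length[i],
                        chrom = NA_character_, n_support = 0L,
                        stringsAsFactors = FALSE))
    tab <- sort(table(gs), decreasing = TRUE)
    if ((length(tab) > 1 && tab[1] == tab[2]) || tab[1] < min_support)
      return(data.frame(contig = nm, length = contigs$length[i],
                        chrom = NA_character_, n_support = as.integer(tab[1]),
                        stringsAsFactors = FALSE))
    g <- names(tab)[1]
    ch <- lg2chrom$chrom[lg2chrom$linkage_group == g]
    data.frame(contig = nm, length = contigs$length[i],
               chrom = if (length(ch) == 1) ch else NA_character_,
               n_support = as.integer(tab[1]), stringsAsFactors = FALSE)
  })
  ctab <- do.call(rbind, rows)
  anchored <- !is.na(ctab$chrom)
  totals <- list(n_anchored = sum(anchored),
                 bp_anchored = sum(ctab$length[anchored]),
                 bp_unplaced = sum(ctab$length),
                 pct_of_unplaced = 100 * sum(ctab$length[anchored]) /
                   max(sum(ctab$length), 1))
  structure(list(contigs = ctab, totals = totals), class = "anchor_report")
}

#' @method print anchor_report
#' @export
print.anchor_report <- function(x, ...) {
  cat(sprintf("anchored %d contigs, %.2f Mb (%.1f%% of %.2f Mb unplaced)\n",
              x$totals$n_anchored, x$totals$bp_anchored / 1e6,
              x$totals$pct_of_unplaced, x$totals$bp_unplaced / 1e6))
  invisible(x)
}

# Longest monotone (non-decreasing or non-increasing, whichever is longer)
# subsequence; ties never conflict, so markers that co-segregate (equal map
# position) are always concordant. Returns a logical keep-vector.
# O(n log n) patience algorithm.
longest_monotone <- function(x) {
  lis <- function(v) {
    n <- length(v)
    if (n == 0) return(logical(0))
    tails <- integer(0)     # index of smallest tail of each length
    pred <- integer(n)
    for (i in seq_len(n)) {
      lo <- 1L; hi <- length(tails) + 1L
      while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (v[tails[mid]] <= v[i]) lo <- mid + 1L else hi <- mid
      }
      pred[i] <- if (lo > 1L) tails[lo - 1L] else 0L
      tails[lo] <- i
    }
    keep <- logical(n)
    k <- tails[length(tails)]
    while (k > 0L) { keep[k] <- TRUE; k <- pred[k] }
    keep
  }
  up <- lis(x)
  dn <- lis(-x)
  if (sum(up) >= sum(dn)) up else dn
}

#' Detect linkage-physical discordance segments
#'
#' On each chromosome, markers are sorted by physical position and the
#' longest subsequence with monotone genetic position (non-decreasing or
#' non-increasing sex-averaged cM, so co-segregating markers never conflict)
#' is computed; markers outside it are discordant, and maximal runs of at
#' least `min_run` consecutive discordant markers become segments with their
#' physical span.
#'
#' @param map a fitted [linkage_map()].
#' @param placements resolved placements.
#' @param lg2chrom a [lg_chromosome_table()] result.
#' @param min_run minimum run length (default 3).
#' @return list with `segments` (chrom, start_bp, end_bp, n_markers) and
#'   `concordant` (per chromosome, marker ids of the longest monotone
#'   subsequence, used downstream for interpolation).
#' @export
detect_discordance <- function(map, placements, lg2chrom, min_run = 3) {
  chroms <- lg2chrom$chrom[!is.na(lg2chrom$chrom)]
  segs <- list()
  conc <- list()
  for (ch in chroms) {
    d <- placed_on_chrom(map, placements, lg2chrom, ch)
    if (is.null(d) || nrow(d) < 2) next
    keep <- longest_monotone((d$male_cM + d$female_cM) / 2)
    conc[[ch]] <- d$marker_id[keep]
    bad <- !keep
    if (!any(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      i1 <- starts[k]; i2 <- ends[k]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start_bp = d$pos[i1], end_bp = d$pos[i2],
        n_markers = i2 - i1 + 1L, stringsAsFactors = FALSE)
    }
  }
  list(segments = if (length(segs) > 0) do.call(rbind, segs) else
         data.frame(chrom = character(), start_bp = integer(),
                    end_bp = integer(), n_markers = integer()),
       concordant = conc)
}

#' Integrate a linkage map with a physical assembly
#'
#' Convenience wrapper running flank placement, multi-hit resolution,
#' per-chromosome concordance, contig anchoring and discordance detection.
#'
#' @param map a fitted [linkage_map()].
#' @param flanks marker flank table.
#' @param genome a `sim_genome` (supplies the assembly sequences, the
#'   chromosome set and the contig table).
#' @param min_support,min_run passed through.
#' @return list with placements, lg2chrom, correlations, anchors,
#'   discordance.
#' @export
integrate_map <- function(map, flanks, genome, min_support = 1, min_run = 3) {
  stopifnot(inherits(genome, "sim_genome"))
  pl <- place_markers_by_flank(flanks, genome)
  chroms <- names(genome$chrom_lengths)
  lg2 <- lg_chromosome_table(map, pl, chroms)
  pl <- resolve_multihit(pl, map, lg2)
  contigs <- data.frame(name = genome$contig_info$name,
                        length = genome$contig_info$length,
                        stringsAsFactors = FALSE)
  list(placements = pl, lg2chrom = lg2,
       correlations = per_chrom_correlation(map, pl, lg2),
       anchors = anchor_contigs(pl, map, contigs, lg2,
                                min_support = min_support),
       discordance = detect_discordance(map, pl, lg2, min_run = min_run))
}
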