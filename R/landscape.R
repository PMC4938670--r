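#' Piecewise-linear genetic-position interpolation
#'
#' Interpolates cM against bp between flanking markers, with constant
#' extrapolation beyond the terminal markers (so the implied recombination
#' rate outside the mapped span is zero). Duplicate physical positions are
#' averaged.
#'
#' @param physical marker physical positions (bp).
#' @param genetic marker genetic positions (cM), jointly monotone with
#'   `physical` after discordant-marker exclusion.
#' @param query query positions (bp).
#' @param chrom_length optional chromosome length; queries outside
#'   `[0, chrom_length]` are an error.
#' @return interpolated cM at `query`.
#' @export
interpolate_cM <- function(physical, genetic, query, chrom_length = NULL) {
  stopifnot(length(physical) == length(genetic), length(physical) >= 2)
  if (!is.null(chrom_length) && (any(query < 0) || any(query > chrom_length)))
    stopf("query outside chromosome [0, %d]", chrom_length)
  approx(physical, genetic, xout = query, rule = 2, ties = mean)$y
}

# Oriented Marey data (bp ascending, cM ascending) for one chromosome and
# sex, restricted to the longest concordant subsequence.
marey_track <- function(map, placements, lg2chrom, discordance, chrom, sex) {
  d <- placed_on_chrom(map, placements, lg2chrom, chrom)
  if (is.null(d)) return(NULL)
  conc <- discordance$concordant[[chrom]]
  if (!is.null(conc)) d <- d[d$marker_id %in% conc, , drop = FALSE]
  if (nrow(d) < 2) return(NULL)
  cm <- if (sex == "male") d$male_cM else d$female_cM
  if (cor(d$pos, cm) < 0) cm <- max(cm) - cm  # orient with the assembly
  data.frame(pos = d$pos - 1, cM = cm)  # 0-based, matching window bounds
}

# Physically ordered per-sex cM track for one chromosome, re-estimated by
# phased crossover counting along the assembly order of the placed markers.
physical_track <- function(map, placements, lg2chrom, chrom, sex) {
  if (is.null(map$tr)) return(NULL)
  d <- placed_on_chrom(map, placements, lg2chrom, chrom)
  if (is.null(d) || nrow(d) < 2) return(NULL)
  d <- d[order(d$pos), ]
  ridx <- match(d$marker_id, map$tr$marker_ids)
  mode <- if (sex == "male") 0L else 1L
  est <- interval_theta_crossover(map$tr, ridx, mode, correct_errors = TRUE,
                                  bin_size = 1)
  th <- ifelse(est$n > 0, est$theta, 0)
  data.frame(pos = d$pos - 1,
             cM = cumsum(c(0, haldane_cM(pmin(th, 0.499999)))))
}

#' Windowed recombination rates along chromosomes
#'
#' Splits each chromosome into `n_windows` equal physical intervals (the
#' classic 2 percent windows for `n_windows = 50`) and evaluates the local
#' recombination-rate proxy cM/Mb per sex as the genetic-length difference
#' across the window divided by its physical span. With `method = "direct"`
#' (the default) the genetic length of each interval is re-estimated by
#' phased crossover counting along the assembly order of the placed markers
#' (a direct Marey estimator: once markers are physically placed, crossovers
#' can be located between physically adjacent markers, which is insensitive
#' to residual noise in the genetic marker order). `method = "marey"`
#' interpolates the fitted genetic map positions against physical position,
#' restricted to the longest concordant subsequence. Chromosomes with fewer
#' than 2 usable markers get all windows flagged undefined.
#'
#' @param map a fitted [linkage_map()].
#' @param placements resolved placements.
#' @param lg2chrom a [lg_chromosome_table()] result.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param discordance a [detect_discordance()] result (its concordant
#'   subsequences feed the `"marey"` interpolator).
#' @param n_windows windows per chromosome (default 50).
#' @param method "direct" or "marey" (see above).
#' @return data frame: chrom, window (1-based), start, end (bp, half-open,
#'   tiling the chromosome exactly), male_rate, female_rate (cM/Mb, NA when
#'   undefined), support (markers placed in the window).
#' @export
window_rates <- function(map, placements, lg2chrom, chrom_lengths,
                         discordance, n_windows = 50,
                         method = c("direct", "marey")) {
  method <- match.arg(method)
  if (method == "direct" && is.null(map$tr)) method <- "marey"
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- as.numeric(chrom_lengths[[ch]])
    b <- round(seq_len(n_windows) / n_windows * L)
    start <- c(0, b[-n_windows]); end <- b
    d <- placed_on_chrom(map, placements, lg2chrom, ch)
    support <- if (is.null(d)) rep(0L, n_windows) else
      vapply(seq_len(n_windows), function(k)
        sum(d$pos > start[k] & d$pos <= end[k]), integer(1))
    mr <- fr <- rep(NA_real_, n_windows)
    track <- function(sex) {
      if (method == "direct") physical_track(map, placements, lg2chrom, ch, sex)
      else marey_track(map, placements, lg2chrom, discordance, ch, sex)
    }
    tm <- track("male")
    tf <- track("female")
    if (!is.null(tm)) {
      cm <- interpolate_cM(tm$pos, tm$cM, c(start, end[n_windows]))
      mr <- diff(cm) / ((end - start) / 1e6)
    }
    if (!is.null(tf)) {
      cm <- interpolate_cM(tf$pos, tf$cM, c(start, end[n_windows]))
      fr <- diff(cm) / ((end - start) / 1e6)
    }
    out[[ch]] <- data.frame(chrom = ch, window = seq_len(n_windows),
                            start = start, end = end, male_rate = mr,
                            female_rate = fr, support = support,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold windowed rates by distance to the nearest telomere
#'
#' Window k of n maps to distance bin `min(k, n + 1 - k)`, so the two
#' mirror-image windows of each chromosome contribute to the same bin; bin
#' means are unweighted across all contributing defined windows.
#'
#' @param windows a [window_rates()] result.
#' @return data frame: bin (1 = outermost), dist_pct (bin upper edge, percent
#'   of chromosome length from the nearest end), male_mean, female_mean,
#'   n_male, n_female (contributing windows).
#' @export
telomere_profile <- function(windows) {
  n_win <- max(windows$window)
  bin <- pmin(windows$window, n_win + 1L - windows$window)
  agg <- function(v) {
    m <- tapply(v, bin, function(x) if (all(is.na(x))) NA_real_ else
      mean(x, na.rm = TRUE))
    n <- tapply(v, bin, function(x) sum(!is.na(x)))
    list(mean = as.numeric(m), n = as.integer(n))
  }
  am <- agg(windows$male_rate); af <- agg(windows$female_rate)
  bins <- sort(unique(bin))
  data.frame(bin = bins, dist_pct = 100 * bins / n_win,
             male_mean = am$mean, female_mean = af$mean,
             n_male = am$n, n_female = af$n)
}

#' Map-level summary statistics from a per-chromosome table
#'
#' Core arithmetic shared by [summarize_maps()]: totals and averages of a
#' per-chromosome map characteristics table.
#'
#' @param tbl data frame with columns `snps`, `physical_bp`, `male_max_cM`,
#'   `female_max_cM`, and optionally `anchored_bp`.
#' @return list of class `map_summary`: per-sex totals, female:male ratio,
#'   SNP count, correlation of SNP count with physical length, kb per SNP on
#'   assembled sequence, cM per SNP per sex, anchored totals.
#' @export
map_table_summary <- function(tbl) {
  stopifnot(all(c("snps", "physical_bp", "male_max_cM", "female_max_cM")
                %in% names(tbl)))
  n_snp <- sum(tbl$snps)
  if (n_snp == 0) stopf("empty map")
  male_total <- sum(tbl$male_max_cM)
  female_total <- sum(tbl$female_max_cM)
  structure(list(
    n_groups = nrow(tbl), n_snps = n_snp,
    male_total_cM = male_total, female_total_cM = female_total,
    ratio = if (male_total > 0) female_total / male_total else NA_real_,
    r_snps_length = if (nrow(tbl) >= 3) cor(tbl$snps, tbl$physical_bp)
                    else NA_real_,
    kb_per_snp = sum(as.numeric(tbl$physical_bp)) / n_snp / 1000,
    cM_per_snp_male = male_total / n_snp,
    cM_per_snp_female = female_total / n_snp,
    anchored_bp = if ("anchored_bp" %in% names(tbl))
      sum(tbl$anchored_bp) else NA_real_,
    table = tbl), class = "map_summary")
}

#' @method print map_summary
#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("%d groups, %d SNPs; male %.1f cM, female %.1f cM (ratio %.2f)\n",
              x$n_groups, x$n_snps, x$male_total_cM, x$female_total_cM,
              x$ratio))
  cat(sprintf("1 SNP per %.1f kb; %.3f cM (male) / %.3f cM (female) per SNP",
              x$kb_per_snp, x$cM_per_snp_male, x$cM_per_snp_female))
  if (!is.na(x$anchored_bp))
    cat(sprintf("; %.1f Mb of contigs anchored", x$anchored_bp / 1e6))
  cat("\n")
  invisible(x)
}

#' Summarise a fitted map integrated with its assembly
#'
#' Builds the per-chromosome characteristics table (SNPs per group, physical
#' length, per-sex map length, anchored contig length) and reduces it with
#' [map_table_summary()].
#'
#' @param map a fitted [linkage_map()].
#' @param placements resolved placements.
#' @param lg2chrom a [lg_chromosome_table()] result.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param anchors optional [anchor_contigs()] report.
#' @return a `map_summary`.
#' @export
summarize_maps <- function(map, placements, lg2chrom, chrom_lengths,
                           anchors = NULL) {
  rows <- lapply(seq_len(nrow(lg2chrom)), function(i) {
    g <- lg2chrom$linkage_group[i]; ch <- lg2chrom$chrom[i]
    m <- map$maps[[g]]
    data.frame(
      linkage_group = g, chrom = ch %||% NA_character_, snps = nrow(m),
      physical_bp = if (!is.na(ch)) as.numeric(chrom_lengths[[ch]]) else 0,
      male_max_cM = max(m$male_cM), female_max_cM = max(m$female_cM),
      anchored_bp = if (!is.null(anchors) && !is.na(ch))
        sum(anchors$contigs$length[!is.na(anchors$contigs$chrom) &
                                     anchors$contigs$chrom == ch]) else 0,
      stringsAsFactors = FALSE)
  })
  map_table_summary(do.call(rbind, rows))
}

#' Marey-style plot of genetic against physical position
#'
#' @param map a fitted [linkage_map()].
#' @param placements resolved placements.
#' @param lg2chrom a [lg_chromosome_table()] result.
#' @param chrom chromosome to plot.
#' @export
plot_marey <- function(map, placements, lg2chrom, chrom) {
  d <- placed_on_chrom(map, placements, lg2chrom, chrom)
  if (is.null(d)) stopf("no placed markers on %s", chrom)
  plot(d$pos / 1e6, d$female_cM, pch = 16, cex = 0.5, col = "firebrick",
       xlab = sprintf("%s physical position (Mb)", chrom),
       ylab = "map position (cM)")
  points(d$pos / 1e6, d$male_cM, pch = 16, cex = 0.5, col = "steelblue")
  legend("topleft", legend = c("female", "male"), pch = 16,
         col = c("firebrick", "steelblue"), bty = "n")
  invisible(d)
}
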