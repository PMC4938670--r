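#' Published per-chromosome summary of the ssalar01 Atlantic salmon map
#'
#' The per-chromosome characteristics of the high-density 'ssalar01'
#' Atlantic salmon SNP linkage map integrated with the GCA_000233375.4
#' assembly: mapped SNP counts, assembled physical length (Mb), unassigned
#' contig length anchored by the map (Mb), and per-sex map length (Max cM)
#' with the genetic-physical correlation. Useful for map-level summary
#' arithmetic (totals, female:male ratio, SNP density) via
#' [map_table_summary()].
#'
#' @return data frame with one row per chromosome (29 rows): `chrom`,
#'   `snps`, `physical_mb`, `unassigned_contig_mb`, `male_max_cM`, `male_r`,
#'   `female_max_cM`, `female_r`.
#' @examples
#' tbl <- ssalar01_map_summary()
#' sum(tbl$female_max_cM) / sum(tbl$male_max_cM)
#' @export
ssalar01_map_summary <- function() {
  path <- system.file("extdata", "ssalar01_map_summary.tsv",
                      package = "salmap", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Map-level summary of the published ssalar01 table
#'
#' Convenience wrapper shaping [ssalar01_map_summary()] into the
#' per-chromosome column scheme expected by [map_table_summary()].
#'
#' @return a `map_summary` (see [map_table_summary()]).
#' @export
ssalar01_summary <- function() {
  tbl <- ssalar01_map_summary()
  map_table_summary(data.frame(
    chrom = tbl$chrom, snps = tbl$snps, physical_bp = tbl$physical_mb * 1e6,
    male_max_cM = tbl$male_max_cM, female_max_cM = tbl$female_max_cM,
    anchored_bp = tbl$unassigned_contig_mb * 1e6))
}
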