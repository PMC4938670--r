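GT_STRINGS <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write genotypes as a minimal VCF
#'
#' One sample per fish, GT field only. CHROM/POS are the marker's assembly
#' target and 1-based position when present in the marker table, else `.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
write_vcf <- function(gm, path) {
  mk <- gm$markers
  chrom <- mk$target %||% rep(".", nrow(mk))
  pos <- mk$pos %||% rep(".", nrow(mk))
  gt <- matrix(GT_STRINGS[as.character(gm$G)], nrow = nrow(gm$G))
  gt[is.na(gm$G)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$individuals$id), collapse = "\t")),
             con)
  body <- cbind(chrom, pos, mk$id, mk$ref, mk$alt, ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF of biallelic genotypes into a genotype matrix
#'
#' @param path VCF path.
#' @param pedigree a pedigree data frame (see [read_pedigree()]); samples are
#'   matched to it by id and ordered accordingly.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, pedigree) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  markers <- data.frame(id = fix[, "ID"], ref = fix[, "REF"],
                        alt = fix[, "ALT"], target = fix[, "CHROM"],
                        pos = suppressWarnings(as.integer(fix[, "POS"])),
                        stringsAsFactors = FALSE)
  miss <- setdiff(pedigree$id, colnames(code))
  if (length(miss) > 0)
    stopf("VCF lacks pedigree sample(s): %s", paste(head(miss), collapse = ", "))
  genotype_matrix(code[, pedigree$id, drop = FALSE], markers,
                  as.data.frame(pedigree))
}

#' Read/write marker flank tables (marker_id, 71-mer, 0-based SNP offset)
#'
#' @param flanks data frame with marker_id, flank, offset.
#' @param path TSV path.
#' @return `write_flanks` the path invisibly; `read_flanks` a data frame.
#' @export
write_flanks <- function(flanks, path) {
  write.table(flanks[, c("marker_id", "flank", "offset")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flanks
#' @export
read_flanks <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "integer"))
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR records with
#' 1-based inclusive coordinates; transcript expression is carried on the
#' mRNA rows as an `expression` attribute.
#'
#' @param models a `gene_models` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, s0, e0, strand, phase, attrs)
    sprintf("%s\tsalmap\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, s0 + 1L, e0, strand, phase, attrs)
  for (gene in models$genes) {
    writeLines(fmt(gene$chrom, "gene", gene$start0, gene$end0, gene$strand,
                   ".", sprintf("ID=%s", gene$id)), con)
    for (tr in gene$transcripts) {
      writeLines(fmt(gene$chrom, "mRNA", min(tr$exons), max(tr$exons),
                     gene$strand, ".",
                     sprintf("ID=%s;Parent=%s;expression=%s", tr$id, gene$id,
                             format(tr$expression))), con)
      emit <- function(type, m, phases = NULL) {
        if (nrow(m) == 0) return()
        for (i in seq_len(nrow(m)))
          writeLines(fmt(gene$chrom, type, m[i, 1], m[i, 2], gene$strand,
                         if (is.null(phases)) "." else phases[i],
                         sprintf("Parent=%s", tr$id)), con)
      }
      emit("exon", tr$exons)
      # CDS phase: codon offset consumed before each piece, transcript order
      cds <- tr$cds
      ord <- if (gene$strand == "+") order(cds[, 1]) else order(-cds[, 1])
      w <- (cds[, 2] - cds[, 1])[ord]
      ph <- (3L - (cumsum(c(0L, w))[seq_along(w)] %% 3L)) %% 3L
      phases <- integer(nrow(cds))
      phases[ord] <- ph
      emit("CDS", cds, phases)
      emit("five_prime_UTR", tr$utr5)
      emit("three_prime_UTR", tr$utr3)
    }
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Rebuilds a `gene_models` object from a GFF3 written by [write_gff3()] (or
#' any GFF3 using the same feature types and Parent attributes).
#'
#' @param path GFF3 path.
#' @return a `gene_models` object.
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("read_gff3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L
  genes <- df[df$type == "gene", ]
  models <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    mr <- df[df$type == "mRNA" & vapply(df$Parent, function(p) gid %in% p,
                                        logical(1)), ]
    transcripts <- lapply(seq_len(nrow(mr)), function(j) {
      tid <- mr$ID[j]
      sub <- df[vapply(df$Parent, function(p) tid %in% p, logical(1)), ]
      take <- function(type) {
        m <- sub[sub$type == type, c("start0", "end")]
        m <- as.matrix(m[order(m$start0), , drop = FALSE])
        dimnames(m) <- NULL
        if (nrow(m) == 0) matrix(integer(0), 0, 2) else m
      }
      list(id = tid,
           expression = as.numeric(mr$expression[j]),
           exons = take("exon"), cds = take("CDS"),
           utr5 = take("five_prime_UTR"), utr3 = take("three_prime_UTR"))
    })
    list(id = gid, chrom = as.character(genes$seqnames[i]),
         strand = as.character(genes$strand[i]),
         start0 = genes$start0[i], end0 = genes$end[i],
         transcripts = transcripts)
  })
  structure(list(genes = models), class = "gene_models")
}

#' Write the truth set of a simulated study as JSON
#'
#' The truth set is test plumbing: it is serialised alongside the fixtures
#' and consulted only by tests, never by pipeline stages.
#'
#' @param truth truth list from [simulate_genotypes()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  truth$landscape <- as.data.frame(truth$landscape)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Simulate a complete linkage-mapping study
#'
#' One-call generator of a self-consistent fixture set: genome with unplaced
#' contigs, gene models written into the sequence, sex-specific crossover
#' landscape, shared-sire pedigree, genotypes with genotyping error and
#' missingness, marker flanks and the truth set. Defaults are desk-scale
#' study conditions: 5 chromosomes of 20 Mb, 22 percent of sequence excised
#' as unplaced contigs, 2,000 markers, 10 sires / 20 dams / 8 offspring per
#' family, male subtelomeric elevation 10x over the outer 10 percent of each
#' chromosome end, female:male map-length ratio 1.5, 0.5 percent genotyping
#' error.
#'
#' @param seed master seed; all stages derive sub-seeds from it.
#' @param n_chrom,length_range,unplaced_fraction see [generate_genome()].
#' @param n_genes see [generate_gene_models()] (0 skips gene simulation).
#' @param n_sires,n_dams,offspring_per_family see [make_pedigree()].
#' @param n_markers,maf_distribution,genotyping_error_rate,missing_rate see
#'   [simulate_genotypes()].
#' @param male_interior_rate,male_subtel_factor,subtel_fraction,target_length_ratio
#'   see [recomb_landscape()].
#' @param dir optional directory: when given, writes genome.fa,
#'   genotypes.vcf, pedigree.tsv, flanks.tsv, genes.gff3 and truth.json.
#' @return list with genome, models, landscape, pedigree, gm, flanks, truth.
#' @export
simulate_study <- function(seed = 1, n_chrom = 5, length_range = c(2e7, 2e7),
                           unplaced_fraction = 0.22, n_genes = 150,
                           n_sires = 10, n_dams = 20, offspring_per_family = 8,
                           n_markers = 2000,
                           maf_distribution = function(n) runif(n, 0.1, 0.5),
                           genotyping_error_rate = 0.005, missing_rate = 0.01,
                           male_interior_rate = 1.25, male_subtel_factor = 10,
                           subtel_fraction = 0.1, target_length_ratio = 1.5,
                           dir = NULL) {
  genome <- generate_genome(n_chrom, length_range, unplaced_fraction,
                            seed = sub_seed(seed, 1))
  models <- NULL
  if (n_genes > 0) {
    gg <- generate_gene_models(genome, n_genes, seed = sub_seed(seed, 2))
    models <- gg$models
    genome <- gg$genome
  }
  landscape <- recomb_landscape(genome, male_interior_rate, male_subtel_factor,
                                subtel_fraction, target_length_ratio)
  pedigree <- make_pedigree(n_sires, n_dams, offspring_per_family,
                            seed = sub_seed(seed, 3))
  sg <- simulate_genotypes(genome, pedigree, n_markers, landscape,
                           maf_distribution, genotyping_error_rate,
                           missing_rate, seed = sub_seed(seed, 4),
                           gene_models = models)
  out <- list(genome = genome, models = models, landscape = landscape,
              pedigree = pedigree, gm = sg$gm, flanks = sg$flanks,
              truth = sg$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(genome, file.path(dir, "genome.fa"))
    write_vcf(sg$gm, file.path(dir, "genotypes.vcf"))
    write_pedigree(pedigree, file.path(dir, "pedigree.tsv"))
    write_flanks(sg$flanks, file.path(dir, "flanks.tsv"))
    if (!is.null(models)) write_gff3(models, file.path(dir, "genes.gff3"))
    write_truth_json(sg$truth, file.path(dir, "truth.json"))
  }
  out
}
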