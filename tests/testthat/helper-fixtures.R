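# Shared fixtures, generated once per test run and memoised.
.fx_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fx_env[[name]])) assign(name, fn(), envir = .fx_env)
  get(name, envir = .fx_env)
}

# two small chromosomes, genotyping error and missingness on
fx_small <- function() fixture("small", function() {
  simulate_study(seed = 42, n_chrom = 2, length_range = c(2e6, 2e6),
                 unplaced_fraction = 0.2, n_genes = 0, n_markers = 250,
                 n_sires = 5, n_dams = 10, offspring_per_family = 10)
})

# error-free fixture with enough genetic length for order recovery
# (2 x 8 Mb: 28 cM male / 42 cM female per chromosome)
fx_clean <- function() fixture("clean", function() {
  simulate_study(seed = 42, n_chrom = 2, length_range = c(8e6, 8e6),
                 unplaced_fraction = 0.2, n_genes = 0, n_markers = 240,
                 genotyping_error_rate = 0, missing_rate = 0)
})

# gene-dense single chromosome for annotation checks (no pedigree realism
# needed: placements are taken from the truth table)
fx_genes <- function() fixture("genes", function() {
  simulate_study(seed = 7, n_chrom = 1, length_range = c(6e5, 6e5),
                 unplaced_fraction = 0, n_genes = 40, n_markers = 500,
                 n_sires = 2, n_dams = 2, offspring_per_family = 2,
                 genotyping_error_rate = 0, missing_rate = 0)
})

# truth-derived unique placements for a simulated study
truth_placements <- function(sim) {
  tm <- sim$truth$markers
  structure(data.frame(marker_id = tm$id, target = tm$target,
                       pos = tm$target_pos0 + 1L, strand = "+",
                       n_exact_hits = 1L, status = "unique",
                       stringsAsFactors = FALSE),
            class = c("physical_placement", "data.frame"))
}

# default-scale end-to-end run shared by the acceptance suite
fx_pipeline <- function() fixture("pipeline", function() {
  sim <- simulate_study(seed = 2024)
  qc <- genotype_qc(sim$gm)
  lm <- linkage_map(qc$gm, seed = 1)
  int <- integrate_map(lm, sim$flanks, sim$genome)
  list(sim = sim, qc = qc, lm = lm, int = int)
})
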