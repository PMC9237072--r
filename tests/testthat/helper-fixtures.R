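# Shared fixtures built in code: tiny deterministic matrices and small
# random instances used across test files.

tiny_counts <- function() {
  m <- matrix(c(0L, 1L, 5L, 2L, 0L, 7L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("u1", "u2")))
  count_matrix(m)
}

random_counts <- function(genes = 50, units = 20, seed = 1, layer = "umi") {
  set.seed(seed)
  m <- matrix(rnbinom(genes * units, mu = 20, size = 2), genes, units,
              dimnames = list(sprintf("g%03d", seq_len(genes)),
                              sprintf("u%03d", seq_len(units))))
  count_matrix(m, layer)
}

phase_annotations <- function(n, phases = rep(c("G1", "G2M"), length.out = n),
                              lineage = NULL) {
  ann <- data.frame(unit_id = sprintf("u%03d", seq_len(n)), phase = phases,
                    stringsAsFactors = FALSE)
  if (!is.null(lineage)) ann$lineage <- lineage
  ann
}

# Unsorted population with a latent phase driving the two canonical panels in
# opposite directions; used by the co-expression tests.
panel_population <- function(n_cells = 400, amplitude = 1, stage = "S1",
                             seed = 1, n_filler = 200) {
  panels <- phase_panels()
  genes <- c(panels$G1S, panels$G2M)
  plant <- data.frame(
    gene = seq_along(genes),
    log2fc = c(rep(-amplitude, length(panels$G1S)),
               rep(amplitude, length(panels$G2M)))
  )
  sim <- simulate_sc(
    sim_params(n_genes = length(genes) + n_filler,
               n_cells_per_phase = n_cells / 2,
               mito_gene_frac = 0, libsize_log = c(log(20000), 0.1),
               nb_dispersion = 0.1, # deeply sequenced atlas-like profiles
               seed = seed),
    phasic_genes = plant
  )
  m <- sim$counts$counts
  rownames(m)[seq_along(genes)] <- genes
  ann <- sim$annotations
  ann$stage <- stage
  list(counts = count_matrix(m), annotations = ann)
}
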