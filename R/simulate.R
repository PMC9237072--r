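#' Simulation parameters
#'
#' Parameters of the negative binomial count generators. The defaults emulate
#' droplet single-cell data from phase-sorted embryonic cells: log-normal gene
#' baselines, log-normal library sizes with a median around 8000 UMI (so the
#' 5000-UMI QC floor is exercised but healthy cells sit above it), NB dispersion
#' 0.2 (variance = mu + phi mu^2), and dropout arising naturally from low means.
#' Phase effects are planted multiplicatively and split symmetrically around the
#' baseline (G1 scaled by 2^(-beta/2), G2M by 2^(+beta/2)) so the phase-averaged
#' expression of a phasic gene stays constant while the differential grows.
#'
#' @param n_genes Number of genes.
#' @param n_cells_per_phase Cells per phase per lineage (before planting
#'   low-quality extras).
#' @param lineages Lineage labels; the first is the reference.
#' @param baseline_mean_log `c(meanlog, sdlog)` of the log-normal gene baseline.
#' @param libsize_log `c(meanlog, sdlog)` of the log-normal cell library size.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param frac_phasic Fraction of genes with a planted phase effect.
#' @param effect_log2fc Magnitude of planted phase effects (log2 units).
#' @param frac_interaction Fraction of phasic genes whose effect is restricted
#'   to `interaction_lineage`.
#' @param interaction_lineage Lineage carrying lineage-specific effects
#'   (default: the second lineage).
#' @param lineage_effect_sd SD (log2 units) of per-gene lineage baseline
#'   effects in non-reference lineages.
#' @param mito_gene_frac Fraction of genes labelled mitochondrial (`mt-`
#'   prefix).
#' @param mito_expr_frac Expected mitochondrial expression fraction in healthy
#'   cells.
#' @param frac_low_quality Fraction of extra planted low-quality cells (half
#'   with library sizes far below the UMI floor, half with inflated
#'   mitochondrial load).
#' @param n_replicates Bulk replicates per phase (bulk generator only).
#' @param n_transcription,n_stability,n_both Planted bulk driver-class counts.
#' @param intron_fraction Intronic library scale relative to exonic.
#' @param genotype Genotype label written into the annotations.
#' @param stage Stage label written into the annotations.
#' @param seed Seed for the generator.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000,
                       n_cells_per_phase = 300,
                       lineages = "L1",
                       baseline_mean_log = c(0, 1),
                       libsize_log = c(log(8000), 0.12),
                       nb_dispersion = 0.2,
                       frac_phasic = 0,
                       effect_log2fc = 1,
                       frac_interaction = 0,
                       interaction_lineage = NULL,
                       lineage_effect_sd = 0.25,
                       mito_gene_frac = 0.01,
                       mito_expr_frac = 0.02,
                       frac_low_quality = 0,
                       n_replicates = 3,
                       n_transcription = 50,
                       n_stability = 50,
                       n_both = 20,
                       intron_fraction = 0.3,
                       genotype = "control",
                       stage = "E9.5",
                       seed = 1) {
  p <- as.list(environment())
  if (length(p$lineages) < 1) stop("need at least one lineage")
  if (is.null(p$interaction_lineage) && length(p$lineages) > 1) {
    p$interaction_lineage <- p$lineages[2]
  }
  for (nm in c("frac_phasic", "frac_interaction", "mito_gene_frac",
               "mito_expr_frac", "frac_low_quality")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (p$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (p$frac_interaction > 0 && length(p$lineages) < 2) {
    stop("lineage-specific effects need >= 2 lineages")
  }
  structure(p, class = "sim_params")
}

#' Simulate phase-sorted single-cell UMI counts with planted truth
#'
#' Generates a gene-by-cell NB count matrix. For a cell in phase p and lineage
#' l, gene g has mean `mu_g * lambda_gl * 2^(s_p * beta_gl) / (column sum) *
#' libsize`, with `s_G1 = -1/2`, `s_G2M = +1/2`; counts are NB with the
#' configured dispersion. Low-quality cells are planted by shrinking the
#' library size far below the UMI floor or inflating the mitochondrial
#' fraction, and are flagged in the annotations. A truth table records every
#' planted effect.
#'
#' @param params A `sim_params`.
#' @param phasic_genes Optional explicit planting: data.frame with `gene`
#'   (index) and `log2fc` (signed), overriding `frac_phasic`/`effect_log2fc`.
#' @return List with `counts` (a `count_matrix`), `annotations` (including a
#'   `planted_low_quality` column), `truth` (per gene: `gene_id`, `is_phasic`,
#'   one `log2fc_<lineage>` column per lineage, `is_mito`), and `params`.
#' @export
simulate_sc <- function(params = sim_params(), phasic_genes = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    G <- p$n_genes
    L <- length(p$lineages)
    n_mito <- round(p$mito_gene_frac * G)
    gene_ids <- sprintf("gene%04d", seq_len(G))
    if (n_mito > 0) gene_ids[seq_len(n_mito)] <- sprintf("mt-sim%02d", seq_len(n_mito))
    is_mito <- startsWith(gene_ids, "mt-")

    mu <- stats::rlnorm(G, p$baseline_mean_log[1], p$baseline_mean_log[2])
    # pin the expected mitochondrial expression share of healthy cells
    if (n_mito > 0) {
      target <- p$mito_expr_frac / (1 - p$mito_expr_frac)
      mu[is_mito] <- mu[is_mito] * target * sum(mu[!is_mito]) / sum(mu[is_mito])
    }

    lambda <- matrix(1, G, L, dimnames = list(gene_ids, p$lineages))
    if (L > 1) {
      for (j in 2:L) lambda[, j] <- 2^stats::rnorm(G, 0, p$lineage_effect_sd)
    }

    beta <- matrix(0, G, L, dimnames = list(gene_ids, p$lineages))
    if (is.null(phasic_genes)) {
      n_phasic <- round(p$frac_phasic * G)
      idx <- sample(which(!is_mito), n_phasic)
      fc <- p$effect_log2fc * sample(c(-1, 1), n_phasic, replace = TRUE)
      phasic_genes <- data.frame(gene = idx, log2fc = fc)
    }
    interaction_gene <- rep(FALSE, G)
    if (nrow(phasic_genes) > 0) {
      n_int <- round(p$frac_interaction * nrow(phasic_genes))
      int_rows <- utils::head(sample(seq_len(nrow(phasic_genes))), n_int)
      for (r in seq_len(nrow(phasic_genes))) {
        g <- phasic_genes$gene[r]
        if (r %in% int_rows) {
          beta[g, p$interaction_lineage] <- phasic_genes$log2fc[r]
          interaction_gene[g] <- TRUE
        } else {
          beta[g, ] <- phasic_genes$log2fc[r]
        }
      }
    }

    # per-(lineage, phase, cell-class) relative expression profiles
    phases <- c("G1", "G2M")
    s_p <- c(G1 = -0.5, G2M = 0.5)
    n_low <- round(p$frac_low_quality * p$n_cells_per_phase)
    n_low_umi <- floor(n_low / 2)
    n_low_mito <- n_low - n_low_umi

    cols <- list()
    meta <- list()
    for (l in seq_len(L)) {
      for (ph in phases) {
        w <- mu * lambda[, l] * 2^(s_p[ph] * beta[, l])
        w_hi_mito <- w
        if (n_mito > 0) {
          w_hi_mito[is_mito] <- w[is_mito] *
            (0.20 / 0.80) * sum(w[!is_mito]) / sum(w[is_mito])
        }
        n_ok <- p$n_cells_per_phase
        classes <- c(rep("ok", n_ok), rep("low_umi", n_low_umi),
                     rep("high_mito", n_low_mito))
        lib <- c(
          stats::rlnorm(n_ok, p$libsize_log[1], p$libsize_log[2]),
          stats::rlnorm(n_low_umi, log(2000), 0.2),
          stats::rlnorm(n_low_mito, p$libsize_log[1], p$libsize_log[2])
        )
        prof <- cbind(ok = w / sum(w), low_umi = w / sum(w),
                      high_mito = w_hi_mito / sum(w_hi_mito))
        mean_mat <- prof[, classes, drop = FALSE] %*% diag(lib, length(lib))
        cnt <- matrix(
          stats::rnbinom(G * length(lib), mu = mean_mat,
                         size = 1 / max(p$nb_dispersion, 1e-12)),
          nrow = G
        )
        cols[[length(cols) + 1L]] <- cnt
        meta[[length(meta) + 1L]] <- data.frame(
          phase = ph, lineage = p$lineages[l], planted_low_quality = classes,
          stringsAsFactors = FALSE
        )
      }
    }
    counts <- do.call(cbind, cols)
    ann <- do.call(rbind, meta)
    ann$unit_id <- sprintf("cell%05d", seq_len(nrow(ann)))
    ann$genotype <- p$genotype
    ann$stage <- p$stage
    dimnames(counts) <- list(gene_ids, ann$unit_id)

    truth <- data.frame(gene_id = gene_ids, is_phasic = rowSums(beta != 0) > 0,
                        stringsAsFactors = FALSE)
    for (l in seq_len(L)) truth[[paste0("log2fc_", p$lineages[l])]] <- beta[, l]
    truth$is_interaction <- interaction_gene
    truth$is_mito <- is_mito

    list(
      counts = count_matrix(counts, "umi"),
      annotations = ann[, c("unit_id", "phase", "lineage", "genotype", "stage",
                            "planted_low_quality")],
      truth = truth,
      params = p
    )
  })
}

#' Simulate exon/intron bulk layers with planted driver classes
#'
#' Generates a paired exon/intron bulk dataset. Per gene, transcription `T` and
#' stability `S` act multiplicatively: intronic abundance is proportional to
#' `T` (introns turn over fast, tracking transcription), exonic abundance to
#' `T * S`. TRANSCRIPTION-class genes carry the phase effect on `T` only,
#' STABILITY-class genes on `S` only, BOTH-class genes on both (independent
#' signs); effects are split +/- beta/2 between phases as in [simulate_sc()].
#' Counts are NB around library-scaled means for `n_replicates` samples per
#' phase.
#'
#' @param params A `sim_params`; uses `n_genes`, `n_replicates`,
#'   `n_transcription`, `n_stability`, `n_both`, `effect_log2fc`,
#'   `nb_dispersion` (bulk default 0.05 is recommended), `intron_fraction`,
#'   `stage`, `seed`.
#' @return List with `exon` and `intron` (`count_matrix` layers sharing
#'   labels), `annotations`, `truth` (with `driver_class` in TRANSCRIPTION,
#'   STABILITY, BOTH, NONE), and `params`.
#' @export
simulate_bulk_exon_intron <- function(params = sim_params(nb_dispersion = 0.05)) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  if (p$n_replicates < 2) stop("need >= 2 replicates per phase")
  with_seed(p$seed, {
    G <- p$n_genes
    gene_ids <- sprintf("gene%04d", seq_len(G))
    n_cls <- c(TRANSCRIPTION = p$n_transcription, STABILITY = p$n_stability,
               BOTH = p$n_both)
    if (sum(n_cls) > G) stop("more planted drivers than genes")
    cls <- rep("NONE", G)
    cls[sample(G, sum(n_cls))] <- rep(names(n_cls), n_cls)

    T0 <- stats::rlnorm(G, 2, 1)
    S0 <- 2^stats::rnorm(G, 0, 0.3)
    betaT <- ifelse(cls %in% c("TRANSCRIPTION", "BOTH"),
                    p$effect_log2fc * sample(c(-1, 1), G, replace = TRUE), 0)
    betaS <- ifelse(cls %in% c("STABILITY", "BOTH"),
                    p$effect_log2fc * sample(c(-1, 1), G, replace = TRUE), 0)

    phases <- rep(c("G1", "G2M"), each = p$n_replicates)
    s_p <- ifelse(phases == "G2M", 0.5, -0.5)
    n_samp <- length(phases)
    unit_ids <- sprintf("%s_%s_rep%d", p$stage, phases,
                        rep(seq_len(p$n_replicates), 2))

    exon <- matrix(0L, G, n_samp, dimnames = list(gene_ids, unit_ids))
    intron <- matrix(0L, G, n_samp, dimnames = list(gene_ids, unit_ids))
    size <- 1 / max(p$nb_dispersion, 1e-12)
    for (j in seq_len(n_samp)) {
      Tj <- T0 * 2^(s_p[j] * betaT)
      Sj <- S0 * 2^(s_p[j] * betaS)
      wE <- Tj * Sj
      wI <- Tj
      libE <- stats::rlnorm(1, log(2e6), 0.1)
      libI <- libE * p$intron_fraction
      exon[, j] <- stats::rnbinom(G, mu = wE / sum(wE) * libE, size = size)
      intron[, j] <- stats::rnbinom(G, mu = wI / sum(wI) * libI, size = size)
    }

    ann <- data.frame(
      unit_id = unit_ids, phase = phases, stage = p$stage,
      replicate = as.character(rep(seq_len(p$n_replicates), 2)),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      gene_id = gene_ids,
      is_phasic = cls != "NONE",
      driver_class = cls,
      log2fc_transcription = betaT,
      log2fc_stability = betaS,
      stringsAsFactors = FALSE
    )
    list(
      exon = count_matrix(exon, "exon"),
      intron = count_matrix(intron, "intron"),
      annotations = ann,
      truth = truth,
      params = p
    )
  })
}

#' Simulate per-cell activity scores with a phase shift
#'
#' Gaussian activity scores (e.g. regulon activity surrogates): G1 cells draw
#' from N(0, 1), G2M cells from N(`shift`, 1).
#'
#' @param n_cells_per_phase Cells per phase (>= 2).
#' @param shift Mean shift of the G2M phase.
#' @param seed Seed.
#' @return List with `scores` and `phases`.
#' @export
simulate_activity_scores <- function(n_cells_per_phase, shift, seed = 1) {
  if (n_cells_per_phase < 2) stop("need >= 2 cells per phase")
  with_seed(seed, {
    list(
      scores = c(stats::rnorm(n_cells_per_phase, 0, 1),
                 stats::rnorm(n_cells_per_phase, shift, 1)),
      phases = rep(c("G1", "G2M"), each = n_cells_per_phase)
    )
  })
}

#' Named simulation presets
#'
#' The study conditions used by the calibration and recovery analyses:
#' \describe{
#'   \item{sc-null}{2000 genes, 300 cells/phase, no planted effects.}
#'   \item{sc-phasic}{2000 genes, 500 cells/phase, 10% of genes planted at
#'     |log2FC| = 1.}
#'   \item{sc-interaction}{3 lineages (neuroepithelium reference), 150
#'     cells/phase/lineage, 5% of genes phasic with the effect (|log2FC| = 1.5)
#'     restricted to the endoderm lineage.}
#'   \item{genotype-pair}{control and mutant datasets, 250 cells/phase each;
#'     the control carries 100 planted phasic genes, the mutant those same 100
#'     plus 50 additional ones (|log2FC| = 1).}
#'   \item{bulk-decomp}{2000 genes, 3 replicates/phase, 50 TRANSCRIPTION + 50
#'     STABILITY + 20 BOTH drivers at 1 log2 unit.}
#' }
#' Single-cell presets plant 4% extra low-quality cells to exercise the QC
#' rules.
#'
#' @param preset Preset name.
#' @param seed Seed.
#' @return For `genotype-pair`, a list with `control` and `mutant` simulation
#'   lists; otherwise a single simulation list (see [simulate_sc()] /
#'   [simulate_bulk_exon_intron()]).
#' @export
simulate_preset <- function(preset = c("sc-null", "sc-phasic",
                                       "sc-interaction", "genotype-pair",
                                       "bulk-decomp"),
                            seed = 1) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  switch(preset,
    "sc-null" = simulate_sc(sim_params(
      n_genes = 2000, n_cells_per_phase = 300, frac_phasic = 0,
      frac_low_quality = 0.04, seed = seed
    )),
    "sc-phasic" = simulate_sc(sim_params(
      n_genes = 2000, n_cells_per_phase = 500, frac_phasic = 0.10,
      effect_log2fc = 1, frac_low_quality = 0.04, seed = seed
    )),
    "sc-interaction" = simulate_sc(sim_params(
      n_genes = 2000, n_cells_per_phase = 150,
      lineages = c("neuroepithelium", "endoderm", "mesoderm"),
      frac_phasic = 0.05, effect_log2fc = 1.5, frac_interaction = 1,
      interaction_lineage = "endoderm", frac_low_quality = 0.04, seed = seed
    )),
    "genotype-pair" = {
      plant <- with_seed(seed, data.frame(
        gene = sample(setdiff(seq_len(2000), seq_len(20)), 150),
        log2fc = sample(c(-1, 1), 150, replace = TRUE)
      ))
      list(
        control = simulate_sc(
          sim_params(n_genes = 2000, n_cells_per_phase = 250,
                     frac_low_quality = 0.04, genotype = "control",
                     seed = seed + 101L),
          phasic_genes = plant[seq_len(100), ]
        ),
        mutant = simulate_sc(
          sim_params(n_genes = 2000, n_cells_per_phase = 250,
                     frac_low_quality = 0.04, genotype = "mutant",
                     seed = seed + 202L),
          phasic_genes = plant
        )
      )
    },
    "bulk-decomp" = simulate_bulk_exon_intron(sim_params(
      n_genes = 2000, n_replicates = 3, n_transcription = 50,
      n_stability = 50, n_both = 20, effect_log2fc = 1,
      nb_dispersion = 0.05, seed = seed
    ))
  )
}
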