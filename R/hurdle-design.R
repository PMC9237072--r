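#' Build a hurdle-model design
#'
#' Treatment-coded design matrix for the two-part model. Allowed terms are
#' `cell_cycle_phase` (G1 reference), `lineage` (reference lineage contributes no
#' dummy column), `cell_cycle_phase:lineage` (requires both main effects) and
#' `fraction_of_detected_genes` (a single numeric covariate approximating
#' transcript capture efficiency). The intercept is always present.
#'
#' @param annotations Per-unit annotation data.frame; must carry `phase`, plus
#'   `lineage` and/or `detection_fraction` when those terms are requested.
#' @param terms Character vector of term names (order kept).
#' @param reference_lineage Reference lineage label; defaults to the first
#'   lineage level encountered.
#' @return A list of class `hurdle_design`: `matrix` (units x coefficients),
#'   `term_cols` (term -> column indices), `terms`, `reference_lineage`,
#'   `lineages`, `phase`.
#' @export
hurdle_design <- function(annotations,
                          terms = c("cell_cycle_phase",
                                    "fraction_of_detected_genes"),
                          reference_lineage = NULL) {
  allowed <- c("cell_cycle_phase", "lineage", "cell_cycle_phase:lineage",
               "fraction_of_detected_genes")
  unknown <- setdiff(terms, allowed)
  if (length(unknown)) stop("unknown term(s): ", paste(unknown, collapse = ", "))
  if ("cell_cycle_phase:lineage" %in% terms &&
      !all(c("cell_cycle_phase", "lineage") %in% terms)) {
    stop("the interaction term requires both main effects")
  }
  phase <- normalize_phase(annotations$phase)
  if (nlevels(droplevels(phase)) < 2) stop("need both phases in the design")
  n <- nrow(annotations)
  X <- matrix(1, n, 1, dimnames = list(annotations$unit_id, "(Intercept)"))
  term_cols <- list()

  lineages <- NULL
  if (any(c("lineage", "cell_cycle_phase:lineage") %in% terms)) {
    if (!"lineage" %in% names(annotations)) stop("annotations lack a lineage column")
    lin <- as.character(annotations$lineage)
    lvls <- unique(lin)
    if (length(lvls) < 2) stop("lineage term requested with a single lineage")
    reference_lineage <- reference_lineage %||% lvls[1]
    if (!reference_lineage %in% lvls) {
      stop("reference lineage '", reference_lineage, "' absent from the data")
    }
    lineages <- c(reference_lineage, setdiff(lvls, reference_lineage))
    lin <- factor(lin, levels = lineages)
  }

  for (term in terms) {
    start <- ncol(X) + 1L
    if (term == "cell_cycle_phase") {
      X <- cbind(X, phaseG2M = as.numeric(phase == "G2M"))
    } else if (term == "lineage") {
      for (l in lineages[-1]) {
        X <- cbind(X, as.numeric(lin == l))
        colnames(X)[ncol(X)] <- paste0("lineage", l)
      }
    } else if (term == "cell_cycle_phase:lineage") {
      for (l in lineages[-1]) {
        X <- cbind(X, as.numeric(phase == "G2M" & lin == l))
        colnames(X)[ncol(X)] <- paste0("phaseG2M:lineage", l)
      }
    } else if (term == "fraction_of_detected_genes") {
      if (!"detection_fraction" %in% names(annotations)) {
        stop("annotations lack detection_fraction; run annotate_qc() first")
      }
      X <- cbind(X, detection = annotations$detection_fraction)
    }
    term_cols[[term]] <- seq.int(start, ncol(X))
  }

  structure(
    list(matrix = X, term_cols = term_cols, terms = terms,
         reference_lineage = reference_lineage, lineages = lineages,
         phase = phase),
    class = "hurdle_design"
  )
}
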