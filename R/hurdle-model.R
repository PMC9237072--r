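#' Fit the two-part hurdle model for one gene
#'
#' The hurdle model combines a logistic regression of the detection indicator
#' (`y > 0`) on the design with a Gaussian maximum-likelihood regression of the
#' expression values among detected units. Degenerate components are dropped:
#' the discrete part when every unit (or no unit) is detected, the continuous
#' part when the number of detected units is at most the number of coefficients
#' plus one. A ridge penalty (default 1e-6) on the discrete coefficients keeps
#' the likelihood finite under perfect separation. A gene with both components
#' degenerate is flagged untestable.
#'
#' @param y Per-unit expression on the modeled scale (>= 0, typically
#'   log2(CPM + 1) of pseudobulk counts).
#' @param design A `hurdle_design`.
#' @param ridge Ridge penalty on the discrete coefficients.
#' @return A list of class `hurdle_fit` with `beta_discrete`, `beta_continuous`,
#'   `sigma2`, `loglik_discrete`, `loglik_continuous`, `loglik` (their sum, a
#'   dropped component contributing 0), `df_discrete`, `df_continuous`,
#'   `n_detected`, `discrete_live`, `continuous_live`, `untestable`.
#' @export
fit_hurdle <- function(y, design, ridge = 1e-6) {
  stopifnot(inherits(design, "hurdle_design"))
  X <- design$matrix
  if (length(y) != nrow(X)) stop("y length must match design rows")
  if (any(y < 0)) stop("modeled expression must be non-negative")
  f <- hurdle_fit_cpp(as.numeric(y), X, ridge)
  names(f$beta_discrete) <- colnames(X)
  names(f$beta_continuous) <- colnames(X)
  f$loglik <- sum(c(f$loglik_discrete, f$loglik_continuous), na.rm = TRUE)
  f$untestable <- !f$discrete_live && !f$continuous_live
  class(f) <- "hurdle_fit"
  f
}

#' Likelihood-ratio test of one model term for one gene
#'
#' Fits the full and term-deleted hurdle models for both live components; the
#' statistic is `2 * (loglik_full - loglik_reduced)` summed over components and
#' referred to a chi-squared distribution whose degrees of freedom sum the rank
#' deficit the deletion induces in each live component.
#'
#' @inheritParams fit_hurdle
#' @param term Term name present in the design, or `"contrast:<lineage>"` to
#'   test a single phase-by-lineage interaction contrast against the reference.
#' @return A one-row data.frame: `term`, `chisq`, `df`, `p_value`, `log2fc`
#'   (continuous-model coefficient of the tested effect; `NA` when the
#'   continuous component is dropped), `n_detected`, `untestable`.
#' @export
lrt_term <- function(y, design, term, ridge = 1e-6) {
  spec <- term_drop_columns(design, term)
  res <- hurdle_lrt_cpp(matrix(as.numeric(y), nrow = 1), design$matrix,
                        list(spec$cols), spec$effect_col, ridge)
  data.frame(
    term = term,
    chisq = res$chisq[1, 1],
    df = res$df[1, 1],
    p_value = stats::pchisq(res$chisq[1, 1], res$df[1, 1], lower.tail = FALSE),
    log2fc = res$effect[1, 1],
    n_detected = res$n_detected[1],
    untestable = res$untestable[1],
    stringsAsFactors = FALSE
  )
}

#' Matrix-wise hurdle likelihood-ratio tests
#'
#' Vectorized version of [lrt_term()] over a genes-x-units expression matrix,
#' optionally testing several column sets (e.g. one per-lineage interaction
#' contrast each) against the same full model.
#'
#' @param expr Genes-x-units matrix on the modeled scale.
#' @param design A `hurdle_design`.
#' @param terms Character vector of terms / contrasts (see [lrt_term()]).
#' @param ridge Ridge penalty on the discrete coefficients.
#' @return A list with per-term matrices `chisq`, `df`, `p_value`, `effect`
#'   (genes x terms) plus vectors `untestable`, `n_detected`.
#' @export
hurdle_lrt <- function(expr, design, terms = "cell_cycle_phase", ridge = 1e-6) {
  expr <- as.matrix(expr)
  specs <- lapply(terms, term_drop_columns, design = design)
  res <- hurdle_lrt_cpp(expr, design$matrix,
                        lapply(specs, `[[`, "cols"),
                        vapply(specs, `[[`, integer(1), "effect_col"),
                        ridge)
  p <- stats::pchisq(res$chisq, res$df, lower.tail = FALSE)
  dimnames(res$chisq) <- dimnames(res$df) <- dimnames(p) <-
    dimnames(res$effect) <- list(rownames(expr), terms)
  list(chisq = res$chisq, df = res$df, p_value = p, effect = res$effect,
       untestable = res$untestable, n_detected = res$n_detected)
}

# Resolve a term (or "contrast:<lineage>") to the design columns deleted under
# the null, plus the continuous coefficient reported as the effect size.
term_drop_columns <- function(design, term) {
  stopifnot(inherits(design, "hurdle_design"))
  X <- design$matrix
  if (startsWith(term, "contrast:")) {
    lineage <- sub("^contrast:", "", term)
    col <- match(paste0("phaseG2M:lineage", lineage), colnames(X))
    if (is.na(col)) stop("no interaction column for lineage '", lineage, "'")
    return(list(cols = col, effect_col = col))
  }
  if (!term %in% names(design$term_cols)) {
    stop("term '", term, "' not in design (has: ",
         paste(names(design$term_cols), collapse = ", "), ")")
  }
  cols <- design$term_cols[[term]]
  effect_col <- if (term == "cell_cycle_phase") {
    match("phaseG2M", colnames(X))
  } else if (length(cols) == 1L) {
    cols
  } else {
    0L
  }
  if (is.na(effect_col)) effect_col <- 0L
  list(cols = as.integer(cols), effect_col = as.integer(effect_col))
}
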