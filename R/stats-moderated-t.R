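#' Empirical-Bayes moderated t tests
#'
#' Per-gene ordinary least-squares fits with gene-wise residual variances shrunk
#' toward a common prior. The prior degrees of freedom `d0` and prior variance
#' `s0^2` are estimated by moment-matching the scaled-F distribution of the
#' sample variances on the log scale: with `e = log(s^2) - digamma(d/2) +
#' log(d/2)`, the excess variance of `e` over `trigamma(d/2)` determines `d0`
#' through the trigamma function (solved by Newton iteration with a bisection
#' fallback), and its mean determines `s0^2`. The moderated statistic for a
#' coefficient is `t = beta / sqrt(s2_post * v)` on `d + d0` degrees of freedom,
#' where `s2_post = (d0 s0^2 + d s^2) / (d0 + d)`. When no finite `d0` solves the
#' moment equation the variances are fully pooled (`d0 = Inf`). As `d0 -> 0` the
#' moderated t reduces to the ordinary t.
#'
#' @param log_expr Genes-x-units matrix on the modeled (log) scale.
#' @param design Units-x-coefficients design matrix (intercept included).
#' @param coef Column name or index of the tested coefficient (default: last).
#' @return A list of class `moderated_tests`: `table` (data.frame with `gene_id`,
#'   `effect`, `t_moderated`, `df_total`, `p_value`), `prior_df`, `prior_var`.
#' @export
moderated_t_test <- function(log_expr, design, coef = ncol(design)) {
  log_expr <- as.matrix(log_expr)
  design <- as.matrix(design)
  n <- ncol(log_expr)
  p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match expression columns")
  if (nrow(log_expr) < 2) stop("variance pooling needs at least 2 genes")
  df_resid <- n - qr(design)$rank
  if (df_resid < 1) stop("saturated design: no residual degrees of freedom")
  if (is.character(coef)) coef <- match(coef, colnames(design))
  if (is.na(coef) || coef < 1 || coef > p) stop("unknown coefficient")
  qrX <- qr(design)
  beta <- t(qr.coef(qrX, t(log_expr)))
  fitted <- beta %*% t(design)
  resid <- log_expr - fitted
  s2 <- rowSums(resid^2) / df_resid
  v <- chol2inv(chol(crossprod(design)))[coef, coef]
  prior <- fit_variance_prior(s2, df_resid)
  d0 <- prior$df
  s02 <- prior$var
  s2_post <- if (is.finite(d0)) (d0 * s02 + df_resid * s2) / (d0 + df_resid) else rep(s02, length(s2))
  tstat <- beta[, coef] / sqrt(s2_post * v)
  df_total <- df_resid + d0
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  structure(
    list(
      table = data.frame(
        gene_id = rownames(log_expr) %||% as.character(seq_len(nrow(log_expr))),
        effect = unname(beta[, coef]),
        t_moderated = unname(tstat),
        df_total = df_total,
        p_value = unname(pval),
        stringsAsFactors = FALSE
      ),
      prior_df = d0,
      prior_var = s02
    ),
    class = "moderated_tests"
  )
}

# Moment-match a scaled-F prior to sample variances with common df.
# Returns list(df = d0, var = s0^2); df = Inf means full pooling.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 1e-300 & is.finite(s2)
  if (sum(ok) < 2) return(list(df = Inf, var = stats::median(s2[s2 > 0], na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(df = Inf, var = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(df = d0, var = s02)
}

# Solve trigamma(y) = x for y > 0. Newton on the log-derivative scale, with a
# bisection fallback for the rare non-convergent case.
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) stop("trigamma_inverse needs x > 0")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-10 && dif / y < 1e-10) return(y)
  }
  f <- function(u) trigamma(u) - x
  lo <- 1e-8
  hi <- 1e8
  if (f(lo) < 0 || f(hi) > 0) return(y)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}
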