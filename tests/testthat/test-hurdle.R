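hurdle_ann <- function(n, lineages = NULL, det = NULL) {
  ann <- data.frame(
    unit_id = sprintf("u%03d", seq_len(n)),
    phase = rep(c("G1", "G2M"), length.out = n),
    stringsAsFactors = FALSE
  )
  if (!is.null(lineages)) ann$lineage <- rep(lineages, length.out = n)
  ann$detection_fraction <- det %||% runif(n, 0.5, 1)
  ann
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("design coding arithmetic follows treatment contrasts", {
  ann <- hurdle_ann(4)
  d <- hurdle_design(ann)
  expect_equal(colnames(d$matrix), c("(Intercept)", "phaseG2M", "detection"))

  ann3 <- hurdle_ann(12, lineages = c("A", "B", "C"))
  d3 <- hurdle_design(ann3, terms = c("cell_cycle_phase", "lineage",
                                      "cell_cycle_phase:lineage",
                                      "fraction_of_detected_genes"),
                      reference_lineage = "A")
  expect_equal(ncol(d3$matrix), 7) # 1 + 1 + 2 + 2 + 1
  expect_true(all(c("lineageB", "lineageC", "phaseG2M:lineageB",
                    "phaseG2M:lineageC") %in% colnames(d3$matrix)))
  expect_false(any(grepl("lineageA", colnames(d3$matrix))))

  expect_error(hurdle_design(ann, terms = "batch"), "unknown term")
  expect_error(
    hurdle_design(ann3, terms = c("cell_cycle_phase",
                                  "cell_cycle_phase:lineage")),
    "both main effects"
  )
  ann1 <- hurdle_ann(6, lineages = "A")
  expect_error(
    hurdle_design(ann1, terms = c("cell_cycle_phase", "lineage")),
    "single lineage"
  )
})

test_that("degenerate components are dropped as specified", {
  ann <- hurdle_ann(10, det = rep(0.8, 10))
  d <- hurdle_design(ann)
  f <- fit_hurdle(rep(4, 10), d) # constant positive expression
  expect_false(f$discrete_live) # all detected
  expect_true(f$continuous_live)
  expect_equal(unname(f$beta_continuous["phaseG2M"]), 0, tolerance = 1e-9)

  f0 <- fit_hurdle(rep(0, 10), d)
  expect_true(f0$untestable)

  # detected units <= coefficients + 1 drops the continuous part
  y <- c(3, 2, 4, 0, rep(0, 6))
  f2 <- fit_hurdle(y, d)
  expect_true(f2$discrete_live)
  expect_false(f2$continuous_live)
})

test_that("hurdle fits reach the penalized maximum likelihood (brute force)", {
  set.seed(20)
  ridge <- 1e-6
  for (i in 1:15) {
    n <- 40
    ann <- hurdle_ann(n)
    d <- hurdle_design(ann)
    X <- d$matrix
    y <- round(pmax(0, rnorm(n, 2, 2)), 2) * rbinom(n, 1, 0.7)
    f <- fit_hurdle(y, d, ridge = ridge)
    z <- as.numeric(y > 0)
    if (f$discrete_live) {
      pll <- function(b) {
        eta <- pmin(pmax(X %*% b, -30), 30)
        sum(z * eta - log1p(exp(eta))) - ridge * sum(b^2)
      }
      o <- optim(rep(0, ncol(X)), function(b) -pll(b), method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
      expect_lte(abs(pll(f$beta_discrete) - (-o$value)), 1e-6)
      expect_gte(pll(f$beta_discrete), -o$value - 1e-6) # never worse
    }
    if (f$continuous_live) {
      det <- y > 0
      Xd <- X[det, , drop = FALSE]
      nll <- function(th) {
        b <- th[1:ncol(X)]; s2 <- exp(th[length(th)])
        r <- y[det] - Xd %*% b
        0.5 * sum(det) * log(2 * pi * s2) + sum(r^2) / (2 * s2)
      }
      o <- optim(c(rep(0, ncol(X)), 0), nll, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
      expect_lte(abs(f$loglik_continuous - (-o$value)), 1e-6)
    }
  }
})

test_that("with no zeros the test is the exact normal-theory LRT", {
  set.seed(21)
  for (i in 1:10) {
    n <- 30
    ann <- hurdle_ann(n)
    d <- hurdle_design(ann)
    y <- rnorm(n, 5, 1) + 0.8 * (ann$phase == "G2M") * (i %% 2)
    y <- pmax(y, 0.1) # all detected
    got <- lrt_term(y, d, "cell_cycle_phase")
    X <- d$matrix
    rss <- function(M) sum(qr.resid(qr(M), y)^2)
    F <- (rss(X[, -2]) - rss(X)) / (rss(X) / (n - ncol(X)))
    p_ref <- pf(F, 1, n - ncol(X), lower.tail = FALSE)
    expect_equal(got$p_value, p_ref, tolerance = 1e-8)
    expect_equal(got$df, 1)
    expect_equal(unname(got$log2fc),
                 unname(qr.coef(qr(X), y)[2]), tolerance = 1e-8)
  }
})

test_that("with a dropped continuous part the test is the logistic LRT", {
  set.seed(22)
  n <- 40
  ann <- hurdle_ann(n, det = rep(0.9, n))
  d <- hurdle_design(ann, terms = "cell_cycle_phase")
  # binary-looking expression: exactly 3 detected units -> continuous dropped
  y <- rep(0, n)
  y[sample(which(ann$phase == "G2M"), 3)] <- 1
  got <- lrt_term(y, d, "cell_cycle_phase")
  z <- as.numeric(y > 0)
  full <- glm(z ~ d$matrix[, "phaseG2M"], family = binomial())
  red <- glm(z ~ 1, family = binomial())
  chisq_ref <- as.numeric(2 * (logLik(full) - logLik(red)))
  expect_equal(got$chisq, chisq_ref, tolerance = 1e-3) # ridge 1e-6 slack
  expect_equal(got$df, 1)
  expect_true(is.na(got$log2fc))
})

test_that("the statistic is invariant to affine rescaling of detection", {
  set.seed(23)
  n <- 50
  ann <- hurdle_ann(n)
  y <- round(pmax(0, rnorm(n, 3, 2)), 2)
  d1 <- hurdle_design(ann)
  ann2 <- ann
  ann2$detection_fraction <- 10 * ann$detection_fraction - 2
  d2 <- hurdle_design(ann2)
  t1 <- lrt_term(y, d1, "cell_cycle_phase")
  t2 <- lrt_term(y, d2, "cell_cycle_phase")
  expect_equal(t1$chisq, t2$chisq, tolerance = 1e-4)
})

test_that("duplicating every unit strengthens a true effect", {
  set.seed(24)
  n <- 30
  ann <- hurdle_ann(n, det = rep(0.8, n))
  y <- round(pmax(0, rnorm(n, 3 + 1.5 * (ann$phase == "G2M"), 1)), 2)
  d1 <- hurdle_design(ann)
  t1 <- lrt_term(y, d1, "cell_cycle_phase")
  ann2 <- rbind(ann, transform(ann, unit_id = paste0(unit_id, "b")))
  d2 <- hurdle_design(ann2)
  t2 <- lrt_term(c(y, y), d2, "cell_cycle_phase")
  expect_gte(t2$chisq, t1$chisq)
})

test_that("a planted lineage-restricted effect is caught by its contrast", {
  set.seed(25)
  per <- 100
  ann <- data.frame(
    unit_id = sprintf("u%04d", 1:(6 * per)),
    phase = rep(rep(c("G1", "G2M"), each = per), 3),
    lineage = rep(c("A", "B", "C"), each = 2 * per),
    detection_fraction = runif(6 * per, 0.7, 1),
    stringsAsFactors = FALSE
  )
  base <- rnorm(6 * per, 5, 0.7)
  eff <- 1.5 * (ann$lineage == "B" & ann$phase == "G2M")
  y <- pmax(base + eff, 0.1)
  d <- hurdle_design(ann, terms = c("cell_cycle_phase", "lineage",
                                    "cell_cycle_phase:lineage",
                                    "fraction_of_detected_genes"),
                     reference_lineage = "A")
  tb <- lrt_term(y, d, "contrast:B")
  tc <- lrt_term(y, d, "contrast:C")
  expect_lt(tb$p_value, 0.01)
  expect_gt(tc$p_value, 0.01)
  expect_equal(unname(tb$log2fc), 1.5, tolerance = 0.35)
  # whole-block deletion also available
  blk <- lrt_term(y, d, "cell_cycle_phase:lineage")
  expect_equal(blk$df, 2)
  expect_lt(blk$p_value, 0.01)
})

test_that("matrix-wise LRT agrees with the single-gene path", {
  set.seed(26)
  n <- 36
  ann <- hurdle_ann(n)
  d <- hurdle_design(ann)
  Y <- matrix(round(pmax(0, rnorm(5 * n, 2, 2)), 2), 5, n,
              dimnames = list(paste0("g", 1:5), ann$unit_id))
  mres <- hurdle_lrt(Y, d, "cell_cycle_phase")
  for (g in 1:5) {
    sres <- lrt_term(Y[g, ], d, "cell_cycle_phase")
    expect_equal(unname(mres$chisq[g, 1]), sres$chisq, tolerance = 1e-10)
    expect_equal(unname(mres$p_value[g, 1]), sres$p_value, tolerance = 1e-10)
  }
})
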