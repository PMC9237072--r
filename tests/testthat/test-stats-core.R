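# Direct step-up formula used as the independent oracle for bh_adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sapply(seq_len(m), function(i) {
    j <- which(o == i) # rank of element i
    min(1, min(m * p[o][seq(j, m)] / seq(j, m)))
  })
}

test_that("bh_adjust matches the step-up formula and its fixed points", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "missing")
  set.seed(1)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("bh_adjust is permutation-equivariant and never below raw p", {
  set.seed(2)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("hypergeometric enrichment handles the boundary cases", {
  all_succ <- hypergeom_enrich(5, 5, 10, 10)
  expect_equal(all_succ$p_value, 1)
  expect_equal(all_succ$fold_enrichment, 1)
  expect_equal(hypergeom_enrich(0, 5, 4, 10)$p_value, 1)
  expect_error(hypergeom_enrich(6, 5, 10, 10), "exceed")
  expect_error(hypergeom_enrich(3, 5, 4, 4), "universe|feasible")
})

test_that("hypergeometric tail matches exhaustive enumeration of draws", {
  # brute force: enumerate all C(N, n) draws, count overlaps >= k
  for (case in list(c(3, 5, 4, 10), c(2, 4, 6, 9), c(1, 3, 3, 8))) {
    k <- case[1]; n <- case[2]; K <- case[3]; N <- case[4]
    draws <- combn(N, n)
    hits <- apply(draws, 2, function(d) sum(d <= K) >= k)
    expect_equal(hypergeom_enrich(k, n, K, N)$p_value, mean(hits),
                 tolerance = 1e-12)
    expect_equal(hypergeom_enrich(k, n, K, N)$fold_enrichment,
                 (k / n) / (K / N))
  }
})

test_that("extreme enrichment survives in log space", {
  res <- hypergeom_enrich(81, 167, 500, 20000)
  expect_gt(res$p_value, 0)
  expect_lt(res$p_value, 1e-50)
  expect_equal(res$fold_enrichment, (81 / 167) / (500 / 20000))
})

# Straightforward independent re-implementation of the trimmed-mean formula
# for one column against a fixed reference, used as the TMM oracle.
tmm_oracle_one <- function(m, k, ref, trimM = 0.3, trimA = 0.05) {
  Nk <- sum(m[, k]); Nr <- sum(m[, ref])
  keep <- m[, k] > 0 & m[, ref] > 0
  yk <- m[keep, k]; yr <- m[keep, ref]
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  w <- (Nk / yk - 1) + (Nr / yr - 1)
  n <- length(M)
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  sel <- rM > floor(n * trimM) & rM <= n - floor(n * trimM) &
    rA > floor(n * trimA) & rA <= n - floor(n * trimA)
  2^(sum(w[sel] * M[sel]) / sum(w[sel]))
}

test_that("TMM factors: identity, scale invariance, product one, formula", {
  x <- random_counts(genes = 400, units = 4, seed = 3)
  m <- x$counts
  m_id <- m[, c(1, 1, 1)]; colnames(m_id) <- paste0("s", 1:3)
  expect_equal(unname(tmm_factors(m_id)), rep(1, 3))

  f <- tmm_factors(m)
  expect_equal(prod(f), 1, tolerance = 1e-12)
  m2 <- m; m2[, 2] <- m2[, 2] * 5L
  expect_equal(unname(tmm_factors(m2)), unname(f), tolerance = 1e-10)

  # spiked instance vs the direct-formula oracle
  set.seed(4)
  sp <- m
  spike <- sample(nrow(sp), nrow(sp) * 0.05)
  sp[spike, 2] <- sp[spike, 2] * 8L
  fsp <- tmm_factors(sp)
  lib <- colSums(sp)
  uq <- apply(sp, 2, quantile, 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  raw <- sapply(seq_len(ncol(sp)), function(k) {
    if (k == ref) 1 else tmm_oracle_one(sp, k, ref)
  })
  expect_equal(unname(fsp), unname(raw / exp(mean(log(raw)))), tolerance = 1e-8)

  bad <- m; bad[, 3] <- 0L
  expect_error(tmm_factors(bad), colnames(m)[3])
})

test_that("CPM follows the formula exactly", {
  one <- matrix(c(1L, 1L, 2L), 3, 1, dimnames = list(letters[1:3], "u"))
  expect_equal(unname(cpm(one)[, 1]), c(250000, 250000, 500000))
  x <- random_counts(seed = 6)
  f <- tmm_factors(x)
  direct <- sweep(x$counts, 2, colSums(x$counts) * f, "/") * 1e6
  expect_equal(cpm(x, f), direct)
  expect_equal(cpm(x), sweep(x$counts, 2, colSums(x$counts), "/") * 1e6)
})

test_that("moderated t: degenerate gene, limit behavior, limma agreement", {
  X <- cbind(1, rep(0:1, each = 3))
  set.seed(7)
  E <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  E[1, ] <- 3 # identical values in both groups
  res <- moderated_t_test(E, X, coef = 2)
  expect_equal(res$table$effect[1], 0, tolerance = 1e-12)
  expect_equal(res$table$t_moderated[1], 0, tolerance = 1e-12)
  expect_equal(res$table$p_value[1], 1, tolerance = 1e-12)
  expect_true(all(res$table$df_total == (6 - 2) + res$prior_df))

  # independent cross-check against limma on a planted instance
  E2 <- matrix(rnorm(200 * 6, sd = sqrt(rchisq(200, 8) / 8)), 200, 6)
  E2[1:20, 4:6] <- E2[1:20, 4:6] + 1.5
  rownames(E2) <- sprintf("g%03d", 1:200)
  mine <- moderated_t_test(E2, X, coef = 2)
  lim <- limma::eBayes(limma::lmFit(E2, X))
  expect_equal(mine$prior_df, lim$df.prior, tolerance = 1e-6)
  expect_equal(mine$table$t_moderated, unname(lim$t[, 2]), tolerance = 1e-9)
  expect_equal(mine$table$p_value, unname(lim$p.value[, 2]), tolerance = 1e-9)

  # shared true variance, many genes: moderated t approaches pooled ordinary t
  set.seed(8)
  E3 <- matrix(rnorm(4000 * 6, sd = 0.7), 4000, 6,
               dimnames = list(sprintf("g%04d", 1:4000), NULL))
  m3 <- moderated_t_test(E3, X, coef = 2)
  expect_gt(m3$prior_df, 50)
  expect_equal(m3$prior_var, 0.49, tolerance = 0.05)
  expect_error(moderated_t_test(E3[, 1:2], cbind(1, 0:1)), "saturated")
})

test_that("moderated t p-values are uniform under the null", {
  set.seed(9)
  X <- cbind(1, rep(0:1, each = 4))
  E <- matrix(rnorm(2000 * 8, sd = sqrt(rchisq(2000, 6) / 6)), 2000, 8,
              dimnames = list(sprintf("g%04d", 1:2000), NULL))
  p <- moderated_t_test(E, X, coef = 2)$table$p_value
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("NB fit reduces to the Poisson log-linear fit at zero dispersion", {
  set.seed(10)
  n <- 12
  off <- log(runif(n, 5e5, 2e6))
  x <- rep(0:1, each = n / 2)
  y <- rpois(n, exp(-8 + 0.6 * x + off))
  fit <- phasic:::nb_irls(y, cbind(1, x), off, phi = 0)
  ref <- glm(y ~ x, family = poisson(), offset = off)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
})

test_that("NB Wald recovers a planted twofold change", {
  set.seed(11)
  G <- 200
  # columns: first 20 at mu 100 (G1), last 20 at mu 200 (G2M)
  m <- cbind(matrix(rnbinom(G * 20, mu = 100, size = 10), G, 20),
             matrix(rnbinom(G * 20, mu = 200, size = 10), G, 20))
  dimnames(m) <- list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:40))
  res <- nb_wald_test(m, rep(c("G1", "G2M"), each = 20),
                      size_factors = 1 / colSums(m))
  # constant offsets: the phase contrast estimates log2(200/100) = 1
  expect_equal(mean(res$log2fc), 1, tolerance = 0.1)
  expect_true(all(res$dispersion >= 1e-8))
  expect_true(all(res$wald_stat >= 0, na.rm = TRUE))
})

test_that("KS phase preference: null, separated, and tiny-sample floor", {
  s <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ph <- rep(c("G1", "G2M"), each = 4)
  null_res <- ks_phase_preference(s, ph)
  expect_equal(null_res$D, 0)
  expect_false(null_res$phase_specific)

  sim <- simulate_activity_scores(1000, shift = 1, seed = 3)
  shifted <- ks_phase_preference(sim$scores, sim$phases)
  expect_lt(shifted$p_value, 1e-12)
  expect_true(shifted$phase_specific)

  tiny <- ks_phase_preference(c(0, 1, 2, 100, 101, 102),
                              rep(c("G1", "G2M"), each = 3))
  expect_false(tiny$phase_specific) # discrete p floor at n = 3 per phase
  expect_error(ks_phase_preference(1:3, c("G1", "G1", "G2M")), "2 units")
})
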