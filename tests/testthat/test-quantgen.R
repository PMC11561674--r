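test_that("marker QC applies MAF and call-rate profiles as configured", {
  doses <- cbind(rep(0, 140),                      # monomorphic
                 c(rep(2, 70), rep(0, 70)),        # MAF 0.5, complete
                 c(rep(NA, 8), rep(c(0, 2), 66)))  # call rate 132/140
  map <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                    id = c("mono", "common", "patchy"),
                    a1 = "A", a2 = "T")
  G <- genotype_matrix(doses, map, sprintf("l%03d", 1:140))
  expect_equal(unname(G$callrate[3]), 132 / 140)
  expect_error(qc_markers(subset_markers(G, 1), 0.05, 0), "no markers")
  grm_set <- qc_markers(G, 0.05, 0.95, "ge")
  expect_equal(grm_set$map$id, "common")           # 0.943 fails >= 0.95
  scan_set <- qc_markers(G, 0.05, 0.80, "gt")
  expect_setequal(scan_set$map$id, c("common", "patchy"))
  all_kept <- qc_markers(G, 0, 0, "ge")
  expect_equal(ncol(all_kept$doses), 3)            # identity at zero thresholds
})

test_that("LD pruning drops duplicates and keeps sub-threshold pairs", {
  set.seed(3)
  base <- rbinom(80, 1, 0.4) * 2
  doses <- cbind(base, base,                                  # r2 = 1
                 ifelse(runif(80) < 0.5, base, rbinom(80, 1, 0.4) * 2))
  map <- data.frame(chrom = "chr1", pos = c(1000, 2000, 3000),
                    id = c("a", "dup", "half"), a1 = "A", a2 = "T")
  G <- genotype_matrix(doses, map, sprintf("l%02d", 1:80))
  kept <- ld_prune(G, r2_max = 0.8, window_bp = 10000, step_bp = 1000)
  expect_false("dup" %in% kept)
  expect_true(all(c("a", "half") %in% kept))       # r2 ~ 0.5 stays
  expect_error(ld_prune(G, step_bp = 0), "step_bp")
})

test_that("LD pruning matches the brute-force window-enumeration oracle", {
  for (s in 1:3) {
    G <- simulate_genotypes(80, 500, ld_decay = 0.9, missing_rate = 0.01,
                            seed = s, spacing_max = 2000)
    G <- qc_markers(G, 0.02, 0.5, "ge")
    expect_identical(ld_prune(G, 0.8, 20000, 1000),
                     prune_oracle(G, 0.8, 20000, 1000))
  }
})

test_that("the GRM matches its definition and the double-loop oracle", {
  G <- simulate_genotypes(20, 200, missing_rate = 0.02, seed = 13)
  G <- qc_markers(G, 0.05, 0.5, "ge")
  W <- scale_doses(G)
  K <- compute_grm(G)
  expect_lt(max(abs(K$K - grm_oracle(W))), 1e-10)
  expect_equal(K$K, t(K$K))

  ## identical lines share diagonal and off-diagonal entries
  dup <- genotype_matrix(G$doses[c(1, 1, 2:20), , drop = FALSE], G$map,
                         sprintf("l%02d", 1:21))
  Kd <- compute_grm(qc_markers(dup, 0.05, 0.5))$K
  expect_equal(Kd[1, 2], Kd[1, 1])
  expect_equal(Kd[1, 2], Kd[2, 2])

  ## independent markers: mean diagonal near 1
  Gi <- simulate_genotypes(100, 4000, ld_decay = 0, missing_rate = 0,
                           seed = 14)
  Ki <- compute_grm(qc_markers(Gi, 0.01, 0.5))
  expect_equal(mean(diag(Ki$K)), 1, tolerance = 3 / sqrt(Ki$m))
})

test_that("REML recovers strong signal and stays near zero under the null", {
  set.seed(17)
  G <- simulate_genotypes(80, 1500, seed = 17)
  K <- compute_grm(qc_markers(G, 0.05, 0.9))$K
  ## phenotype drawn from N(0, K) with tiny residual
  L <- chol(K + 1e-8 * diag(80))
  y <- as.numeric(t(L) %*% rnorm(80)) + rnorm(80, 0, 0.01)
  f <- fit_gblup(y, NULL, K, se = FALSE)
  expect_gte(f$h2, 0.95)

  h2_null <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    fit_gblup(rnorm(80), NULL, K, se = FALSE)$h2
  }, numeric(1))
  expect_lt(median(h2_null), 0.1)
})

test_that("the profiled restricted likelihood is a global optimum", {
  G <- simulate_genotypes(60, 800, seed = 23)
  ph <- simulate_phenotype(G, 0.5, seed = 23)
  K <- compute_grm(qc_markers(G, 0.05, 0.9))$K
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- as.numeric(crossprod(eg$vectors, ph$phenotype$delay))
  Xt <- crossprod(eg$vectors, matrix(1, 60, 1))
  core <- rapasens:::.gblup_core(yt, Xt, d)
  rll_at <- function(loglam) {
    lam <- exp(loglam); ld1 <- lam * d + 1; w <- 1 / ld1
    A <- crossprod(Xt, w * Xt)
    beta <- solve(A, crossprod(Xt, w * yt))
    r <- yt - Xt %*% beta
    s2e <- sum(w * r^2) / (length(yt) - 1)
    -0.5 * ((length(yt) - 1) * (log(s2e) + 1) + sum(log(ld1)) +
              determinant(A, logarithm = TRUE)$modulus[1])
  }
  set.seed(5)
  probes <- vapply(runif(1000, -10, 10), rll_at, numeric(1))
  expect_gte(core$loglik + 1e-8, max(probes))
})

test_that("gBLUP REML agrees with a dense generic-optimizer oracle", {
  for (s in 1:3) {
    G <- simulate_genotypes(50, 800, seed = s)
    ph <- simulate_phenotype(G, 0.5, seed = s)
    K <- compute_grm(qc_markers(G, 0.05, 0.9))$K
    X <- matrix(1, 50, 1)
    f <- fit_gblup(ph$phenotype$delay, X, K, se = FALSE)
    h2o <- dense_reml_oracle(ph$phenotype$delay, X, K)
    expect_lt(abs(f$h2 - h2o), 1e-4)
  }
})

test_that("fit_gblup validates its inputs and reports uncertainty", {
  G <- simulate_genotypes(60, 800, seed = 31)
  ph <- simulate_phenotype(G, 0.6, seed = 31)
  K <- compute_grm(qc_markers(G, 0.05, 0.9))
  f <- fit_gblup(ph$phenotype$delay, NULL, K)
  expect_true(f$h2 >= 0 && f$h2 <= 1)
  expect_true(is.na(f$h2_se) || f$h2_se > 0)
  expect_lt(abs(mean(f$ghat)), 0.15)
  expect_error(fit_gblup(ph$phenotype$delay, matrix(1, 60, 2), K),
               "rank deficient")
  expect_error(fit_gblup(ph$phenotype$delay, NULL, -K$K), "positive semi-definite")
})

test_that("marker effects backsolve reconstructs the genomic values", {
  G <- simulate_genotypes(40, 300, missing_rate = 0, seed = 41)
  G <- qc_markers(G, 0.05, 0.9)
  W <- scale_doses(G)
  K <- compute_grm(G)
  ph <- simulate_phenotype(G, 0.7, seed = 41)
  f <- fit_gblup(ph$phenotype$delay, NULL, K, se = FALSE)
  s <- backsolve_marker_effects(W, K, f$ghat)
  expect_lt(max(abs(W %*% s - f$ghat)), 1e-8)  # full-rank K

  ## single marker: least-squares coefficient of ghat on that column
  W1 <- W[, 1, drop = FALSE]
  K1 <- list(K = tcrossprod(W1) / 1, line_ids = G$line_ids, m = 1L)
  class(K1) <- "grm"
  s1 <- backsolve_marker_effects(W1, K1, f$ghat)
  expect_equal(s1, sum(W1 * f$ghat) / sum(W1^2), tolerance = 1e-8)

  ## a duplicated marker splits its effect equally
  Wd <- cbind(W, W[, 1])
  Kd <- list(K = tcrossprod(Wd) / ncol(Wd), line_ids = G$line_ids,
             m = ncol(Wd))
  class(Kd) <- "grm"
  sd_ <- backsolve_marker_effects(Wd, Kd, f$ghat)
  expect_equal(sd_[1], sd_[ncol(Wd)], tolerance = 1e-10)
  expect_error(backsolve_marker_effects(W[1:10, ], K, f$ghat), "mismatch")
})

test_that("bootstrap subsampling is deterministic and exact at full size", {
  G <- simulate_genotypes(50, 600, seed = 51)
  ph <- simulate_phenotype(G, 0.5, seed = 51)
  K <- compute_grm(qc_markers(G, 0.05, 0.9))
  full <- fit_gblup(ph$phenotype$delay, NULL, K, se = FALSE)$h2
  bs <- bootstrap_h2(ph$phenotype$delay, NULL, K, sizes = c(30, 50),
                     n_reps = 5, seed = 3)
  ## full-size subsamples only reorder lines; the refit agrees with the
  ## full fit up to eigendecomposition round-off
  expect_equal(bs$h2[bs$size == 50], rep(full, 5), tolerance = 1e-5)
  bs2 <- bootstrap_h2(ph$phenotype$delay, NULL, K, sizes = c(30, 50),
                      n_reps = 5, seed = 3)
  expect_identical(bs, bs2)
})

test_that("the permutation null counts exceedances of the observed H2", {
  G <- simulate_genotypes(60, 800, seed = 61)
  ph <- simulate_phenotype(G, 0.9, seed = 61)
  K <- compute_grm(qc_markers(G, 0.05, 0.9))
  pm <- permute_h2(ph$phenotype$delay, NULL, K, n_perm = 49, seed = 9)
  expect_equal(pm$p_value, max(pm$count, 1) / 49)
  expect_true(pm$p_value >= 1 / 49 && pm$p_value <= 1)
  expect_length(pm$h2_perm, 49)
  pm2 <- permute_h2(ph$phenotype$delay, NULL, K, n_perm = 49, seed = 9)
  expect_identical(pm$h2_perm, pm2$h2_perm)
  ## permuted null is right-skewed and zero-inflated
  expect_lt(median(pm$h2_perm), 0.25)
})
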