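test_that("per-sample normalization centres, scales and is idempotent", {
  sm <- simulate_metabolome(n_metabolites = 30, seed = 101)
  M <- normalize_metabolome(sm$matrix)
  expect_lt(max(abs(rowMeans(M$intensity))), 1e-9)
  expect_lt(max(abs(apply(M$intensity, 1, sd) - 1)), 1e-9)
  M2 <- normalize_metabolome(M)
  expect_equal(M2$intensity, M$intensity, tolerance = 1e-12)

  ## multiplying one sample's raw row by a constant changes nothing
  raw2 <- sm$matrix
  raw2$intensity[3, ] <- raw2$intensity[3, ] * 17
  expect_equal(normalize_metabolome(raw2)$intensity[3, ], M$intensity[3, ],
               tolerance = 1e-12)

  flat <- sm$matrix
  flat$intensity[2, ] <- 5
  expect_error(normalize_metabolome(flat), "zero within-sample SD")
  neg <- sm$matrix
  neg$intensity[1, 2] <- 0
  expect_error(normalize_metabolome(neg), "non-positive")
})

test_that("batch correction is near-identity when batches coincide", {
  sm <- simulate_metabolome(n_metabolites = 40, reps = 2, seed = 103,
                            batch_shifts = data.frame(batch = "b1",
                                                      location = 0, scale = 1))
  M <- normalize_metabolome(sm$matrix)
  ## duplicate every sample into a second, identical batch
  dup <- metabolite_matrix(rbind(M$intensity, M$intensity),
                           rbind(transform(M$meta, batch = "x1"),
                                 transform(M$meta,
                                           sample = paste0(M$meta$sample, "b"),
                                           batch = "x2")),
                           normalized = TRUE)
  out <- correct_batch(dup)
  ## the EB priors leave a small residual even with coinciding batches
  expect_equal(out$intensity, dup$intensity, tolerance = 0.02)
  expect_gt(stats::cor(as.numeric(out$intensity), as.numeric(dup$intensity)),
            0.9999)
  one <- metabolite_matrix(M$intensity,
                           transform(M$meta,
                                     batch = c("solo", rep("big", nrow(M$meta) - 1))),
                           normalized = TRUE)
  expect_error(correct_batch(one), "single sample")
})

test_that("batch correction removes an injected location shift with shrinkage", {
  sm <- simulate_metabolome(n_metabolites = 154, reps = 2, seed = 107,
                            batch_shifts = data.frame(batch = c("b1", "b2"),
                                                      location = c(0, 3),
                                                      scale = c(1, 1)))
  M <- normalize_metabolome(sm$matrix)
  out <- correct_batch(M)
  b2 <- M$meta$batch == "b2"
  pre <- colMeans(M$intensity[b2, ]) - colMeans(M$intensity[!b2, ])
  post <- colMeans(out$intensity[b2, ]) - colMeans(out$intensity[!b2, ])
  expect_lt(mean(abs(post)), mean(abs(pre)))
  ## residual differences are shrunk toward zero relative to the raw
  ## per-metabolite estimates, but remain positively aligned with them
  expect_gt(stats::cor(pre, pre - post), 0.5)
  expect_lt(stats::sd(post), stats::sd(pre))
})

test_that("PCA orients components and reconstructs the data", {
  set.seed(109)
  latent <- rnorm(20)
  load <- rnorm(10)
  x <- outer(latent, load) + matrix(rnorm(200, 0, 1e-4), 20, 10)
  pc <- pca_scores(x)
  expect_gt(pc$var_frac[1], 0.999)
  ## orientation convention: largest-magnitude loading positive
  for (k in 1:5) {
    l <- pc$loadings[, k]
    expect_gte(l[which.max(abs(l))], 0)
  }
  ## full-rank reconstruction
  set.seed(110)
  y <- matrix(rnorm(20 * 10), 20, 10)
  pcy <- pca_scores(y)
  rec <- pcy$scores %*% t(pcy$loadings)
  rec <- sweep(rec, 2, pcy$center, "+")
  expect_equal(rec, y, tolerance = 1e-8, ignore_attr = TRUE)
  ## covariance-eigendecomposition oracle (up to sign)
  ev <- eigen(stats::cov(y), symmetric = TRUE)
  for (k in 1:3)
    expect_equal(abs(as.numeric(pcy$loadings[, k])), abs(ev$vectors[, k]),
                 tolerance = 1e-8)
  expect_error(pca_scores(rbind(y, NA)), "missing")
})

test_that("the Type-III mixed ANOVA matches the fixed-effects oracle at zero line variance", {
  skip_if_not_installed("car")
  set.seed(42)
  meta <- balanced_design(reps = 2)
  e <- rnorm(nrow(meta), 0, 0.4)
  e <- e - stats::ave(e, meta$line)    # no between-line variance at all
  y <- 0.5 * (meta$treatment == "rapamycin") + e
  M <- metabolite_matrix(matrix(y, ncol = 1, dimnames = list(NULL, "met1")),
                         meta, normalized = TRUE)
  ia <- interaction_anova(M)
  expect_true(ia$singular)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  lmfit <- stats::lm(y ~ treatment * phenotype, data = data.frame(
    treatment = factor(meta$treatment, levels = c("control", "rapamycin")),
    phenotype = factor(meta$class, levels = c("resistant", "sensitive"))))
  av <- car::Anova(lmfit, type = 3)
  expect_lt(abs(ia$p_treatment - av["treatment", "Pr(>F)"]), 1e-6)
  expect_lt(abs(ia$p_phenotype - av["phenotype", "Pr(>F)"]), 1e-6)
  expect_lt(abs(ia$p_interaction - av["treatment:phenotype", "Pr(>F)"]), 1e-6)
})

test_that("mixed-model results are invariant to sample and metabolite order", {
  sm <- simulate_metabolome(n_metabolites = 6, reps = 2, seed = 113,
                            effects = cbind(treatment = rep(0.5, 6),
                                            phenotype = 0, interaction = 0))
  M <- normalize_metabolome(sm$matrix)
  ia <- interaction_anova(M)
  perm <- sample(nrow(M$intensity))
  Mp <- metabolite_matrix(M$intensity[perm, c(3, 1, 2, 6, 5, 4)],
                          M$meta[perm, ], normalized = TRUE)
  iap <- interaction_anova(Mp)
  expect_equal(iap$p_interaction[match(ia$metabolite, iap$metabolite)],
               ia$p_interaction, tolerance = 1e-6)
  es <- treatment_effects_by_class(M, "sensitive")
  esp <- treatment_effects_by_class(Mp, "sensitive")
  expect_equal(esp$beta[match(es$metabolite, esp$metabolite)], es$beta,
               tolerance = 1e-8)
})

test_that("treatment effects flip sign exactly under label swap", {
  ## effect on 8 of 40 metabolites (a uniform effect on every metabolite
  ## would be absorbed by the per-sample centring)
  sm <- simulate_metabolome(n_metabolites = 40, reps = 2, seed = 127,
                            effects = cbind(treatment = rep(c(-1, 0), c(8, 32)),
                                            phenotype = 0, interaction = 0))
  M <- normalize_metabolome(sm$matrix)
  es <- treatment_effects_by_class(M, "sensitive")
  expect_true(all(es$beta[1:8] < 0))     # simulated negative effect recovered
  swapped <- M
  swapped$meta$treatment <- ifelse(M$meta$treatment == "control",
                                   "rapamycin", "control")
  es2 <- treatment_effects_by_class(swapped, "sensitive")
  expect_equal(es2$beta, -es$beta, tolerance = 1e-8)
})

test_that("Spearman concordance matches the rank-then-Pearson oracle", {
  expect_equal(effect_sign_concordance(1:10, 1:10)$rho, 1)
  expect_equal(effect_sign_concordance(1:10, 10:1)$rho, -1)
  set.seed(131)
  x <- rnorm(154)
  y <- 0.5 * x + rnorm(154)
  got <- effect_sign_concordance(x, y)
  oracle <- stats::cor(rank(x), rank(y))
  expect_lt(abs(got$rho - oracle), 1e-12)
  expect_error(effect_sign_concordance(rep(1, 10), rnorm(10)), "constant")
})
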