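test_that("kNN imputation averages the nearest metabolite columns", {
  ## target duplicated by 10 identical neighbours
  base <- c(1, 4, 2, 8, 5, 3, 7, 6)
  M <- cbind(target = base, matrix(rep(base, 10), ncol = 10),
             matrix(rnorm(8 * 5, 10, 3), ncol = 5))
  colnames(M) <- c("target", paste0("nb", 1:10), paste0("far", 1:5))
  M[3, "target"] <- NA
  out <- impute_knn(M, k = 10)
  expect_equal(unname(out[3, "target"]), base[3])

  ## k = all other metabolites: imputed value is the row mean of the rest
  set.seed(141)
  M2 <- matrix(rnorm(50), 5, 10)
  M2[2, 4] <- NA
  out2 <- impute_knn(M2, k = 9)
  expect_equal(out2[2, 4], mean(M2[2, -4], na.rm = TRUE))
})

test_that("kNN imputation matches an exhaustive distance-sort oracle", {
  set.seed(143)
  M <- matrix(rnorm(200), 10, 20)
  holes <- cbind(sample(10, 6, replace = TRUE), sample(20, 6))
  holes <- holes[!duplicated(holes[, 2]), , drop = FALSE]
  M[holes] <- NA
  out <- impute_knn(M, k = 4)
  for (r in seq_len(nrow(holes))) {
    s <- holes[r, 1]; j <- holes[r, 2]
    cand <- setdiff(which(!is.na(M[s, ])), j)
    d <- sapply(cand, function(i) {
      ok <- !is.na(M[, i]) & !is.na(M[, j])
      sqrt(sum((M[ok, i] - M[ok, j])^2))
    })
    nb <- cand[order(d)][1:4]
    expect_equal(out[s, j], mean(M[s, nb]))
  }
})

test_that("harmonization filters, merges duplicate ions and intersects names", {
  tc <- simulate_starvation_timecourse(n_metabolites = 90, seed = 151,
                                       n_single_missing = 6,
                                       n_double_missing = 3, dup_pairs = 9,
                                       noise_sd = 0.1)
  truth <- attr(tc, "truth")
  sm <- simulate_metabolome(n_metabolites = 154, seed = 151)
  query <- normalize_metabolome(sm$matrix)
  base <- sprintf("ref%03d", 1:87)  # 90 minus the 3 double-missing, at most
  ## map the first 84 surviving reference metabolites onto query names
  ref_names <- setdiff(colnames(tc)[-(1:2)], truth$dup_pairs$ref_b)
  ref_names <- ref_names[1:84]
  nm <- data.frame(ref = ref_names, query = sprintf("met%03d", 1:84))
  dup_rows <- truth$dup_pairs[paste0(truth$dup_pairs$base, "_pos") %in% ref_names, ]
  nm <- rbind(nm, data.frame(ref = dup_rows$ref_b,
                             query = nm$query[match(paste0(dup_rows$base, "_pos"),
                                                    nm$ref)]))
  hp <- harmonize(tc, query, nm, dup_pairs = truth$dup_pairs)
  expect_lte(ncol(hp$ref), 84)
  expect_gte(ncol(hp$ref), 80)       # the double-missing columns are gone
  expect_identical(colnames(hp$ref), colnames(hp$query))
  expect_false(anyNA(hp$ref))

  ## undeclared many-to-one mapping is an error (the first map rows are
  ## duplicate-pair bases, which always survive the missingness filter)
  bad <- nm
  bad$query[2] <- bad$query[1]
  expect_error(harmonize(tc, query, bad, dup_pairs = truth$dup_pairs),
               "collision")
})

test_that("a duplicate-ion pair of identical columns merges to itself", {
  set.seed(153)
  v <- rnorm(10)
  ref <- data.frame(sample = sprintf("s%02d", 1:10), time_h = rep(1:5, 2),
                    a_pos = v, a_neg = v,
                    b = rnorm(10), c = rnorm(10), d = rnorm(10))
  nm <- data.frame(ref = c("a_pos", "a_neg", "b", "c", "d"),
                   query = c("A", "A", "B", "C", "D"))
  qx <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  hp <- harmonize(ref, qx, nm,
                  dup_pairs = data.frame(ref_a = "a_pos", ref_b = "a_neg"))
  ## after per-sample normalization both members are the same column, so
  ## the merged column equals either member scaled per metabolite
  rx <- as.matrix(ref[, 3:7])
  rx <- (rx - rowMeans(rx)) / apply(rx, 1, sd)
  expect_equal(unname(hp$ref[, "A"]), as.numeric(scale(rx[, "a_pos"])),
               tolerance = 1e-12)
})

test_that("the reference axis recovers generating loadings and scores", {
  loadings <- local({ set.seed(155); l <- rnorm(40); l / sqrt(sum(l^2)) })
  tc <- simulate_starvation_timecourse(n_metabolites = 40, loadings = loadings,
                                       noise_sd = 0.05, seed = 155)
  ref <- as.matrix(tc[, -(1:2)])
  ax <- fit_reference_axis(ref, tc$time_h)
  cosine <- abs(sum(ax$loading * loadings))
  expect_gt(cosine, 0.95)
  ## orientation: scores increase with time
  expect_gt(stats::cor(ax$scores, tc$time_h, method = "spearman"), 0)
  ## fit consistency: projecting the training samples reproduces scores
  expect_equal(unname(project(ref, ax)), ax$scores, tolerance = 1e-10)
  ## shuffled times leave orientation poorly determined (and may defeat
  ## the trajectory fit, which is reported as a second warning)
  w <- capture_warnings(fit_reference_axis(ref, sample(tc$time_h)))
  expect_true(any(grepl("orientation", w)))
})

test_that("trajectory fitting recovers the printed constants on clean data", {
  t5 <- rep(c(0, 2, 4, 6, 8), each = 5)
  s <- starvation_score(t5, 20.53, 2.77, 10.01)
  fit <- fit_trajectory(s, t5)
  expect_equal(fit$a, 20.53, tolerance = 1e-6)
  expect_equal(fit$b, 2.77, tolerance = 1e-6)
  expect_equal(fit$c, 10.01, tolerance = 1e-6)
  expect_gt(fit$r2, 1 - 1e-10)
  ## the fitted curve at t = 0 is exactly -c
  expect_equal(starvation_score(0, fit$a, fit$b, fit$c), -fit$c)

  flat <- fit_trajectory(rep(2, 10), rep(c(0, 2, 4, 6, 8), 2))
  expect_true(flat$degenerate)
  expect_equal(flat$a, 0)
  expect_equal(flat$r2, 0)
})

test_that("trajectory fitting matches a lattice-plus-polish oracle", {
  set.seed(157)
  for (i in 1:20) {
    a <- runif(1, 5, 30); b <- runif(1, 0.5, 6); cc <- runif(1, -5, 15)
    tt <- rep(c(0, 2, 4, 6, 8), each = 3)
    s <- starvation_score(tt, a, b, cc) + rnorm(length(tt), 0, 0.3)
    fit <- fit_trajectory(s, tt)
    orc <- trajectory_oracle(s, tt)
    sse_fit <- sum((s - (fit$a * tt / (tt + fit$b) - fit$c))^2)
    expect_lt(sse_fit, orc$sse + 1e-4)
    if (abs(sse_fit - orc$sse) < 1e-8) {
      expect_equal(fit$a, orc$a, tolerance = 1e-3)
      expect_equal(fit$b, orc$b, tolerance = 1e-3)
    }
  }
})

test_that("projection is linear and centred on the training mean profile", {
  loadings <- local({ set.seed(161); l <- rnorm(30); l / sqrt(sum(l^2)) })
  tc <- simulate_starvation_timecourse(n_metabolites = 30, loadings = loadings,
                                       noise_sd = 0.1, seed = 161)
  ref <- as.matrix(tc[, -(1:2)])
  ax <- fit_reference_axis(ref, tc$time_h)
  mu <- matrix(ax$means, 1, dimnames = list(NULL, ax$metabolites))
  expect_equal(unname(project(mu, ax)), 0, tolerance = 1e-10)
  x <- ref[3, , drop = FALSE]
  y <- ref[7, , drop = FALSE]
  lhs <- project(0.3 * x + 0.7 * y, ax)
  expect_equal(unname(lhs),
               unname(0.3 * project(x, ax) + 0.7 * project(y, ax)),
               tolerance = 1e-10)
  expect_error(project(x[, -1, drop = FALSE], ax), "missing")
})

test_that("axis displacement shows up in the interaction test and not its F under label swap", {
  loadings <- local({ set.seed(163); l <- rnorm(40); l / sqrt(sum(l^2)) })
  tc <- simulate_starvation_timecourse(n_metabolites = 40, loadings = loadings,
                                       noise_sd = 0.1, seed = 163)
  ax <- fit_reference_axis(as.matrix(tc[, -(1:2)]), tc$time_h)
  ## sensitive+rapamycin samples displaced along the generating loadings
  meta <- balanced_design(reps = 2)
  set.seed(164)
  disp <- 3 * (meta$treatment == "rapamycin") * (meta$class == "sensitive")
  qx <- matrix(ax$means, nrow(meta), 40, byrow = TRUE,
               dimnames = list(meta$sample, ax$metabolites)) +
    outer(disp, loadings) + matrix(rnorm(nrow(meta) * 40, 0, 0.1), ncol = 40)
  sc <- project(qx, ax)
  ## mean projected displacement recovers the injected shift
  expect_equal(mean(sc[disp > 0]) - mean(sc[disp == 0 &
                                              meta$class == "sensitive"]),
               3, tolerance = 0.3)
  dt <- displacement_test(sc, meta)
  expect_lt(dt$interaction[["p"]], 1e-4)
  swapped <- meta
  swapped$treatment <- ifelse(meta$treatment == "control", "rapamycin",
                              "control")
  dt2 <- displacement_test(sc, swapped)
  expect_equal(dt2$interaction[["F"]], dt$interaction[["F"]], tolerance = 1e-6)
  expect_equal(unname(dt2$beta["treatment1"]), -unname(dt$beta["treatment1"]),
               tolerance = 1e-6)
})
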