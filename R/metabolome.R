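## Metabolome analysis: per-sample normalisation, empirical-Bayes batch
## correction, PCA, and per-metabolite mixed models for treatment,
## phenotype-class and interaction effects with Storey FDR.

#' Normalize a metabolite intensity matrix
#'
#' Natural-log transforms raw positive intensities, then centres each
#' SAMPLE (row) to mean 0 and scales it to SD 1. Applied to an
#' already-normalized matrix the log step is skipped and the re-centring
#' is a no-op, so the operation is idempotent on its own output.
#'
#' @param M a [metabolite_matrix()].
#' @return a normalized [metabolite_matrix()].
#' @export
normalize_metabolome <- function(M) {
  x <- M$intensity
  if (!M$normalized) {
    bad <- which(!(x > 0), arr.ind = TRUE)
    if (nrow(bad))
      stop2("non-positive intensity at sample %s, metabolite %s",
            rownames(x)[bad[1, 1]] %||% bad[1, 1],
            colnames(x)[bad[1, 2]] %||% bad[1, 2])
    x <- log(x)
  }
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop2("zero within-sample SD for sample(s): %s",
          paste(rownames(x)[sds == 0 | !is.finite(sds)], collapse = ", "))
  x <- (x - rowMeans(x)) / sds
  metabolite_matrix(x, M$meta, normalized = TRUE)
}

#' Empirical-Bayes batch correction
#'
#' Removes extraction-batch location/scale effects per metabolite with the
#' parametric empirical-Bayes adjustment (normal prior on batch means,
#' inverse-gamma on batch variances, iterative moment shrinkage), with no
#' covariate matrix preserved. The adjustment is delegated to
#' `sva::ComBat`.
#'
#' @param M a normalized [metabolite_matrix()].
#' @param batches optional sample -> batch assignment; defaults to
#'   `M$meta$batch`.
#' @return a corrected [metabolite_matrix()].
#' @export
correct_batch <- function(M, batches = NULL) {
  b <- batches %||% M$meta$batch
  tab <- table(b)
  if (length(tab) < 2) stop2("need at least 2 batches")
  if (any(tab < 2))
    stop2("batch(es) with a single sample: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  corrected <- suppressMessages(
    sva::ComBat(dat = t(M$intensity), batch = as.character(b),
                par.prior = TRUE, prior.plots = FALSE))
  metabolite_matrix(t(corrected), M$meta, normalized = M$normalized)
}

#' Principal components of a metabolite matrix
#'
#' SVD-based PCA with metabolites as variables. Each component is
#' oriented so its largest-magnitude loading is positive.
#'
#' @param M a [metabolite_matrix()] or plain samples x metabolites matrix.
#' @param center,scale passed to the column centring/scaling step.
#' @return list: `scores` (samples x PCs), `loadings` (orthonormal),
#'   `var_frac`, `center`, `scale`.
#' @export
pca_scores <- function(M, center = TRUE, scale = FALSE) {
  x <- if (inherits(M, "metabolite_matrix")) M$intensity else as.matrix(M)
  if (anyNA(x)) stop2("missing values: impute before PCA")
  if (nrow(x) < 2) stop2("need more than one sample")
  pc <- stats::prcomp(x, center = center, scale. = scale)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       var_frac = pc$sdev^2 / sum(pc$sdev^2),
       center = pc$center, scale = pc$scale)
}

## Random-intercept mixed model with Type-III (sum-to-zero) F tests.
## Denominator df is residual-based: n - p - (g - 1), or n - p when the
## line variance collapses to the boundary, in which case the fit reduces
## exactly to the fixed-effects model.
.lmm_type3 <- function(y, dat, formula_rhs, terms) {
  dat$.y <- y
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(paste(".y ~", formula_rhs, "+ (1 | line)")),
                 data = dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  X <- stats::model.matrix(fit)
  asg <- attr(X, "assign")
  labs <- attr(stats::terms(stats::as.formula(paste("~", formula_rhs))), "term.labels")
  n <- length(y); p <- length(beta)
  g <- length(unique(dat$line))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_line <- vc$vcov[vc$grp == "line"]
  singular <- s2_line < 1e-8 * sum(vc$vcov)
  ddf <- if (singular) n - p else n - p - (g - 1)
  out <- lapply(terms, function(tm) {
    j <- which(asg == match(tm, labs))
    q <- length(j)
    if (!q) return(c(F = NA, df1 = NA, df2 = NA, p = NA))
    b <- beta[j]
    Fv <- as.numeric(crossprod(b, solve(V[j, j, drop = FALSE], b))) / q
    c(F = Fv, df1 = q, df2 = ddf, p = stats::pf(Fv, q, ddf, lower.tail = FALSE))
  })
  names(out) <- terms
  list(tests = out, beta = beta, vcov = V, sigma2_line = s2_line,
       singular = singular, fit = fit)
}

#' Per-metabolite interaction ANOVA with a line random effect
#'
#' Fits `metabolite ~ bT + bP + bTxP + (1|line)` by REML for each
#' metabolite and reports Type-III (sum-to-zero contrast) marginal F
#' tests per fixed term, with Storey q-values across metabolites per
#' term. Metabolites whose model cannot be fit are flagged and excluded
#' from the FDR.
#'
#' @param M a normalized, batch-corrected [metabolite_matrix()].
#' @param design optional data.frame overriding `M$meta` (needs `line`,
#'   `class`, `treatment`).
#' @return data.frame per metabolite: F, df and p per term (`treatment`,
#'   `phenotype`, `interaction`), line variance, `singular`, and q-values
#'   per term.
#' @export
interaction_anova <- function(M, design = NULL) {
  meta <- design %||% M$meta
  stopifnot(all(c("line", "class", "treatment") %in% names(meta)))
  if (length(unique(meta$treatment)) < 2) stop2("both treatments must be present")
  if (any(table(unique(meta[c("line", "class")])$class) < 2))
    stop2("need >= 2 lines per phenotype class")
  dat <- data.frame(line = factor(meta$line),
                    treatment = factor(meta$treatment,
                                       levels = c("control", "rapamycin")),
                    phenotype = factor(meta$class,
                                       levels = c("resistant", "sensitive")))
  terms <- c("treatment", "phenotype", "treatment:phenotype")
  rows <- lapply(seq_len(ncol(M$intensity)), function(j) {
    r <- .lmm_type3(M$intensity[, j], dat, "treatment * phenotype", terms)
    if (is.null(r))
      return(data.frame(metabolite = colnames(M$intensity)[j],
                        F_treatment = NA, p_treatment = NA,
                        F_phenotype = NA, p_phenotype = NA,
                        F_interaction = NA, p_interaction = NA,
                        df2 = NA, sigma2_line = NA, singular = NA))
    data.frame(metabolite = colnames(M$intensity)[j],
               F_treatment = r$tests[["treatment"]][["F"]],
               p_treatment = r$tests[["treatment"]][["p"]],
               F_phenotype = r$tests[["phenotype"]][["F"]],
               p_phenotype = r$tests[["phenotype"]][["p"]],
               F_interaction = r$tests[["treatment:phenotype"]][["F"]],
               p_interaction = r$tests[["treatment:phenotype"]][["p"]],
               df2 = r$tests[["treatment"]][["df2"]],
               sigma2_line = r$sigma2_line, singular = r$singular,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_treatment <- storey_qvalues(out$p_treatment)
  out$q_phenotype <- storey_qvalues(out$p_phenotype)
  out$q_interaction <- storey_qvalues(out$p_interaction)
  out
}

#' Treatment effects on metabolites within one phenotype class
#'
#' Within the chosen class, fits `metabolite ~ bT + (1|line)` per
#' metabolite (treatment coded control -> rapamycin, so `beta_T` is the
#' rapamycin displacement) and reports Wald t tests with Storey q-values
#' across metabolites.
#'
#' @param M a normalized, batch-corrected [metabolite_matrix()].
#' @param class `"resistant"` or `"sensitive"`.
#' @return data.frame per metabolite: `beta`, `se`, `t`, `df`,
#'   `p_value`, `q_value`.
#' @export
treatment_effects_by_class <- function(M, class = c("sensitive", "resistant")) {
  class <- match.arg(class)
  sel <- M$meta$class == class
  if (length(unique(M$meta$line[sel])) < 2)
    stop2("class %s has fewer than 2 lines", class)
  meta <- M$meta[sel, , drop = FALSE]
  x <- M$intensity[sel, , drop = FALSE]
  dat <- data.frame(line = factor(meta$line),
                    treatment = factor(meta$treatment,
                                       levels = c("control", "rapamycin")))
  n <- nrow(dat); g <- nlevels(dat$line)
  rows <- lapply(seq_len(ncol(x)), function(j) {
    dat$.y <- x[, j]
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(.y ~ treatment + (1 | line), data = dat, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(metabolite = colnames(x)[j], beta = NA, se = NA,
                        t = NA, df = NA, p_value = NA))
    beta <- lme4::fixef(fit)[["treatmentrapamycin"]]
    se <- sqrt(as.matrix(stats::vcov(fit))[2, 2])
    vc <- as.data.frame(lme4::VarCorr(fit))
    singular <- vc$vcov[vc$grp == "line"] < 1e-8 * sum(vc$vcov)
    df <- if (singular) n - 2 else n - 2 - (g - 1)
    tv <- beta / se
    data.frame(metabolite = colnames(x)[j], beta = beta, se = se, t = tv,
               df = df, p_value = 2 * stats::pt(-abs(tv), df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- storey_qvalues(out$p_value)
  out
}

#' Spearman concordance of treatment-effect signs between classes
#'
#' Rank correlation (average ranks for ties) between the per-metabolite
#' treatment effects estimated in resistant and in sensitive lines, with
#' the t approximation for the p-value.
#'
#' @param effects_r,effects_s equal-length effect vectors (length >= 4).
#' @return list with `rho` and `p_value`.
#' @export
effect_sign_concordance <- function(effects_r, effects_s) {
  stopifnot(length(effects_r) == length(effects_s), length(effects_r) >= 4)
  if (stats::sd(effects_r) == 0 || stats::sd(effects_s) == 0)
    stop2("correlation undefined for a constant effect vector")
  ct <- suppressWarnings(
    stats::cor.test(effects_r, effects_s, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
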