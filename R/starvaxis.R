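## Starvation principal-component axis: harmonize a reference starvation
## time-course metabolome with the study metabolome, build the PC axis,
## fit its saturating time trajectory, project query samples, and test
## treatment x phenotype displacement along the axis.

#' k-nearest-neighbour mean imputation of missing metabolite values
#'
#' Neighbours are metabolites (columns): the `k` metabolites closest in
#' Euclidean distance to the target, computed over samples where both are
#' observed. A missing cell is filled with the mean of the neighbours'
#' values in that sample; neighbours missing in that sample are skipped,
#' and when fewer than `k` usable neighbours exist all available ones are
#' used.
#'
#' @param M numeric matrix, samples x metabolites, with NA cells.
#' @param k number of neighbours (>= 1).
#' @return the completed matrix.
#' @export
impute_knn <- function(M, k = 10L) {
  stopifnot(k >= 1)
  if (any(rowSums(!is.na(M)) == 0))
    stop2("sample(s) with all metabolites missing")
  miss <- which(is.na(M), arr.ind = TRUE)
  for (r in seq_len(nrow(miss))) {
    s <- miss[r, 1]; j <- miss[r, 2]
    cand <- setdiff(which(!is.na(M[s, ])), j)
    d <- vapply(cand, function(i) {
      both <- !is.na(M[, i]) & !is.na(M[, j])
      if (!any(both)) return(Inf)
      sqrt(sum((M[both, i] - M[both, j])^2))
    }, numeric(1))
    cand <- cand[is.finite(d)]
    d <- d[is.finite(d)]
    if (!length(cand)) stop2("no usable neighbours for metabolite column %d", j)
    nb <- cand[order(d)][seq_len(min(k, length(cand)))]
    M[s, j] <- mean(M[s, nb])
  }
  M
}

#' Harmonize a reference time-course table with a query metabolome
#'
#' Applies, in order: (1) drop reference metabolites with more than one
#' missing value; (2) impute single-missing metabolites by k-nearest-
#' neighbour mean; (3) per-sample mean-centre and scale the reference;
#' (4) for declared duplicate-ion pairs (one metabolite measured in both
#' positive and negative ion mode), scale each member per metabolite and
#' average the pair into one column; (5) rename via the name map and
#' intersect with the query columns.
#'
#' @param ref reference data.frame: `sample` column, optional `time_h`,
#'   metabolite columns (may contain NA).
#' @param query a normalized [metabolite_matrix()] (or samples x
#'   metabolites matrix).
#' @param name_map data.frame with columns `ref` and `query`: one row per
#'   (reference name, query name) match.
#' @param dup_pairs optional data.frame with columns `ref_a`, `ref_b`
#'   naming the declared duplicate-ion pairs; any other many-to-one
#'   mapping in `name_map` is an error.
#' @param k neighbours for imputation.
#' @return object of class `harmonized_pair`: `ref` and `query` matrices
#'   with identical metabolite columns (query naming), `times` (if the
#'   reference carried `time_h`), and the map actually used.
#' @export
harmonize <- function(ref, query, name_map, dup_pairs = NULL, k = 10L) {
  stopifnot(all(c("ref", "query") %in% names(name_map)))
  qx <- if (inherits(query, "metabolite_matrix")) query$intensity else as.matrix(query)
  met_cols <- setdiff(names(ref), c("sample", "time_h"))
  rx <- as.matrix(ref[, met_cols, drop = FALSE])
  rownames(rx) <- ref$sample %||% rownames(rx)

  ## (1) missingness filter, (2) imputation
  n_miss <- colSums(is.na(rx))
  rx <- rx[, n_miss <= 1, drop = FALSE]
  if (anyNA(rx)) rx <- impute_knn(rx, k = k)

  ## (3) per-sample centre/scale
  sds <- apply(rx, 1, stats::sd)
  if (any(sds == 0)) stop2("zero within-sample SD in reference")
  rx <- (rx - rowMeans(rx)) / sds

  ## (4) duplicate-ion averaging after per-metabolite scaling
  if (!is.null(dup_pairs) && nrow(dup_pairs)) {
    for (i in seq_len(nrow(dup_pairs))) {
      a <- dup_pairs$ref_a[i]; b <- dup_pairs$ref_b[i]
      have <- intersect(c(a, b), colnames(rx))
      if (length(have) == 0) next
      if (length(have) == 2) {
        za <- as.numeric(scale(rx[, a]))
        zb <- as.numeric(scale(rx[, b]))
        merged <- (za + zb) / 2
      } else merged <- as.numeric(scale(rx[, have]))
      rx <- rx[, setdiff(colnames(rx), c(a, b)), drop = FALSE]
      rx <- cbind(rx, merged)
      colnames(rx)[ncol(rx)] <- a  # pair keyed by its first member in the map
    }
    ## collapse map rows of a pair onto the surviving key
    name_map <- name_map[!(name_map$ref %in% dup_pairs$ref_b), , drop = FALSE]
  }

  ## (5) rename and intersect
  nm <- name_map[name_map$ref %in% colnames(rx), , drop = FALSE]
  dup_q <- nm$query[duplicated(nm$query)]
  if (length(dup_q))
    stop2("name collision: several reference metabolites map onto query %s (declare duplicate-ion pairs explicitly)",
          paste(unique(dup_q), collapse = ", "))
  common <- nm[nm$query %in% colnames(qx), , drop = FALSE]
  if (!nrow(common)) stop2("no overlapping metabolites after harmonization")
  r_out <- rx[, common$ref, drop = FALSE]
  colnames(r_out) <- common$query
  structure(list(ref = r_out,
                 query = qx[, common$query, drop = FALSE],
                 times = ref$time_h, map = common),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("harmonized_pair: %d matched metabolites; %d reference x %d query samples\n",
              ncol(x$ref), nrow(x$ref), nrow(x$query)))
  invisible(x)
}

#' Fit the saturating trajectory score = a t/(t + b) - c
#'
#' Least-squares fit with starts `a0 = range(scores)`, `c0 =
#' -min(scores)`, `b0 = median(times)` plus four jittered restarts; `b`
#' is bounded below zero. The fitted curve at `t = 0` equals `-c` by
#' construction.
#'
#' @param scores training scores.
#' @param times matching times (hours, >= 0; at least 3 distinct).
#' @return list `a`, `b`, `c`, `r2`, `fitted`, `degenerate`.
#' @export
fit_trajectory <- function(scores, times) {
  stopifnot(length(scores) == length(times), all(times >= 0))
  if (length(unique(times)) < 3) stop2("need >= 3 distinct times")
  ss_tot <- sum((scores - mean(scores))^2)
  if (ss_tot == 0) {
    return(list(a = 0, b = stats::median(times), c = -scores[1], r2 = 0,
                fitted = scores, degenerate = TRUE))
  }
  dat <- data.frame(s = scores, t = times)
  a0 <- diff(range(scores)); c0 <- -min(scores)
  b0 <- max(stats::median(times), 1e-3)
  best <- NULL
  ## fixed multiplicative jitter: restarts are deterministic
  jit <- rbind(c(1, 1, 1), c(0.5, 0.5, 1), c(2, 2, 1), c(1, 0.25, 0.5),
               c(1.5, 4, 1.5))
  for (i in seq_len(nrow(jit))) {
    st <- list(a = a0 * jit[i, 1], b = b0 * jit[i, 2],
               c = if (abs(c0) > 0) c0 * jit[i, 3] else jit[i, 3] - 1)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        s ~ a * t / (t + b) - c, data = dat, start = st,
        lower = c(a = -Inf, b = 1e-9, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop2("trajectory fit failed to converge from all starts (n = %d, score range %.3g)",
          length(scores), diff(range(scores)))
  cf <- stats::coef(best$fit)
  list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
       r2 = 1 - best$rss / ss_tot,
       fitted = as.numeric(stats::fitted(best$fit)), degenerate = FALSE)
}

#' Build the starvation axis from a harmonized reference time course
#'
#' PCA on the reference (metabolites centred by their training means);
#' the axis is the first principal-component loading vector, oriented so
#' projected training scores increase with starvation time (positive
#' score-time Spearman correlation), with the saturating trajectory
#' fitted to the training scores.
#'
#' @param ref harmonized reference matrix (samples x matched metabolites)
#'   or a `harmonized_pair`.
#' @param times per-sample starvation times (hours); taken from the
#'   `harmonized_pair` when omitted.
#' @return object of class `starvation_axis`: `metabolites`, `means`
#'   (training means), `loading` (unit norm, oriented), `orientation`,
#'   `scores` (training), `var_frac` of PC1, `trajectory` (a, b, c, r2).
#' @export
fit_reference_axis <- function(ref, times = NULL) {
  if (inherits(ref, "harmonized_pair")) {
    times <- times %||% ref$times
    ref <- ref$ref
  }
  stopifnot(!is.null(times), nrow(ref) >= 3, length(times) == nrow(ref))
  if (length(unique(times)) < 2) stop2("need >= 2 time points")
  mu <- colMeans(ref)
  xc <- sweep(ref, 2, mu)
  sv <- svd(xc)
  loading <- sv$v[, 1]
  scores <- as.numeric(xc %*% loading)
  var_frac <- sv$d[1]^2 / sum(sv$d^2)
  if (var_frac < 0.10)
    warning(sprintf("PC1 explains only %.1f%% of reference variance: axis weakly defined",
                    100 * var_frac))
  rho <- suppressWarnings(stats::cor(scores, times, method = "spearman"))
  if (!is.finite(rho) || abs(rho) < 0.3)
    warning("score-time correlation is weak; axis orientation is poorly determined")
  orientation <- if (is.finite(rho) && rho < 0) -1 else 1
  loading <- loading * orientation
  scores <- scores * orientation
  names(loading) <- colnames(ref)
  trajectory <- tryCatch(fit_trajectory(scores, times), error = function(e) {
    warning(sprintf("trajectory fit failed (%s); axis returned without one",
                    conditionMessage(e)))
    NULL
  })
  structure(list(metabolites = colnames(ref), means = mu, loading = loading,
                 orientation = orientation, scores = scores,
                 var_frac = var_frac, times = times,
                 trajectory = trajectory),
            class = "starvation_axis")
}

#' @export
print.starvation_axis <- function(x, ...) {
  cat(sprintf("starvation_axis: %d metabolites, PC1 var %.1f%%\n",
              length(x$metabolites), 100 * x$var_frac))
  tr <- x$trajectory
  if (!is.null(tr))
    cat(sprintf("  trajectory a = %.2f, b = %.2f h, c = %.2f (r2 = %.2f)\n",
                tr$a, tr$b, tr$c, tr$r2))
  invisible(x)
}

#' Project query samples onto a starvation axis
#'
#' `score = sum_i loading_i * (x_i - training mean_i)`; the loading is
#' already oriented so scores increase with starvation. Setting
#' `center = FALSE` applies the raw dot product without subtracting the
#' reference training means.
#'
#' @param query harmonized query matrix (samples x matched metabolites)
#'   or a `harmonized_pair`.
#' @param axis a `starvation_axis`.
#' @param center subtract the reference training means (default TRUE).
#' @return named numeric vector of per-sample scores.
#' @export
project <- function(query, axis, center = TRUE) {
  qx <- if (inherits(query, "harmonized_pair")) query$query else as.matrix(query)
  missing <- setdiff(axis$metabolites, colnames(qx))
  extra <- setdiff(colnames(qx), axis$metabolites)
  if (length(missing) || length(extra))
    stop2("query columns do not match the axis (missing: %s; extra: %s)",
          paste(missing, collapse = ",") %|e|% "none",
          paste(extra, collapse = ",") %|e|% "none")
  qx <- qx[, axis$metabolites, drop = FALSE]
  if (center) qx <- sweep(qx, 2, axis$means)
  stats::setNames(as.numeric(qx %*% axis$loading), rownames(qx))
}

#' Test treatment x phenotype displacement along the axis
#'
#' Fits `score ~ bT + bP + bTxP + (1|line)` by REML and reports Type-III
#' F tests per fixed term (same machinery as [interaction_anova()]).
#'
#' @param scores projected per-sample scores.
#' @param design data.frame aligned with `scores`: `line`, `class`
#'   (resistant | sensitive), `treatment` (control | rapamycin).
#' @return list with one `(F, df1, df2, p)` row per term and the fixed
#'   effects.
#' @export
displacement_test <- function(scores, design) {
  stopifnot(length(scores) == nrow(design),
            all(c("line", "class", "treatment") %in% names(design)))
  if (length(unique(design$class)) < 2 || length(unique(design$treatment)) < 2)
    stop2("both classes and both treatments must be represented")
  dat <- data.frame(line = factor(design$line),
                    treatment = factor(design$treatment,
                                       levels = c("control", "rapamycin")),
                    phenotype = factor(design$class,
                                       levels = c("resistant", "sensitive")))
  r <- .lmm_type3(scores, dat, "treatment * phenotype",
                  c("treatment", "phenotype", "treatment:phenotype"))
  if (is.null(r)) stop2("mixed model failed to fit")
  list(treatment = r$tests[["treatment"]],
       phenotype = r$tests[["phenotype"]],
       interaction = r$tests[["treatment:phenotype"]],
       beta = r$beta, sigma2_line = r$sigma2_line, singular = r$singular)
}
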