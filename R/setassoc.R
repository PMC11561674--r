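## Single-marker association against line genomic values, Storey q-values,
## feature-set construction (gene, gene +/- window, pathway) and the
## covariance association test (CVAT) with permutation empirical p-values.

#' Single-marker scan against line genomic values
#'
#' For each marker, the simple linear regression of the genomic BLUPs on
#' the (centred/scaled) dose is summarized as a t statistic with `n - 2`
#' degrees of freedom and a two-sided p-value. The whole scan is one
#' vectorized pass. Constant markers get NA and are flagged.
#'
#' @param W centred/scaled dose matrix (lines x markers).
#' @param ghat line genomic values from [fit_gblup()].
#' @param qvalues add Storey q-values?
#' @return data.frame with `id`, `level = "marker"`, `statistic` (t),
#'   `n_markers`, `p_value`, `q_value`.
#' @export
single_marker_scan <- function(W, ghat, qvalues = TRUE) {
  n <- nrow(W)
  stopifnot(length(ghat) == n, n > 2)
  gc <- ghat - mean(ghat)
  sw <- sqrt(colSums(scale(W, scale = FALSE)^2))
  r <- as.numeric(crossprod(scale(W, scale = FALSE), gc)) /
    (sw * sqrt(sum(gc^2)))
  r[!is.finite(r)] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  out <- data.frame(id = colnames(W) %||% paste0("m", seq_len(ncol(W))),
                    level = "marker", statistic = tt, n_markers = 1L,
                    p_value = p, stringsAsFactors = FALSE)
  out$q_value <- if (qvalues) storey_qvalues(p) else NA_real_
  out
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 with the natural-cubic-spline smoother evaluated at lambda = 0.95,
#' clipped to (0, 1], then computes
#' `q_i = pi0 * min_{p_j >= p_i} (m * p_j / rank_j)`. With fewer than 10
#' p-values (or `pi0 = 1` forced), this reduces exactly to
#' Benjamini-Hochberg.
#'
#' @param p p-values in `[0, 1]`.
#' @param pi0 optionally force the null proportion (e.g. 1 for BH).
#' @return q-values in the input order (NA where p is NA).
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop2("p-values must be in [0, 1]")
  pv <- p[ok]
  m <- length(pv)
  if (is.null(pi0)) {
    if (m < 10) pi0 <- 1
    else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0_lam <- vapply(lam, function(l) mean(pv > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(fit, x = 0.95)$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  o <- order(pv, decreasing = TRUE)
  q <- pmin(1, cummin(pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]))
  out <- rep(NA_real_, length(p))
  out[ok] <- q[order(o)]
  attr(out, "pi0") <- pi0
  out
}

#' Build marker feature sets: genes, widened genes, pathways
#'
#' Gene-level features contain all markers whose position falls inside the
#' primary-transcript interval (closed, 1-based); `window_bp` widens the
#' interval on each side (e.g. 1000 for the gene +/- 1 kb level). Pathway
#' features are the duplicate-free union of their member genes' markers,
#' filtered to pathways with at least `pathway_min_genes` genes and
#' `pathway_min_markers` markers. Markers inside several genes contribute
#' to every containing feature.
#'
#' @param annotations data.frame of gene intervals: `gene`, `chrom`,
#'   `start`, `end` (1-based closed).
#' @param map marker metadata (`chrom`, `pos`, `id`), e.g. `G$map`.
#' @param window_bp widening in bp on each side of the transcript.
#' @param pathways named list mapping pathway id to member gene ids (e.g.
#'   from [read_gmt()]); NULL builds gene-level features.
#' @param min_markers minimum markers for a gene-level feature.
#' @param pathway_min_genes,pathway_min_markers pathway-level filters.
#' @return object of class `feature_sets`: `features` (named list of
#'   marker column indices), `genes` (member genes, pathway level),
#'   `level`, `n_markers`.
#' @export
build_feature_sets <- function(annotations, map, window_bp = 0,
                               pathways = NULL, min_markers = 1L,
                               pathway_min_genes = 2L,
                               pathway_min_markers = 200L) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(annotations)),
            all(c("chrom", "pos", "id") %in% names(map)))
  gene_idx <- stats::setNames(vector("list", nrow(annotations)), annotations$gene)
  for (ch in unique(annotations$chrom)) {
    gi <- which(annotations$chrom == ch)
    mi <- which(map$chrom == ch)
    if (!length(mi)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = map$pos[mi], width = 1L),
      IRanges::IRanges(start = pmax(annotations$start[gi] - window_bp, 1L),
                       end = annotations$end[gi] + window_bp))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (k in seq_along(gi))
      gene_idx[[gi[k]]] <- sort(mi[qh[sh == k]])
  }

  if (is.null(pathways)) {
    nm <- vapply(gene_idx, length, integer(1))
    keep <- nm >= min_markers
    return(structure(list(
      features = gene_idx[keep], genes = NULL,
      level = if (window_bp > 0) "gene_1kb" else "gene",
      n_markers = nm[keep]), class = "feature_sets"))
  }

  feats <- vector("list", length(pathways))
  genes <- vector("list", length(pathways))
  names(feats) <- names(genes) <- names(pathways)
  for (pw in names(pathways)) {
    g <- pathways[[pw]]
    unknown <- setdiff(g, names(gene_idx))
    if (length(unknown)) {
      warning(sprintf("pathway %s: skipping %d gene(s) without annotation",
                      pw, length(unknown)))
      g <- setdiff(g, unknown)
    }
    g <- g[vapply(gene_idx[g], length, integer(1)) > 0]
    feats[[pw]] <- sort(unique(unlist(gene_idx[g], use.names = FALSE)))
    genes[[pw]] <- g
  }
  n_genes <- vapply(genes, length, integer(1))
  nm <- vapply(feats, length, integer(1))
  keep <- n_genes >= pathway_min_genes & nm >= pathway_min_markers
  structure(list(features = feats[keep], genes = genes[keep],
                 level = "pathway", n_markers = nm[keep]),
            class = "feature_sets")
}

#' @export
print.feature_sets <- function(x, ...) {
  cat(sprintf("feature_sets (%s): %d features, %s markers each\n", x$level,
              length(x$features),
              if (length(x$n_markers)) paste0(min(x$n_markers), "-", max(x$n_markers))
              else "0"))
  invisible(x)
}

#' Per-marker covariance contributions to the genomic variance
#'
#' Marker i's genomic contribution is the line vector `g_i = W[, i] *
#' s_hat[i]`; its covariance contribution is the sample covariance (over
#' lines, denominator n - 1) between the total genomic values and `g_i`.
#' Summed over all markers of a full-rank decomposition these equal
#' `var(ghat)`.
#'
#' @param W centred/scaled dose matrix.
#' @param s_hat backsolved marker effects (see
#'   [backsolve_marker_effects()]).
#' @param ghat line genomic values.
#' @return numeric vector of per-marker covariances.
#' @export
cvat_contributions <- function(W, s_hat, ghat) {
  stopifnot(ncol(W) == length(s_hat), nrow(W) == length(ghat))
  gc <- ghat - mean(ghat)
  cw <- as.numeric(crossprod(scale(W, scale = FALSE), gc)) / (length(ghat) - 1)
  s_hat * cw
}

#' Covariance association test statistic for one feature
#'
#' `T = sum over the feature's markers of cov(ghat, g_i)` — the part of
#' the genomic variance attributable to the feature's markers.
#'
#' @param W,s_hat,ghat as in [cvat_contributions()].
#' @param feature integer marker (column) indices of the feature.
#' @return the statistic T (scalar).
#' @export
cvat_statistic <- function(W, s_hat, ghat, feature) {
  if (!length(feature)) stop2("empty feature")
  sum(cvat_contributions(W, s_hat, ghat)[feature])
}

#' Permutation empirical p-value for a CVAT statistic
#'
#' Null statistics are sums of the per-marker covariance contributions
#' over random marker subsets of the feature's size, sampled without
#' replacement; the test is one-sided (large positive covariance =
#' association). The p-value is `(# null T >= T_obs) / n_perm`, floored
#' at `1/n_perm` when no null draw reaches the observed value.
#'
#' @param T_obs observed statistic.
#' @param feature_size number of markers in the feature.
#' @param all_contribs per-marker contributions over all markers
#'   ([cvat_contributions()]).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: `p_value`, `count`, `at_floor`, `degenerate` (TRUE when
#'   the feature spans all markers, where p = 1 trivially).
#' @export
cvat_empirical_p <- function(T_obs, feature_size, all_contribs,
                             n_perm = 1e5L, seed = 1L) {
  m <- length(all_contribs)
  stopifnot(n_perm >= 1, feature_size >= 1, feature_size <= m)
  if (feature_size == m)
    return(list(p_value = 1, count = as.integer(n_perm), at_floor = FALSE,
                degenerate = TRUE))
  count <- with_stage_seed(seed, "cvat-perm", {
    null_T <- vapply(seq_len(n_perm), function(i)
      sum(all_contribs[sample.int(m, feature_size)]), numeric(1))
    sum(null_T >= T_obs - 1e-12 * max(1, abs(T_obs)))
  })
  list(p_value = max(count, 1L) / n_perm, count = count,
       at_floor = count == 0L, degenerate = FALSE)
}

#' End-to-end marker-set association analysis
#'
#' QC (GRM profile) -> optional LD pruning -> GRM -> gBLUP/REML ->
#' backsolved marker effects -> per-level CVAT with permutation empirical
#' p-values -> Storey q-values within each level, plus a single-marker
#' scan on the scan-profile marker set.
#'
#' @param G a [genotype_matrix()].
#' @param phenotype numeric phenotype named by line (normalized delay).
#' @param X covariate design matrix or NULL.
#' @param annotations gene intervals (see [build_feature_sets()]), or NULL
#'   to skip feature levels.
#' @param pathways named list pathway -> gene ids, or NULL.
#' @param config pipeline configuration (see [default_config()]); the QC
#'   profiles, LD pruning, permutation count and seed are read from it.
#' @return list with `fit` (gblup_fit), `scan`, and one association table
#'   per feature level (`gene`, `gene_1kb`, `pathway` as available), plus
#'   `skipped` counts of features below the size filters.
#' @export
run_set_analysis <- function(G, phenotype, X = NULL, annotations = NULL,
                             pathways = NULL, config = default_config()) {
  y <- if (!is.null(names(phenotype))) phenotype[G$line_ids] else phenotype
  if (anyNA(y)) stop2("phenotype missing for some lines")

  Gq <- qc_markers(G, config$qc$grm$maf_min, config$qc$grm$callrate_min, "ge")
  if (isTRUE(config$qc$grm$ld_prune)) {
    ids <- ld_prune(Gq, config$qc$grm$r2_max, config$qc$grm$window_bp,
                    config$qc$grm$step_bp)
    Gq <- subset_markers(Gq, match(ids, Gq$map$id))
  }
  W <- scale_doses(Gq)
  K <- compute_grm(Gq)
  fit <- fit_gblup(y, X, K)
  s_hat <- backsolve_marker_effects(W, K, fit$ghat)
  contribs <- cvat_contributions(W, s_hat, fit$ghat)

  Gs <- qc_markers(G, config$qc$scan$maf_min, config$qc$scan$callrate_min, "gt")
  scan <- single_marker_scan(scale_doses(Gs), fit$ghat)

  out <- list(fit = fit, scan = scan, K = K, grm_markers = Gq$map$id,
              skipped = integer(0))
  if (is.null(annotations)) return(out)

  levels <- list(gene = 0, gene_1kb = config$feature_window_bp)
  for (lv in names(levels)) {
    fs <- build_feature_sets(annotations, Gq$map, window_bp = levels[[lv]],
                             min_markers = config$gene_min_markers)
    out[[lv]] <- .cvat_table(fs, W, s_hat, fit$ghat, contribs, config)
  }
  if (!is.null(pathways)) {
    fs <- build_feature_sets(annotations, Gq$map,
                             window_bp = config$feature_window_bp,
                             pathways = pathways,
                             pathway_min_genes = config$pathway_min_genes,
                             pathway_min_markers = config$pathway_min_markers)
    out$pathway <- .cvat_table(fs, W, s_hat, fit$ghat, contribs, config)
  }
  out
}

.cvat_table <- function(fs, W, s_hat, ghat, contribs, config) {
  ids <- names(fs$features)
  if (!length(ids))
    return(data.frame(id = character(0), level = character(0),
                      statistic = numeric(0), n_markers = integer(0),
                      p_value = numeric(0), q_value = numeric(0)))
  stat <- vapply(fs$features, function(f) sum(contribs[f]), numeric(1))
  p <- vapply(seq_along(ids), function(k)
    cvat_empirical_p(stat[k], fs$n_markers[k], contribs,
                     n_perm = config$n_perm,
                     seed = stage_seed(config$seed, ids[k]))$p_value,
    numeric(1))
  data.frame(id = ids, level = fs$level, statistic = as.numeric(stat),
             n_markers = as.integer(fs$n_markers), p_value = p,
             q_value = storey_qvalues(p), stringsAsFactors = FALSE)
}
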