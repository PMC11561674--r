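## Synthetic-data generators.
##
## These emulate the statistical structure of a DGRP-style study — a panel
## of fully inbred (homozygous) lines genotyped at biallelic markers with
## local LD, replicated pupation records in two treatments, a samples x
## metabolites intensity table with line/class/treatment/batch structure,
## and a short starvation time course with a saturating latent trajectory —
## and return ground-truth records so downstream estimators can be tested
## for recovery.

#' Construct a genotype matrix object
#'
#' Container for a panel of inbred lines: allele-dose matrix (lines x
#' markers, doses in \{0, 2, NA\} because lines are homozygous), marker map,
#' and per-marker minor-allele frequency and call rate.
#'
#' @param doses numeric matrix, lines x markers, values 0, 2 or NA.
#' @param map data.frame with columns `chrom`, `pos`, `id`, `a1`, `a2`.
#' @param line_ids character vector of line identifiers.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(doses, map, line_ids) {
  stopifnot(is.matrix(doses), nrow(map) == ncol(doses),
            length(line_ids) == nrow(doses))
  bad <- doses[!is.na(doses)]
  if (length(bad) && !all(bad %in% c(0, 2)))
    stop2("doses must be 0, 2 or NA (homozygous inbred lines)")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p)) stop2("positions must be non-decreasing within chromosome %s", ch)
  }
  rownames(doses) <- line_ids
  colnames(doses) <- map$id
  freq <- colMeans(doses, na.rm = TRUE) / 2
  structure(list(
    doses = doses, map = map, line_ids = line_ids,
    maf = pmin(freq, 1 - freq),
    callrate = colMeans(!is.na(doses))
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$doses), ncol(x$doses), length(unique(x$map$chrom))))
  cat(sprintf("  MAF range %.3f-%.3f; mean call rate %.3f\n",
              min(x$maf, na.rm = TRUE), max(x$maf, na.rm = TRUE),
              mean(x$callrate)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$doses)

#' Simulate inbred-line genotypes with local LD
#'
#' Lines are fully homozygous, so allele doses are 0 or 2. Linkage
#' disequilibrium is generated by first-order Markov copying along each
#' chromosome: at each marker, each line copies its allele at the previous
#' marker with probability `ld_decay`, otherwise draws a fresh allele at
#' that marker's target frequency. This gives a simple, controllable
#' adjacent-r^2 structure; it is not a coalescent simulation.
#'
#' @param n_lines number of lines (>= 2).
#' @param n_markers total number of biallelic markers.
#' @param maf_range length-2 interval in (0, 0.5] for target minor-allele
#'   frequencies.
#' @param ld_decay per-adjacent-marker copying probability in `[0, 1]`.
#' @param missing_rate probability a dose is missing, in `[0, 1)`.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param n_chrom number of chromosome arms to spread markers over.
#' @param spacing_max maximum inter-marker spacing in bp (spacings are
#'   uniform on `1:spacing_max`).
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_lines, n_markers,
                               maf_range = c(0.05, 0.5),
                               ld_decay = 0.8, missing_rate = 0.002,
                               seed = 1L, n_chrom = 4L,
                               spacing_max = 3000L) {
  stopifnot(n_lines >= 2, n_markers >= 1)
  assert_prob(ld_decay, "ld_decay")
  assert_prob(missing_rate, "missing_rate", hi_open = TRUE)
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop2("maf_range must be an interval within (0, 0.5]")
  ## achievable sample MAFs are k/n_lines; the range must contain one
  k_lo <- ceiling(maf_range[1] * n_lines - 1e-9)
  k_hi <- floor(maf_range[2] * n_lines + 1e-9)
  if (k_lo > k_hi || k_hi < 1)
    stop2("maf_range [%g, %g] is infeasible for %d lines: no achievable frequency k/%d falls inside it",
          maf_range[1], maf_range[2], n_lines, n_lines)

  with_stage_seed(seed, "genotypes", {
    chrom_names <- paste0("chr", seq_len(n_chrom))
    chrom_of <- rep(chrom_names, length.out = n_chrom)[
      rep(seq_len(n_chrom), diff(round(seq(0, n_markers, length.out = n_chrom + 1L))))]
    x <- matrix(0L, n_lines, n_markers)
    p_target <- stats::runif(n_markers, maf_range[1], maf_range[2])
    pos <- integer(n_markers)
    for (ch in chrom_names) {
      idx <- which(chrom_of == ch)
      if (!length(idx)) next
      pos[idx] <- cumsum(sample.int(spacing_max, length(idx), replace = TRUE))
      x[, idx[1]] <- stats::rbinom(n_lines, 1L, p_target[idx[1]])
      for (j in idx[-1]) {
        fresh <- stats::rbinom(n_lines, 1L, p_target[j])
        if (ld_decay <= 0) x[, j] <- fresh
        else if (ld_decay >= 1) x[, j] <- x[, j - 1L]
        else {
          copy <- stats::rbinom(n_lines, 1L, ld_decay)
          x[, j] <- ifelse(copy == 1L, x[, j - 1L], fresh)
        }
      }
    }
    doses <- 2 * x
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n_lines * n_markers) < missing_rate,
                     n_lines, n_markers)
      doses[miss] <- NA_real_
    }
    alleles <- matrix(0L, n_markers, 2)
    for (j in seq_len(n_markers))
      alleles[j, ] <- sample.int(4L, 2L)
    map <- data.frame(
      chrom = chrom_of, pos = pos,
      id = sprintf("m%06d", seq_len(n_markers)),
      a1 = c("A", "C", "G", "T")[alleles[, 1]],
      a2 = c("A", "C", "G", "T")[alleles[, 2]],
      stringsAsFactors = FALSE)
    genotype_matrix(doses, map, sprintf("line%03d", seq_len(n_lines)))
  })
}

#' Simulate a polygenic line phenotype with known heritability
#'
#' Builds `y = X beta + sum_j w_j b_j + batch offset + e` on centred/scaled
#' doses. Marker effects and the residual are rescaled so that the realized
#' genetic-variance fraction, `var(g) / (var(g) + var(e))` computed from
#' the recorded truth, equals `h2` exactly (both components are scaled to
#' their target sample variances).
#'
#' @param G a [genotype_matrix()].
#' @param h2 target SNP heritability in `[0, 1]`.
#' @param causal_features integer marker indices, a `feature_sets` object
#'   (union of member markers), or NULL to spread effects over `n_causal`
#'   random markers.
#' @param batch_design named vector mapping line id to batch id, or NULL
#'   for a single batch.
#' @param covariates data.frame with a `line` column plus binary covariate
#'   columns (e.g. Wolbachia, inversion genotypes), or NULL.
#' @param n_causal number of causal markers when `causal_features` is NULL.
#' @param batch_sd SD of batch offsets (phenotype units).
#' @param covariate_sd SD of covariate fixed effects.
#' @param mu baseline phenotype (delay, days).
#' @param seed integer seed.
#' @return list with `phenotype` (data.frame line, batch, delay) and
#'   `truth` (a `sim_truth` list: marker effects, realized h2, causal ids,
#'   batch offsets, covariate effects, residual SD).
#' @export
simulate_phenotype <- function(G, h2, causal_features = NULL,
                               batch_design = NULL, covariates = NULL,
                               n_causal = 100L, batch_sd = 0.5,
                               covariate_sd = 0.5, mu = 2, seed = 1L) {
  assert_prob(h2, "h2")
  n <- nrow(G$doses)
  m <- ncol(G$doses)
  with_stage_seed(seed, "phenotype", {
    causal <- if (is.null(causal_features)) {
      sort(sample.int(m, min(n_causal, m)))
    } else if (inherits(causal_features, "feature_sets")) {
      sort(unique(unlist(causal_features$features)))
    } else sort(unique(as.integer(causal_features)))
    if (!length(causal)) stop2("no causal markers defined")

    W <- scale_doses(G, zero_variance = "zero")
    effects <- numeric(m)
    g <- numeric(n)
    if (h2 > 0) {
      b <- stats::rnorm(length(causal))
      g_raw <- as.numeric(W[, causal, drop = FALSE] %*% b)
      if (stats::sd(g_raw) == 0)
        stop2("causal markers carry no genetic variance in this panel")
      sc <- sqrt(h2) / stats::sd(g_raw)
      effects[causal] <- b * sc
      g <- g_raw * sc
    }
    e <- numeric(n)
    if (h2 < 1) {
      e <- stats::rnorm(n)
      e <- (e - mean(e)) / stats::sd(e) * sqrt(1 - h2)
    }

    batch <- if (is.null(batch_design)) {
      stats::setNames(rep("b1", n), G$line_ids)
    } else batch_design[G$line_ids]
    batches <- sort(unique(batch))
    batch_offsets <- stats::setNames(
      if (length(batches) > 1) stats::rnorm(length(batches), 0, batch_sd)
      else 0, batches)

    cov_effect <- numeric(n)
    cov_beta <- NULL
    if (!is.null(covariates)) {
      Xc <- as.matrix(covariates[match(G$line_ids, covariates$line),
                                 setdiff(names(covariates), "line"), drop = FALSE])
      cov_beta <- stats::setNames(stats::rnorm(ncol(Xc), 0, covariate_sd),
                                  colnames(Xc))
      cov_effect <- as.numeric(Xc %*% cov_beta)
    }

    y <- mu + g + e + batch_offsets[batch] + cov_effect
    vg <- stats::var(g); ve <- stats::var(e)
    truth <- structure(list(
      effects = effects, h2_true = h2,
      h2_realized = if (vg + ve > 0) vg / (vg + ve) else 0,
      causal = causal, genetic_values = g, residuals = e,
      batch_offsets = batch_offsets, covariate_beta = cov_beta,
      residual_sd = sqrt(max(ve, 0))), class = "sim_truth")
    list(phenotype = data.frame(line = G$line_ids, batch = unname(batch),
                                delay = as.numeric(y),
                                stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate per-vial pupation records
#'
#' Development time of each larva is Gaussian around the requested
#' line-by-condition mean and recorded as a (rounded) whole observation
#' day; survival to pupation is binomial thinning of the larvae seeded per
#' vial.
#'
#' @param line_means data.frame with columns `line`, `control`,
#'   `rapamycin` (mean pupation day per condition).
#' @param n_vials replicate vials per line x condition.
#' @param larvae_per_vial larvae seeded per vial.
#' @param sd_days SD of individual development time (days, >= 0).
#' @param survival per-larva probability of surviving to pupation.
#' @param batch_design named vector line -> batch id, or NULL (one batch).
#' @param seed integer seed.
#' @return data.frame (class `pupation_records`) with columns `vial`,
#'   `line`, `treatment`, `batch`, `day`, `count`.
#' @export
simulate_pupation_records <- function(line_means, n_vials = 4L,
                                      larvae_per_vial = 40L, sd_days = 1,
                                      survival = 0.85, batch_design = NULL,
                                      seed = 1L) {
  stopifnot(all(c("line", "control", "rapamycin") %in% names(line_means)),
            larvae_per_vial >= 1, n_vials >= 1, sd_days >= 0)
  assert_prob(survival, "survival")
  with_stage_seed(seed, "pupation", {
    out <- vector("list", nrow(line_means) * 2L * n_vials)
    k <- 0L
    for (i in seq_len(nrow(line_means))) {
      ln <- line_means$line[i]
      bt <- if (is.null(batch_design)) "b1" else unname(batch_design[ln])
      for (tr in c("control", "rapamycin")) {
        mu <- line_means[[tr]][i]
        for (v in seq_len(n_vials)) {
          n_pup <- stats::rbinom(1L, larvae_per_vial, survival)
          if (n_pup == 0L) next
          days <- if (sd_days > 0) round(stats::rnorm(n_pup, mu, sd_days))
                  else rep(round(mu), n_pup)
          days <- pmax(days, 1)
          tab <- table(days)
          k <- k + 1L
          out[[k]] <- data.frame(
            vial = sprintf("%s_%s_%s_v%d", bt, ln, substr(tr, 1, 4), v),
            line = ln, treatment = tr, batch = bt,
            day = as.integer(names(tab)), count = as.integer(tab),
            stringsAsFactors = FALSE)
        }
      }
    }
    rec <- do.call(rbind, out[seq_len(k)])
    rownames(rec) <- NULL
    class(rec) <- c("pupation_records", "data.frame")
    rec
  })
}

#' Construct a metabolite matrix object
#'
#' @param intensity numeric matrix, samples x metabolites.
#' @param meta data.frame with columns `sample`, `line`, `class`
#'   (resistant | sensitive), `treatment` (control | rapamycin), `batch`,
#'   aligned with the rows of `intensity`.
#' @param normalized logical: has per-sample log/centre/scale been applied?
#' @return object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(intensity, meta, normalized = FALSE) {
  stopifnot(is.matrix(intensity), nrow(meta) == nrow(intensity),
            all(c("sample", "line", "class", "treatment", "batch") %in% names(meta)))
  rownames(intensity) <- meta$sample
  structure(list(intensity = intensity, meta = meta, normalized = normalized),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("metabolite_matrix: %d samples x %d metabolites (%s)\n",
              nrow(x$intensity), ncol(x$intensity),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Simulate a larval metabolome with class, treatment and batch structure
#'
#' Log-scale signal per sample and metabolite is
#' `line effect + bT*T + bP*P + bTxP*T*P + batch shift + noise`, then
#' exponentiated onto a positive raw intensity scale. Effects are supplied
#' in units of a metabolite's total between-sample SD,
#' `sqrt(line_sd^2 + noise_sd^2)`. Batch location shifts vary per
#' metabolite around the requested batch location (SD `batch_loc_sd`), as
#' extraction-batch artefacts do; a perfectly uniform shift would already
#' be removed by per-sample centring.
#'
#' @param n_lines_per_class named integer vector
#'   `c(resistant = ..., sensitive = ...)`.
#' @param n_metabolites number of metabolites.
#' @param effects NULL (all zero) or a matrix `n_metabolites x 3` with
#'   columns `treatment`, `phenotype`, `interaction`, in total-SD units.
#' @param batch_shifts data.frame with columns `batch`, `location`,
#'   `scale` (scale > 0); rows define the batches, samples are assigned to
#'   batches by replicate.
#' @param reps replicates per line x treatment (replicate r falls in batch
#'   `batch_shifts$batch[(r - 1) %% n_batches + 1]`).
#' @param line_sd SD of per-line, per-metabolite random effects.
#' @param noise_sd residual (vial replicate) SD; small relative to
#'   `line_sd` in pooled-larvae LC-MS.
#' @param batch_loc_sd per-metabolite SD of the batch location shift.
#' @param base_mean mean log baseline abundance of a metabolite.
#' @param seed integer seed.
#' @return list with `matrix` (a raw-scale [metabolite_matrix()]) and
#'   `truth` (absolute effects, batch shifts per metabolite, line effects).
#' @export
simulate_metabolome <- function(n_lines_per_class = c(resistant = 6L, sensitive = 7L),
                                n_metabolites = 154L, effects = NULL,
                                batch_shifts = data.frame(batch = c("b1", "b2"),
                                                          location = c(0, 0),
                                                          scale = c(1, 1)),
                                reps = 2L, line_sd = 1, noise_sd = 0.35,
                                batch_loc_sd = 0.5, base_mean = 8, seed = 1L) {
  stopifnot(all(c("resistant", "sensitive") %in% names(n_lines_per_class)),
            all(batch_shifts$scale > 0), reps >= 1)
  if (is.null(effects)) effects <- matrix(0, n_metabolites, 3)
  stopifnot(nrow(effects) == n_metabolites, ncol(effects) == 3)
  colnames(effects) <- c("treatment", "phenotype", "interaction")
  tot_sd <- sqrt(line_sd^2 + noise_sd^2)

  with_stage_seed(seed, "metabolome", {
    lines <- c(sprintf("R%02d", seq_len(n_lines_per_class[["resistant"]])),
               sprintf("S%02d", seq_len(n_lines_per_class[["sensitive"]])))
    cls <- rep(c("resistant", "sensitive"), n_lines_per_class[c("resistant", "sensitive")])
    meta <- expand.grid(rep = seq_len(reps),
                        treatment = c("control", "rapamycin"),
                        line = lines, stringsAsFactors = FALSE)
    meta$class <- cls[match(meta$line, lines)]
    nb <- nrow(batch_shifts)
    meta$batch <- batch_shifts$batch[(meta$rep - 1L) %% nb + 1L]
    meta$sample <- sprintf("s%03d", seq_len(nrow(meta)))
    met_ids <- sprintf("met%03d", seq_len(n_metabolites))

    ns <- nrow(meta)
    base <- stats::rnorm(n_metabolites, base_mean, 1)
    line_eff <- matrix(stats::rnorm(length(lines) * n_metabolites, 0, line_sd),
                       length(lines), n_metabolites, dimnames = list(lines, met_ids))
    batch_delta <- matrix(stats::rnorm(nb * n_metabolites), nb, n_metabolites) *
      batch_loc_sd + batch_shifts$location
    rownames(batch_delta) <- batch_shifts$batch

    t01 <- as.numeric(meta$treatment == "rapamycin")
    p01 <- as.numeric(meta$class == "sensitive")
    fx <- outer(t01, effects[, "treatment"] * tot_sd) +
      outer(p01, effects[, "phenotype"] * tot_sd) +
      outer(t01 * p01, effects[, "interaction"] * tot_sd)
    z <- line_eff[meta$line, , drop = FALSE] + fx +
      matrix(stats::rnorm(ns * n_metabolites, 0, noise_sd), ns, n_metabolites)
    sc <- batch_shifts$scale[match(meta$batch, batch_shifts$batch)]
    logx <- sweep(z, 1, sc, "*") + batch_delta[meta$batch, , drop = FALSE] +
      matrix(base, ns, n_metabolites, byrow = TRUE)
    colnames(logx) <- met_ids
    mm <- metabolite_matrix(exp(logx),
                            meta[, c("sample", "line", "class", "treatment", "batch")])
    list(matrix = mm,
         truth = list(effects_sd_units = effects,
                      effects_abs = effects * tot_sd,
                      total_sd = tot_sd, line_effects = line_eff,
                      batch_delta = batch_delta, base = base))
  })
}

#' Saturating starvation-score trajectory
#'
#' The latent starvation score at time `t` is `a * t / (t + b) - c`: it
#' starts at `-c` at `t = 0` and saturates at `a - c` as `t` grows, with
#' half-saturation time `b`.
#'
#' @param t time (hours).
#' @param a amplitude (score units).
#' @param b half-saturation time (hours, > 0).
#' @param c score offset at time zero (score units).
#' @return numeric score(s).
#' @export
starvation_score <- function(t, a, b, c) a * t / (t + b) - c

#' Simulate a starvation time-course metabolite reference table
#'
#' Generates per-sample latent scores along the saturating trajectory and
#' metabolite values `base + loading * score + noise`, with a configurable
#' pattern of missing cells and duplicate-ion metabolite pairs to exercise
#' harmonization.
#'
#' @param a,b,c trajectory parameters (see [starvation_score()]); `b > 0`.
#' @param times time points in hours.
#' @param reps replicates per time point.
#' @param n_metabolites number of metabolites before duplication.
#' @param loadings per-metabolite weights; NULL draws a random unit-norm
#'   vector.
#' @param noise_sd per-cell measurement noise SD.
#' @param score_noise_sd per-sample noise on the latent score.
#' @param n_single_missing metabolites given exactly one missing cell.
#' @param n_double_missing metabolites given two missing cells (these
#'   should be dropped by the harmonization filter).
#' @param dup_pairs number of metabolites reported twice (positive and
#'   negative ion mode columns, suffixes `_pos` / `_neg`).
#' @param seed integer seed.
#' @return data.frame (`sample`, `time_h`, metabolite columns) with
#'   attribute `truth` holding latent scores, loadings and the duplicate
#'   pair table.
#' @export
simulate_starvation_timecourse <- function(a = 20.53, b = 2.77, c = 10.01,
                                           times = c(0, 2, 4, 6, 8), reps = 5L,
                                           n_metabolites = 90L, loadings = NULL,
                                           noise_sd = 0.2, score_noise_sd = 0,
                                           n_single_missing = 0L,
                                           n_double_missing = 0L,
                                           dup_pairs = 0L, seed = 1L) {
  stopifnot(b > 0, reps >= 1)
  if (is.null(loadings)) {
    loadings <- with_stage_seed(seed, "starv-loadings", stats::rnorm(n_metabolites))
    loadings <- loadings / sqrt(sum(loadings^2))
  }
  stopifnot(length(loadings) == n_metabolites)
  with_stage_seed(seed, "starvation", {
    tt <- rep(times, each = reps)
    ns <- length(tt)
    s <- starvation_score(tt, a, b, c) +
      if (score_noise_sd > 0) stats::rnorm(ns, 0, score_noise_sd) else 0
    met_ids <- sprintf("ref%03d", seq_len(n_metabolites))
    base <- stats::rnorm(n_metabolites, 5, 1)
    vals <- outer(s, loadings) +
      matrix(base, ns, n_metabolites, byrow = TRUE) +
      if (noise_sd > 0) matrix(stats::rnorm(ns * n_metabolites, 0, noise_sd),
                               ns, n_metabolites) else 0
    colnames(vals) <- met_ids

    n_miss <- n_single_missing + n_double_missing
    if (n_miss > n_metabolites - dup_pairs)
      stop2("too many missing-value metabolites requested")
    keep_complete <- seq_len(dup_pairs)  # duplicated columns stay complete
    miss_pool <- setdiff(seq_len(n_metabolites), keep_complete)
    miss_cols <- sample(miss_pool, n_miss)
    single_cols <- miss_cols[seq_len(n_single_missing)]
    double_cols <- setdiff(miss_cols, single_cols)
    for (j in single_cols) vals[sample.int(ns, 1L), j] <- NA_real_
    for (j in double_cols) vals[sample.int(ns, 2L), j] <- NA_real_

    dup_tab <- NULL
    if (dup_pairs > 0) {
      dup_tab <- data.frame(base = met_ids[seq_len(dup_pairs)],
                            ref_a = paste0(met_ids[seq_len(dup_pairs)], "_pos"),
                            ref_b = paste0(met_ids[seq_len(dup_pairs)], "_neg"),
                            stringsAsFactors = FALSE)
      extra <- vals[, seq_len(dup_pairs), drop = FALSE] +
        matrix(stats::rnorm(ns * dup_pairs, 0, noise_sd), ns, dup_pairs)
      colnames(extra) <- dup_tab$ref_b
      colnames(vals)[seq_len(dup_pairs)] <- dup_tab$ref_a
      vals <- cbind(vals, extra)
    }

    out <- data.frame(sample = sprintf("t%02d_r%02d", rep(seq_along(times), each = reps),
                                       rep(seq_len(reps), length(times))),
                      time_h = tt, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(vals))
    attr(out, "truth") <- list(scores = s, loadings = loadings,
                               dup_pairs = dup_tab,
                               params = c(a = a, b = b, c = c))
    out
  })
}

#' Simulate gene annotations over a marker map
#'
#' Draws non-degenerate transcript intervals (1-based closed) uniformly
#' along each chromosome of the map, so that genes capture contiguous
#' runs of markers.
#'
#' @param map marker metadata (`chrom`, `pos`), e.g. `G$map`.
#' @param n_genes number of genes.
#' @param span_bp transcript length in bp (recycled).
#' @param seed integer seed.
#' @return annotation data.frame: `gene`, `chrom`, `start`, `end`.
#' @export
simulate_annotations <- function(map, n_genes, span_bp = 20000L, seed = 1L) {
  with_stage_seed(seed, "annotations", {
    chroms <- unique(map$chrom)
    ch <- sample(chroms, n_genes, replace = TRUE)
    span <- rep_len(span_bp, n_genes)
    start <- integer(n_genes)
    for (cc in chroms) {
      i <- which(ch == cc)
      hi <- max(map$pos[map$chrom == cc])
      start[i] <- sample.int(max(hi - span[i], 1L), length(i), replace = TRUE)
    }
    ann <- data.frame(gene = sprintf("g%04d", seq_len(n_genes)), chrom = ch,
                      start = start, end = start + span - 1L,
                      stringsAsFactors = FALSE)
    ann[order(ann$chrom, ann$start), , drop = FALSE]
  })
}

#' Simulate gene sets (pathways)
#'
#' @param genes gene ids to draw from.
#' @param n_sets number of sets.
#' @param size_range inclusive range of genes per set.
#' @param seed integer seed.
#' @return named list mapping set id to gene ids.
#' @export
simulate_gene_sets <- function(genes, n_sets, size_range = c(3L, 15L),
                               seed = 1L) {
  with_stage_seed(seed, "gene-sets", {
    sets <- lapply(seq_len(n_sets), function(i) {
      sz <- sample(size_range[1]:size_range[2], 1L)
      sort(sample(genes, min(sz, length(genes))))
    })
    stats::setNames(sets, sprintf("pw%03d", seq_len(n_sets)))
  })
}
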