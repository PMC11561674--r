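## Genotype QC, LD pruning, genomic relationship matrix, gBLUP/REML SNP
## heritability, backsolved marker effects, bootstrap subsampling and a
## permutation null.

#' Centred and scaled dose matrix
#'
#' Missing doses are imputed to the marker mean (0 after centring) once,
#' up front; every downstream computation (GRM, scan, CVAT) sees the same
#' imputed matrix. Each column is centred to mean 0 and scaled to SD 1.
#'
#' @param G a [genotype_matrix()].
#' @param zero_variance `"error"` stops at a zero-variance (monomorphic)
#'   marker — the contract after QC — while `"zero"` returns an all-zero
#'   column for it (used when simulating phenotypes on unfiltered panels).
#' @return numeric matrix lines x markers.
#' @export
scale_doses <- function(G, zero_variance = c("error", "zero")) {
  zero_variance <- match.arg(zero_variance)
  D <- G$doses
  mu <- colMeans(D, na.rm = TRUE)
  for (j in which(G$callrate < 1)) D[is.na(D[, j]), j] <- mu[j]
  sdv <- apply(D, 2, stats::sd)
  zero <- which(sdv == 0 | !is.finite(sdv))
  if (length(zero)) {
    if (zero_variance == "error")
      stop2("zero-variance marker(s) after imputation: %s",
            paste(utils::head(G$map$id[zero], 5), collapse = ", "))
    sdv[zero] <- 1
  }
  scale(D, center = mu, scale = sdv)
}

#' Marker quality control
#'
#' Filters markers by minor-allele frequency and call rate. The screen
#' used two profiles: the GRM set keeps markers with MAF >= 5% and call
#' rate >= 95% (`strict = "ge"`), the single-marker scan set keeps
#' MAF > 5% and call rate > 80% (`strict = "gt"`).
#'
#' @param G a [genotype_matrix()].
#' @param maf_min MAF threshold.
#' @param callrate_min call-rate threshold.
#' @param strict `"ge"` (thresholds inclusive) or `"gt"` (exclusive).
#' @return a filtered [genotype_matrix()].
#' @export
qc_markers <- function(G, maf_min = 0.05, callrate_min = 0.95,
                       strict = c("ge", "gt")) {
  strict <- match.arg(strict)
  cmp <- if (strict == "ge") `>=` else `>`
  pass_maf <- cmp(G$maf, maf_min)
  pass_cr <- cmp(G$callrate, callrate_min)
  keep <- which(pass_maf & pass_cr)
  if (!length(keep))
    stop2("no markers pass QC (failed MAF: %d, failed call rate: %d of %d)",
          sum(!pass_maf), sum(!pass_cr), length(G$maf))
  subset_markers(G, keep)
}

#' Subset a genotype matrix by marker index or line index
#'
#' @param G a [genotype_matrix()].
#' @param idx marker (or line) indices to keep.
#' @return a [genotype_matrix()].
#' @export
subset_markers <- function(G, idx) {
  genotype_matrix(G$doses[, idx, drop = FALSE], G$map[idx, , drop = FALSE],
                  G$line_ids)
}

#' @rdname subset_markers
#' @export
subset_lines <- function(G, idx) {
  genotype_matrix(G$doses[idx, , drop = FALSE], G$map, G$line_ids[idx])
}

## TRUE iff markers at positions p_i <= p_j share at least one sliding
## window [s_k, s_k + window) with s_k = min_pos + k * step, k >= 0.
.co_windowed <- function(p_i, p_j, min_pos, window_bp, step_bp) {
  lo <- ceiling((p_j - window_bp + 1 - min_pos) / step_bp)  # smallest k with s_k > p_j - window
  lo <- pmax(lo, 0)
  hi <- floor((p_i - min_pos) / step_bp)                    # largest k with s_k <= p_i
  lo <= hi
}

#' Greedy LD pruning in sliding windows
#'
#' Left-to-right greedy pruning: a marker is dropped when its squared
#' Pearson dose correlation with any retained marker sharing a window
#' exceeds `r2_max`. Windows are `window_bp` wide and advance by
#' `step_bp` within each chromosome, so every retained pair that ever
#' co-occurs in a window satisfies r^2 <= `r2_max`.
#'
#' @param G a [genotype_matrix()] with position-sorted markers.
#' @param r2_max maximum retained squared correlation.
#' @param window_bp window width in bp.
#' @param step_bp window step in bp (> 0).
#' @return character vector of retained marker ids.
#' @export
ld_prune <- function(G, r2_max = 0.8, window_bp = 200000L, step_bp = 5000L) {
  if (step_bp <= 0) stop2("step_bp must be positive")
  W <- scale_doses(G)
  n1 <- nrow(W) - 1
  keep <- logical(ncol(W))
  for (ch in unique(G$map$chrom)) {
    idx <- which(G$map$chrom == ch)
    pos <- G$map$pos[idx]
    min_pos <- min(pos)
    kept_idx <- integer(0)
    kept_pos <- numeric(0)
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      pj <- pos[jj]
      ## kept markers close enough to ever share a window with j
      lo <- findInterval(pj - window_bp, kept_pos) + 1L
      drop <- FALSE
      if (lo <= length(kept_pos)) {
        cand <- lo:length(kept_pos)
        elig <- cand[.co_windowed(kept_pos[cand], pj, min_pos, window_bp, step_bp)]
        if (length(elig)) {
          rr <- as.numeric(crossprod(W[, kept_idx[elig], drop = FALSE], W[, j])) / n1
          drop <- any(rr * rr > r2_max)
        }
      }
      if (!drop) { keep[j] <- TRUE
        kept_idx <- c(kept_idx, j); kept_pos <- c(kept_pos, pj) }
    }
  }
  G$map$id[keep]
}

#' Genomic relationship matrix
#'
#' `K = W W' / m` on the centred, unit-variance dose matrix `W` (missing
#' doses imputed to the marker mean). With this construction the mean
#' diagonal is close to 1 for independent markers.
#'
#' @param G a [genotype_matrix()].
#' @return object of class `grm`: list with `K` (n x n), `line_ids`, `m`.
#' @export
compute_grm <- function(G) {
  W <- scale_doses(G)
  K <- tcrossprod(W) / ncol(W)
  dimnames(K) <- list(G$line_ids, G$line_ids)
  structure(list(K = K, line_ids = G$line_ids, m = ncol(W)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d lines, %d markers; mean diagonal %.3f\n",
              nrow(x$K), x$m, mean(diag(x$K))))
  invisible(x)
}

.as_K <- function(K) if (inherits(K, "grm")) K$K else as.matrix(K)

## REML profile over lambda = s2g/s2e for rotated data.
## yt = U'y, Xt = U'X, d = eigenvalues of K. Returns the fit at the
## optimum of the restricted log-likelihood on log(lambda) in [-10, 10].
.gblup_core <- function(yt, Xt, d, tol = 1e-9) {
  n <- length(yt); p <- ncol(Xt)
  rll <- function(loglam) {
    lam <- exp(loglam)
    ld1 <- lam * d + 1
    w <- 1 / ld1
    A <- crossprod(Xt, w * Xt)
    beta <- solve(A, crossprod(Xt, w * yt))
    r <- yt - Xt %*% beta
    s2e <- sum(w * r^2) / (n - p)
    -0.5 * ((n - p) * (log(s2e) + 1) + sum(log(ld1)) +
              determinant(A, logarithm = TRUE)$modulus[1])
  }
  opt <- stats::optimize(rll, c(-10, 10), maximum = TRUE, tol = tol)
  loglam <- opt$maximum
  lam <- exp(loglam)
  ld1 <- lam * d + 1
  w <- 1 / ld1
  A <- crossprod(Xt, w * Xt)
  beta <- solve(A, crossprod(Xt, w * yt))
  r <- yt - Xt %*% beta
  s2e <- sum(w * r^2) / (n - p)
  list(lambda = lam, loglam = loglam, s2e = s2e, s2g = lam * s2e,
       h2 = lam / (1 + lam), beta = as.numeric(beta),
       resid_rot = as.numeric(r), loglik = opt$objective,
       boundary = loglam < -10 + 0.01 || loglam > 10 - 0.01)
}

## REML criterion as a function of the variance components themselves;
## used for the numerical Hessian behind the H^2 standard error.
.rll_vc <- function(vg, ve, yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  v <- vg * d + ve
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  A <- crossprod(Xt, w * Xt)
  beta <- solve(A, crossprod(Xt, w * yt))
  r <- yt - Xt %*% beta
  -0.5 * (sum(log(v)) + determinant(A, logarithm = TRUE)$modulus[1] +
            sum(w * r^2))
}

#' Fit a gBLUP mixed model by REML
#'
#' Fits `y = X beta + g + e`, `g ~ N(0, K s2g)`, `e ~ N(0, I s2e)` by
#' restricted maximum likelihood: `K` is eigendecomposed once, the
#' restricted likelihood is profiled over `lambda = s2g/s2e`, and lambda
#' is optimized by bracketed 1-D search on `log(lambda)` in `[-10, 10]`.
#' Returns GLS fixed effects at the optimum, line genomic BLUPs
#' `ghat = s2g K V^-1 (y - X beta)`, SNP heritability
#' `H2 = s2g / (s2g + s2e)`, and an SE for H2 from the numerical Hessian
#' of the restricted likelihood in `(s2g, s2e)` (delta method).
#'
#' @param y phenotype vector (one value per line).
#' @param X covariate design matrix (with intercept), or NULL for an
#'   intercept-only model. Must have full column rank.
#' @param K a `grm` object or an n x n PSD matrix aligned with `y`.
#' @param se whether to compute the Hessian-based SE of H2.
#' @return object of class `gblup_fit`: `sigma2_g`, `sigma2_e`, `h2`,
#'   `h2_se`, `beta`, `ghat`, `residuals`, `loglik`, `lambda`,
#'   `boundary` (TRUE when the optimizer hit the log-lambda bracket).
#' @export
fit_gblup <- function(y, X = NULL, K, se = TRUE) {
  Km <- .as_K(K)
  n <- length(y)
  stopifnot(nrow(Km) == n, ncol(Km) == n)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop2("covariate design X is rank deficient")
  if (n <= ncol(X) + 1) stop2("need more lines than fixed effects")
  eg <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
    stop2("K is not positive semi-definite (min eigenvalue %.3g)", min(eg$values))
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- as.numeric(crossprod(U, y))
  Xt <- crossprod(U, X)
  fit <- .gblup_core(yt, Xt, d)

  vdiag <- fit$s2g * d + fit$s2e
  ghat <- as.numeric(U %*% (fit$s2g * d / vdiag * fit$resid_rot))
  resid <- as.numeric(y - X %*% fit$beta - ghat)

  h2_se <- NA_real_
  if (se) {
    vg <- fit$s2g; ve <- fit$s2e
    hg <- max(vg, ve) * 1e-4
    if (vg > 2 * hg && ve > 2 * hg) {
      f <- function(a, b) .rll_vc(a, b, yt, Xt, d)
      H <- matrix(NA_real_, 2, 2)
      H[1, 1] <- (f(vg + hg, ve) - 2 * f(vg, ve) + f(vg - hg, ve)) / hg^2
      H[2, 2] <- (f(vg, ve + hg) - 2 * f(vg, ve) + f(vg, ve - hg)) / hg^2
      H[1, 2] <- H[2, 1] <-
        (f(vg + hg, ve + hg) - f(vg + hg, ve - hg) -
           f(vg - hg, ve + hg) + f(vg - hg, ve - hg)) / (4 * hg^2)
      cv <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(cv) && all(diag(cv) > 0)) {
        grad <- c(ve, -vg) / (vg + ve)^2
        v_h2 <- as.numeric(t(grad) %*% cv %*% grad)
        if (is.finite(v_h2) && v_h2 >= 0) h2_se <- sqrt(v_h2)
      }
    }
  }

  structure(list(sigma2_g = fit$s2g, sigma2_e = fit$s2e, h2 = fit$h2,
                 h2_se = h2_se, beta = stats::setNames(fit$beta, colnames(X)),
                 ghat = ghat, residuals = resid, loglik = fit$loglik,
                 lambda = fit$lambda, boundary = fit$boundary,
                 n = n, eigen = list(values = d, vectors = U)),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("gBLUP/REML fit on %d lines\n  H2_SNP = %.3f%s  (s2g = %.4g, s2e = %.4g)%s\n",
              x$n, x$h2,
              if (is.finite(x$h2_se)) sprintf(" +/- %.3f (SE)", x$h2_se) else "",
              x$sigma2_g, x$sigma2_e,
              if (x$boundary) "  [boundary optimum]" else ""))
  invisible(x)
}

#' Backsolve marker effects from line genomic values
#'
#' Recovers per-marker effects `s = W' K^+ ghat / m` (Moore-Penrose
#' pseudo-inverse for rank-deficient `K`), so that `W s` is the projection
#' of `ghat` onto the column space of `W`.
#'
#' @param W centred/scaled dose matrix used to build `K`.
#' @param K the matching `grm` (`K = W W'/m`).
#' @param ghat line genomic values from [fit_gblup()].
#' @return numeric vector of per-marker effects.
#' @export
backsolve_marker_effects <- function(W, K, ghat) {
  Km <- .as_K(K)
  if (nrow(W) != length(ghat) || nrow(Km) != length(ghat))
    stop2("dimension mismatch between W (%d lines), K (%d) and ghat (%d)",
          nrow(W), nrow(Km), length(ghat))
  m <- ncol(W)
  eg <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  u <- eg$vectors[, pos, drop = FALSE] %*%
    (crossprod(eg$vectors[, pos, drop = FALSE], ghat) / eg$values[pos])
  as.numeric(crossprod(W, u)) / m
}

#' Heritability over bootstrap subsamples of lines
#'
#' For each requested size, draws `n_reps` subsamples of that many lines
#' without replacement (with-replacement duplication would make `K`
#' singular) and refits the gBLUP model on the aligned subset. Replicates
#' whose subsampled design matrix loses rank are dropped and counted.
#'
#' @param y,X,K as in [fit_gblup()].
#' @param sizes integer vector of subsample sizes (each <= n lines).
#' @param n_reps replicates per size.
#' @param seed integer seed.
#' @return data.frame with columns `size`, `rep`, `h2`; attribute
#'   `n_dropped` counts rank-deficient replicates per size.
#' @export
bootstrap_h2 <- function(y, X = NULL, K, sizes, n_reps = 200L, seed = 1L) {
  Km <- .as_K(K)
  n <- length(y)
  stopifnot(all(sizes >= 2), all(sizes <= n))
  if (is.null(X)) X <- matrix(1, n, 1)
  with_stage_seed(seed, "bootstrap", {
    res <- vector("list", length(sizes))
    dropped <- stats::setNames(integer(length(sizes)), sizes)
    for (si in seq_along(sizes)) {
      sz <- sizes[si]
      h2s <- rep(NA_real_, n_reps)
      for (r in seq_len(n_reps)) {
        idx <- sample.int(n, sz)
        Xs <- X[idx, , drop = FALSE]
        if (qr(Xs)$rank < ncol(Xs)) { dropped[si] <- dropped[si] + 1L; next }
        h2s[r] <- fit_gblup(y[idx], Xs, Km[idx, idx], se = FALSE)$h2
      }
      res[[si]] <- data.frame(size = sz, rep = seq_len(n_reps), h2 = h2s)
    }
    out <- do.call(rbind, res)
    attr(out, "n_dropped") <- dropped
    out
  })
}

#' Permutation null for SNP heritability
#'
#' The phenotype vector is permuted across lines while `(X, K)` are held
#' fixed together, breaking both covariate and kinship association, and
#' the model is refit for each permutation. The empirical p-value is
#' `(# permuted H2 >= observed H2) / n_perm`, floored at `1/n_perm` when
#' no permutation reaches the observed value.
#'
#' @param y,X,K as in [fit_gblup()].
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list: `h2_obs`, `h2_perm` (vector), `count`, `p_value`,
#'   `at_floor` (TRUE when the count was zero).
#' @export
permute_h2 <- function(y, X = NULL, K, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1)
  Km <- .as_K(K)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  eg <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  Xt <- crossprod(U, X)
  h2_obs <- .gblup_core(as.numeric(crossprod(U, y)), Xt, d)$h2
  h2_perm <- with_stage_seed(seed, "permute", {
    vapply(seq_len(n_perm), function(i) {
      yp <- y[sample.int(n)]
      .gblup_core(as.numeric(crossprod(U, yp)), Xt, d)$h2
    }, numeric(1))
  })
  count <- sum(h2_perm >= h2_obs)
  list(h2_obs = h2_obs, h2_perm = h2_perm, count = count,
       p_value = max(count, 1L) / n_perm, at_floor = count == 0L)
}
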