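## Independent oracle implementations used to cross-check the package:
## deliberately naive (loops, dense algebra, generic optimizers) and kept
## separate from the code paths they validate.

## textbook pooled two-sample SD / SE
pooled_oracle <- function(n_r, n_c, s_r, s_c) {
  s <- sqrt(((n_r - 1) * s_r^2 + (n_c - 1) * s_c^2) / (n_r + n_c - 2))
  list(s = s, se = s * sqrt(1 / n_r + 1 / n_c))
}

## double-loop covariance GRM
grm_oracle <- function(W) {
  n <- nrow(W); m <- ncol(W)
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      K[i, j] <- sum(W[i, ] * W[j, ]) / m
  K
}

## greedy LD pruning by explicit window enumeration
prune_oracle <- function(G, r2_max, window_bp, step_bp) {
  W <- scale_doses(G)
  n1 <- nrow(W) - 1
  keep <- rep(TRUE, ncol(W))
  for (ch in unique(G$map$chrom)) {
    idx <- which(G$map$chrom == ch)
    pos <- G$map$pos[idx]
    for (s in seq(min(pos), max(pos), by = step_bp)) {
      memb <- idx[pos >= s & pos < s + window_bp]
      if (length(memb) < 2) next
      for (jj in seq_along(memb)[-1]) {
        j <- memb[jj]
        if (!keep[j]) next
        for (ii in seq_len(jj - 1)) {
          i <- memb[ii]
          if (!keep[i]) next
          r <- sum(W[, i] * W[, j]) / n1
          if (r * r > r2_max) { keep[j] <- FALSE; break }
        }
      }
    }
  }
  G$map$id[keep]
}

## dense REML with explicit V and a generic optimizer
dense_reml_oracle <- function(y, X, K) {
  n <- length(y)
  nll <- function(lp) {
    vg <- exp(lp[1]); ve <- exp(lp[2])
    V <- vg * K + ve * diag(n)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(1e10)
    Vi <- chol2inv(cV)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    0.5 * (2 * sum(log(diag(cV))) + determinant(A)$modulus[1] +
             as.numeric(t(r) %*% Vi %*% r))
  }
  o <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  vg <- exp(o$par[1]); ve <- exp(o$par[2])
  vg / (vg + ve)
}

## saturating-trajectory fit by lattice search plus local polish
trajectory_oracle <- function(scores, times) {
  sse <- function(p) sum((scores - (p[1] * times / (times + p[2]) - p[3]))^2)
  rng <- diff(range(scores))
  grid <- expand.grid(a = rng * c(0.25, 0.5, 1, 2, 4) * sign(rng + 1e-12),
                      b = c(0.25, 0.5, 1, 2, 4, 8, 16),
                      c = -min(scores) + rng * seq(-1, 1, by = 0.25))
  ss <- apply(grid, 1, sse)
  st <- as.numeric(grid[which.min(ss), ])
  o <- stats::optim(st, sse, method = "L-BFGS-B",
                    lower = c(-Inf, 1e-9, -Inf),
                    control = list(maxit = 2000, factr = 1e3))
  list(a = o$par[1], b = o$par[2], c = o$par[3], sse = o$value)
}

## balanced two-class metabolome design (6 resistant + 7 sensitive lines,
## both treatments, `reps` replicates) used by the mixed-model tests
balanced_design <- function(reps = 2) {
  lines <- c(sprintf("R%02d", 1:6), sprintf("S%02d", 1:7))
  cls <- rep(c("resistant", "sensitive"), c(6, 7))
  meta <- expand.grid(rep = seq_len(reps),
                      treatment = c("control", "rapamycin"),
                      line = lines, stringsAsFactors = FALSE)
  meta$class <- cls[match(meta$line, lines)]
  meta$batch <- paste0("b", meta$rep)
  meta$sample <- sprintf("s%03d", seq_len(nrow(meta)))
  meta[, c("sample", "line", "class", "treatment", "batch")]
}
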