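## Developmental-delay phenotyping: per-vial pupation records -> per-line
## delay phenotypes with pooled errors -> normalized values for
## association testing.

#' Summarize pupation records per line, batch and condition
#'
#' Pools all pupae across replicate vials of a line x condition: the mean
#' pupation day is the count-weighted mean over vials, the SD uses
#' denominator n - 1, and n is the total pupa count. Line x batch x
#' condition cells with zero pupae are simply absent from the output.
#'
#' @param records a `pupation_records` data.frame (columns `vial`, `line`,
#'   `treatment`, `batch`, `day`, `count`).
#' @return data.frame with columns `line`, `batch`, `treatment`, `mean`,
#'   `sd`, `n`.
#' @export
summarize_pupation <- function(records) {
  stopifnot(all(c("line", "treatment", "batch", "day", "count") %in% names(records)))
  if (any(records$count < 0)) stop2("pupae counts must be non-negative")
  records <- records[records$count > 0, , drop = FALSE]
  if (!nrow(records)) stop2("no pupae in records")
  key <- interaction(records$line, records$batch, records$treatment, drop = TRUE)
  pieces <- split(records, key)
  out <- do.call(rbind, lapply(pieces, function(d) {
    mo <- weighted_moments(d$day, d$count)
    data.frame(line = d$line[1], batch = d$batch[1], treatment = d$treatment[1],
               mean = mo$mean, sd = mo$sd, n = mo$n, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$line, out$batch, out$treatment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled standard deviation and standard error of a two-condition contrast
#'
#' `pooled s = sqrt(((n_r - 1) s_r^2 + (n_c - 1) s_c^2) / (n_r + n_c - 2))`
#' and `pooled SE = pooled s * sqrt(1/n_r + 1/n_c)` — the textbook pooled
#' two-sample formula. All arguments are vectorized.
#'
#' @param n_r,n_c pupa counts in the rapamycin and control conditions
#'   (each >= 1, jointly >= 3).
#' @param s_r,s_c per-condition SDs (days, >= 0).
#' @return data.frame with columns `pooled_s` and `pooled_se`.
#' @export
pooled_se <- function(n_r, n_c, s_r, s_c) {
  if (any(n_r < 1) || any(n_c < 1)) stop2("n_r and n_c must be >= 1")
  if (any(n_r + n_c <= 2))
    stop2("pooled SD undefined for n_r + n_c <= 2 (degenerate input)")
  if (any(s_r < 0) || any(s_c < 0)) stop2("SDs must be non-negative")
  s <- sqrt(((n_r - 1) * s_r^2 + (n_c - 1) * s_c^2) / (n_r + n_c - 2))
  data.frame(pooled_s = s, pooled_se = s * sqrt(1 / n_r + 1 / n_c))
}

#' Developmental delay per line from condition summaries
#'
#' Delay is the mean pupation time on rapamycin minus the mean on control;
#' percent delay is 100 * delay / control mean. Negative delays (lines
#' that pupariate marginally faster on drug) are allowed. Line x batch
#' cells missing either condition are dropped with a warning.
#'
#' @param summary output of [summarize_pupation()].
#' @return data.frame (class `delay_phenotype`) with per line x batch
#'   condition means, counts, SDs, `delay`, `percent_delay`, `pooled_s`,
#'   `pooled_se`.
#' @export
developmental_delay <- function(summary) {
  key <- interaction(summary$line, summary$batch, drop = TRUE)
  pieces <- split(summary, key)
  keep <- vapply(pieces, function(d)
    all(c("control", "rapamycin") %in% d$treatment), logical(1))
  if (any(!keep)) {
    bad <- vapply(pieces[!keep], function(d)
      paste0(d$line[1], "/", d$batch[1]), character(1))
    warning(sprintf("dropping %d line x batch cell(s) missing a condition: %s",
                    sum(!keep), paste(bad, collapse = ", ")))
  }
  out <- do.call(rbind, lapply(pieces[keep], function(d) {
    ctrl <- d[d$treatment == "control", ]
    rapa <- d[d$treatment == "rapamycin", ]
    data.frame(line = d$line[1], batch = d$batch[1],
               mean_control = ctrl$mean, mean_rapamycin = rapa$mean,
               n_c = ctrl$n, n_r = rapa$n, s_c = ctrl$sd, s_r = rapa$sd,
               delay = rapa$mean - ctrl$mean,
               percent_delay = 100 * (rapa$mean - ctrl$mean) / ctrl$mean,
               stringsAsFactors = FALSE)
  }))
  out <- cbind(out, pooled_se(out$n_r, out$n_c, out$s_r, out$s_c))
  out <- out[order(out$line, out$batch), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("delay_phenotype", "data.frame")
  out
}

#' Box-Cox lambda by profile log-likelihood
#'
#' Maximizes the profile log-likelihood of the one-parameter Box-Cox
#' transform for a mean-only model over a grid on `[-2, 2]` (step 0.01),
#' then refines by Brent search in the winning grid cell.
#'
#' @param y positive observations.
#' @param grid candidate lambda values.
#' @return the maximizing lambda.
#' @export
boxcox_lambda <- function(y, grid = seq(-2, 2, by = 0.01)) {
  if (any(y <= 0)) stop2("Box-Cox requires positive values")
  if (stats::sd(y) == 0) return(1)  # constant input: identity transform
  n <- length(y)
  slog <- sum(log(y))
  ll <- function(lam) {
    z <- box_cox(y, lam)
    v <- mean((z - mean(z))^2)
    -n / 2 * log(v) + (lam - 1) * slog
  }
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(ll, c(lo, hi), maximum = TRUE)$maximum
}

#' Box-Cox power transform
#'
#' @param y positive values.
#' @param lambda transform parameter; `(y^lambda - 1)/lambda`, or `log(y)`
#'   at `lambda = 0`.
#' @return transformed values.
#' @export
box_cox <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Normalize delay phenotypes for association testing
#'
#' Shifts delays by +1 (to remove negative values), Box-Cox transforms
#' with a single lambda fitted over all lines, then within each batch
#' subtracts the mean transformed value of the reference lines assayed in
#' every batch, and divides by the SD of the centred values over all lines
#' in the batch. Reference lines are retained in the output and flagged.
#'
#' @param delays data.frame with columns `line`, `batch`, `delay` (e.g. a
#'   `delay_phenotype`).
#' @param reference_lines character ids of the lines included in every
#'   batch (the screen used four).
#' @return the input with added columns `normalized` and `is_reference`;
#'   attributes `lambda` and `batch_stats` record the fit.
#' @export
normalize_delay <- function(delays, reference_lines) {
  stopifnot(all(c("line", "batch", "delay") %in% names(delays)))
  y <- delays$delay + 1
  if (any(y <= 0))
    stop2("delay <= -1 day for line(s) %s: shifted Box-Cox transform undefined",
          paste(delays$line[y <= 0], collapse = ", "))
  for (b in unique(delays$batch)) {
    present <- delays$line[delays$batch == b]
    miss <- setdiff(reference_lines, present)
    if (length(miss))
      stop2("batch %s is missing reference line(s): %s", b,
            paste(miss, collapse = ", "))
  }
  lambda <- boxcox_lambda(y)
  z <- box_cox(y, lambda)

  out <- delays
  out$is_reference <- out$line %in% reference_lines
  out$normalized <- NA_real_
  batch_stats <- list()
  for (b in unique(out$batch)) {
    i <- which(out$batch == b)
    ref_mean <- mean(z[i][out$is_reference[i]])
    centred <- z[i] - ref_mean
    s <- stats::sd(centred)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("batch %s: SD of centred values is 0; scaling skipped (degenerate)", b))
      s <- 1
    }
    out$normalized[i] <- centred / s
    batch_stats[[b]] <- c(ref_mean = ref_mean, sd = s)
  }
  attr(out, "lambda") <- lambda
  attr(out, "batch_stats") <- batch_stats
  out
}
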