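#' Coefficient of determination
#'
#' `R^2 = 1 - RSS/TSS` with `RSS = sum((y - yhat)^2)` and
#' `TSS = sum((y - mean(y))^2)`.
#'
#' @param y Ground-truth vector (length >= 2, non-constant).
#' @param yhat Predictions, same length.
#' @return R-squared (can be negative for models worse than the mean).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("r_squared: length mismatch")
  if (length(y) < 2) stop("r_squared: need at least 2 observations")
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop("r_squared: non-finite values")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("r_squared: constant ground truth (TSS = 0), undefined")
  1 - sum((y - yhat)^2) / tss
}

#' Aggregate repeated runs into a variant report
#'
#' Keeps the `top_n` runs by validation performance and reports the mean
#' test R-squared with a two-sided 95% Student-t confidence interval
#' (df = n - 1) over the kept runs — the "best ten of the executed runs"
#' protocol.
#'
#' @param runs List of `mirex_run` objects (each with `r2_test`).
#' @param variant Label: `"baseline"`, `"all_mirna"`, `"mirex"`,
#'   `"abs_corr"`, or any tag.
#' @param top_n Number of runs retained (default 10).
#' @param rank_by `"val_r2"` (default) or `"val_loss"` — the validation
#'   criterion used to pick the retained runs.
#' @param conf_level Confidence level (default 0.95).
#' @return A `variant_report`: `variant`, `r2_runs` (retained, ranked),
#'   `mean_r2`, `ci95 = c(low, high)`, `n_total`, `seeds`.
#' @export
aggregate_runs <- function(runs, variant = "model", top_n = 10,
                           rank_by = c("val_r2", "val_loss"),
                           conf_level = 0.95) {
  rank_by <- match.arg(rank_by)
  stopifnot(length(runs) >= 1)
  if (length(runs) < top_n)
    warning(sprintf("aggregate_runs: only %d run(s) for top_n = %d; using all",
                    length(runs), top_n))
  score <- vapply(runs, function(r)
    if (rank_by == "val_r2") -r$r2_val else r$best_val_loss, numeric(1))
  seeds <- vapply(runs, function(r) r$seed, numeric(1))
  keep <- order(score, seeds)[seq_len(min(top_n, length(runs)))]
  r2 <- vapply(runs[keep], function(r) r$r2_test, numeric(1))
  if (any(is.na(r2)))
    stop("aggregate_runs: runs lack test R-squared (train with a test batch)")
  m <- mean(r2)
  n <- length(r2)
  half <- if (n > 1) qt(1 - (1 - conf_level) / 2, df = n - 1) * sd(r2) / sqrt(n) else 0
  structure(list(variant = variant, r2_runs = unname(r2), mean_r2 = m,
                 ci95 = c(low = m - half, high = m + half),
                 n_total = length(runs), seeds = seeds[keep]),
            class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat(sprintf("%-10s mean test R2 = %.4f  95%% CI [%.4f, %.4f]  (best %d of %d runs)\n",
              x$variant, x$mean_r2, x$ci95[1], x$ci95[2],
              length(x$r2_runs), x$n_total))
  invisible(x)
}

#' Pairwise significance of variant differences
#'
#' Two-sided Welch t-tests on the retained per-run test R-squared samples
#' for every variant pair. P-values are reported raw (no multiple-testing
#' correction is applied in the comparison protocol).
#'
#' @param reports List of `variant_report`s (each with >= 2 retained runs).
#' @return Symmetric matrix of p-values (diagonal `NA`); degenerate pairs
#'   with zero variance in both samples are `NA` with a warning.
#' @export
compare_variants <- function(reports) {
  stopifnot(length(reports) >= 2,
            all(vapply(reports, inherits, logical(1), "variant_report")))
  nm <- vapply(reports, function(r) r$variant, character(1))
  if (anyDuplicated(nm)) stop("compare_variants: duplicated variant labels")
  p <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    a <- reports[[i]]$r2_runs
    b <- reports[[j]]$r2_runs
    if (length(a) < 2 || length(b) < 2)
      stop("compare_variants: each report needs >= 2 retained runs")
    if (sd(a) == 0 && sd(b) == 0) {
      warning(sprintf("compare_variants: zero variance in both %s and %s; p undefined",
                      nm[i], nm[j]))
      next
    }
    p[i, j] <- p[j, i] <- tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
                                   error = function(e) NA_real_)
  }
  p
}

#' Tabulate variant reports
#'
#' @param reports List of `variant_report`s.
#' @param pairwise_p Optional matrix from [compare_variants()]; adds the
#'   p-value of each variant against `"baseline"`.
#' @return Data frame with one row per variant.
#' @export
report_table <- function(reports, pairwise_p = NULL) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(variant = r$variant, mean_r2 = r$mean_r2,
               ci_low = unname(r$ci95[1]), ci_high = unname(r$ci95[2]),
               n_runs = length(r$r2_runs), stringsAsFactors = FALSE)))
  if (!is.null(pairwise_p) && "baseline" %in% rownames(pairwise_p))
    df$p_vs_baseline <- pairwise_p[df$variant, "baseline"]
  rownames(df) <- NULL
  df
}
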