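#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). Requires at least 3 pairs; if either vector has zero rank
#' variance the correlation is undefined and `NA` is returned so callers
#' can mark the miRNA ineligible.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("spearman_rho: length mismatch")
  if (length(a) < 3) stop("spearman_rho: need at least 3 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("spearman_rho: non-finite values")
  if (sd(rank(a)) == 0 || sd(rank(b)) == 0) return(NA_real_)
  unname(cor(a, b, method = "spearman"))
}

#' Rank miRNAs by residual-CWCS Spearman correlation
#'
#' The selection procedure at the core of the method: a miRNA that
#' represses its targets makes the baseline model (which knows nothing of
#' miRNAs) over-predict them, giving negative residuals
#' (`y - yhat`); TargetScan's CWCS is more negative for stronger
#' predicted repression, so informative miRNAs show a positive Spearman
#' correlation between their targets' residuals and CWCS. Each miRNA is
#' scored over its target genes present in the residual map — one
#' (gene, CWCS) pair contributes one point — in either `signed` mode
#' (residuals as-is; direct repression) or `absolute` mode
#' (`|residual|`; indirect regulation).
#'
#' @param residuals Named numeric vector of baseline residuals per gene
#'   (typically train+validation genes, see [residuals_from_baseline()]).
#' @param targets Target table `data.frame(mirna_id, gene_id, cwcs)`.
#' @param mode `"signed"` or `"absolute"`.
#' @param min_targets Minimum usable target genes for a miRNA to be
#'   eligible (default 10; rank correlation over fewer points is noise).
#' @return A `selection_result`: data frame `ranked` (`mirna_id`, `rho`,
#'   `n_targets`) sorted by rho descending with lexicographic tie-break,
#'   plus `mode`, `min_targets`, and `excluded` (ineligible miRNAs).
#' @export
rank_mirnas <- function(residuals, targets, mode = c("signed", "absolute"),
                        min_targets = 10) {
  mode <- match.arg(mode)
  stopifnot(min_targets >= 3)
  if (is.null(names(residuals)))
    stop("rank_mirnas: residuals must be named by gene")
  if (nrow(targets) == 0) {
    warning("rank_mirnas: empty target table")
    return(structure(list(
      ranked = data.frame(mirna_id = character(), rho = numeric(),
                          n_targets = integer(), stringsAsFactors = FALSE),
      mode = mode, min_targets = min_targets, excluded = character()),
      class = "selection_result"))
  }
  r <- if (mode == "absolute") abs(residuals) else residuals
  usable <- targets[targets$gene_id %in% names(residuals), , drop = FALSE]
  by_mirna <- split(usable, usable$mirna_id)
  rows <- lapply(names(by_mirna), function(mid) {
    tg <- by_mirna[[mid]]
    n <- nrow(tg)
    rho <- if (n >= min_targets) spearman_rho(r[tg$gene_id], tg$cwcs) else NA_real_
    data.frame(mirna_id = mid, rho = rho, n_targets = n,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  all_ids <- unique(targets$mirna_id)
  seen <- if (is.null(tab)) character() else tab$mirna_id
  orphans <- setdiff(all_ids, seen)
  excluded <- sort(c(tab$mirna_id[is.na(tab$rho)], orphans))
  tab <- tab[!is.na(tab$rho), , drop = FALSE]
  tab <- tab[order(-tab$rho, tab$mirna_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(ranked = tab, mode = mode, min_targets = min_targets,
                 excluded = excluded),
            class = "selection_result")
}

#' Select the top-k ranked miRNAs
#'
#' @param result A `selection_result` from [rank_mirnas()].
#' @param k Number of miRNAs to keep (the method's default is 10).
#' @return Character vector of the first `min(k, eligible)` miRNA IDs.
#' @export
select_top_k <- function(result, k = 10) {
  stopifnot(inherits(result, "selection_result"), k >= 1)
  n <- nrow(result$ranked)
  if (n < k)
    warning(sprintf("select_top_k: only %d eligible miRNAs for k = %d", n, k))
  result$ranked$mirna_id[seq_len(min(k, n))]
}

#' Residual map of a baseline run
#'
#' Residuals are `y - yhat` per gene. Restricted to `gene_ids` when given;
#' genes without residuals are an error.
#'
#' @param run A `mirex_run` (or a list of runs, whose residual maps are
#'   averaged gene-wise — equivalent to residuals of the averaged
#'   predictions).
#' @param gene_ids Optional gene universe to extract.
#' @return Named numeric vector of residuals.
#' @export
residuals_from_baseline <- function(run, gene_ids = NULL) {
  runs <- if (inherits(run, "mirex_run")) list(run) else run
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, logical(1), "mirex_run")))
  res <- runs[[1]]$residuals
  if (length(runs) > 1) {
    genes <- names(res)
    for (r in runs[-1]) {
      if (!setequal(names(r$residuals), genes))
        stop("residuals_from_baseline: runs cover different gene sets")
      res <- res + r$residuals[genes]
    }
    res <- res / length(runs)
  }
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, names(res))
    if (length(missing))
      stop(sprintf("residuals_from_baseline: no residuals for gene(s): %s",
                   paste(head(missing, 10), collapse = ", ")))
    res <- res[gene_ids]
  }
  res
}

#' Write/read a selection result as TSV
#'
#' Columns: `mirna_id`, `rho`, `n_targets`, `selected` (0/1 flag for the
#' top-k set).
#'
#' @param result A `selection_result`.
#' @param path Output TSV path.
#' @param k Top-k flagged as selected.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path, k = 10) {
  df <- result$ranked
  df$selected <- as.integer(seq_len(nrow(df)) <= min(k, nrow(df)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("miRNA selection (%s mode): %d eligible, %d excluded (< %d targets or undefined rho)\n",
              x$mode, nrow(x$ranked), length(x$excluded), x$min_targets))
  print(head(x$ranked, 10))
  invisible(x)
}
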