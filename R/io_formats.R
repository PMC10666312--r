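#' TSS-centered window specification
#'
#' Defines how many bases of the plus-strand reference are taken before and
#' from the transcription start site (TSS). The model's published input
#' window is 10,500 bases: 3000 upstream of the TSS and 7500 from the TSS
#' onward. Coordinates are 0-based and windows are half-open
#' `[tss - upstream, tss + downstream)`, so the base at window index
#' `upstream` (1-based: `upstream + 1`) is the TSS base itself.
#'
#' @param upstream Integer, bases before the TSS (default 3000).
#' @param downstream Integer, bases from the TSS onward, TSS included
#'   (default 7500).
#' @return A `window_spec` object (list with `upstream`, `downstream`,
#'   `width`).
#' @export
window_spec <- function(upstream = 3000, downstream = 7500) {
  stopifnot(length(upstream) == 1, length(downstream) == 1)
  upstream <- as.integer(upstream)
  downstream <- as.integer(downstream)
  if (is.na(upstream) || is.na(downstream) || upstream < 0 || downstream < 0)
    stop("window_spec: upstream and downstream must be nonnegative integers")
  if (upstream + downstream < 1L)
    stop("window_spec: window must contain at least one base")
  structure(list(upstream = upstream, downstream = downstream,
                 width = upstream + downstream),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("TSS window: %d upstream + %d downstream = %d bases\n",
              x$upstream, x$downstream, x$width))
  invisible(x)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] accepting plain
#' character input over the A/C/G/T/N alphabet.
#'
#' @param x Single DNA string.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a TSS-centered sequence window
#'
#' Takes `spec$upstream` bases before and `spec$downstream` bases from the
#' (0-based) TSS position on the plus strand of `genome_sequence`; for
#' minus-strand genes the same plus-strand slice (mirrored around the TSS)
#' is reverse-complemented, so the returned window always reads 5'->3' in
#' the direction of transcription with the TSS base at window index
#' `spec$upstream` (0-based).
#'
#' @param genome_sequence Chromosome/contig sequence as a single string.
#' @param tss_position 0-based TSS coordinate on the plus strand.
#' @param strand `"+"` or `"-"`.
#' @param spec A [window_spec()].
#' @param gene_id Gene identifier used in error messages.
#' @param pad_n If `TRUE`, out-of-bounds positions are filled with `N`
#'   instead of raising an error.
#' @return A string of exactly `spec$width` bases.
#' @export
extract_window <- function(genome_sequence, tss_position, strand = c("+", "-"),
                           spec = window_spec(), gene_id = "<gene>",
                           pad_n = FALSE) {
  strand <- match.arg(strand)
  stopifnot(inherits(spec, "window_spec"))
  tss <- as.integer(tss_position)
  if (is.na(tss) || tss < 0)
    stop(sprintf("extract_window: gene %s has invalid TSS position", gene_id))
  glen <- nchar(genome_sequence)
  # on the minus strand "upstream of the TSS" lies at larger plus-strand
  # coordinates, so the plus-strand slice is mirrored around the TSS
  if (strand == "+") {
    start0 <- tss - spec$upstream
    end0 <- tss + spec$downstream            # half-open
  } else {
    start0 <- tss - spec$downstream + 1L
    end0 <- tss + spec$upstream + 1L
  }
  left_pad <- max(0L, -start0)
  right_pad <- max(0L, end0 - glen)
  if ((left_pad > 0L || right_pad > 0L) && !pad_n)
    stop(sprintf(
      "extract_window: window for gene %s [%d, %d) exceeds sequence bounds [0, %d) by %d base(s)",
      gene_id, start0, end0, glen, left_pad + right_pad))
  core <- substr(genome_sequence, start0 + left_pad + 1L, end0 - right_pad)
  win <- paste0(strrep("N", left_pad), core, strrep("N", right_pad))
  if (strand == "-") win <- revcomp(win)
  win <- toupper(win)
  stopifnot(nchar(win) == spec$width)
  win
}

#' Log-normalize nonnegative counts
#'
#' The expression transform used throughout the pipeline:
#' `x <- log10(x + 0.1)`, which maps 0 to -1 and tames the right skew of
#' raw count data.
#'
#' @param x Numeric vector of nonnegative values.
#' @return `log10(x + 0.1)`, same shape as `x`.
#' @export
lognorm <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("lognorm: input must be finite and nonnegative")
  log10(x + 0.1)
}

#' Construct an expression matrix
#'
#' Raw-count matrix of genes or miRNAs (rows) by samples (columns), with
#' unique row and column identifiers.
#'
#' @param values Numeric matrix of nonnegative raw counts with rownames
#'   (entity IDs) and colnames (sample IDs).
#' @return The validated matrix, classed `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression_matrix: row and column names are required")
  if (anyDuplicated(rownames(values)))
    stop("expression_matrix: duplicated row IDs")
  if (anyDuplicated(colnames(values)))
    stop("expression_matrix: duplicated sample IDs")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression_matrix: values must be finite and nonnegative")
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Per-group mean expression of raw counts
#'
#' Arithmetic mean of raw counts within each sample group (e.g. a cancer
#' subtype), plus an `overall` column pooling the union of all group
#' samples — the pooled mean over samples, not the mean of group means.
#'
#' @param m An [expression_matrix()] (rows = genes or miRNAs).
#' @param sample_groups Named list of sample-ID character vectors.
#' @param overall Add the pooled `overall` column? Default `TRUE`.
#' @return Numeric matrix rows x groups (+ `overall`).
#' @export
mean_expression <- function(m, sample_groups, overall = TRUE) {
  stopifnot(is.list(sample_groups), length(sample_groups) > 0)
  if (is.null(names(sample_groups)) || any(names(sample_groups) == ""))
    stop("mean_expression: sample_groups must be a named list")
  for (g in names(sample_groups)) {
    ids <- sample_groups[[g]]
    if (length(ids) == 0) stop(sprintf("mean_expression: group '%s' is empty", g))
    missing <- setdiff(ids, colnames(m))
    if (length(missing))
      stop(sprintf("mean_expression: group '%s' has unknown samples: %s",
                   g, paste(missing, collapse = ", ")))
  }
  out <- vapply(sample_groups,
                function(ids) rowMeans(m[, ids, drop = FALSE]),
                numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), names(sample_groups)))
  if (overall) {
    pooled <- unique(unlist(sample_groups, use.names = FALSE))
    out <- cbind(out, overall = rowMeans(m[, pooled, drop = FALSE]))
  }
  out
}

#' Filter a gene list by keep/exclusion lists
#'
#' Returns `gene_ids` restricted to `keep_list` (e.g. protein-coding genes)
#' minus the union of exclusion lists (e.g. histone genes, Y-chromosome
#' genes), preserving the input order. Overlapping exclusion lists are
#' unioned, never double-counted.
#'
#' @param gene_ids Character vector of candidate gene IDs.
#' @param exclusion_lists Named list of ID vectors to drop.
#' @param keep_list IDs allowed to remain; default all of `gene_ids`.
#' @return Filtered character vector, input order preserved.
#' @export
filter_genes <- function(gene_ids, exclusion_lists = list(), keep_list = gene_ids) {
  excluded <- unique(unlist(exclusion_lists, use.names = FALSE))
  out <- gene_ids[gene_ids %in% keep_list & !(gene_ids %in% excluded)]
  if (length(out) == 0) warning("filter_genes: no genes survived filtering")
  out
}

#' Read a miRNA target table with CWCS values
#'
#' Parses a tab-separated table of (miRNA ID, gene ID, CWCS) triples, where
#' CWCS is the TargetScan Cumulative Weighted Context++ Score (more
#' negative = stronger predicted repression). Duplicate (miRNA, gene) pairs
#' are collapsed by `collapse` (default: minimum CWCS, keeping the
#' strongest predicted repression).
#'
#' @param path TSV file with columns `mirna_id`, `gene_id`, `cwcs`.
#' @param header Does the file carry a header row? Default `TRUE`.
#' @param collapse Rule for duplicate pairs: `"min"`, `"max"` or `"mean"`.
#' @return `data.frame(mirna_id, gene_id, cwcs)` with unique pairs.
#' @export
read_targets <- function(path, header = TRUE, collapse = c("min", "max", "mean")) {
  collapse <- match.arg(collapse)
  raw <- read.delim(path, header = header, sep = "\t",
                    colClasses = c("character", "character", "character"),
                    col.names = c("mirna_id", "gene_id", "cwcs"))
  if (nrow(raw) == 0)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      cwcs = numeric(), stringsAsFactors = FALSE))
  cwcs <- suppressWarnings(as.numeric(raw$cwcs))
  bad <- which(!is.finite(cwcs))
  if (length(bad))
    stop(sprintf("read_targets: unparseable CWCS at line %d of %s",
                 bad[1] + as.integer(header), path))
  df <- data.frame(mirna_id = raw$mirna_id, gene_id = raw$gene_id,
                   cwcs = cwcs, stringsAsFactors = FALSE)
  collapse_targets(df, collapse)
}

collapse_targets <- function(df, collapse = "min") {
  fun <- switch(collapse, min = min, max = max, mean = mean)
  key <- paste(df$mirna_id, df$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(df$cwcs, key, fun)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$cwcs <- as.numeric(agg[paste(df$mirna_id, df$gene_id, sep = "\r")])
  }
  rownames(df) <- NULL
  df
}

#' Write a miRNA target table
#'
#' @param targets `data.frame(mirna_id, gene_id, cwcs)`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  write.table(targets[, c("mirna_id", "gene_id", "cwcs")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an expression matrix TSV
#'
#' First column = entity ID, header = sample IDs, values = raw counts.
#'
#' @param path TSV path.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "numeric"
  rownames(vals) <- ids
  expression_matrix(vals)
}

#' @rdname read_expression_matrix
#' @param m An [expression_matrix()].
#' @param id_name Name of the leading ID column.
#' @export
write_expression_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

HALFLIFE_FEATURES <- c("utr5_len", "utr5_gc", "orf_len", "orf_gc",
                       "utr3_len", "utr3_gc", "intron_len", "exon_junction_density")

#' Read/write half-life features and expression targets
#'
#' The half-life table carries, per gene, the eight gene-structure
#' covariates that proxy mRNA degradation (lengths and CG content of
#' 5'UTR/ORF/3'UTR, intron length, exon-junction density) and the
#' log-normalized mean expression target `y`.
#'
#' @param path TSV path with columns `gene_id`, the eight feature columns,
#'   and `y`.
#' @return `data.frame` with `gene_id`, eight half-life columns and `y`.
#' @export
read_halflife <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", HALFLIFE_FEATURES, "y")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("read_halflife: missing columns: %s", paste(missing, collapse = ", ")))
  df <- df[, need]
  num <- as.matrix(df[, c(HALFLIFE_FEATURES, "y")])
  if (any(!is.finite(num))) stop("read_halflife: non-finite feature values")
  df
}

#' @rdname read_halflife
#' @param features Data frame as returned by [read_halflife()].
#' @export
write_halflife <- function(features, path) {
  write.table(features[, c("gene_id", HALFLIFE_FEATURES, "y")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Train/validation/test gene split
#'
#' @param train_ids,val_ids,test_ids Pairwise-disjoint gene-ID vectors.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_ids, val_ids, test_ids) {
  all <- c(train_ids, val_ids, test_ids)
  if (anyDuplicated(all))
    stop("split_spec: partitions must be pairwise disjoint")
  structure(list(train = as.character(train_ids), val = as.character(val_ids),
                 test = as.character(test_ids)),
            class = "split_spec")
}

#' Read/write a gene split file
#'
#' Two-column TSV: `gene_id`, `partition` in `{train, val, test}`.
#'
#' @param path TSV path.
#' @return A [split_spec()].
#' @export
read_split <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "partition") %in% names(df)))
  bad <- setdiff(unique(df$partition), c("train", "val", "test"))
  if (length(bad))
    stop(sprintf("read_split: unknown partition label(s): %s", paste(bad, collapse = ", ")))
  split_spec(df$gene_id[df$partition == "train"],
             df$gene_id[df$partition == "val"],
             df$gene_id[df$partition == "test"])
}

#' @rdname read_split
#' @param split A [split_spec()].
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    gene_id = c(split$train, split$val, split$test),
    partition = rep(c("train", "val", "test"),
                    c(length(split$train), length(split$val), length(split$test))),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write TSS-centered gene windows as FASTA
#'
#' Window FASTA records are named `gene_id strand=+/-`; reading returns the
#' `data.frame(gene_id, sequence, strand)` gene-record table used
#' downstream.
#'
#' @param path FASTA path.
#' @return `data.frame(gene_id, sequence, strand)`.
#' @export
read_windows_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  gene_id <- sub("\\s.*$", "", nm)
  strand <- ifelse(grepl("strand=-", nm), "-", "+")
  data.frame(gene_id = unname(gene_id),
             sequence = unname(toupper(as.character(ss))),
             strand = unname(strand), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @rdname read_windows_fasta
#' @param records `data.frame(gene_id, sequence, strand)`.
#' @export
write_windows_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- paste0(records$gene_id, " strand=", records$strand)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a TSS coordinate table
#'
#' BED-like 4-column TSV: `chrom`, `tss` (0-based), `strand`, `gene_id`.
#'
#' @param path TSV path.
#' @return `data.frame(chrom, tss, strand, gene_id)`.
#' @export
read_tss_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "tss", "strand", "gene_id") %in% names(df)))
  df$tss <- as.integer(df$tss)
  if (any(is.na(df$tss) | df$tss < 0)) stop("read_tss_table: invalid TSS coordinates")
  if (!all(df$strand %in% c("+", "-"))) stop("read_tss_table: strand must be + or -")
  df
}

#' Extract all gene windows from a genome
#'
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param tss_table Data frame as returned by [read_tss_table()].
#' @param spec A [window_spec()].
#' @param pad_n Pad out-of-bounds windows with `N` instead of erroring.
#' @return `data.frame(gene_id, sequence, strand)`.
#' @export
extract_gene_windows <- function(genome, tss_table, spec = window_spec(),
                                 pad_n = FALSE) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  seqs <- character(nrow(tss_table))
  for (i in seq_len(nrow(tss_table))) {
    chrom <- tss_table$chrom[i]
    if (!chrom %in% names(genome))
      stop(sprintf("extract_gene_windows: unknown chromosome '%s' for gene %s",
                   chrom, tss_table$gene_id[i]))
    seqs[i] <- extract_window(genome[[chrom]], tss_table$tss[i],
                              tss_table$strand[i], spec,
                              gene_id = tss_table$gene_id[i], pad_n = pad_n)
  }
  data.frame(gene_id = tss_table$gene_id, sequence = seqs,
             strand = tss_table$strand, stringsAsFactors = FALSE)
}
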