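BASES <- c("A", "C", "G", "T")

seq_to_codes <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(chars, BASES)          # NA for anything not A/C/G/T
  bad <- which(is.na(codes) & chars != "N")
  if (length(bad))
    stop(sprintf("one_hot: invalid character '%s' at position %d",
                 chars[bad[1]], bad[1]))
  codes[is.na(codes)] <- 0L
  as.integer(codes)
}

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence over `{A,C,G,T,N}` (case-insensitive) as a `W x 4`
#' binary matrix with column order A, C, G, T. `N` (and only `N`) maps to
#' the all-zero row; any other character is an error naming its position.
#'
#' @param sequence DNA string.
#' @return Integer matrix of shape `nchar(sequence) x 4`, colnames
#'   `A,C,G,T`.
#' @export
one_hot <- function(sequence) {
  codes <- seq_to_codes(sequence)
  m <- matrix(0L, nrow = length(codes), ncol = 4L,
              dimnames = list(NULL, BASES))
  nz <- which(codes > 0L)
  m[cbind(nz, codes[nz])] <- 1L
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot()]; all-zero rows decode to `N`.
#'
#' @param m `W x 4` one-hot matrix, column order A,C,G,T.
#' @return DNA string.
#' @export
decode_one_hot <- function(m) {
  stopifnot(ncol(m) == 4)
  idx <- max.col(m, ties.method = "first")
  idx[rowSums(m) == 0] <- 5L
  paste(c(BASES, "N")[idx], collapse = "")
}

# n_genes x W integer code matrix (0 = N) for a character vector of
# equal-length sequences; rows named by gene_id
seqs_to_code_matrix <- function(sequences, gene_ids) {
  W <- unique(nchar(sequences))
  if (length(W) != 1)
    stop("all sequences must have equal length (one window spec)")
  m <- matrix(0L, nrow = length(sequences), ncol = W,
              dimnames = list(gene_ids, NULL))
  for (i in seq_along(sequences)) m[i, ] <- seq_to_codes(sequences[i])
  m
}

#' Per-gene miRNA feature vector
#'
#' Builds the vector `x` for one gene: `x[i]` is the expression level of
#' the i-th miRNA of `mirna_order` if that miRNA targets the gene, and
#' exactly 0 otherwise. The CWCS is deliberately not encoded here — it is
#' consumed only by the selection stage.
#'
#' @param gene_id Gene identifier.
#' @param mirna_order Character vector fixing the miRNA positions.
#' @param targets Target table `data.frame(mirna_id, gene_id, cwcs)`.
#' @param mirna_expr Named numeric vector of miRNA expression levels
#'   (log-normalized mean expression); must cover `mirna_order`.
#' @return Numeric vector of length `length(mirna_order)`, named by miRNA.
#' @export
build_mirna_vector <- function(gene_id, mirna_order, targets, mirna_expr) {
  missing <- setdiff(mirna_order, names(mirna_expr))
  if (length(missing))
    stop(sprintf("build_mirna_vector: no expression value for miRNA(s): %s",
                 paste(missing, collapse = ", ")))
  hits <- unique(targets$mirna_id[targets$gene_id == gene_id])
  x <- numeric(length(mirna_order))
  names(x) <- mirna_order
  on <- mirna_order %in% hits
  x[on] <- as.numeric(mirna_expr[mirna_order[on]])
  x
}

#' Gene x miRNA feature matrix
#'
#' [build_mirna_vector()] applied over a gene set; row per gene, column
#' per miRNA in `mirna_order`.
#'
#' @inheritParams build_mirna_vector
#' @param gene_ids Character vector of gene IDs (rows).
#' @return Numeric matrix `length(gene_ids) x length(mirna_order)`.
#' @export
build_mirna_matrix <- function(gene_ids, mirna_order, targets, mirna_expr) {
  missing <- setdiff(mirna_order, names(mirna_expr))
  if (length(missing))
    stop(sprintf("build_mirna_matrix: no expression value for miRNA(s): %s",
                 paste(missing, collapse = ", ")))
  m <- matrix(0, nrow = length(gene_ids), ncol = length(mirna_order),
              dimnames = list(gene_ids, mirna_order))
  keep <- targets$gene_id %in% gene_ids & targets$mirna_id %in% mirna_order
  t2 <- unique(targets[keep, c("mirna_id", "gene_id")])
  if (nrow(t2))
    m[cbind(match(t2$gene_id, gene_ids), match(t2$mirna_id, mirna_order))] <-
      as.numeric(mirna_expr[t2$mirna_id])
  m
}

#' Assemble model-ready train/validation/test batches
#'
#' Joins sequence windows, half-life features and miRNA feature vectors
#' into the three batches the model trains on. Row order within each
#' partition is deterministic (genes sorted lexicographically), so the
#' output is invariant to the input record order.
#'
#' Sequences are stored as compact integer base codes (0 = N, 1..4 =
#' A,C,G,T), the exact sparse equivalent of the one-hot matrix that
#' [one_hot()] produces; the model core expands them on the fly.
#'
#' @param records `data.frame(gene_id, sequence, strand)`.
#' @param features Half-life/target table from [read_halflife()].
#' @param mirna_matrix Gene x miRNA matrix from [build_mirna_matrix()], or
#'   `NULL` for the baseline (zero miRNA columns).
#' @param split A [split_spec()].
#' @return List with `train`, `val`, `test`, each a list of `seq_codes`
#'   (n x W integer), `halflife` (n x 8), `mirna` (n x K), `y` (length n),
#'   `gene_ids`; plus `window_width` and `mirna_order`.
#' @export
assemble_dataset <- function(records, features, mirna_matrix = NULL, split) {
  stopifnot(inherits(split, "split_spec"))
  wanted <- c(split$train, split$val, split$test)
  miss_seq <- setdiff(wanted, records$gene_id)
  miss_feat <- setdiff(wanted, features$gene_id)
  miss_mir <- if (is.null(mirna_matrix)) character() else
    setdiff(wanted, rownames(mirna_matrix))
  if (length(c(miss_seq, miss_feat, miss_mir)))
    stop(sprintf(
      "assemble_dataset: genes missing a block — sequence: %s; features: %s; miRNA: %s",
      paste(head(miss_seq, 5), collapse = ","),
      paste(head(miss_feat, 5), collapse = ","),
      paste(head(miss_mir, 5), collapse = ",")))
  hl <- as.matrix(features[, HALFLIFE_FEATURES])
  rownames(hl) <- features$gene_id
  y <- setNames(features$y, features$gene_id)
  seqs <- setNames(records$sequence, records$gene_id)

  one_batch <- function(ids) {
    ids <- sort(ids)
    K <- if (is.null(mirna_matrix)) 0L else ncol(mirna_matrix)
    mir <- if (K > 0) mirna_matrix[ids, , drop = FALSE] else
      matrix(0, nrow = length(ids), ncol = 0, dimnames = list(ids, NULL))
    list(seq_codes = seqs_to_code_matrix(seqs[ids], ids),
         halflife = hl[ids, , drop = FALSE],
         mirna = mir,
         y = y[ids],
         gene_ids = ids)
  }
  out <- list(train = one_batch(split$train),
              val = one_batch(split$val),
              test = one_batch(split$test))
  out$window_width <- ncol(out$train$seq_codes)
  out$mirna_order <- if (is.null(mirna_matrix)) character() else colnames(mirna_matrix)
  out
}

#' Restrict a dataset to a subset of miRNA columns
#'
#' Used to derive the selected-miRNA variants from the all-miRNA dataset
#' without re-encoding sequences.
#'
#' @param dataset Output of [assemble_dataset()].
#' @param mirna_ids miRNA columns to keep (order preserved as given); use
#'   `character()` for the baseline.
#' @return A dataset with the miRNA blocks subset.
#' @export
subset_mirnas <- function(dataset, mirna_ids) {
  missing <- setdiff(mirna_ids, dataset$mirna_order)
  if (length(missing))
    stop(sprintf("subset_mirnas: unknown miRNA(s): %s", paste(missing, collapse = ", ")))
  for (part in c("train", "val", "test"))
    dataset[[part]]$mirna <- dataset[[part]]$mirna[, mirna_ids, drop = FALSE]
  dataset$mirna_order <- mirna_ids
  dataset
}
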