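test_that("one-hot encoding follows the A,C,G,T column order with N as zero row", {
  expect_equal(unname(one_hot("ACGT")), diag(4), ignore_attr = TRUE)
  expect_equal(unname(one_hot("N")), matrix(0L, 1, 4))
  expect_equal(one_hot("acgtn"), one_hot("ACGTN"))
  expect_error(one_hot("ACXG"), "position 3")
  m <- one_hot("ACGTN")
  expect_equal(rowSums(m), c(1, 1, 1, 1, 0))
})

test_that("decoding inverts encoding", {
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    expect_equal(decode_one_hot(one_hot(s)), s)
  }
  expect_equal(decode_one_hot(one_hot("ACNNGT")), "ACNNGT")
})

test_that("the per-gene miRNA vector carries expression where targeting exists and exact zeros elsewhere", {
  # toy pattern: each gene targeted by exactly one miRNA
  order3 <- c("miRNA_1", "miRNA_2", "miRNA_3")
  expr <- c(miRNA_1 = 1.10, miRNA_2 = 1.34, miRNA_3 = 1.26)
  targets <- data.frame(mirna_id = c("miRNA_2", "miRNA_3", "miRNA_1"),
                        gene_id = c("Gene_1", "Gene_2", "Gene_3"),
                        cwcs = c(-0.3, -0.2, -0.4), stringsAsFactors = FALSE)
  expect_equal(unname(build_mirna_vector("Gene_1", order3, targets, expr)),
               c(0, 1.34, 0))
  expect_equal(unname(build_mirna_vector("Gene_2", order3, targets, expr)),
               c(0, 0, 1.26))
  expect_equal(unname(build_mirna_vector("Gene_3", order3, targets, expr)),
               c(1.10, 0, 0))
  # untargeted gene: all-zero vector
  expect_equal(unname(build_mirna_vector("Gene_9", order3, targets, expr)),
               c(0, 0, 0))
  # gene targeted by every miRNA: vector equals the expression vector
  all_t <- data.frame(mirna_id = order3, gene_id = "Gene_1",
                      cwcs = -0.1, stringsAsFactors = FALSE)
  expect_equal(build_mirna_vector("Gene_1", order3, all_t, expr), expr)
  expect_error(build_mirna_vector("Gene_1", c(order3, "miRNA_9"), targets, expr),
               "miRNA_9")
})

test_that("nonzero entries of a miRNA vector equal the gene's target count when expressions are nonzero", {
  set.seed(9)
  mirnas <- sprintf("m%02d", 1:15)
  expr <- setNames(runif(15, 0.5, 2), mirnas)
  for (rep in 1:10) {
    hits <- sample(mirnas, sample(0:15, 1))
    targets <- if (length(hits))
      data.frame(mirna_id = hits, gene_id = "g", cwcs = -0.1) else
      data.frame(mirna_id = character(), gene_id = character(), cwcs = numeric())
    v <- build_mirna_vector("g", mirnas, targets, expr)
    expect_equal(sum(v != 0), length(hits))
  }
})

test_that("the miRNA matrix agrees with per-gene vectors", {
  set.seed(10)
  genes <- sprintf("g%d", 1:6)
  mirnas <- sprintf("m%d", 1:4)
  expr <- setNames(runif(4, 1, 2), mirnas)
  targets <- data.frame(mirna_id = sample(mirnas, 8, replace = TRUE),
                        gene_id = sample(genes, 8, replace = TRUE),
                        cwcs = -runif(8), stringsAsFactors = FALSE)
  m <- build_mirna_matrix(genes, mirnas, targets, expr)
  for (g in genes)
    expect_equal(m[g, ], build_mirna_vector(g, mirnas, targets, expr))
})

make_toy_inputs <- function(n = 10, W = 30, K = 3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(n))
  records <- data.frame(
    gene_id = ids,
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), W, replace = TRUE), collapse = ""),
      character(1)),
    strand = "+", stringsAsFactors = FALSE)
  hl <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, mirex:::HALFLIFE_FEATURES))
  features <- data.frame(gene_id = ids, hl, y = rnorm(n), stringsAsFactors = FALSE)
  mirnas <- sprintf("m%d", seq_len(K))
  mm <- build_mirna_matrix(ids, mirnas,
                           data.frame(mirna_id = rep(mirnas, 2),
                                      gene_id = sample(ids, 2 * K, replace = TRUE),
                                      cwcs = -0.5),
                           setNames(runif(K, 1, 2), mirnas))
  split <- if (n >= 10) split_spec(ids[1:6], ids[7:8], ids[9:10]) else NULL
  list(records = records, features = features, mm = mm, split = split)
}

test_that("dataset assembly is deterministic and invariant to input row order", {
  ti <- make_toy_inputs()
  ds <- assemble_dataset(ti$records, ti$features, ti$mm, ti$split)
  expect_equal(dim(ds$train$seq_codes), c(6, 30))
  expect_equal(dim(ds$val$halflife), c(2, 8))
  expect_equal(ncol(ds$test$mirna), 3)
  # code matrix matches one_hot on the decoded sequence
  g1 <- ds$train$gene_ids[1]
  s1 <- ti$records$sequence[ti$records$gene_id == g1]
  oh <- one_hot(s1)
  codes <- ds$train$seq_codes[1, ]
  expect_equal(which(oh[5, ] == 1), unname(codes[5]), ignore_attr = TRUE)

  perm <- sample(nrow(ti$records))
  ds2 <- assemble_dataset(ti$records[perm, ], ti$features[sample(10), ],
                          ti$mm, ti$split)
  expect_identical(ds, ds2)
})

test_that("assembly with a 1/1/1 split, a zero-miRNA block, and missing genes behaves per contract", {
  ti <- make_toy_inputs(n = 3)
  sp <- split_spec("g01", "g02", "g03")
  ds <- assemble_dataset(ti$records, ti$features, NULL, sp)
  expect_equal(nrow(ds$train$seq_codes), 1)
  expect_equal(ncol(ds$train$mirna), 0)
  expect_equal(ds$mirna_order, character())

  sp_bad <- split_spec("g01", "g02", c("g03", "g99"))
  expect_error(assemble_dataset(ti$records, ti$features, NULL, sp_bad), "g99")
})

test_that("subsetting miRNA columns preserves values and rejects unknown IDs", {
  ti <- make_toy_inputs()
  ds <- assemble_dataset(ti$records, ti$features, ti$mm, ti$split)
  sub <- subset_mirnas(ds, c("m3", "m1"))
  expect_equal(colnames(sub$train$mirna), c("m3", "m1"))
  expect_equal(sub$train$mirna[, "m3"], ds$train$mirna[, "m3"])
  expect_error(subset_mirnas(ds, "m9"), "m9")
})
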