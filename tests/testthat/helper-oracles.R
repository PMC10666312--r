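# Independent brute-force oracles, kept free of package internals.

# reverse complement by explicit character mapping
revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# average ranks computed from scratch (sort-based, ties averaged)
rank_oracle <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Spearman rho = Pearson on average ranks, Pearson by the sum formula
spearman_oracle <- function(a, b) {
  ra <- rank_oracle(a)
  rb <- rank_oracle(b)
  n <- length(a)
  num <- sum(ra * rb) - n * mean(ra) * mean(rb)
  den <- sqrt((sum(ra^2) - n * mean(ra)^2) * (sum(rb^2) - n * mean(rb)^2))
  num / den
}

r_squared_oracle <- function(y, yhat) {
  rss <- 0
  tss <- 0
  for (i in seq_along(y)) {
    rss <- rss + (y[i] - yhat[i])^2
    tss <- tss + (y[i] - mean(y))^2
  }
  1 - rss / tss
}

# model-ready batch built by hand (bypasses assemble_dataset)
make_batch <- function(n, W, K = 0, seed = 1, y = NULL) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n))
  codes <- matrix(sample(1:4, n * W, replace = TRUE), n, W,
                  dimnames = list(ids, NULL))
  storage.mode(codes) <- "integer"
  hl <- matrix(rnorm(n * 8), n, 8,
               dimnames = list(ids, mirex:::HALFLIFE_FEATURES))
  mir <- matrix(if (K > 0) abs(rnorm(n * K)) else numeric(0), n, K,
                dimnames = list(ids, if (K > 0) sprintf("m%02d", 1:K)))
  if (is.null(y)) y <- rnorm(n)
  list(seq_codes = codes, halflife = hl, mirna = mir,
       y = setNames(y, ids), gene_ids = ids)
}

tiny_model_cfg <- function(W = 60, K = 0, blocks = list(c(4, 5, 1, 5)),
                           dense = 8) {
  model_config(window = W, conv_blocks = blocks, dense_units = dense,
               dropout = 0, k_mirnas = K)
}
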