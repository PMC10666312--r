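test_that("Spearman rho matches hand-computed values and the brute-force oracle", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  # ranks (1,2,3) vs (3,1,2): Pearson on ranks = -0.5
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)),
               spearman_oracle(c(1, 2, 3), c(3, 1, 2)))
  set.seed(21)
  for (i in 1:50) {
    a <- rnorm(15)
    b <- if (i %% 2) rnorm(15) else round(rnorm(15))   # with ties
    expect_equal(spearman_rho(a, b), spearman_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(spearman_rho(1:2, 1:2), "3")
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
})

make_screen <- function(seed = 1, n_genes = 400, n_planted = 5, n_decoy = 15,
                        targets_per = 50) {
  set.seed(seed)
  genes <- sprintf("g%03d", 1:n_genes)
  residuals <- setNames(rnorm(n_genes, 0, 0.3), genes)
  mk <- function(mid, planted) {
    tg <- sample(genes, targets_per)
    cwcs <- -abs(rnorm(targets_per, 0, 0.3))
    if (planted)    # residual tracks CWCS for planted miRNAs
      residuals[tg] <<- 0.8 * cwcs + rnorm(targets_per, 0, 0.05)
    data.frame(mirna_id = mid, gene_id = tg, cwcs = cwcs,
               stringsAsFactors = FALSE)
  }
  planted_ids <- sprintf("mir_p%02d", 1:n_planted)
  decoy_ids <- sprintf("mir_d%02d", 1:n_decoy)
  targets <- rbind(
    do.call(rbind, lapply(planted_ids, mk, planted = TRUE)),
    do.call(rbind, lapply(decoy_ids, mk, planted = FALSE)))
  list(residuals = residuals, targets = targets, planted = planted_ids)
}

test_that("ranking recovers planted repressors and matches an exhaustive rho recomputation", {
  sc <- make_screen(seed = 42)
  res <- rank_mirnas(sc$residuals, sc$targets, "signed", min_targets = 10)
  expect_equal(sort(res$ranked$mirna_id[1:5]), sort(sc$planted))
  expect_true(all(diff(res$ranked$rho) <= 0))
  expect_true(all(res$ranked$rho >= -1 & res$ranked$rho <= 1))
  # oracle: recompute every rho by brute force
  for (i in seq_len(nrow(res$ranked))) {
    mid <- res$ranked$mirna_id[i]
    tg <- sc$targets[sc$targets$mirna_id == mid, ]
    expect_equal(res$ranked$rho[i],
                 spearman_oracle(sc$residuals[tg$gene_id], tg$cwcs),
                 tolerance = 1e-12)
    expect_equal(res$ranked$n_targets[i], nrow(tg))
  }
})

test_that("a perfectly monotone miRNA ranks first with rho one", {
  genes <- sprintf("g%d", 1:20)
  residuals <- setNames(seq(-1, 1, length.out = 20), genes)
  targets <- rbind(
    data.frame(mirna_id = "mir_mono", gene_id = genes,
               cwcs = seq(-2, 0, length.out = 20)),
    data.frame(mirna_id = "mir_rand", gene_id = genes,
               cwcs = rep(c(-1, -0.2), 10)))
  res <- rank_mirnas(residuals, targets, "signed", min_targets = 10)
  expect_equal(res$ranked$mirna_id[1], "mir_mono")
  expect_equal(res$ranked$rho[1], 1)
})

test_that("miRNAs below the minimum target count are ineligible", {
  genes <- sprintf("g%d", 1:30)
  residuals <- setNames(rnorm(30), genes)
  targets <- rbind(
    data.frame(mirna_id = "mir_small", gene_id = genes[1:2], cwcs = -0.5),
    data.frame(mirna_id = "mir_big", gene_id = genes, cwcs = -runif(30)))
  res <- rank_mirnas(residuals, targets, "signed", min_targets = 3)
  expect_equal(res$ranked$mirna_id, "mir_big")
  expect_true("mir_small" %in% res$excluded)
})

test_that("signed and absolute modes agree when all residuals are nonnegative", {
  sc <- make_screen(seed = 7)
  res_pos <- abs(sc$residuals)
  s <- rank_mirnas(res_pos, sc$targets, "signed", min_targets = 10)
  a <- rank_mirnas(res_pos, sc$targets, "absolute", min_targets = 10)
  expect_equal(s$ranked, a$ranked)
})

test_that("top-k selection is stable with lexicographic tie-breaks", {
  genes <- sprintf("g%d", 1:12)
  residuals <- setNames(seq_len(12), genes)
  # two miRNAs with identical target sets -> identical rho (exact tie)
  targets <- rbind(
    data.frame(mirna_id = "mir_b", gene_id = genes, cwcs = seq(-1.2, -0.1, length.out = 12)),
    data.frame(mirna_id = "mir_a", gene_id = genes, cwcs = seq(-1.2, -0.1, length.out = 12)),
    data.frame(mirna_id = "mir_c", gene_id = genes, cwcs = rev(seq(-1.2, -0.1, length.out = 12))))
  res <- rank_mirnas(residuals, targets, "signed", min_targets = 10)
  expect_equal(res$ranked$rho[1], res$ranked$rho[2])
  expect_equal(res$ranked$mirna_id[1:2], c("mir_a", "mir_b"))
  expect_equal(select_top_k(res, 2), c("mir_a", "mir_b"))
  expect_warning(got <- select_top_k(res, 10), "eligible")
  expect_equal(got, res$ranked$mirna_id)
  expect_identical(select_top_k(res, 2), select_top_k(res, 2))
})

test_that("an empty target table yields an empty ranking with a warning", {
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      cwcs = numeric())
  expect_warning(res <- rank_mirnas(c(g1 = 0.1, g2 = -0.2, g3 = 0), empty), "empty")
  expect_equal(nrow(res$ranked), 0)
})

test_that("baseline residual extraction passes through and averages linearly", {
  stub_run <- function(res, seed = 1) structure(
    list(residuals = res, seed = seed, r2_val = 0.5), class = "mirex_run")
  r <- c(g1 = 1, g2 = -1, g3 = 0.5)
  expect_equal(residuals_from_baseline(stub_run(r)), r)
  expect_error(residuals_from_baseline(stub_run(r), gene_ids = c("g1", "g9")), "g9")
  # mean of residual maps equals residuals of mean predictions (linearity)
  runs <- list(stub_run(r), stub_run(r * 3), stub_run(r - 1))
  avg <- residuals_from_baseline(runs)
  expect_equal(avg, (r + r * 3 + (r - 1)) / 3)
})

test_that("selection TSV export flags the top-k", {
  sc <- make_screen(seed = 3)
  res <- rank_mirnas(sc$residuals, sc$targets, "signed", min_targets = 10)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_selection(res, tf, k = 5)
  back <- read.delim(tf)
  expect_equal(sum(back$selected), 5)
  expect_equal(back$mirna_id[back$selected == 1], res$ranked$mirna_id[1:5])
})
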