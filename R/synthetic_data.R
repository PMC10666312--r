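#' Synthetic dataset configuration
#'
#' Defines a fully synthetic study with known ground truth carrying the
#' statistical structure the model assumes: promoter windows with planted
#' motifs of additive effect, eight half-life covariates with linear
#' coefficients, and a set of miRNAs of which `n_planted` causally repress
#' their targets on the log-expression scale proportionally to
#' `|CWCS| * miRNA log-expression`, while the remaining decoys carry
#' target annotations (with identically distributed CWCS) but no causal
#' effect.
#'
#' @param n_genes Number of genes (default 2000).
#' @param window A [window_spec()]; toy default 300 + 700 = 1000 bases.
#' @param n_mirnas Number of miRNAs (default 20).
#' @param n_planted Number of causally repressive miRNAs (default 5).
#' @param targets_per_mirna Target genes per miRNA (default 50).
#' @param motif_effects List of `list(motif = <string>, coef = <effect>)`;
#'   each motif is planted in half the genes and adds `coef` to their
#'   log-expression.
#' @param halflife_coeffs Eight linear coefficients for the half-life
#'   covariates (standard-normal simulated).
#' @param repression_scale Log10-expression units of repression per unit
#'   `|CWCS| * miRNA log-expression` (default 1.5).
#' @param noise_sd Gaussian noise SD on log-expression (default 0.35).
#' @param n_samples miRNA expression samples drawn per miRNA (default 30).
#' @param intercept Baseline log10 expression level (default 2).
#' @param split_frac Train/val/test fractions (default 0.8/0.1/0.1).
#' @param seed Integer seed; identical configs generate identical data.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_genes = 2000, window = window_spec(300, 700),
                       n_mirnas = 20, n_planted = 5, targets_per_mirna = 50,
                       motif_effects = list(
                         list(motif = "TATAAAGC", coef = 0.5),
                         list(motif = "GCCACGTG", coef = -0.4)),
                       halflife_coeffs = c(0.45, -0.25, 0.35, -0.2,
                                           0.3, -0.15, 0.2, 0.1),
                       repression_scale = 1.5, noise_sd = 0.35,
                       n_samples = 30, intercept = 2,
                       split_frac = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(n_genes >= 10, n_mirnas >= 0, n_planted >= 0,
            n_planted <= n_mirnas, length(halflife_coeffs) == 8,
            repression_scale > 0, noise_sd >= 0, n_samples >= 1,
            length(split_frac) == 3, abs(sum(split_frac) - 1) < 1e-8)
  if (n_mirnas > 0 && targets_per_mirna > n_genes)
    stop("sim_config: targets_per_mirna exceeds n_genes")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic dataset with known ground truth
#'
#' Sequences are i.i.d. uniform A/C/G/T; each configured motif is planted
#' (at a random position inside its own half of the window, so motifs
#' never overwrite each other) in a random half of the genes and adds its
#' coefficient to the gene's log-expression. Half-life covariates are
#' standard normal with linear contribution. miRNA raw counts are Poisson
#' draws around a per-miRNA abundance, and the miRNA log-expression the
#' pipeline computes (`lognorm` of the mean count) is exactly the value
#' used in the causal repression term, so the planted effect is what the
#' model can see. Planted miRNAs subtract
#' `repression_scale * |CWCS| * log-expression` from each target gene;
#' decoys have target records with identically distributed CWCS but no
#' effect. Gaussian noise completes the target:
#' `y = intercept + motif + halflife - repression + noise`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `records` (gene windows), `features` (half-life + `y`),
#'   `mirna_counts` ([expression_matrix()] of raw counts),
#'   `mirna_expr` (named log-expression vector), `targets`, `split`
#'   ([split_spec()]), `truth` (planted IDs and per-gene deterministic
#'   components).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(cfg$seed)
  W <- cfg$window$width
  n <- cfg$n_genes
  gene_ids <- sprintf("gene_%04d", seq_len(n))

  base_mat <- matrix(sample(BASES, n * W, replace = TRUE), nrow = n)
  seqs <- apply(base_mat, 1, paste, collapse = "")

  # motifs: region half h of the window per motif, planted in half the genes
  motif_term <- numeric(n)
  n_motifs <- length(cfg$motif_effects)
  for (mi in seq_len(n_motifs)) {
    me <- cfg$motif_effects[[mi]]
    mlen <- nchar(me$motif)
    region_len <- W %/% max(1, n_motifs)
    lo <- (mi - 1) * region_len + 1
    hi <- min(W, mi * region_len) - mlen
    if (hi < lo) stop("generate_dataset: window too short for motif region")
    carriers <- sample(n, n %/% 2)
    pos <- sample(lo:hi, length(carriers), replace = TRUE)
    for (j in seq_along(carriers)) {
      g <- carriers[j]
      substr(seqs[g], pos[j], pos[j] + mlen - 1) <- me$motif
    }
    motif_term[carriers] <- motif_term[carriers] + me$coef
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  records <- data.frame(gene_id = gene_ids, sequence = seqs,
                        strand = strand, stringsAsFactors = FALSE)

  hl <- matrix(rnorm(n * 8), nrow = n,
               dimnames = list(gene_ids, HALFLIFE_FEATURES))
  halflife_term <- as.numeric(hl %*% cfg$halflife_coeffs)

  # miRNAs: planted first, then decoys; Poisson raw counts around a fixed
  # per-miRNA abundance so the pipeline-computed log-expression is exact
  K <- cfg$n_mirnas
  mirna_ids <- if (K > 0) sprintf("mir_%03d", seq_len(K)) else character()
  planted <- mirna_ids[seq_len(cfg$n_planted)]
  repression_term <- numeric(n)
  names(repression_term) <- gene_ids
  targets <- data.frame(mirna_id = character(), gene_id = character(),
                        cwcs = numeric(), stringsAsFactors = FALSE)
  mirna_counts <- NULL
  mirna_expr <- numeric()
  if (K > 0) {
    abundance_log <- runif(K, 0.8, 2.2)
    counts <- matrix(rpois(K * cfg$n_samples, lambda = 10^abundance_log - 0.1),
                     nrow = K,
                     dimnames = list(mirna_ids,
                                     sprintf("sample_%02d", seq_len(cfg$n_samples))))
    mirna_counts <- expression_matrix(counts)
    mirna_expr <- mirna_log_expression(mirna_counts)
    tg <- lapply(mirna_ids, function(mid) {
      idx <- sample(n, cfg$targets_per_mirna)
      data.frame(mirna_id = mid, gene_id = gene_ids[idx],
                 cwcs = -abs(rnorm(cfg$targets_per_mirna, 0, 0.3)),
                 stringsAsFactors = FALSE)
    })
    targets <- do.call(rbind, tg)
    for (mid in planted) {
      tt <- targets[targets$mirna_id == mid, ]
      eff <- cfg$repression_scale * abs(tt$cwcs) * mirna_expr[[mid]]
      repression_term[tt$gene_id] <- repression_term[tt$gene_id] + eff
    }
  }

  noise <- rnorm(n, 0, cfg$noise_sd)
  y <- cfg$intercept + motif_term + halflife_term - repression_term + noise
  features <- data.frame(gene_id = gene_ids, hl, y = y,
                         row.names = NULL, stringsAsFactors = FALSE)

  perm <- sample(n)
  n_tr <- round(cfg$split_frac[1] * n)
  n_va <- round(cfg$split_frac[2] * n)
  split <- split_spec(gene_ids[perm[seq_len(n_tr)]],
                      gene_ids[perm[n_tr + seq_len(n_va)]],
                      gene_ids[perm[(n_tr + n_va + 1):n]])

  truth <- list(planted_mirnas = planted,
                motif_term = setNames(motif_term, gene_ids),
                halflife_term = setNames(halflife_term, gene_ids),
                repression_term = repression_term,
                noise = setNames(noise, gene_ids),
                intercept = cfg$intercept,
                mirna_expr = mirna_expr,
                y = setNames(y, gene_ids))
  list(records = records, features = features, mirna_counts = mirna_counts,
       mirna_expr = mirna_expr, targets = targets, split = split,
       truth = truth, config = cfg)
}

#' miRNA log-expression from raw counts
#'
#' Mean raw count per miRNA across all samples, then the `log10(x + 0.1)`
#' transform (mean-then-log order).
#'
#' @param counts An [expression_matrix()] of miRNA raw counts.
#' @return Named numeric vector of log-expression values.
#' @export
mirna_log_expression <- function(counts) {
  groups <- list(all = colnames(counts))
  m <- mean_expression(counts, groups, overall = TRUE)
  setNames(lognorm(m[, "overall"]), rownames(counts))
}

#' Score a selection against the planted truth
#'
#' @param selection A `selection_result`, or a character vector of
#'   selected miRNA IDs.
#' @param truth The `truth` element of [generate_dataset()] output.
#' @param k Top-k used when `selection` is a `selection_result`.
#' @return List: `recovered` (count of planted miRNAs selected),
#'   `precision`, `recall`.
#' @export
truth_eval <- function(selection, truth, k = 10) {
  selected <- if (inherits(selection, "selection_result"))
    select_top_k(selection, k) else as.character(selection)
  planted <- truth$planted_mirnas
  rec <- length(intersect(selected, planted))
  list(recovered = rec,
       precision = if (length(selected)) rec / length(selected) else NA_real_,
       recall = if (length(planted)) rec / length(planted) else NA_real_)
}

#' Write/read a synthetic dataset directory
#'
#' Emits the self-contained plain-text layout every pipeline stage reads:
#' `sequences.fa`, `halflife.tsv`, `mirna_expr.tsv` (raw counts),
#' `targets.tsv`, `split.tsv`, `truth.json`.
#'
#' @param sim Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_windows_fasta(sim$records, file.path(dir, "sequences.fa"))
  write_halflife(sim$features, file.path(dir, "halflife.tsv"))
  if (!is.null(sim$mirna_counts))
    write_expression_matrix(sim$mirna_counts, file.path(dir, "mirna_expr.tsv"),
                            id_name = "mirna_id")
  write_targets(sim$targets, file.path(dir, "targets.tsv"))
  write_split(sim$split, file.path(dir, "split.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sim_dataset
#' @return `read_sim_dataset`: a list shaped like [generate_dataset()]
#'   output (without the per-gene noise decomposition unless `truth.json`
#'   is present).
#' @export
read_sim_dataset <- function(dir) {
  counts_path <- file.path(dir, "mirna_expr.tsv")
  counts <- if (file.exists(counts_path)) read_expression_matrix(counts_path) else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(records = read_windows_fasta(file.path(dir, "sequences.fa")),
       features = read_halflife(file.path(dir, "halflife.tsv")),
       mirna_counts = counts,
       mirna_expr = if (is.null(counts)) numeric() else mirna_log_expression(counts),
       targets = read_targets(file.path(dir, "targets.tsv")),
       split = read_split(file.path(dir, "split.tsv")),
       truth = truth)
}
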