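# mirex

Predicting per-gene mRNA expression levels from promoter sequence, mRNA
half-life features and miRNA target repression — with residual-guided
selection of the miRNAs worth including.

## The problem

Sequence-based expression models (convolutional regressors over a
TSS-centered DNA window plus gene-structure "half-life" covariates) ignore
post-transcriptional regulation. miRNAs repress their target mRNAs, so such
a baseline model systematically *over*-predicts repressed genes: the
residual `r = y − ŷ` is negative where repression bites. TargetScan's
Cumulative Weighted Context++ Score (CWCS) is more negative the stronger
the predicted miRNA–target repression. `mirex` exploits the implied
relationship: for each miRNA, it computes the Spearman correlation ρ
between its targets' baseline residuals and their CWCS, keeps the ten
miRNAs with the highest ρ, and retrains with a per-gene feature vector
**x** where `x_i` is miRNA *i*'s log-normalized expression if miRNA *i*
targets the gene and 0 otherwise.

The model is a convolutional network: one-hot `W × 4` sequence → conv/ReLU
/max-pool blocks → flatten → concatenate the 8 half-life values and the K
miRNA features → dense ReLU → linear output, trained with plain SGD on MSE
(batch 32, lr 5e-4, ≤100 epochs, early stopping with patience 20, best
validation weights restored). Performance is `R² = 1 − RSS/TSS` on held-out
genes; each variant is trained 12 times and the best 10 runs by validation
R² are reported as mean ± 95% CI, with Welch t-tests between variants.
Four variants are compared: **baseline** (no miRNAs), **all_mirna** (every
miRNA), **mirex** (top-10 by signed residual–CWCS correlation) and
**abs_corr** (top-10 by |residual|–CWCS correlation).

Everything runs on synthetic data with planted ground truth
(`generate_dataset()`): motifs with additive effects, half-life covariates
with known coefficients, and planted repressive miRNAs whose effect is
`repression_scale × |CWCS| × miRNA log-expression` — so selection and the
four-way comparison are testable end to end without external downloads.
Real data in the standard formats (FASTA windows or genome+TSS table, TSV
expression/target/split tables) flows through the same readers.

## Worked example

```r
library(mirex)

# 2,000 genes, a 243-miRNA screen of which 5 are planted repressors
sim <- generate_dataset(sim_config(n_mirnas = 243, seed = 42))
pl  <- run_pipeline(sim, seed = 42)   # 4 variants x 12 runs, ~10 min on 1 CPU
print(pl$table, digits = 4)
#>     variant mean_r2 ci_low ci_high n_runs p_vs_baseline
#> 1  baseline  0.6595 0.6393  0.6796     10            NA
#> 2 all_mirna  0.5244 0.4853  0.5635     10     8.476e-06
#> 3     mirex  0.6918 0.6819  0.7017     10     6.169e-03
#> 4  abs_corr  0.6539 0.6418  0.6661     10     6.028e-01

truth_eval(pl$selected$mirex, sim$truth)
#> $recovered
#> [1] 5
#> $precision
#> [1] 0.5
#> $recall
#> [1] 1

head(pl$selection$signed$ranked, 5)
#>   mirna_id       rho n_targets
#> 1  mir_004 0.7733860        45
#> 2  mir_001 0.7221092        46
#> 3  mir_005 0.5443270        44
#> 4  mir_002 0.4204216        45
#> 5  mir_003 0.4168363        46
```

Reading: the signed selection ranked all 5 planted repressors in its top 5
(`recall = 1`), and retraining with the selected miRNA features lifted
mean test R² from 0.660 to 0.692 (Welch p ≈ 0.006), while feeding the
model *all* 243 mostly-zero miRNA columns degraded it to 0.524 — the
sparse-vector collapse the selection step exists to avoid.
`run_pipeline(..., out_dir = ...)` persists per-run checkpoints, selection
TSVs and the report, and resumes from them on rerun.

A thin command-line wrapper ships in `inst/scripts/mirex.R`
(`simulate` / `run-all` subcommands).

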