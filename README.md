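# ramrsgl

Robust adaptive multinomial regression with sparse group lasso (RAMRSGL)
for multiclass cancer classification and gene selection from expression
matrices.

## The problem

Expression-based cancer diagnosis is a multiclass problem with tens of
samples, thousands of genes, and gross entry-wise corruption. Group
penalties need a biologically meaningful gene grouping — and each cancer
subtype has its own co-expression structure — while the corruption distorts
both clustering and coefficient estimates. `ramrsgl` addresses both in one
pipeline:

1. **Robust PCA** splits the samples-by-genes matrix into a clean low-rank
   part `D` and a sparse noise part `E` (`min ‖D‖* + λ‖E‖₁ s.t. X = D+E`).
2. **Affinity propagation** clusters genes within each class on `D`
   (z-scored profiles, negative squared Euclidean similarity, median
   preference), so every subtype contributes its own group structure.
3. **Overlap expansion** duplicates the `M` genes once per class into a
   `K·M`-column design with block-contiguous groups.
4. **Adaptive weights** `w_j = ‖Ē·j‖₁ + ε` penalize noisy genes more.
5. A **weighted multinomial sparse group lasso** path

   ```
   min  -(1/n) Σᵢ [s_{i,yᵢ} - log Σ_k exp(s_{ik})]
        + (1-α)λ Σ_k Σ_l √m_l ‖β_l^(k)‖₂ + αλ Σ_k Σ_j w_j |β_j^(k)|
   ```

   is fitted by block coordinate descent (compiled, warm-started), with
   `(α, λ)` chosen by stratified cross-validated accuracy; selected genes
   are those with any nonzero coefficient across class copies.

A synthetic-data generator with full ground truth, baseline configurations
(`MRSGL`, `MRGL`, `L1`), repeated-split stability analysis ("key genes"),
TSV readers/writers and a small CLI round out the package.

## Worked example

```r
library(ramrsgl)

sim <- simulate_expression(seed = 2)        # 60 x 120, 3 classes, truth known
run <- ramrsgl_run(sim$dataset$X, sim$dataset$y, seed = 2)
print(run)
#> RAMRSGL fit (RAMRSGL): 39 samples x 120 genes, 3 classes
#>   RPCA: rank(D) = 16, 56.4% noisy entries
#>   groups: 12 (expanded design: 360 columns)
#>   chosen alpha = 0.1, lambda = 0.14528 (CV accuracy 1.000)
#>   selected genes: 38
#>   test accuracy: 0.952 (21 test samples)
```

The fit reports the rank of the clean part, the per-class group structure
(here 12 groups over the 360 expanded columns), the cross-validated
`(α, λ)` choice, and the deduplicated selected genes — in this run 38
genes, all of them members of the planted informative groups, and 95%
held-out accuracy. `predict()`, `coef()`, `plot()` (CV accuracy along the
path) and `summary()` work as for any fitted model object;
`ramrsgl_repeat()` repeats the experiment over random splits and reports
per-gene selection counts and the stable key genes.

A command-line interface over the same functions is in
`inst/cli/ramrsgl.R` (subcommands `simulate`, `decompose`, `cluster`,
`expand`, `fit`, `run`).

See `vignettes/ramrsgl-methods.Rmd` for the model, algorithmic details,
tuning parameters, generator design, and known limitations.

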