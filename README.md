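# ermqsar

Quantitative structure–activity relationship (QSAR) model building by
multiple linear regression on small molecular-descriptor subsets, selected
from a large descriptor pool with the Replacement Method (RM), the Enhanced
Replacement Method (ERM), or exhaustive full search (FS).

The package is written for the common QSAR situation: a few dozen compounds
with measured potencies (here vasorelaxant EC50 values of flavonoids, in
μM), and hundreds of externally computed molecular descriptors of which only
a handful should enter a linear model. It provides the whole modelling
chain:

1. **Activity handling** — EC50 (μM) to pEC50 = −log10(EC50·10⁻⁶)
   transformation, strict train/test split labels, CSV I/O, and an embedded
   35-flavonoid benchmark (`table4_fixture()`, `table1_fixture()`), stored
   exactly as printed with its arithmetic inconsistencies flagged rather
   than repaired.
2. **Descriptor-pool pruning** — constant columns removed
   (`drop_constant()`), then one of every pair with |Pearson r| > 0.75
   (`correlation_prune()`, deterministic keep-the-earlier rule).
3. **Subset selection by SD minimisation** — the objective is the residual
   standard deviation of the OLS fit, SD = √(Σᵢ resᵢ² / (N − d − 1)) on the
   N training compounds with d descriptors plus an intercept.
   `full_search()` enumerates all C(D, d) subsets (the global-optimum
   oracle); `replacement_method()` iteratively swaps the descriptor whose
   coefficient carries the largest relative standard error;
   `enhanced_replacement_method()` adds forced-replacement escape moves and
   returns the best model ever visited.
4. **Validation** — leave-one-out cross-validation, Q² = 1 − PRESS/TSS
   (`loo_cv()`), external test-set R² as squared Pearson correlation
   (`test_set_r2()`), and the overfitting cap keeping d strictly below 20%
   of the training-set size (`max_subset_size()`; 26 training compounds
   admit at most 5 descriptors).
5. **Synthetic benchmark pools** — `generate_pool()` plants a known linear
   model inside a pool with constant columns, intercorrelated blocks and
   Gaussian response noise, so selection and validation can be tested
   against a known truth; `paper_shaped_spec()` reproduces the benchmark
   shape (35 compounds, 26/9 split, ~299 descriptors after pruning, d = 5).

The published five-descriptor flavonoid model is embedded verbatim as
`eq1_model()`:

```
-Log(EC50) = 0.442*H5m - 0.465*SIC2 + 0.287*DISPe - 0.518*Mor03u - 0.574*L3m + 4.376
```

## Worked example

```r
library(ermqsar)

g   <- generate_pool(paper_shaped_spec(seed = 7))  # 35 cmpds, 320-col pool
fit <- qsar_mlr(g$dataset, d = 5, seed = 7)        # prune + ERM + validate
fit
#> QSAR model (ERM selection, seed 7)
#>   pec50 = -0.317*V161 - 0.671*V005 + 0.476*V188 - 0.198*V282 + 0.798*V001 + 3.820
#>   N = 26, d = 5: R2 = 0.939, SD = 0.389, F = 61.8; Q2_loo = 0.906, R2_test = 0.524

g$truth
#> Planted truth: {V001, V002, V003, V004, V005}, noise SD = 0.6, SNR = 3.54
```

The run reads as a cautionary tale the package makes easy to demonstrate:
with 26 training compounds against ~299 candidate descriptors, the selected
model mixes two planted descriptors with three spurious ones and *beats*
the truth on training R² (0.939) and even on post-selection Q² (0.906) —
but the held-out test set (R²_test = 0.524) exposes the overfit. `summary()`,
`coef()`, `predict()`, `residuals()`, `plot()` (observed vs predicted by
split) and `simulate()` work as for any fitted-model object.

The embedded benchmark activities are available directly:

```r
head(table4_fixture()[, c("compound_id", "ec50_uM", "pec50", "predicted", "residual", "split")], 4)
#>   compound_id ec50_uM pec50 predicted residual split
#> 1           1     9.3 5.032     4.977    0.055  test
#> 2           2     4.6 5.337     4.976    0.361 train
#> 3           3    24.0 4.620     4.841   -0.221 train
#> 4         10a     7.6 5.119     5.245   -0.126 train
```

An end-to-end run with file artifacts (pruned pool, prune report, selection
trace, model JSON, validation report, Table-4-shaped predictions, checksum
manifest — byte-reproducible from config + seed):

```r
run_pipeline(run_config(simulate = paper_shaped_spec(seed = 7),
                        d = 5, seed = 7, out_dir = "run1"))
```

or from a shell via the thin wrapper `inst/scripts/qsar-pipeline.R`.

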