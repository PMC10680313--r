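# mtsynergy

Joint neural prediction of **anticancer drug-combination synergy** and
**monotherapy sensitivity** from drug chemistry and cell-line gene
expression, for computational pharmacologists pre-screening combination
spaces before wet-lab work.

## The model

For drugs *A*, *B* on cell line *c*, the network predicts four outputs in
one pass:

* the Loewe-additivity synergy score `s(A,B,c)` (positive = the pair
  inhibits growth beyond dose additivity) and the probability that the
  pair is strongly synergistic (`s > 30`),
* the monotherapy sensitivity `RI(A,c)` (Relative Inhibition: normalized
  log10 area under the single-drug dose-response curve, ~0–100) and the
  probability that the drug is active (`RI > 50`).

Drugs are featurized as 1024-bit hashed circular (Morgan-style, radius 3)
fingerprints concatenated with filtered molecular descriptors; cell lines
as z-scored top-variance log2(TPM+1) expression vectors. Pre-trained
autoencoders compress both (codes of width 128 and 256 by default), and a
shared trunk (two FC layers, batch norm, ReLU) maps each
`[drug code, cell code]` pair to a representation. Representation I‖II of
the two drug orderings feeds the synergy branch; representation I alone
feeds the sensitivity branch; each branch ends in a linear regression head
and a 2-unit softmax head. The loss is the unweighted sum

```
L = MSE_syn + MSE_sen + BCE_syn + BCE_sen
```

Training runs every sample in both drug orders, and reported synergy
predictions average the two orders, so they are exactly symmetric in the
drugs. Generalization is measured with a dual five-fold protocol:
leave-combination-out folds for synergy, independent leave-drug-out folds
for sensitivity, with an in-batch leakage filter so a round's sensitivity
evaluation drugs never contribute sensitivity training signal.

## Worked example

The package ships a seeded generator producing a complete miniature screen
(valid SMILES, TPM matrix with tissues, synergy and sensitivity tables with
signal planted on the engineered features). `run_synthetic_study()` runs
the full pipeline — featurize, pre-train autoencoders, dual five-fold
cross-validation of the multi-task model and of its synergy-only ablation —
and pools out-of-fold metrics:

```r
library(mtsynergy)
study <- run_synthetic_study(seed = 1)   # ~10 min on one CPU
study$metrics
#>          model        task   mse  rmse   pcc roc_auc pr_auc   acc
#> 1         full     synergy  90.6  9.52 0.888   0.957  0.843 0.945
#> 2         full sensitivity 100.7 10.04 0.850   0.914  0.927 0.844
#> 3 only-synergy     synergy  85.9  9.27 0.894   0.959  0.845 0.950
```

Reading the rows: on 9,360 held-out (combination, cell line) samples the
full model explains the planted synergy signal with Pearson correlation
0.888 (MSE 90.6 on the Loewe scale; the irreducible noise floor is 25) and
classifies strong synergy at ROC-AUC 0.957. On held-out *drugs* — the much
harder split — sensitivity is recovered at correlation 0.850. The
synergy-only ablation edges out the full model on synergy here (85.9 vs
90.6 MSE): with ~9k training samples carrying a low-rank planted signal the
synergy task is not data-starved, so on this fixture the auxiliary task
adds mild interference rather than the benefit seen on real screens, where
monotherapy data contribute drug-level information the synergy table
lacks.

Single pairs are scored by id once a model is trained:

```r
model <- train_synergy_model(synergy, sensitivity, drug_features, cell_features)
predict_pair(model, "drug_07", "drug_23", "cell_12")
```

A thin CLI covers the same pipeline
(`simulate`, `featurize`, `pretrain-ae`, `train`, `cv`, `grid-search`,
`predict`, `evaluate`):

```sh
Rscript inst/cli/mtsynergy.R simulate --seed 1 --out data/
Rscript inst/cli/mtsynergy.R cv --data data/ --seed 1 --out results/
```

See `vignettes/multitask-synergy.Rmd` for the model assumptions, every
tunable default, and the design decisions.

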