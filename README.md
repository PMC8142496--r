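# phosml

Machine-learning prediction of protein phosphorylation sites (pS / pT / pY)
from sequence, structural and functional features.

## What it does

Phosphorylation — addition of a phosphate to a serine, threonine or
tyrosine side chain — is the most common post-translational modification,
and computational site prediction is the standard complement to slow,
costly experimental mapping. `phosml` implements a complete prediction
pipeline:

1. **Windows.** Every candidate S/T/Y residue is represented by its
   21-residue window (±10 flanking residues, `'X'`-padded at termini).
2. **Feature encoding**, five schemes: physicochemical scales
   (7 per position → 147 columns), one-hot sequence identity
   (20 per position → 420), structural features — accessible surface area,
   coil/helix/strand state and an intrinsic-disorder flag at a strict 0.5
   cutoff (5 per position → 105) — plus protein-level binary membership in
   GO/domain/KEGG terms and in UP_SEQ_FEATURE/UP_KEYWORDS annotations.
3. **Two-stage feature selection.** Greedy minimum-redundancy
   maximum-relevance (mRMR, MID form) ranking within each feature
   category retains the top 50 per category; the pooled survivors are then
   ranked by symmetrical uncertainty
   `SU(X,Y) = 2 I(X;Y) / (H(X) + H(Y))` against the label.
4. **Classification** with a random forest or an RBF-kernel SVM (Platt
   probabilities), stratified 80/20 train/test split and stratified
   five-fold cross-validation.
5. **Evaluation**: ACC, SN, SP, PRE, F-score, MCC and trapezoidal ROC/AUC,
   with the standard zero-denominator conventions.

A seeded synthetic-data generator emulates all required inputs (FASTA,
site table, structural profiles, term vocabularies) with plantable
class-conditional signal, so the whole pipeline is testable without any
external database. See the vignette in `vignettes/phosml-methods.Rmd` for
the model details and design rationale.

## Worked example

```r
library(phosml)

# a self-contained synthetic study: proteins, labelled sites, structural
# profiles, annotation vocabularies
bundle <- synth_bundle(synth_config(seed = 101))

fit <- phospho_fit(bundle$proteins, bundle$sites, residue = "S",
                   profiles = bundle$profiles, vocab = bundle$vocab,
                   seed = 1)
fit
#> phospho_fit: pS predictor (RF, schemes PP+BE+SS+FF+FA)
#>   861 fragments (689 train / 172 test), 165 of 692 features kept
#>   held-out test: n = 172   TP 86  TN 74  FP 9  FN 3
#> ACC 93.0%  SN 96.6%  SP 89.2%  PRE 90.5%  F 93.5%  MCC 0.862  AUC 0.973

summary(fit)
#>             n   acc    sn    sp   pre     f  mcc   auc
#> cv_pooled 689 93.5% 97.5% 89.2% 90.6% 93.9% 0.87 0.973
#> test      172 93.0% 96.6% 89.2% 90.5% 93.5% 0.86 0.973
```

The 692 columns are the 147 + 420 + 105 sequence/structure features plus
one column per vocabulary term; 165 survive the two-stage selection, and
on this bundle they include 100% of the generator's planted signal
columns. `cv_pooled` is pooled out-of-fold performance on the training
partition; `test` is the untouched 20% hold-out. Scoring new candidate
sites re-encodes them through the same pipeline:

```r
new_sites <- fit$split$test[1:3, c("protein_id", "position")]
predict(fit, bundle$proteins, new_sites, type = "label")
#>    protein_id position score label
#> 12     SP0003       20  0.95     1
#> 20     SP0004       63  0.02     0
#> 21     SP0004       65  0.01     0
```

`plot(fit)` draws the held-out ROC curve. `run_pipeline("run.yaml")`
drives the same steps from a YAML configuration and writes stamped
artifacts (feature metadata, both selection rankings, a metrics report,
the fitted model); `inst/cli/phosml.R` is a thin command-line front end
with `make-fixtures`, `describe`, `run` and `predict` subcommands.

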