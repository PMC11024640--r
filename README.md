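# plantlnc

Identification and characterization of plant long non-coding RNAs
(lncRNAs) from assembled transcripts.

Plant lncRNAs — transcripts longer than 200 nt with no protein-coding
capacity — are hard to recognise with classifiers trained on human or animal
data. `plantlnc` provides the computational core of a plant-oriented lncRNA
workflow for transcriptomics researchers: retrainable coding-potential
classifiers over three established feature schemas, a stringent two-model
ensemble, a full evaluation toolkit, and the downstream annotation stages
(candidate filtering, protein-homology filtering, positional classification,
transposable-element origin, redundancy removal). Seeded synthetic-data
generators make every stage testable end to end without external downloads.

## The models

**Feature schemas** (per transcript sequence, forward strand):

* `cpat` — maximum ORF length *L*<sub>ORF</sub>, ORF coverage
  *L*<sub>ORF</sub>/*L*, the Fickett TESTCODE statistic, and the hexamer
  usage bias
  *h* = (1/*m*) Σ<sub>i</sub> [log *f*<sub>c</sub>(*w*<sub>i</sub>) −
  log *f*<sub>n</sub>(*w*<sub>i</sub>)]
  over the in-frame hexamers *w*<sub>i</sub> of the longest ORF, where
  *f*<sub>c</sub> and *f*<sub>n</sub> are coding/noncoding background
  frequencies learned from training data (4 features; logistic regression).
* `plek` — sliding-window k-mer frequencies for k = 1..5, scaled by
  *w*<sub>k</sub> = 1/4<sup>5−k</sup> (1364 features; RBF-kernel SVM).
* `lncfinder-lite` — ORF geometry, hexamer log-frequency means, GC
  fraction, and EIIP power-spectrum features capturing the period-3 signal
  of coding sequence (11 features; RBF-kernel SVM).

**Classifiers.** lncRNA is the positive class throughout. The logistic
model maximises the L2-penalised Bernoulli log-likelihood on z-scored
features; the SVM solves the soft-margin RBF dual and maps decision values
to probabilities with a Platt logistic calibration fitted on seeded 3-fold
out-of-fold decision values.

**Ensemble rule.** A transcript is called lncRNA only when *both* member
models call it lncRNA — the ensemble positive set is exactly the
intersection of the member positive sets, which can only reduce false
positives.

**Evaluation.** Sensitivity TP/(TP+FN), specificity TN/(FP+TN), accuracy
(TP+TN)/(TP+FP+TN+FN), precision TP/(TP+FP), F1 =
2·precision·sensitivity/(precision+sensitivity), plus ROC curves with
trapezoidal AUC (equal to the Mann–Whitney pairwise statistic).

**Annotation pipeline.** Candidates → length/monoexonic/sense-overlap
filter (FEELnc-style semantics) → ensemble prediction → homology filter
(identity > 80 and e-value < 1e−5 flags potential coding) → six-way
positional classification (antisense-exonic, intronic, bidirectional,
upstream, downstream, intergenic; 2000-bp proximity window) → TE origin by
exonic interval intersection. Redundancy removal uses CD-HIT-EST-style
greedy clustering at 80% identity.

## Worked example

Train a CPAT-style model on simulated plant-like transcripts and evaluate
it on held-out sequences:

```r
library(plantlnc)
library(dplyr)

cfg   <- sim_config(seed = 7, n_mrna = 400, n_lnc = 400)
lnc   <- simulate_lncrna(cfg)$sequences   # positives: no ORF over 120 nt
mrna  <- simulate_mrna(cfg)$sequences     # negatives: codon-biased ORFs

model <- train_coding_model(lnc[1:300, ], mrna[1:300, ],
                            model_spec("logistic", "cpat"), seed = 7)
model
#> <lnc_model> logistic / schema 'cpat'
#>   features: 4
#>   threshold: 0.5  trained on n = 600

test  <- bind_rows(lnc[301:400, ], mrna[301:400, ])
truth <- c(rep("lncRNA", 100), rep("mRNA", 100))
calls <- classify_sequences(test, model)
head(calls, 3)
#> # A tibble: 3 × 3
#>   transcript_id score label
#>   <chr>         <dbl> <chr>
#> 1 lnc_00301         1 lncRNA
#> 2 lnc_00302         1 lncRNA
#> 3 lnc_00303         1 lncRNA

cc <- confusion(truth, calls$label)
bind_cols(cc, metrics(cc))
#> # A tibble: 1 × 9
#>      TP    TN    FP    FN sensitivity specificity accuracy precision    f1
#>   <int> <int> <int> <int>       <dbl>       <dbl>    <dbl>     <dbl> <dbl>
#> 1   100   100     0     0           1           1        1         1     1

roc_curve(calls$score, truth)
#> <lnc_roc> 127 points, AUC = 1
```

The score is the probability that a transcript is a lncRNA; labels apply
the model's decision threshold (0.5 by default). On this synthetic fixture
the ORF/hexamer signal is strong enough for perfect held-out separation —
the metrics row shows the five headline statistics computed from the
confusion counts, and the ROC object carries the trapezoidal AUC.

A full annotation run (`run_pipeline()`, or `exec/plantlnc pipeline` from a
shell) takes assembled-candidate GTF + FASTA, a reference GTF, two trained
models, optional homology hits and TE BED, and writes `lncRNA.gtf`,
`lncRNA.fa`, `classification.tsv` and a per-stage `summary.tsv` whose
counts satisfy input = kept + removed.

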