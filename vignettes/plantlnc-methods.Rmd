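---
title: "Methods: coding-potential models and the lncRNA annotation pipeline"
author: "plantlnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coding-potential models and the lncRNA annotation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`plantlnc`: the feature schemas and classifiers, the evaluation framework,
the annotation pipeline's rules, what the synthetic-data generators emulate,
and the places where the design was genuinely open and a decision had to be
made.

## The problem

Long non-coding RNAs are transcripts longer than 200 nt without
protein-coding capacity. Distinguishing them from mRNAs by sequence alone
relies on coding signatures — a long open reading frame, codon/hexamer usage
bias, position-dependent base asymmetry, and the period-3 periodicity of
coding sequence. Classifiers trained on animal data transfer poorly to
plants, so `plantlnc` makes the classifiers *retrainable*: every model is
fitted from user-supplied (or simulated) plant positive/negative sets, with
lncRNA as the positive class everywhere.

## Feature schemas

**ORF features.** The longest ATG-initiated ORF is searched over the three
forward frames only; assembled transcripts are stranded, which matches the
convention of coding-potential tools. ORF length includes the stop codon.
By default `find_longest_orf()` requires an in-frame stop; feature
extraction instead accepts an ORF running to the last full codon
(`require_stop = FALSE`), so 5'-truncated assemblies still yield an
informative ORF length. Ties are broken by smallest start, then smallest
frame. Coordinates are reported 1-based inclusive — the native convention of
R/Bioconductor containers used throughout; GTF/BED I/O converts dialects at
the boundary.

**Fickett TESTCODE.** For each base the position value is
max(counts over the three codon positions) / (min + 1) and the content value
is the base's overall fraction; both are mapped through the classic
published lookup tables and combined with the published weights. The weights
sum to 1.60, so the score lives in (0, 1.6] with the familiar interpretive
cutoffs (below ~0.74 noncoding-looking, above ~0.95 coding-looking). `N`
residues are removed before both statistics; at least 3 non-`N` residues are
required.

**Hexamer usage bias.** The coding background counts in-frame (step-3)
hexamers over each coding training sequence's longest ORF; the noncoding
background counts all overlapping (step-1) hexamers of each noncoding
sequence — the asymmetry reflects that codon bias is a property of the
reading frame while noncoding sequence has none. Counts receive a
pseudocount (default 1.0), are normalised over all 4096 hexamers, and are
stored as natural logs. Scoring takes the mean log-ratio over a transcript's
in-frame ORF hexamers when the ORF is at least 6 nt, otherwise over all
hexamers of the sequence; hexamers containing `N` are skipped and a
transcript with nothing scorable scores 0 (the neutral value of a log
ratio). Whether the original tools used in-frame or whole-sequence counting
for the noncoding background is not documented; whole-sequence counting is
this package's explicit choice.

**k-mer profile (`plek` schema).** Sliding-window frequencies for
k = 1..5, each k scaled by `w_k = 1/4^(5-k)` so that longer k-mers — which
carry most of the discriminative signal but have smaller individual
frequencies — contribute on a comparable numeric scale. 1364 features;
windows containing `N` are excluded from both numerator and denominator.
The weighting constant is exposed (`k_min`, `k_max` arguments) rather than
hard-wired.

**EIIP spectrum (`lncfinder-lite` schema).** Residues map to
electron–ion interaction pseudopotential values (A 0.1260, C 0.1340,
G 0.0806, T 0.1335; `N` takes the mean). The discrete-Fourier power
spectrum of this series shows a peak at one third of the sequence length in
coding sequence. Features: power at index round(L/3), the signal-to-noise
ratio (period-3 power over mean nonzero-frequency power, scale-invariant by
construction), and the quartiles of the mean-normalised spectrum. A
numerically flat series (homopolymer) is reported as all-zero rather than
leaving the ratio 0/0 undefined. The full LncFinder feature set also
includes RNA secondary-structure features; computing them needs a folding
engine, so this package deliberately ships a composition/physicochemical
subset (`lncfinder-lite`) and accepts externally computed structure columns
through `extract_features(..., extra_features = )`.

## Classifiers

Features are z-scored with training statistics; constant features are
dropped and recorded on the model object.

**Logistic (CPAT-style).** The fit maximises the L2-penalised Bernoulli
log-likelihood (intercept unpenalised) by damped Newton iterations to a
gradient-infinity-norm of 1e-8, with step halving whenever a full Newton
step would increase the penalised deviance. The default penalty is
`lambda = 0`, matching the plain logistic regression of the original tool;
on linearly separable data the optimum is at infinity and the fit stops at
the iteration cap with saturated (but correctly ordered) probabilities.
The in-package solver exists because the contract is a *penalised-likelihood
maximum to a stated tolerance*, which off-the-shelf fitters meet only for
`lambda = 0`.

**SVM-RBF (PLEK/LncFinder-style).** `e1071::svm` solves the soft-margin
dual with defaults C = 1 and `gamma = 1/n_features` (features are already
standardised, so the usual variance heuristic reduces to this). Decision
values are mapped to probabilities with a Platt logistic calibration fitted
on out-of-fold decision values from a seeded 3-fold split — fitting the map
on resubstitution decision values would bias probabilities toward 0/1. The
calibration learns the decision-value sign, so no orientation convention of
the SVM library is relied on.

**Thresholds.** Default decision threshold 0.5 for both kinds; scores
exactly at the threshold are called lncRNA (documented boundary
convention). The retrained cutoffs of the original tools are not published,
so 0.5 is the neutral stand-in; an optional `youden_cv` policy picks the
Youden-J-optimal cutoff on seeded out-of-fold scores instead.

**Ensemble.** lncRNA iff both members call lncRNA. Disagreement resolves
to mRNA — the stringent direction, chosen because the ensemble's purpose is
reducing false-positive lncRNA calls. The set identity (ensemble positives
= intersection of member positives) gives the testable consequences
FP_ens ≤ min(FP_a, FP_b) and TP_ens ≤ min(TP_a, TP_b).

## Evaluation

Confusion counts define the five metrics (sensitivity, specificity,
accuracy, precision, F1). A metric whose denominator is zero is reported as
`NA`, never 0 — collapsing "undefined" to 0 silently distorts averages. ROC
thresholds are the unique scores in descending order with a +Inf sentinel;
tied scores are grouped at one threshold; the AUC is the trapezoidal
integral, which equals the Mann–Whitney statistic
P(score_pos > score_neg) + 0.5·P(tie) — the suite asserts this equality
against an O(n²) oracle. When several species' calls are evaluated, metrics
can be computed pooled (default) or per set and averaged; pooling weights
every transcript equally.

## Annotation pipeline

Stages run in a fixed order, and every removed transcript appears exactly
once in the removal log with its first failing rule, so stage counts always
conserve (input = kept + Σ removed).

1. **Structural filter.** Exonic length < 200 nt removes; monoexonic
   handling follows `monoex_mode` — the default `antisense_only` keeps a
   monoexonic candidate only when one of its exons overlaps a reference
   exon on the opposite strand (the FEELnc "monoex = -1" behaviour, exposed
   as an enum rather than a magic number); any same-strand exon–exon
   overlap of a known mRNA removes. Antisense exon overlap is never a
   removal cause — it is a positional class. Reason precedence: length,
   monoexonic, sense-overlap.
2. **Ensemble prediction** with two trained models over their own schemas.
3. **Homology filter.** A candidate is flagged as potential coding iff any
   alignment hit has identity > 80 *and* e-value < 1e-5, both strictly, as
   the thresholds are printed; candidates without hits are kept.
4. **Positional classification.** The six classes are assigned by
   precedence: antisense-exonic, intronic, bidirectional, upstream,
   downstream, intergenic. The source material lists the categories without
   defining a precedence or the bidirectional geometry; this package's
   choices are (a) overlap classes before proximal classes, (b)
   bidirectional before upstream (a divergent transcript would otherwise
   always be swallowed by the upstream rule), and (c) bidirectional defined
   as: no gene overlap, opposite strand of the nearest gene, located on
   that gene's upstream side, TSS-to-TSS distance within the window
   (default 2000 bp, adjustable). Distances are absolute position
   differences in 1-based coordinates; upstream/downstream windows accept
   either strand, and the partner gene is the nearest qualifying gene with
   lexicographic tie-break.
5. **TE origin.** Total exonic overlap with the union of TE intervals
   (strand-agnostic); a lncRNA is TE-derived at ≥ 1 bp overlap by default,
   and the overlap fraction is reported so users can re-threshold.

**Redundancy removal** (used on training sets, exposed as
`deduplicate()`): greedy incremental clustering, sequences sorted by length
descending (ties by id), joining the first representative with pairwise
identity above the threshold (default 0.80). Identity = matched columns of
the best local alignment (match +1, mismatch -1, gap open -2, gap extend
-1) divided by the *shorter* sequence's length — the CD-HIT-EST convention.

## Synthetic data

The generators produce the statistical structure the classifiers assume,
not just labels:

* `simulate_mrna()` — 5'UTR + ATG-initiated ORF + 3'UTR; ORF codons drawn
  from a codon-bias table skewed toward a 20-codon preferred subset
  (weight 8:1), ORF coverage uniform on [0.5, 0.9], lengths 400–3000 nt,
  GC 0.45. The bias creates a genuine hexamer/ORF signal learnable at
  n = 1000 per class.
* `simulate_lncrna()` — GC-matched random sequence whose longest ORF is
  kept below 120 nt by truncating any over-long ORF with an early in-frame
  stop. Values emulate plant lncRNA databases' length/GC ranges; the
  120-nt ORF cap reflects the common "no ORF > 100–120 codons·nt"
  working definition of noncoding.
* `simulate_genome()` — a single ~75-kb chromosome with six reference
  genes and one planted lncRNA locus per positional class, each satisfying
  its defining geometry, plus decoys exercising every removal branch
  (sub-200-nt, non-antisense monoexonic, sense-overlap, re-assembled known
  mRNA, strongly coding ORF, strong homology hit) and deliberately
  sub-threshold homology hits (identity exactly 80.0; e-value 1e-4) that
  must be kept. Planted lncRNA sequences are written into the genome last,
  so candidate sequences extracted from the genome are consistent with the
  planted truth table.

All generators run under an isolated seeded RNG (`withr::with_seed`) and
never touch the global random state; identical configurations give
byte-identical files.

**What passing tests on this data do and do not show.** The generator's
mRNAs have clean single-ORF structure and a strong uniform codon bias; real
plant transcripts have splice noise, truncated assemblies, pseudogenes and
weaker, lineage-specific codon bias. Perfect synthetic separation therefore
validates the *machinery* (features carry the signal, training recovers it,
the pipeline applies its rules exactly), not field performance; real-data
accuracy depends on the user's training sets.

## Problem sizes and numerical notes

The shipped test-suite and acceptance script use n = 1000 + 1000 training
transcripts, 10-fold cross-validation, held-out splits of 20%, ROC oracle
instances up to n = 200, 1000 random sequences (≤ 2000 nt) for the ORF
oracle, and ~50-sequence planted-duplicate fixtures for clustering — sizes
chosen to exercise every code path at desk scale while keeping a full run
in minutes on one CPU. Other numerical choices: natural log throughout;
hexamer pseudocount 1.0; IRLS tolerance 1e-8 with ridge jitter 1e-12 on the
Hessian; flat-spectrum guard at 1e-9 relative to the DC component; model
files are version-tagged RDS archives.

## Known limitations

* No RNA secondary-structure features (extension point only), no
  deep-learning classifier, no read mapping or assembly — assembled
  transcripts are consumed, not produced.
* Positional classification assumes one coordinate system; candidates on
  chromosomes absent from the reference are warned about and treated as
  having no genomic context.
* The greedy clustering is O(n²) pairwise alignment in the worst case —
  appropriate for training-set curation, not for millions of sequences.
* Cross-species benchmark performance of the retrained models depends
  entirely on the supplied training data and cannot be certified by the
  synthetic suite.
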