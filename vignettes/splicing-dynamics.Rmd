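---
title: "Methods: quantifying and testing cassette-exon splicing dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and testing cassette-exon splicing dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedyn)
```

## Scope and model

`splicedyn` analyses exon-level alternative splicing from junction counts.
The unit of analysis is a cassette (skipped) exon event with inclusion
(long-form) junction reads $L$ and skipping (short-form) reads $S$ per
sample. Inclusion is quantified as percent spliced in,

$$\mathrm{PSI} = \frac{L}{L + S},$$

undefined (missing) when $L + S = 0$. Everything downstream — differential
calling between conditions, trend testing over an ordered developmental
series, tissue-specificity scoring, exon annotation and motif analysis —
operates on this PSI matrix plus typed sample metadata (group, stage,
tissue), never on column-name conventions.

All internal coordinates are 0-based, half-open genomic intervals; GTF
(1-based closed) and the rMATS-style event-table dialect are converted only
at file boundaries, and BED output is emitted in the internal convention.

## Quantification, imputation, filtering

Missing PSI cells (no junction support, or masked upstream) are imputed
before testing. The default imputer is k-nearest-neighbour over event rows
(k = 10, Euclidean distance over samples observed in both rows): events
with correlated splicing profiles donate their value at the missing sample.
A seeded iterative chained-regression imputer (`method = "iterative"`) is
provided as a deterministic stand-in for iterative random-forest imputation,
which would need a forest implementation not guaranteed in minimal
installations. Both methods leave observed cells bit-exact and clamp
imputed values to $[0,1]$; the pre-imputation missingness mask is preserved
because one of the quality filters is defined on it.

Events then pass a four-rule quality filter with these defaults:

| rule | statistic | default |
|---|---|---|
| 1 | mean PSI across samples | within $[0.05, 0.95]$ |
| 2 | mean total junction count $L+S$ | $\ge 10$ |
| 3 | samples missing pre-imputation | $< 5$ (strict) |
| 4 | $\max(\mathrm{PSI}) - \min(\mathrm{PSI})$ | $> 0.05$ (strict) |

Rules 1, 2 and 4 are evaluated on the imputed matrix and retained counts;
rule 3 must be evaluated on the pre-imputation mask, since nothing is
missing afterwards — the only coherent reading of filters listed after
imputation. The rules are conjunctive, hence order-independent, and the
filter report names every violated rule per removed event.

## Quasi-binomial GLM and the QLRT

Both the two-condition test and the developmental test share one engine: a
logit-link quasi-binomial GLM fit by iteratively reweighted least squares
(relative deviance change $< 10^{-10}$, 100 iterations), with dispersion
$\hat\varphi = X^2_{\mathrm{Pearson}} / (n - p)$. Nested models are
compared with the quasi-likelihood ratio F-test

$$F = \frac{(D_0 - D_1)/\mathrm{df}_{num}}{\hat\varphi_{full}}, \qquad
F \sim F(\mathrm{df}_{num},\ n - p_{full}),$$

the standard quasi-likelihood analysis of deviance. Constant-PSI events get
$p = 1$ by convention and are never called; non-converged fits are flagged
and excluded from calling.

**Differential (GM vs DM):** the full model is an intercept plus a group
indicator; $\Delta\mathrm{PSI}$ is the plain difference of group means,
signed DM $-$ GM so that positive means more inclusion upon
differentiation. A differentiation-associated event (DASE) requires
$|\Delta\mathrm{PSI}| > 0.1$ and BH-FDR $< 0.05$, both strict.

**Developmental:** stage labels are rank-transformed (mixed embryonic-day /
postnatal-day labels need only an ordering) and enter as a natural cubic
spline with 3 df by default, capped at (number of distinct stages − 1); the
null is intercept-only. A developmentally dynamic event (devSE) has
BH-adjusted $p \le 0.05$, inclusive as the threshold is conventionally
printed. The spline choice (rather than polynomials or monotone trends) is
a design decision: it tracks smooth non-monotone trajectories over ~27
stages without overfitting, and the df is exposed.

### Precision weights

PSI values backed by $n = L + S$ reads enter the GLM with prior weight

$$w = \frac{n}{1 + (n - 1)\rho_0}, \qquad \rho_0 = 0.02$$

(imputed cells: $w = 1$, carrying no count evidence). Raw totals are the
naive choice, but under intra-class correlation $\rho$ (read-level
correlation within an event–sample cell) the sampling variance of PSI is
$p(1-p)\,[1 + (n-1)\rho]/n$: precision saturates at $p(1-p)\rho$ no matter
how deep the coverage. Weighting by raw $n$ therefore over-weights deep
cells exactly where overdispersion caps their information, makes the
per-cell quasi-dispersion heterogeneous, and measurably inflates the QLRT
type-I error in our null simulations (mean rejection 0.066 at nominal 0.05
with raw totals, 0.054 with moderated weights, over 5 seeds × 2000 null
events). The moderated form is the inverse-variance weight; $\rho_0 = 0$
recovers raw totals, and the parameter is an argument to both tests.
$\rho_0 = 0.02$ matches the simulator's default intra-class correlation —
a documented prior for junction-count data of this type, not an estimate
from any particular dataset.

## Tissue specificity: modH

Per event, tissue means of (imputed) PSI are computed, and specificity is
scored by a modified Shannon entropy. With tissue means $x_1,\dots,x_T$:

1. robust centre $c$ = one-step Tukey biweight about the median
   (tuning constant $c = 5$, MAD floor $\varepsilon = 10^{-4}$; if the
   unscaled MAD is zero the median is returned);
2. deviations $x_j' = |x_j - c|$, normalised to $p_j = x_j'/\sum x'$;
3. $\mathrm{modH} = -\sum_j p_j \log_2 p_j$, with $0\log 0 = 0$ and
   $\mathrm{modH} = \log_2 T$ by convention for an exactly constant vector
   (maximally non-specific).

A single outlying tissue concentrates the deviation mass, driving modH
toward 0; events with $\mathrm{modH} < 2$ (strict) are called
tissue-specific. Which tissue(s) drive the call is decided by an explicit
rule — tissue $j$ is an outlier when $|x_j - c|$ exceeds 3 × (1.4826 ×
MAD of the remaining tissues, floored at $\varepsilon$) — labelled
*included* (positive deviation) or *skipped* (negative). Reference
implementations of this entropy statistic use an AIC-based outlier search;
the fixed deviation rule was chosen because downstream analysis consumes
only the modH cutoff, and an explicit rule is deterministic and testable.
Note the point-mass limit $\mathrm{modH}=0$ presumes the flat bulk of
tissues dominates so the robust centre sits on it; with $T=2$ the statistic
is degenerate by symmetry ($\mathrm{modH}=1$).

## Exon annotation and NMD

Microexons are cassette exons of 3–27 nt, both bounds inclusive; frame
preservation is length divisible by 3. GC content is $(G+C)/(A+C+G+T)$ with
N excluded from the denominator. Distribution comparisons (e.g. exon length
between event classes) use the two-sided Mann–Whitney U test with normal
approximation, tie correction and continuity correction.

NMD potential is predicted by the exon-junction rule. From the backbone
transcript (the coding transcript containing the cassette with the longest
CDS — a deterministic choice when several qualify), the inclusion and
exclusion isoforms are built sharing the annotated start codon, and each is
translated; an isoform is NMD-targeted when its first stop codon ends more
than 50 nt (the conventional 50–55 nt rule; configurable) upstream of its
last exon–exon junction. Cassettes entirely within UTR are `"none"` by rule
scope; cassettes straddling a CDS boundary are flagged ambiguous and not
called. The prediction is strand-invariant by construction, which the test
suite verifies on mirrored gene models.

## Motif analysis

IUPAC motifs (with `[..]` groups; U ≡ T so RNA-style patterns scan DNA) are
matched at every position, overlapping matches included. Around each
cassette, five meta-regions are extracted in pre-mRNA sense orientation:
the intron flank downstream of the upstream exon, the intron immediately
upstream of the cassette, the cassette itself, the intron immediately
downstream, and the intron flank upstream of the downstream exon — ±250 nt
windows by default, truncated (and flagged) when an intron is shorter.
Offsets are reported 0-based from each region's 5' end, with a 1-based
column alongside, because "N nt downstream" phrasing in the literature is
ambiguous between the two anchorings.

Positional enrichment compares a regulated (target) against a background
exon set: per position, the fraction of events whose motif hits cover that
position, smoothed over a centred 50-nt window; target vs background is
compared per position with a one-sided two-proportion z-test,
BH-corrected across positions. Motif-map servers use a Wilcoxon variant
here; the simpler documented test was chosen because only the enrichment
profile is consumed, and the test is exposed for replacement.

## The synthetic-data generator

The generator produces the statistical structure the pipeline is designed
for, with exported ground truth:

* **Totals** $n \sim \mathrm{NegBin}$ (mean 100, dispersion 0.1 —
  coverage CV ≈ 0.33, a realistic spread for junction support of
  moderately expressed exons).
* **Inclusion counts** $L \sim \mathrm{BetaBinomial}(n, \psi, \rho)$ with
  intra-class correlation $\rho = 0.02$ by default ($\rho = 0$ reduces to
  binomial). $\rho$ for real junction data is not well established; 0.02
  is a documented placeholder, not a claim about any dataset.
* **True PSI patterns**: constant; condition shift (GM→DM); logistic
  trajectory over stage rank 1..27 (amplitude, midpoint, slope); or a
  single-tissue outlier over ten tissues. Implied PSI is validated in
  $[0,1]$ and clamped to $[0.001, 0.999]$ before sampling to avoid
  degenerate beta parameters — the same band the event filter excludes.
* **Missingness**: cells masked completely at random at rate 0.006, the
  magnitude observed in real stage-series PSI matrices.
* Default designs mirror the motivating datasets: 5 + 5 samples for the
  two-condition comparison, 27 stages × 2 replicates for the
  developmental series, and 57 samples over ten tissues (7 × 6 + 3 × 5)
  for the tissue panel.

Gene-model simulation builds one gene with a cassette exon, GT..AG introns,
inclusion/exclusion transcripts sharing the start codon, and a stop-free
CDS (internal stops scrubbed deterministically; terminal TAA). The realized
genomic GC is brought within ±0.05 of target by a bounded
regenerate-and-check loop. When the cassette length is not a multiple of 3,
a random downstream sequence would fail to contain a shifted-frame stop
with small probability, making the frameshift scenario seed-dependent; the
generator therefore writes the codon triplet `TTA ATT AAT` (Leu-Ile-Asn,
stop-free in frame 0 but reading TAA in both shifted frames) just after the
cassette junction, guaranteeing a premature termination codon on skipping.

`plant_motifs` first scrubs the background of accidental motif matches by
deterministically mutating the middle base of each match to a base outside
that position's IUPAC class (iterated to convergence, leaving the rest of
the background untouched), then writes a concrete motif expansion at the
requested offsets and re-scrubs incidental boundary matches. Scrubbing is
deterministic rather than resampled because the generator contract promises
bit-identical output for identical seeds, and this function takes none.

### What a green test does not establish

The simulator draws independent events, independent samples, missingness
completely at random, and single-cassette splice graphs. Real data violate
all four: events within a gene are correlated, samples share batch and
library-size structure, missingness tracks expression, and splice graphs
are entangled. Recovery rates measured here are therefore upper bounds on
real-data performance, and the headline event counts of any particular
study are not reproducible at desk scale — the acceptance suite instead
checks the in-paper arithmetic (summary fractions, up/down consistency),
coordinate-exact motif recovery, and the statistical calibration and
recovery properties under the stated noise model.

## Numerical choices and degenerate inputs

* IRLS: deviance tolerance $10^{-10}$, linear predictor clamped to ±30,
  fitted means to $[10^{-8}, 1-10^{-8}]$; rank-deficient designs error.
* Saturated fits (no residual df) yield undefined dispersion and $p = 1$.
* BH: step-up with `cummin` from the largest rank, capped at 1; input
  order preserved; ties handled by the ordering, which cancels in the
  adjusted values.
* All thresholds are applied exactly as conventionally printed: DASE
  thresholds strict, devSE threshold inclusive, modH threshold strict,
  missing-sample filter strict, microexon bounds inclusive.
* Percentages are kept unrounded internally and rounded (two decimals by
  default) only at presentation.

## Known limitations

Only two-form events are modelled statistically (other event types are
accepted and treated as two-form); no paired designs; no PWM scoring; no
orthology discovery (conserved-event counting consumes a user-supplied
ortholog-exon map); imputation assumes correlated events exist in the
matrix; the NMD rule ignores long 3'UTR and EJC-independent decay.
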