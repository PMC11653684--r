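# splicedyn

Splicing dynamics of cassette exons: PSI quantification, differential /
developmental / tissue-specific exon calling, exon annotation, and
flanking-intron RBP-motif analysis — with a seeded simulator providing
ground truth for every stage.

## Who this is for

Transcriptomics analysts working with exon-level junction counts (e.g.
rMATS-style skipped-exon tables) across two-condition designs (such as
proliferating vs differentiating myoblasts), ordered developmental series,
or multi-tissue panels, who want the full calling pipeline as tested,
scriptable R functions rather than a chain of one-off scripts.

## The statistics at the core

* **PSI (percent spliced in)** per event and sample:
  `PSI = L / (L + S)` over inclusion-junction (`L`) and skipping-junction
  (`S`) reads; missing when `L + S = 0`, imputed (kNN by default), then
  filtered by four quality rules (mean PSI in [0.05, 0.95]; mean total
  ≥ 10; < 5 missing samples; PSI range > 0.05).
* **Quasi-binomial GLM + quasi-likelihood ratio F-test** for both
  differential calling (`|ΔPSI| > 0.1` and BH-FDR `< 0.05` ⇒ DASE) and
  developmental dynamics (natural spline of stage rank, 3 df; BH-adjusted
  `p ≤ 0.05` ⇒ devSE), with precision weights
  `w = n / (1 + (n − 1)ρ₀)` moderating deep-coverage cells.
* **modH**, a robust-entropy tissue-specificity score: Shannon entropy of
  absolute deviations of per-tissue mean PSI from their one-step Tukey
  biweight centre; `modH < 2` ⇒ tissue-specific, with per-tissue
  included/skipped direction.
* **Exon annotation**: microexons (3–27 nt), frame preservation, GC, and
  NMD prediction by the 50-nt exon-junction rule on inclusion vs exclusion
  isoforms.
* **Motif analysis**: overlapping IUPAC scans (e.g. `GTGTG`,
  `A[CU]GAC[AG]`), strand-aware ±250 nt flanking-intron extraction, and
  positional enrichment profiles of target vs background exon sets.

## Worked example

Simulate a 5 + 5 GM/DM comparison with 10 events carrying a planted
inclusion shift of +0.35 and 30 flat events, then run the pipeline:

```r
library(splicedyn)

md <- sample_metadata(sprintf("s%02d", 1:10),
                      group = rep(c("GM", "DM"), each = 5))
models <- c(replicate(30, psi_model("constant", base_psi = 0.4),
                      simplify = FALSE),
            replicate(10, psi_model("group_shift", base_psi = 0.3,
                                    delta = 0.35), simplify = FALSE))
sim <- simulate_junction_counts(models, md, noise_params(), seed = 20)

psi  <- impute_missing(compute_psi(sim$counts), seed = 20)
kept <- filter_events(psi)
res  <- call_dases(test_two_group(kept$psi))

attr(res, "counts")
#>    up  down total
#>    10     0    10
head(res[res$is_dase, c("event_id", "delta_psi", "pvalue", "fdr", "direction")], 3)
#>    event_id delta_psi   pvalue      fdr direction
#> 31   ev0031     0.336 1.36e-06 5.42e-05        up
#> 32   ev0032     0.318 2.08e-04 1.39e-03        up
#> 33   ev0033     0.353 1.62e-03 6.47e-03        up
sprintf("%.2f%%", summarize_overlap(sum(res$is_dase), nrow(res)))
#> [1] "25.00%"
```

All 10 planted shifts are recovered as DASEs (direction `up` = more
included in DM), no flat event is called, and the summary fraction is the
plain intersection percentage used for reporting. The same `psi_matrix`
feeds `qlrt_devtest()` (stage series) and `call_tissue_specific()` (tissue
panels).

A command-line wrapper is installed at `exec/splicedyn` inside the package
library, with subcommands `simulate`, `psi`, `filter`, `diff`, `devtest`,
`tissuespec`, `annotate`, `motifscan`, `motifmap`, `summarize`:

```sh
$(Rscript -e 'cat(find.package("splicedyn"))')/exec/splicedyn \
    summarize --intersection 5857 --total 7861
# 74.51
```

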