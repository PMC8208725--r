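# strainwise

Natural genetic variation between inbred mouse strains reshapes how
macrophage enhancers respond to signals such as IL-4: the same stimulus can
induce an enhancer strongly in one strain and not at all in another.
`strainwise` implements the full inference chain for dissecting these
differences as a tested, reusable R package, and ships a synthetic
strain-pair generator with ground-truth labels so every stage can be
validated end to end without any external data.

The chain, mirroring how such studies are analysed:

1. **Responsive-element calling** — an element is stimulus-*induced* when
   both activity markers (H3K27ac and RNA Pol II) rise at least 2.5-fold
   from basal to stimulated, *repressed* when both fall 2.5-fold, *neutral*
   below 1.4-fold change, after filtering elements under 16 (H3K27ac) or 8
   (Pol II) normalized tags. ROSE-style super enhancers are called by
   stitching within 12.5 kb and cutting the scaled rank–signal curve at the
   slope-one tangent.
2. **Strain categorization** — enhancers (and genes) induced in exactly one
   strain of a pair are split by basal level: *high basal* when the
   noninduced strain has ≥2-fold (genes: ≥1.5-fold) more basal signal,
   *low basal* when the induced strain does, *equal basal* in between.
   Strain-difference tiers (>1.5 to >4-fold) quantify how the fraction of
   enhancers containing variants grows with divergence.
3. **cis/trans decomposition** — with F1-hybrid allelic counts, a gene is
   *cis* when |log2(parental FC) − log2(F1 FC)| < 1 and *trans* when the F1
   ratio collapses toward 1 despite a ≥2-fold parental difference.
4. **Motif-mutation association** — for homologous sequence pairs from
   responsive (positive) and unresponsive (negative) strains, the per-pair
   difference in best PWM log-odds score is tested against a zero median
   (Wilcoxon signed-rank); the statistic `sign × −log10 p` identifies
   transcription-factor motifs whose mutation tracks activity loss. Motifs
   are clustered at score-difference correlation > 0.6 and filtered at
   2 TPM factor expression.
5. **Sequence-model variant prioritization** — a three-convolutional-layer
   network classifies 300-bp active-enhancer sequences against GC-matched
   genomic backgrounds; per-nucleotide importance (gradient×input against a
   uniform reference, strand-combined by absolute maximum) defines the top
   20% (60/300) *predicted functional* positions, and variants landing on
   them are flagged as putatively causal.
6. **Enhancer connectivity** — proximity-ligation interaction anchors are
   matched to elements within 2.5 kb to classify enhancer–enhancer,
   enhancer–promoter and promoter–promoter pairs; strain-differential
   enhancers lacking local functional variants are attributed to flagged
   variants at connected enhancers (`local_only` / `both_ends` /
   `connected_only` / `neither`).

## Worked example

```r
library(strainwise)

cfg <- pipeline_config(seed = 7L)           # all thresholds in one object
res <- run_pipeline(cfg, generator_params() # simulate + analyse end to end
                    , out_dir = "sw_run")

# mechanism recovery against the generator's truth
mechanism_recovery(res$dataset)$recovery
#> [1] 0.9914712

# the motif-mutation scan ranks the planted signal-factor motif first,
# far ahead of 20 random decoy motifs
head(res$motifs[order(-abs(res$motifs$signed_logp)), c("motif", "signed_logp")], 3)
#>           motif signed_logp
#> 3  SDTF_GASlike   30.211637
#> 1  LDTF_ETSlike   22.895779
#> 11      decoy07   -2.920094

res$model$auroc                              # held-out test auROC
#> [1] 0.9950643

# attribution of differential enhancers to local vs connected variants
round(attr(res$attribution, "percentages"), 1)
#>     local_only      both_ends connected_only        neither
#>            5.5           65.5           28.6            0.3
```

The mechanism-recovery rate says that 99.1% of elements planted with a
low/equal/high-basal mechanism were re-identified with their true category
from the simulated signals alone. The signed motif statistic (+30.2 for the
GAS-like signal-factor motif) says that losing that motif's score strongly
tracks losing inducibility across strain sequence pairs. The attribution
split mirrors how differential enhancers decompose: most carry a flagged
local variant (here usually alongside a flagged connected one), while the
generator's variant-free "wired" enhancers land in `connected_only`.
The run directory contains one
TSV per stage (element calls, strain categories, cis/trans labels, motif
statistics, flagged variants, classified interactions, attribution), a
plain-text report with confusion matrices against the generator truth, and
a YAML manifest with config hash and file digests.

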