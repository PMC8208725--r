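---
title: "strainwise: models, thresholds and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strainwise: models, thresholds and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the statistical
rules at each stage, the generative model behind the synthetic data, the
tunable parameters with their defaults and rationale, numerical choices at
edge cases, and known limitations. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The analysis chain

**Element calling.** An element's response state is decided by the fold
changes of both activity markers between conditions, computed as
`(stimulated + 1) / (basal + 1)`. The +1 pseudocount (on normalized tags
per 1e7) stabilizes ratios at weakly covered elements; the thresholds are
`induce_fc = 2.5` (both markers up: induced; both down by the reciprocal:
repressed), `neutral_fc = 1.4` (both markers strictly inside the band:
neutral), with minimum-signal filtering at 16 H3K27ac / 8 Pol II normalized
tags applied to the maximum over conditions. Elements with intermediate or
discordant markers are reported as an explicit `ambiguous` state rather
than silently dropped, so the five states partition every element.

**Super enhancers.** Enhancers within `stitch_dist_bp = 12500` are stitched;
member signal inside ±2500 bp of a TSS is excluded. With both axes of the
ranked-signal curve scaled to [0, 1], the cutoff point minimizes the number
of points below the slope-one line through it, and regions strictly above
the cutoff signal are super enhancers. Degenerate inputs (all totals equal)
yield no super enhancers; fewer than three regions is an error since the
curve geometry is undefined. The 12.5-kb stitching distance is the
convention of the original ranking algorithm; only the TSS exclusion
distance is prescribed by the upstream protocol, so both are configuration
fields.

**Strain categorization.** Pairwise comparisons keep elements induced in
exactly one strain whose H3K27ac induction fold changes differ more than
`gene_induce_fc = 2`-fold between strains. The basal H3K27ac ratio
(noninduced/induced, pseudocount 1) then splits categories at
`enhancer_basal_fc = 2` (genes: `gene_basal_fc = 1.5` on TPM). Boundary
semantics follow the rule statements: category thresholds are inclusive
(`>=`), strain-similar/tier boundaries strict (`<` 1.5 similar, `>` t for
tier membership, so a ratio exactly at a threshold belongs to neither).
Tiers are cumulative: a 5-fold element belongs to >1.5 through >4.

**cis/trans.** With parental fold change `P` (strain ratio of expression)
and F1 fold change `F` (allelic ratio), a gene is cis when
`|log2 P − log2 F| < 1`, else trans when `|log2 P| >= log2 2` and
`|log2 F| < |log2 P|` (the attenuation criterion applied symmetrically to
both directions), else unclassified. F1 allelic counts are assigned
proportionally to informative (variant-overlapping) reads; transcripts with
zero informative reads on either allele are flagged filtered. The upstream
description multiplies by a "ratio times 10" factor that cancels in any
ratio; proportional assignment keeps the intent without the cosmetic
scaling.

**Motif-mutation association.** Per homologous pair, the difference of best
log-odds scores (positive-strain minus negative-strain sequence, both
strands scanned). Zero differences are uninformative for that motif and are
dropped; remaining differences are tested against a zero median with the
Wilcoxon signed-rank test — exact null when there are fewer than 26
tie-free nonzero differences, normal approximation with continuity
correction otherwise — and summarized as `sign(median) × −log10 p`.
Antisymmetry under label swap is exact. Motifs are clustered by single
linkage at Pearson correlation > 0.6 between score-difference vectors;
constant vectors have undefined correlation and stay singletons. Clusters
are kept when any member's factor gene exceeds 2 TPM (strictly) in any
condition. No multiple-testing correction is applied to the signed
statistic itself (it is a ranking device); a Benjamini–Hochberg column is
emitted alongside for users.

**Sequence model.** Input sequences are one-hot encoded 300-bp windows
centered on elements; ambiguous bases are all-zero columns. The
architecture is three 1-D convolutional layers (defaults 12/16/16 filters,
kernels 10/5/3, max pooling 4 after the first two) whose output is
flattened into two fully connected layers (32 hidden units, logit output).
The flattened head matters beyond accuracy: gradients reach every input
position through many paths, which a global-max head would funnel through
one argmax per filter and thereby starve most positions of attribution.
Training uses binary cross-entropy, Adam, He initialization,
reverse-complement augmentation of the training partition, and L2 weight
decay 1e-4. The learning rate starts at `lr_init = 1e-3` and is multiplied
by 0.9 whenever validation loss has not improved for 5 consecutive epochs;
training stops after 20 epochs without improvement (or `max_epochs`), and
the best-validation weights are kept. The 1e-3 default deviates from the
1e-4 used by the fine-tuning protocol this emulates: fine-tuning starts
from pretrained features, whereas this package trains from random
initialization (no external weights), and at 1e-4 the loss cannot leave
its initial plateau before the 20-epoch stop rule fires. Batches are sized
so an epoch makes ~300 optimizer steps regardless of training-set size,
keeping convergence epoch counts comparable across scales. On the single
synthetic chromosome, coordinate blocks replace chromosome holdouts:
`split_by_thirds()` defaults to equal thirds, and the pipeline uses an
8:1:1 split mirroring the train-heavy chromosome-holdout protocol
(train on all but two chromosomes, validate and test on one each).
Training is deterministic given the seed on a single CPU thread.

**Importance and variant prioritization.** Attribution is gradient×input
against a uniform (0.25) reference on the positive-class logit, computed
for the sequence and its reverse complement; the reverse-complement track
is reversed to align positions and the final score is the elementwise
absolute maximum, making tracks strand-symmetric by construction. Exactly
`round(0.2 × 300) = 60` positions per element are predicted functional
(ties broken leftmost). A variant is flagged when any base of its
left-aligned reference allele lies on a predicted functional position of
any covering element window. 5-mer interpretation scores each occurrence
by mean importance, takes the global top 10% of occurrences, and reports a
Haldane-corrected odds ratio with a two-sided Fisher exact p per 5-mer.

**Connectivity.** Interaction anchors match elements at gap ≤ 2500 bp
(interpreting the merge distance of the upstream peak-merging step), with
promoter precedence when an anchor matches both kinds — keeping
enhancer-promoter counts conservative. The promoter–enhancer state
contingency is tested with Fisher's exact test on three collapsed 2×2
comparisons. Connected-enhancer correlations (Pearson across strains,
requiring ≥3 strains) are compared against two nulls — same-chromosome
random pairs and distance-matched unconnected pairs (tolerance 100 kb,
configuration-exposed) — by Mann–Whitney U with Cohen's d. Attribution
assigns each differential enhancer exactly one of `local_only`,
`both_ends`, `connected_only`, `neither` from flagged variants within
±150 bp of its center and at its connected enhancers.

## The synthetic generator

The generator emulates the three mechanisms by which strain variation
alters stimulus-induced enhancer activity, on one synthetic chromosome
(`chrS`) carrying 300-bp elements every ~3 kb.

*Sequence layer.* The genome has isochore-like local GC structure (20-kb
blocks, GC ~ N(0.50, 0.04) clamped to [0.35, 0.65]) so GC-matched
backgrounds exist near every element. Every element carries a
lineage-factor (LDTF) site planted one sharp-column mismatch below
consensus — licensed but improvable — and responsive elements additionally
carry a signal-factor (SDTF) consensus site. The packaged matrices are
synthetic consensus-like PWMs (an ETS-like and C/EBP-like LDTF class; a
GAS-like and EGR-like SDTF class) with two column sharpnesses: sharp
columns (0.85 consensus probability; worst-base penalty 5.9 bits) and soft
columns (0.55; penalty 1.9 bits), giving a controllable occupancy ladder.

*Occupancy and activity.* Occupancy is a logistic function of the planted
(cognate) site's log-odds score, anchored so a consensus site occupies at
0.95, with slope 0.68 per bit. Scoring the cognate site rather than the
window-wide best match keeps truth labels exact: in 300-bp windows, chance
matches otherwise rival deliberately weakened sites. Mean H3K27ac is
`min(12 + 120·occL + 530·occL·occS·stim, 175)` normalized tags; Pol II is
half that; ATAC and TF tracks follow occupancy analogously. The saturation
cap creates the high-basal phenotype: an improved LDTF site raises basal
signal ~3-fold while stimulation cannot push activity further (fold change
~1.39 < 1.4). The coefficients were calibrated analytically against the
mechanism contracts before any acceptance run: conserved elements induce
~3.9-fold (both strains); equal-basal edits (one sharp plus one or two
soft SDTF mismatches) abolish induction (strain-B fold change 1.27 or
1.08) without touching basal signal, at strain stimulated-signal ratios
of 3.1 and 3.6 spanning the upper tiers; low-basal edits (three further
sharp LDTF mismatches) drop strain B below the minimum-signal filter
(stimulated ratio ~13); trans-regulated "wired" elements fill the 1.5-4
ratio range. High-basal improvement gives a 2.9-fold basal gain at a
1.39-fold strain-B response.

*Noise.* Tag counts are negative-binomial with dispersion 0.005 on the
normalized-tag scale, three replicates per condition averaged into the
signal table — the scale of technical variation in deeply sequenced ChIP
replicates. Dispersion 0 returns exact means, giving the deterministic
limit used by exactness tests. Expression adds log-normal replicate noise
(sd 0.15) on TPM; q-values come from a Welch t-test on log2 counts across
replicates (BH-adjusted) so the significance gate of gene calling is
exercised; at zero variance the p-value degenerates to 0/1 by mean
comparison.

*Variants and truth.* Mechanism edits are the causal variants (the
mutated positions are drawn at random within their column-sharpness class,
so edits are not stereotyped across elements); silent variants are planted
at motif-free positions so that they form `frac_silent_variants = 0.5` of
all variants. Criterion-style motif analyses use a variant-dense setting
(0.93) emulating a highly divergent strain pair, which also gives decoy
motifs enough informative pairs for their null p-values to be
approximately continuous. The truth tables record each element's
mechanism, each variant's causality, and each gene's cis/trans status.

*Genes and F1.* cis/trans genes get a ±[1.8, 3] log2 parental ratio; F1
allelic counts are binomial draws of 200 informative reads at the parental
ratio (cis) or 1:1 (trans). A subset of genes is induced in one strain
with planted basal-ratio categories, and promoter elements (every ~8th
element) inherit their gene's induction state.

*Wiring.* A labeled subset of variant-free "wired" enhancers mirrors
trans-regulation through connectivity: their strain-B stimulated signal is
attenuated by a factor with log2 drawn from 0.585 plus a truncated
exponential (rate 1, cap 1.415; i.e. ratios 1.5–4 with a decaying tail) —
populating the strain-difference tiers with variant-free elements — and
each is connected to a causal-variant low-basal partner. Wired elements
and their partners avoid promoter-adjacent positions because a 5-kb
interaction anchor also matches immediate neighbours and promoter
precedence would reclassify the pair. Random enhancer pairs and
state-biased promoter wiring (induced promoters contact induced enhancers
at 70%) complete the interaction table.

## What passing tests do and do not show

The generator plants clean, single-site mechanisms with independent noise;
real data add peak-calling uncertainty, mapping bias around variants,
correlated replicates, multi-site enhancers, indels and structural
variation, and motif grammar beyond two factor classes. Recovery rates and
auROCs on synthetic data therefore validate the *implementation* of each
rule and the end-to-end plumbing — they are upper bounds, not forecasts of
performance on experimental data. Indels are representable in the variant
model (left-aligned, position = first base) but the generator plants SNPs
only. The connected-correlation comparison needs ≥3 strains and is
exercised with directly constructed multi-strain tables rather than the
two-strain generator.

## Problem sizes

Validation uses the study conditions: mechanism recovery on 1500 elements;
cis/trans on 500+500 genes; motif recovery on 50 replicates of 72
equal-basal pairs against 20 screened decoys; model training on 2000
planted-motif positives plus 2000 GC-matched backgrounds (coordinate-third
holdouts); variant prioritization and attribution on the 1500-element
pipeline run. These sizes make every stage's signal unambiguous while a
full run of the acceptance script completes on a laptop-class single CPU.

## Known limitations

- Two strains and one chromosome in the generator; multi-strain joint
  analyses (beyond the correlation comparison) are out of scope.
- The sequence model is a compact from-scratch implementation in base R
  matrix algebra; it is single-threaded and sized for hundreds-to-thousands
  of training sequences, not genome-scale corpora.
- Differential-interaction analysis between conditions is not implemented;
  the interaction set is treated as condition-static.
- Super-enhancer calling quantifies stitched signal from the provided
  element-level signal, not from read-level data.
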