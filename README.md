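# lncscope

Identification and characterization of long non-coding RNA (lncRNA) genes
from multiple transcript-model sources, written for transcriptomics analysts
who have (i) a genome annotation, (ii) a short-read assembly, and (iii) a
long-read full-length transcript set, and want one merged, filtered,
positionally classified lncRNA gene catalogue plus the downstream analytics
that usually follow it: stage/tissue specificity, co-expression-based
cis/trans target calling, and knockout differential expression.

## What the package computes

**Identification cascade.** Short-read transcripts are kept when they are
multi-exonic, ≥ 200 nt of exonic length, free of exonic overlap with coding
exons on either strand, and labeled noncoding by an external coding-potential
tool. Unstranded long-read transcripts get a transcription direction from
stranded read counts: with *p* plus-strand and *m* minus-strand reads, a
χ² goodness-of-fit against an equal split,

    χ² = (p − m)² / (p + m),  df = 1,

assigns the majority strand iff the fold ratio max(p,m)/min(p,m) > 2 **and**
p ≤ 0.05; stranded long reads are then dropped if they share any intron
(exact donor–acceptor pair, same strand) with a coding transcript. The three
sources merge by intron-chain identity (the cuffmerge-style equivalence;
terminal exon ends may differ, the representative takes the widest ends), and
same-strand transcripts overlapping ≥ 1 bp cluster into XLOC-style gene loci.
Loci below 1 FPKM in every sample are removed.

**Positional taxonomy.** Each lncRNA locus gets exactly one of five classes
relative to coding genes, in precedence order: *antisense* (opposite-strand
gene-body overlap), *intronic* (≥ 50 % of exonic bases inside same-strand
coding introns), *divergent* / *convergent* (nearest gene ≤ 1 kb away,
opposite / same strand), *intergenic* (> 1 kb from everything).

**Expression analytics.** The stage-specificity index

    τ = Σᵢ (1 − x̂ᵢ) / (N − 1),   x̂ᵢ = xᵢ / max(x)

is 0 for uniform and 1 for single-stage expression (computed on
log2(FPKM+1) stage means; τ ≥ 0.8 flags a stage-specific gene). Also:
expressed/not-expressed calls per stage, pairwise stage sharing and the
accumulation curve, Spearman correlation structure with average-linkage
clustering and PCA, and retina-versus-body-panel tissue specificity.

**Regulation.** A cis target is the single nearest coding gene within
100 kb whose expression correlates with the lncRNA at r ≥ 0.90 and raw
p ≤ 0.05 (Pearson on log2(FPKM+1)); a trans target is any coding gene with
r ≥ 0.90 that sits in the same co-expression module (correlation-distance
hierarchical clustering with a fixed-height cut). χ² term enrichment (2×2,
df 1) scores target sets against a background.

**Differential expression.** An in-repo negative-binomial Wald test
(median-of-ratios size factors, method-of-moments dispersion shrunk toward
an a₀ + a₁/μ trend) calls a gene differential iff |log2 fold change| ≥ 1
and raw p ≤ 0.05, restricted to strict intergenic lncRNAs, with
cross-contrast direction summaries.

**Synthetic data.** `make_toy_genome()`, `make_stranded_counts()`,
`make_expression()` and `make_mutant_counts()` generate every input the
pipeline consumes with planted ground truth (true classes, strands,
stage-specific genes, cis/trans pairs, fold changes), so the whole workflow
is testable without any download.

## Worked example

```r
library(lncscope)
res <- lnc_demo("demo_out", seed = 7)
res$manifest$counts
```

The demo plants 25 lncRNA loci (5 per class) among 20 coding genes, runs the
full pipeline from the files it wrote, and reports:

```
$identified_loci
[1] 25
$identified_class_counts
$antisense: 5  $divergent: 5  $convergent: 5  $intronic: 5  $intergenic: 5
$gated_loci
[1] 25
$strand_assigned
[1] 21
$cis_calls
[1] 5
$trans_calls
[1] 5
$de_genes
KO1 KO2 KO3
  6   5   6
```

All 25 planted loci are recovered with their true positional classes; all
21 long-read transcripts in the stranded count table (including a planted
decoy that shares an intron with a coding gene, and is later removed by the
intron filter) pass the joint fold/χ² strand rule at the demo's read depth;
the 5 cis and 5 trans calls match the planted regulatory pairs (the
acceptance script measures precision and recall on a 50-pair benchmark), and
each simulated knockout contrast recovers its planted differential genes. `demo_out/` holds the merged GTF, the class,
τ, sharing, tissue-specificity, regulation and DE tables, and a
`manifest.json` whose hash is identical on reruns with the same seed.

Individual stages are ordinary functions over tibbles, e.g.

```r
calls <- assign_strand(counts)            # per-transcript strand calls
merged <- merge_sources(ann, sr, lr)      # lnc_merge object; tidy(merged)
classes <- classify_loci(merged, coding)  # five-class tibble
tau(c(4, 2, 2, 0))                        # 0.6667
```

`tidy()`, `glance()`, `autoplot()` and the `plot_*()` helpers work on the
result objects (`lnc_merge`, `lnc_corstruct`, `lnc_de`, `lnc_cross`).

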