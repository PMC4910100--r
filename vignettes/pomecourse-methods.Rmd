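---
title: "Methods: models, parameters and design choices in pomecourse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in pomecourse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pomecourse analyses a multi-cultivar fruit-development RNA-seq panel:
five cultivars, six developmental stages and one post-harvest
senescence stage in the default layout, with per-cultivar SNP calls on
a shared reference. This vignette is the package's own account of each
method, the parameters that matter, and the choices made where the
design was genuinely open.

## Quantification and the presence filter

RPKM is computed in its closed form,
$\mathrm{rpkm}_{gs} = 10^9 c_{gs} / (L_g N_s)$, with $L_g$ the
exon-union length in bp of the gene's longest mRNA and $N_s$ the
per-sample total of mapped reads. Gene length by exon-union of the
longest mRNA is a deliberate choice: it is the genome-side analogue of
quantifying against a transcript set, and it is stable when a gene has
several mRNAs. $N_s$ is whatever the mapping summary declares; the
simulator declares equal library sizes (2 × 10⁶) so that planted
expression shapes survive quantification exactly, and when counts are
read from files with no declared totals the pipeline falls back to
column sums.

The presence filter keeps, per cultivar, the genes expressed in at
least `min_stages = 5` of its 7 stages. "Expressed" means RPKM
*strictly above* `min_rpkm`, and `min_rpkm` defaults to 0, so
positivity is the definition — a zero-count gene is never "expressed"
at the default. The stage-based (per-cultivar) reading of the filter is
the primary one; a panel-wide reading over all 35 samples is available
via `scope = "all_samples"` because the phrase "five expression sets"
is ambiguous between the two.

## Sample dendrogram

Samples are correlated by Spearman's rank correlation (midrank ties) on
`log2(RPKM+1)`; the tree is average-linkage (UPGMA) on the distance
$1-\rho$. Two open choices were closed as follows: correlations use the
log scale by default (variance stabilization; a raw-RPKM flag exists),
and the distance is $1-\rho$, not $1-|\rho|$, because anti-correlated
stage profiles should be far apart in a developmental tree. Samples are
put in lexicographic label order before clustering, which fixes the
merge order under exact ties and makes the tree invariant to input
order. Newick output follows the ultrametric convention (a node merged
at height $h$ sits at depth $h/2$) and quotes labels that need it.

## Model-profile clustering

The candidate profiles are every length-7 integer series that starts at
0 with successive differences in $\{-c,\dots,c\}$; `c = 2` by default
(the published default of the short time-series method this follows),
giving $5^6-1 = 15\,624$ non-flat candidates. From these, `m = 20`
model profiles are selected greedily: start from the pair at maximum
distance ($1-$ Pearson correlation between templates), then repeatedly
add the candidate whose minimum distance to the chosen set is largest.
Ties are broken toward the lexicographically smallest template, so the
selection is deterministic; it is also computed once and cached. One
shared profile set serves all cultivars — selection is global, not
per-cultivar — so that cross-cultivar membership comparisons (the Venn
overlap of a profile across five cultivars) are well defined.

Genes enter as `log2(RPKM+1)` series anchored at stage 1 and are
assigned to the profile with maximal Pearson correlation; exact ties go
to the lowest profile id, and zero-variance series are excluded rather
than forced into a profile. Assignment is invariant to affine
transforms of a gene's series, a property of the correlation.

Significance per profile: each gene's 7 stage values are permuted
(`n_perm = 1000` by default, sampled uniformly from the $7!$ orders; an
exhaustive mode exists) and re-assigned with the same tie-break; the
expected count of a profile is its mean count over permutations; the
p-value is the binomial upper tail $P(X \ge \mathrm{obs})$ at success
probability expected/total, Bonferroni-corrected over the $m$ profiles.
Measured over 200 null panels, the family-wise error rate of this
procedure at $\alpha = 0.05$ is ~2.5% — conservative, as the binomial
discreteness predicts.

## Maturation contrast and the group test

Fold change between maturity and senescence uses a pseudocount of 1:
$\mathrm{fc} = \log_2((r_7+1)/(r_6+1))$. Genes expressed (RPKM > 0) in
stage 6 or 7 form the denominator; up is $\mathrm{fc} \ge 1$, down is
$\mathrm{fc} \le -1$, everything else unchanged, so the three sets
partition the denominator exactly (at `threshold = 0`, a fold change of
exactly 0 stays "unchanged"). The threshold, pseudocount and test
variant are all configuration, because the up/down rule behind reported
percentage figures of this kind is conventionally unstated; the group
test itself does not depend on the rule when applied to reported
percentages directly.

The group test is Welch's unequal-variance two-sample *t* with
Satterthwaite degrees of freedom, two-tailed; a pooled-variance variant
is available by flag. Applied to the five reported per-cultivar
up-regulation percentages (43.95, 44.63 vs 21.39, 24.33, 27.04) it
gives t = 12.023, df = 2.169, p = 0.005032, which is the package's
reference check for this operation. The degenerate case of two
constant groups (possible on tiny panels where percentages coincide)
returns the analytic limit (t = 0, p = 1 for equal means) instead of
erroring.

Group-exclusive sets use the intersection-minus-union reading: "only up
in post-ripening" is the intersection of the up sets over post-ripening
cultivars minus the union of up sets over the others, with an "any"
mode that relaxes the inclusion side to a union, since either reading
is defensible.

## SNP effectiveness classification

The classifier works from genome + gene models only, in 1-based
inclusive coordinates throughout (the convention of both GFF3 and VCF;
no conversions anywhere). Per mRNA it precomputes strand-aware 2 kb
upstream/downstream flanks (truncated at chromosome ends, not trimmed
against neighbours — a neighbouring gene's own context wins by
precedence), intron intervals, the two *intronic* bases at each
exon–intron junction as the splice-boundary region (the canonical
donor/acceptor dinucleotides; exonic boundary bases keep their codon
class), and the spliced, phase-trimmed CDS with a genomic-to-CDS offset
map.

Codon classes substitute the strand-corrected allele into the spliced
CDS and translate the affected codon under the standard nuclear code:
first codon → class 5 unless the new codon still encodes the ATG
initiator (class 11); last codon → class 6 unless the new codon is
still a stop (class 10); internal → class 8 if the new codon is a stop,
7 if the amino acid is unchanged, 9 otherwise. Class 11 is provably
empty for ATG starts (every substitution leaves non-ATG), so it is kept
as a predicate for non-ATG annotated starts and the synthetic generator
reports it "unplantable" rather than pretending to plant it.

A variant overlapping several contexts yields one record per mRNA plus
flank records; summaries reduce to one record per variant by the total
precedence order N(12) > codon > exonic-non-CDS > splice(3) > intron(4)
> upstream(1) > downstream(2) > intergenic(0), ties across genes broken
by lexicographic gene id. The order favours the most functionally
specific call and makes the class counts mutually exclusive. Exonic
positions outside any CDS have no class in the twelve-way taxonomy and
are flagged `unclassified_utr` instead of being forced into one;
frame-broken models are excluded from codon classes and flagged
likewise. Intron class 4 is read as plain intronic; no
alternative-splicing inference is attempted.

Two independent checks guard this module: planted variants (whose class
is fixed at planting time by direct sequence inspection) must agree
100% with the classifier, and a structurally different oracle —
rebuild the whole mutant transcript, translate ref and alt proteins,
compare — must agree 100% as well. Reverse-complementing an entire
fixture (genome, models, variants) must leave every class unchanged.

## Enrichment and co-expression

Over-representation is the exact hypergeometric upper tail
$P(X \ge k)$ computed by `phyper`; the defensible universe for
expression-derived sets is the presence-filtered background, and the
caller supplies it explicitly. Correction defaults to "none" (matching
how raw enrichment p-values are conventionally reported), with BH and
Bonferroni available.

The co-expression network is the standard soft-threshold construction:
$a_{ij} = |\mathrm{cor}_{ij}|^\beta$ on `log2(RPKM+1)` (signed variant
by flag), $\beta = 6$ by default, and the topological overlap
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i,k_j) + 1 - a_{ij})$. Modules come from average-linkage
clustering on $1-\mathrm{TOM}$ with a *static* cut at 0.75 and a
minimum size of 5 — simpler and fully deterministic compared with
dynamic hybrid cutting, which is a documented divergence from the full
WGCNA procedure and adequate at the scale this package targets. Genes
are clustered in canonical id order and module labels renumbered by
size, so labelling is permutation-invariant. $\mathrm{TOM} \ge a$ is
*not* asserted anywhere: it is false in general.

## The synthetic-data generator

The generator exists so that every downstream stage has ground truth:

* **Genomes** are uniform A/C/G/T with a configurable fraction of 'N'
  positions (0.2% in the default fixture), which makes class 12
  reachable.
* **Gene models**: non-overlapping genes, about half on the minus
  strand, 1–4 exons, 60–200 codons, introns of 60–300 bp, separated by
  at least 4001 bp so the 2 kb flanks of neighbours never overlap.
  Each CDS is written into the genome on its coding strand with an ATG
  start, a stop end, no internal stop, and length divisible by 3. Exon
  boundaries may split codons, as in real genes. The default fixture is
  2 chromosomes × 100 kb with 40 genes: the smallest round size that
  accommodates 40 genes at the 4001 bp spacing with full flanks.
* **Variants** are planted per requested class from sites whose context
  guarantees the class by construction (e.g. class 7 sites are
  third-position changes verified synonymous against the codon table at
  planting time; class 1 sites lie in exactly one gene's upstream flank
  and in no gene body). All planted positions are distinct, and REF
  always equals the genome base.
* **Counts** follow per-gene templates on the log2 scale
  (steady decrease, steady increase, flat, late peak) with integer
  baseline counts (16–256) so that zero-noise means are exact, and
  negative-binomial dispersion (`noise`, default 0.05) otherwise —
  overdispersed counts, as real RNA-seq requires. The stage-7 mean is
  decoupled from the template: per cultivar, a planted fraction of
  genes is up-regulated (× 2²) or down-regulated (× 2⁻²) relative to
  stage 6, and the rest are held flat across 6→7. This keeps the two
  planted structures — trajectory shape and maturation direction —
  independent, so each can be recovered without confounding the other.
  Default up-fractions are 0.44 (post-ripening) and 0.24
  (non-post-ripening) with per-cultivar spreads of 0.005 and 0.028,
  i.e. the magnitude and spread of the reference percentages this
  package's group test is checked against.
* **Annotations** give each term its own background frequency
  (5–20%) and can plant one term at a stated odds ratio inside a chosen
  subset.

What the generator does *not* emulate: read-level artefacts (mapping
bias, positional coverage, duplicates), correlated gene-gene noise
outside the planted structures, UTRs (CDS = exons by default),
overlapping genes (a stress fixture for the precedence rule can be
built by hand), multi-mRNA genes, and indels. Passing tests therefore
demonstrate correctness of the computations on clean, known-truth
input, not robustness to upstream artefacts of real libraries.

## Problem sizes and reproducibility

The test-suite and acceptance runs use desk-scale sizes chosen to make
every check sharp but quick: 40-gene genomes with ~525 planted variants
for the classifier checks; 300–400 gene panels for recovery and power
properties; 80-gene null panels over 20 seeds for calibration; 100
simulated panels for the maturation power estimate; `n_perm` of
300–1000 depending on the check. All generators and stochastic stages
are seeded; the pipeline derives per-stage seeds from the global seed
by hashing the stage name, so toggling one stage never reshuffles
another's randomness, and identical configurations produce
byte-identical text outputs.

## Known limitations

* The classifier assumes single-nucleotide substitutions; indels are
  counted and skipped at VCF parsing.
* Splice-boundary semantics ("2 bp around the junction") follow the
  intronic donor/acceptor reading; tools using an exon-inclusive
  window will count class 3 differently.
* The static tree cut can split a sprawling module that dynamic
  cutting would keep whole.
* Profile significance treats genes as independent when computing the
  binomial tail; strongly co-expressed gene blocks can inflate observed
  counts faster than the null expects (the permutation preserves only
  per-gene exchangeability).
* UTR-bearing annotations produce `unclassified_utr` flags rather than
  classes; a taxonomy with explicit UTR classes would need one more
  category.
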