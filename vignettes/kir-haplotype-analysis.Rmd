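---
title: "Methods: KIR haplotype motifs, frequencies, diversity and dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KIR haplotype motifs, frequencies, diversity and dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirhaplo)
```

## The scientific setting

The human killer cell immunoglobulin-like receptor (KIR) locus on
chromosome 19 is a compact cluster of highly homologous genes encoding NK
cell receptors for HLA class I. Four framework loci are essentially always
present — *3DL3* at the centromeric end, *3DL2* at the telomeric end, and
the *3DP1*–*2DL4* pair in the middle — and they bracket two variable
regions. The centromeric and telomeric halves each come in a small number
of gene-content *motifs* (here: cA01, cB01, cB02, cB03 centromeric; tA01,
tB01 telomeric), and observed haplotypes are Cen × Tel combinations of
these motifs, reassorted by reciprocal recombination in the unique sequence
between *3DP1* and *2DL4*. Several genes are allele-level splits of a
single locus (*2DL2*/*2DL3* → *2DL2L3*, *3DL1*/*3DS1* → *3DL1S1*,
*2DS3*/*2DS5* → *2DS3S5*, *2DL5A*/*2DL5B* → *2DL5*): gene-content
arithmetic works at locus level, while motif identity is defined at allele
level (cA01 carries *2DL3*, cB01 carries *2DL2*).

`kirhaplo` models this structure (`load_registry()`), deduces haplotype
pairs from presence/absence plus linking typing and estimates haplotype
frequencies by EM (`em_estimate()`), quantifies nucleotide diversity
(`nucleotide_diversity()`), builds NJ trees from TN93 distances with
bootstrap and midpoint rooting, scans alignments for recombination
breakpoints (`breakpoint_scan()`), and estimates divergence times under a
calibrated strict clock (`date_divergence()`). A seeded synthetic-data
module generates every input with known truth, so the full pipeline is
testable without any external data.

## The registry and the motif nomenclature

The registry ships as an editable YAML fixture rather than hard-coded
tables: 13 loci (11 genes, 2 pseudogenes), six motifs with their gene
orders, and the seven observed Cen|Tel structures. The gene content of a
structure is the union of its two motifs plus the four framework loci;
*3DP1* is treated as part of every structure even though motif gene orders
do not list it, since it sits on the centromeric edge of the central
framework. The content of cB03 is only available from a published figure;
the fixture carries the transcription 3DL3–2DS2–2DL3–2DP1–2DL1. Where
*2DS3S5* occurs on both halves of one haplotype (cB01|tB01), the registry
models positional occurrences within each motif and reports locus-level
presence once.

Allele-level names follow the motif nomenclature `cXnn:mmm|tXnn:mmm`:
within each motif, the first distinct allele-combination registered gets
001, the next 002, and identical vectors re-use their number
(`name_allele_haplotype()`). Numbering follows registration order because
no frequency-based ordering rule is defined for this nomenclature; *3DP1*
alleles are counted with the centromeric vector.

## Haplotype-pair deduction and the EM frequency model

The default assay panel has one presence/absence assay per locus and one
linking (cis) assay per within-motif gene adjacency, at allele resolution,
and no assay spanning the *3DP1*–*2DL4* junction. A genotype signature is
the union of the two haplotypes' contents and within-haplotype links;
enumeration of all unordered structure pairs (`enumerate_ambiguity_classes()`)
shows which genotypes the panel cannot distinguish. Two properties of the
registry are worth spelling out:

* The classic phase ambiguities (cA01|tA01 + cB01|tB01 vs
  cA01|tB01 + cB01|tA01, and the cB02 analogue) arise exactly because no
  assay crosses the central junction: both alternative pairs involve the
  same four motifs.
* A junction-spanning assay (`cross_central = TRUE`) resolves such a class
  only when the junction-adjacent genes differ between the centromeric
  motifs involved. It separates the cA01/cB02 class (cB02 ends in *2DL2*,
  cA01 in *2DL1*) but not the cA01/cB01 class (both end in *2DL1*):
  gene-level adjacency carries no phase information there. Additional
  classes exist because cB02's presence and linking signature is a strict
  subset of cB01's — a cB01/cB02 heterozygote types identically to a cB01
  homozygote.

Frequencies are estimated by maximum likelihood under Hardy–Weinberg
random pairing: the E-step distributes each individual over its compatible
unordered pairs with weight proportional to $2 f_i f_j$ ($i \ne j$) or
$f_i^2$, the M-step counts expected chromosomes, and the log-likelihood is
asserted non-decreasing at every iteration (initialisation uniform,
tolerance $10^{-8}$ on the log-likelihood, at most 1000 iterations, no
restarts — the likelihood for this model class at this scale is
well-behaved). With no ambiguity the estimate reduces to direct allele
counting in one effective step.

Individuals whose signature matches no registered pair carry at least one
unregistered haplotype. Reference cohorts report such *chromosomes* (not
individuals) as "other", implying that the known chromosome of a half-other
individual is resolved. The default estimator therefore includes an
explicit "other" frequency class: an unmatched individual is explained as
(h, other) for every registered haplotype h whose complete presence and
linking signature is contained in the observation, or as (other, other).
This is approximate — the emission probability of an "other" haplotype's
content is not modelled, and a registered haplotype whose signature is a
subset of another's (cB02 under cB01) can absorb a little posterior mass
from half-other individuals — but it keeps the frequency estimates of
haplotypes with distinctive signatures unbiased, which parameter-recovery
simulations at cohort scale (200 cohorts of 192 individuals) confirm. Set
`other_class = FALSE` to instead exclude unmatched individuals entirely.

## Nucleotide diversity

`nucleotide_diversity()` estimates $\pi$, the mean proportion of differing
sites over all sequence pairs. Complete deletion (drop all columns with a
gap or N; the default, matching the conventional whole-gene analysis) and
pairwise deletion are both available. The sampling variance is the
standard closed form combining stochastic and sampling components,

$$V(\hat\pi) = \frac{n+1}{3(n-1)L}\,\pi + \frac{2(n^2+n+3)}{9n(n-1)}\,\pi^2,$$

with $L$ the number of compared sites (mean pairwise $L$ under pairwise
deletion). Gene regions are extracted from 250 bp upstream of the start
codon through the polyadenylation site; annotations flagged truncated
(3DP1-style) end at exon 5 instead. Because the original region-level
segmentation is not specified numerically anywhere recoverable, the
region profile is realised as sliding windows (default 500 columns,
step 100) and the segment-level comparison (`segment_group_summary()`) is
validated by *ranking* properties on synthetic data, not by absolute
values. Coordinates are 1-based inclusive alignment columns throughout
(the GFF3 convention); BED-like partition files are converted at input.

## Phylogenetics and the breakpoint scan

Distances are Tamura–Nei (TN93) with pairwise deletion by default,
computed by `ape::dist.dna()` behind `tn93_distance()`; saturated pairs
receive a configurable finite ceiling (default 5 substitutions/site) with
a warning. Trees are neighbor-joining (`ape::nj()`); negative branches are
clamped to zero with the deficit moved to the sister branch. Bootstrap
support resamples columns with replacement (default B = 500) and counts
the replicate trees containing each bipartition of the point estimate;
rooting is by midpoint. Parsimony search is deliberately omitted — for
these data NJ and parsimony were found interchangeable — and no
likelihood/Bayesian tree search is attempted.

The recombination scan replaces interactive breakpoint inspection with an
executable statistic. Each column is scored as supporting one of two
candidate bipartitions (both sides monomorphic at two distinct bases);
the breakpoint estimate maximises the 2×2 chi-square of support counts
left versus right of a candidate split, reported at the midpoint of the
uninformative gap between the flanking informative columns (every split
inside that gap yields the same table, and the midpoint halves the
worst-case localisation error, which is set by the local density of
informative sites — about one per 20 columns at 5% parental divergence).
Significance comes from permuting the order of the informative columns
(default 999 permutations, seeded). With the default study conditions
(5% parental divergence, 1000 columns) simulated breakpoints are located
within ±25 columns in at least 18 of 20 replicates.

## Strict-clock divergence dating

Full Bayesian node dating is replaced by a desk-scale calibrated strict
clock: for a calibration split of age $t$ the mean between-group distance
satisfies $\bar d = 2rt$, so the per-lineage rate is fitted by least
squares through the origin over the calibrations,
$r = \sum_k \bar d_k t_k / (2\sum_k t_k^2)$. Two-sided calibrations (e.g.
human–chimpanzee 6.5–10 My) contribute their midpoint; one-sided bounds
(gorilla > 10 My, orangutan < 18 My) contribute the bound value, flagged
as such. A query split is dated as $\bar d / (2r)$, with a column
bootstrap re-estimating both $\bar d$ and $r$ per replicate to give a
percentile CI and SD. Between-group distance is the arithmetic mean over
all cross pairs rather than a tree-path quantity, which is robust to
non-ultrametric noise and matches the calibration identity. Ages are
exactly scale-equivariant in the calibration ages. Recombinant sequences
violate the single-history assumption and must be excluded; the `exclude`
argument takes the labels flagged by `breakpoint_scan()`. Acceptance of
this module is by parameter recovery on clock-like simulations (50
replicates, 3 kb, rate 0.002 subs/site/My, a 6 My query split calibrated
at a sibling 8.25 My node), not by reproducing published real-data ages,
which would require the original alignments and sampler.

## The synthetic-data module

`simulate_cohort()` draws 2n haplotypes i.i.d. from a frequency vector —
by default the pooled reference vector derived from the published
chromosome counts (232, 45, 10, 34, 28, 13, 2, and 21 "other",
normalised) — and types them with the panel. "Other" chromosomes get a
random unregistered gene content (framework plus a fair coin per remaining
locus, rejecting registered contents) and contribute presence but no
linking signal, since their gene order is unknown by construction. True
pairs are retained for recovery scoring.

`simulate_alignment_on_tree()` evolves sequences along a dated tree under
a Kimura two-parameter process (default transition/transversion rate
ratio 2.0), with branch ages in My multiplied by a rate in
substitutions/site/My; TN93 is used only for estimation, so the
estimator-vs-simulator model mismatch is itself exercised.
`make_mosaic()` builds recombinants with known breakpoints, and
`simulate_ab_gene_fixture()` produces the per-gene, per-segment diversity
contrast (12 genes across Cen-A/Cen-B/Tel-A/Tel-B; default 8 sequences ×
1500 columns per gene at baseline diversity 0.005, values typical of
KIR-scale allelic variation) used to test segment-ranking properties such
as "Tel-A ranks highest when generated at 3× diversity".

What the generators deliberately do not emulate: coalescent demography
and linkage between loci in cohorts (chromosomes are i.i.d. draws),
indels and alignment error, copy-number variation beyond presence/absence,
rate variation among sites and lineages, and sequencing/typing error.
Passing tests therefore demonstrate correctness of the estimators under
their own assumptions, not robustness to every property of real data.

## Numerical choices and degenerate inputs

* EM: uniform initialisation; `tol = 1e-8` on the log-likelihood;
  monotonicity asserted; cohorts where no individual matches any pair are
  an error.
* Diversity: zero usable sites is an error; identical sequences give
  $\pi = 0$ with zero variance; trailing partial windows are dropped.
* TN93: saturation → ceiling with warning, never NaN. NJ: ties inherit
  the agglomeration order of the underlying implementation; negative
  branches clamped. Midpoint ties are broken by the implementation's
  traversal order (measure-zero for continuous branch lengths).
* Breakpoint scan: no informative columns is an error; all informative
  columns favouring one grouping returns a degenerate no-signal result
  (p = 1) rather than a spurious split.
* Dating: zero between-group calibration distance is an error; groups
  must be disjoint and present.
* All generators take a `seed` argument and are bit-reproducible under it.

## Problem sizes used in the packaged checks

The packaged test suite runs at the sizes chosen for the study design:
200 cohorts of 192 individuals for frequency recovery; 1000 random
alignments (n ≤ 8, L ≤ 200) for the diversity oracle; 100 random additive
trees (n ≤ 12) for NJ exactness; 20 mosaic replicates for breakpoint
localisation; 50 clock-like replicates (B = 100 bootstrap) for dating
recovery; 100 seeds for the segment-ranking property. These sizes make
the whole suite run in a couple of minutes on one CPU while keeping
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The "other" class is a coarse mixture model; frequencies of registered
  haplotypes whose typing signature is a subset of another's (cB02 vs
  cB01) are the least identifiable quantities under the default panel.
* The strict clock assumes rate constancy across the tree; lineage-specific
  rate variation biases ages in proportion.
* The breakpoint scan detects a single dominant breakpoint per run; nested
  or multiple breakpoints require scanning sub-regions.
* The registry describes gene-content haplotypes; copy-number expansions,
  deletions of framework genes and fusion genes are out of scope and are
  surfaced only as "other" genotypes.
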