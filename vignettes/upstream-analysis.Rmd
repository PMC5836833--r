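---
title: "Upstream analysis: from expression changes to master regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upstream analysis: from expression changes to master regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upstreamr)
```

## The question the pipeline answers

A differential-expression experiment tells you *which* genes moved; it
does not tell you *why*. Upstream analysis works backwards through two
layers of regulation to propose a causal answer:

1. **Promoter layer.** If a coherent set of genes is up-regulated, the
   transcription factors (TFs) driving them should leave a footprint:
   binding sites for those TFs should be over-represented in the
   promoters of the up-regulated ("Yes") genes relative to promoters of
   unchanged ("No") genes, and the sites of cooperating TFs should
   co-localize the way enhanceosome components do.
2. **Signaling layer.** The implicated TFs are themselves activated by
   signaling cascades. Searching a directed signal-transduction network
   for nodes that sit upstream of many of the implicated TFs within a
   bounded number of steps points to *master regulators* — the nodes
   whose perturbation would move the whole transcriptional program, and
   hence natural drug-target candidates.

A final *positive-feedback filter* keeps only master regulators whose own
encoding gene is up-regulated **and** whose promoter carries the
discovered composite module: such loops can maintain an expression state
(for instance, a drug-resistance program) autonomously.

Because the data that motivated this design — microarrays of drug-treated
cancer cell lines and the commercial TRANSFAC/TRANSPATH databases — are
not redistributable, every stage here is validated against a
synthetic-data generator that plants a known truth (motifs, site pairs,
spiked genes, a wired-in regulator, a dose-response curve) and then asks
each stage to find it.

## Promoter scanning

Promoters are windows around the transcription start site; the
conventional window, and our default, is 1000 bases upstream plus 100
downstream (1100 bases). Motifs are position weight matrices (PWMs):
per-position nucleotide counts. A subsequence of matrix length $L$ is
scored by the information-weighted normalized similarity

$$\mathrm{score} = \frac{\mathrm{Current}-\mathrm{Min}}
{\mathrm{Max}-\mathrm{Min}},\qquad
\mathrm{Current}=\sum_{i=1}^{L} I(i)\, f_i(b_i),\qquad
I(i)=\sum_b f_i(b)\ln 4 f_i(b),$$

where $f_i(b)$ are column frequencies after a pseudocount of 0.25 per
cell, and Max/Min substitute each column's most/least likely base. The
score lives in $[0,1]$; the consensus word scores exactly 1; an `N` base
contributes the column minimum; a zero-information (uniform) matrix is
defined to score 0. The pseudocount keeps $\ln f$ finite; its size only
matters for near-degenerate columns. Both strands are scanned by default
(whether the original tools did is not documented; a flag disables it),
and minus-strand sites are reported at their forward-strand start so
co-localization windows are strand-agnostic. All offsets are 0-based,
windows half-open. Overlapping sites are all reported — deduplication
would only matter for speed, not correctness, at this scale. The inner
scan loops are C++; everything else is plain R.

## Per-matrix enrichment (cutoff optimization)

For one PWM with cutoff $c$, count sites at score $\ge c$ in the Yes and
No sets. Enrichment is the ratio of per-sequence site frequencies

$$R_{YN} = \frac{\mathrm{Sites}_{Yes}/\mathrm{Sites}_{No}}
{\mathrm{Seq}_{Yes}/\mathrm{Seq}_{No}},$$

and its significance is the binomial upper tail of seeing
$x=\mathrm{Sites}_{Yes}$ of $N=\mathrm{Sites}_{Yes}+\mathrm{Sites}_{No}$
sites land in the Yes set when each lands there with probability
$p=\mathrm{Seq}_{Yes}/(\mathrm{Seq}_{Yes}+\mathrm{Seq}_{No})$. Using
sequence counts for $p$ is exact when both sets use equal-length
windows, which the extraction step guarantees. The numerator of $p$ is
read as the Yes sequence count — the only reading under which $p$ is a
success probability. The optimizer walks the distinct observed scores
from the top, keeps thresholds with $p \le \alpha$ (default 0.01) and at
least `min_yes_sites` (default 5 — a floor we add to exclude degenerate
one-site optima) Yes sites, and returns the ratio maximum, breaking ties
toward smaller $p$ and then the higher threshold. When
$\mathrm{Sites}_{No}=0$ a pseudocount of 0.5 keeps the ratio finite; the
binomial tail needs no such correction. Matrices with $R_{YN}>1$ and
$p<0.01$ pass to the next stage; no multiple-testing correction is
applied at this step (a BH-adjusted column is emitted for information
only), matching the conventional use of this filter as a candidate
generator rather than an inference.

## Composite modules by genetic algorithm

Cooperating TFs bind near one another. A *composite module* is a set of
2–15 matrices, each with its own cutoff and nonnegative weight, plus a
co-localization window $w$. A promoter's composite score is the maximum
over window placements of the weighted sum of each member's best site
(at or above its cutoff) inside the window; it is enough to anchor
candidate windows at observed site starts. The functional form is the
simplest one consistent with a single per-promoter score; pairwise
distance bonuses are deliberately omitted — the window already encodes
co-localization.

The GA encodes (membership, cutoffs, weights, window) per individual;
fitness is $-\log_{10}$ of the one-sided Wilcoxon rank-sum p-value (Yes
scores larger). We use the one-sided test because a module that scores
*No* promoters higher is not a discovery under this model; AUC breaks
fitness ties. Operators: tournament selection (k = 3), uniform crossover
on membership with parameters inherited from the contributing parent,
Gaussian mutation on cutoffs (sd 0.05) and weights (sd 0.2),
multiplicative window mutation, membership add/drop, elitism 2. Defaults
are population 100 and 200 generations — enough for planted-pair
recovery to saturate at desk scale — and the whole search is a pure
function of its seed. Whether the original fitness added site-count
penalties is unknown; ours is the pure rank-sum form.

The *critical value* reported with a module is the composite-score
threshold minimizing the sum of false-positive and false-negative rates
on the training sets (ties toward the higher threshold). Two caveats are
worth stating plainly. First, published critical values from other
systems (e.g. 8.77 on a commercial matrix library) are on a different
score scale and are not comparable; the critical value is always
data-derived here. Second, all module metrics are **training** metrics:
with ~20 candidate matrices and continuous cutoffs the GA can and does
overfit, so when a planted pair covers only a fraction $q$ of Yes
promoters the *population* AUC cannot exceed $q + (1-q)/2$, while the
training AUC can sit slightly above it. Passing planted-pair tests shows
the machinery works; it does not certify out-of-sample separation on
real promoters.

## Master-regulator search

The network is a directed graph of molecules (proteins, complexes,
modified forms); an edge points from regulator to regulated. For a
candidate node $m$ and TF set $T$, with $d(m,t)$ the shortest directed
path length, the score is

$$S(m) = \frac{1}{|T|}\sum_{t \in T,\ d(m,t)\le r} \frac{1}{1+d(m,t)},$$

with radius $r = 12$ steps by default. The form is a reconstruction
(the published tool does not print its formula): it rewards covering
many TFs at short distances, is bounded in $(0,1]$, and a node directly
regulating every TF scores 0.5. Significance comes from a permutation
null — `n_perm` random TF sets of the same size, giving a per-node
$z$-score (sd floored at $10^{-9}$) and an empirical FDR (the fraction
of all null scores at least as high as the observed one, divided by the
fraction of observed scores at least as high, clipped to $[0,1]$).
`ranks_sum` adds the score rank and the $z$ rank (min-tie rule), and the
output is sorted by it. The null draws from all gene-annotated nodes by
default rather than only annotated TFs: with realistic inputs the
annotated-TF universe can be barely larger than the observed set, which
degenerates the null; the `tf_universe` argument restores the stricter
choice when the network is rich enough. Complexes and modified forms are
distinct nodes sharing gene symbols, and the feedback filter passes a
node if *any* of its member genes is an up-regulated composite-module
carrier, since one constitutively activated member suffices to close the
loop.

## Differential expression, GSEA, overlap, IC50

*Differential expression* goes through the standard linear-model
empirical-Bayes route (limma), which is also what the original analysis
used; a plain Welch t per gene is available as a cross-check
(`method = "welch"`). Technical replicates are averaged before testing —
unbiased for the fold change and conservative for the p-value, a simpler
stand-in for duplicate-correlation modelling. DEG thresholds are strict
inequalities, default p < 0.05 and |logFC| > 0.58 (fold change 1.5);
multiple testing is Benjamini–Hochberg (the source analysis does not
name its correction).

*GSEA* uses the weighted running-sum statistic (weight exponent 1 on
|logFC|), gene-label permutations (the pipeline receives a precomputed
ranking, so phenotype permutation is unavailable), sign-matched NES
normalization, and an add-one permutation p. The magnitude extremum
defines ES, with exact positive/negative ties resolved positive.
*Set overlap* uses the hypergeometric upper tail; the universe size is a
parameter because it rarely appears in print. *IC50* comes from probit
regression of the dead fraction on $\log_{10}$ concentration
(quasi-binomial GLM/IRLS; logit via flag), zero-concentration controls
excluded, fractions nudged by $1/(2n)$ to keep the transform finite,
$\mathrm{IC}_{50} = 10^{-\beta_0/\beta_1}$ with a delta-method standard
error. The default concentration series (34, 17, 8.5, 4.25, 2.2, 0 uM,
triplicates) mirrors a typical cytotoxicity design.

## What the synthetic generator does and does not emulate

The generator produces: Dirichlet-biased PWMs with one consensus base
per column (count columns summing to ~100); i.i.d. background promoters
at a chosen GC content split evenly within S/W pairs; planted sites
sampled from the matrix columns (consensus planting is a flag used by
exactness tests) on random strands, pairs placed within a bounded gap;
Gaussian log2 expression with spiked fold changes in a
2-condition × 3-line × 2-replicate layout; a directed Erdős–Rényi
network with a planted regulator wired to a chosen fraction of TF nodes
within a bounded depth; and probit dose-response tables with additive
noise. Defaults (promoter length 1100, GC 0.5, noise sd 0.2 log2 units,
spike 1 log2 unit, 70%/60% plant fractions, six-concentration triplicate
viability at IC50 15 uM with noise 0.05) reflect the magnitudes typical
of such studies and are fixed once — tests treat them as the study
condition, not as dials.

It deliberately does **not** emulate: array probe effects or
normalization artifacts, promoter sequence composition beyond i.i.d.
background (no CpG islands, repeats, or real genomic context),
correlated gene expression, scale-free network topology, or
multi-isoform TSS structure. Passing plant-recovery tests therefore
demonstrates correctness of the algorithms under their own model
assumptions, not performance on real regulatory genomics data.

## Pipeline assembly and problem sizes

`run_pipeline()` chains the stages: DEGs → Yes set (up-regulated genes;
the focus is positive feedback, which is maintained through
up-regulation) → No set (clearly non-changed genes, |logFC| < 0.2 and
p > 0.5, capped at five times the Yes size by a seeded subsample; GC/
length matching is off by default) → enrichment → composite module
(candidates are the passing matrices when at least four pass, else the
whole library) → master regulators → feedback filter, with GSEA and
IC50 side channels. Every intermediate is written as TSV/JSON, and the
manifest records the seed, a config hash and per-stage row counts, which
is sufficient to reproduce the run. All stage seeds derive from the one
config seed, so reruns are byte-identical.

The shipped synthetic study uses 2000 genes (150 spiked), ~20 matrices,
one 1100-base promoter per gene, a 300-node network and 1000
permutations; the test suite and the acceptance script use these or
smaller sizes so a full run takes minutes on one core. They scale
linearly in genes × promoter length × matrices for scanning and in
population × generations × promoters for the GA.

## Numerical choices and degenerate inputs

- Scores are clamped to $[0,1]$ after the normalized-sum division to
  absorb floating-point underflow at the boundaries.
- The binomial tail is `pbinom(..., lower.tail = FALSE)` (log-space
  internally); $x = 0$ returns 1 exactly.
- The Wilcoxon test enumerates all splits when the pooled size is at
  most 12 (ties handled by mid-ranks in the U statistic); otherwise the
  normal approximation with tie correction, without continuity
  correction. All-tied input returns p = 1.
- Probit fitting refuses flat responses (zero variance after nudging)
  and non-positive slopes rather than returning an extrapolated IC50.
- Empty enrichment score lists, empty gene sets, constant-expression
  genes, and promoters shorter than a matrix are all handled as
  explicit, warned or rejected cases rather than NaNs.

## Known limitations

The Match-style score, composite-score form, master-regulator score and
ranks-sum are reconstructions from tool descriptions, not ports; their
published counterparts may differ in detail, so absolute values
(cutoffs, critical values, scores) should not be compared across
implementations — only the within-run ordering and significance logic.
Training-set module metrics overstate generalization (see above). The
permutation FDR is a coarse empirical estimate, not a proper q-value.
The generator's independence assumptions make plant-recovery easier than
real data; thresholds that pass here may need re-tuning on real
promoters and networks.
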