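---
title: "Methods: multi-region subclonal reconstruction in mrclone"
author: "mrclone authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region subclonal reconstruction in mrclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrclone` analyzes tumors sampled in several regions per animal. Each stage
of the pipeline rests on a small mixing model between cancer cells (a
fraction $p$ of the sample, the *purity*) and admixed normal cells; this
vignette lays out the models, the tunable parameters, the numerical
decisions, and what the synthetic validation does and does not establish.

## Purity from a qPCR standard curve

The assay amplifies a template that Cre recombination removes from tumor
cells, so the Ct value rises linearly with the fraction of cancer cells.
`fitStandardCurve()` fits $Ct = A\,x + B$ by ordinary least squares over
*all replicate points* of the dilution series (0, 10, 20, 40, 60, 80, 100%
cancer-cell DNA, triplicate). Fitting raw replicates rather than replicate
means uses all the information and weights dilution levels by their
replicate counts; with balanced triplicates the two choices coincide.
`estimatePurity()` inverts the line per replicate, averages, and clamps to
$[0,1]$ — assay noise can push an estimate slightly past the outermost
standard, and a clamp is preferable to a hard error there.

## Copy number

The observed log ratio of a segment is

$$\log_2 R^{obs} = \log_2\!\frac{p\,CN_T + (1-p)\,CN_N}{CN_N},$$

which `purityCorrect()` inverts to a real-valued copy number, rounded to
integer and floored at zero. The inversion is exact: round-tripping every
$CN_T \in [0,10]$ through the forward map at any $p > 0$ recovers the input.
$CN_N = 2$ on autosomes; sex chromosomes are excluded from focal calling.

**Segmentation.** Probe tracks are segmented by recursive binary splitting:
the candidate split maximizes the standardized mean difference
$|\bar x_L - \bar x_R|\sqrt{k(n-k)/n}$, and is accepted when it beats the
permutation distribution of that statistic at level $\alpha = 0.01$
(100 permutations per decision by default; with the $+1$ correction this
effectively demands zero permutation exceedances, a deliberately strict
gate). Boundaries sit halfway between flanking probes; segments need at
least 3 probes. Over-segmentation from noise is then undone by
`mergeUndo()`: adjacent segments whose means differ by less than 3 pooled
within-segment standard deviations are merged, closest pair first, to a
fixpoint — so the operation is idempotent.

**Focal and large-scale events.** Focal events are homozygous deletions
($CN_T = 0$) or amplifications ($CN_T \ge 5$, i.e. a gain of at least three
copies over diploid) under 4 Mb, on at least 5 probes, on autosomes;
same-class events with boundaries under 100 kb apart merge into one; events
must overlap the coding span of at least one gene (any positive overlap —
no minimum is imposed beyond 1 bp). The 4 Mb limit is configurable
(`pipelineParams(focalSizeLimit=)`); 5 Mb appears as an alternative
definition in parts of the literature and is a flag away. Events from
different regions (or different mice, for recurrence counting) are the
*same* event when their spans share overlap/union $\ge$ 50% — evaluated in
integer base pairs (`2·overlap ≥ union`) so the printed boundary is exact.
A chromosome is a large-scale gain (loss) when segments above (below)
$CN_N$ cumulatively cover at least half its length; cumulative rather than
single-segment, since segmentation may fragment one arm-level event.

Internal coordinates are 0-based half-open throughout (BED convention);
SEG I/O converts from 1-based inclusive at the boundary of the package.

## Allelic imbalance

With one allele lost in the tumor cells, the expected tumor minor allele
frequency is

$$\mathrm{MAF} = \frac{1-p}{2-p},$$

0.5 at $p = 0$ and 0 at $p = 1$, strictly decreasing in between. Because
the observable separation between this and the balanced 0.5 class shrinks
with purity and coverage, the calling threshold is calibrated *per sample*:
`calibrateMafThreshold()` simulates 10,000 binomial SNPs per class at the
sample's coverage, averages MAFs over disjoint consecutive subsets of 10
(1,000 points per class — disjoint blocks, since the averaging is a
variance-reduction device, not a bootstrap), sweeps thresholds 0–0.50 in
steps of 0.01 classifying "below threshold = imbalance", and keeps the
maximum-F1 threshold among those with sensitivity and specificity above
0.8. If no threshold qualifies, the sample is flagged `lacking_power` and
contributes nothing downstream.

`testAllelicImbalance()` compares tumor and normal MAFs at the 10
informative SNPs (both depths $\ge 20$) nearest each gene midpoint (mean of
coding start and end, same chromosome, distance ties broken by lower
coordinate) with a one-tailed *paired* t test — pairing is the natural
choice since tumor and normal are measured at the same positions.
Benjamini–Hochberg correction is applied once per sample across all tested
genes; a gene is called only when FDR < 5% *and* its mean tumor MAF is
below the calibrated threshold. Per mouse, region calls are unioned over
powered regions; cohort-level enrichment per gene is an upper-tail binomial
test at the mean per-mouse AI fraction, BH-corrected across genes, with $n$
counting powered mice only.

## Cancer cell prevalence and multiplicity

For a mutation at multiplicity $m$ in a locus of copy number $CN_T$,

$$v_{exp} = \frac{p\,m\,C}{p\,CN_T + (1-p)\,CN_N},$$

and the variant read count is $\mathrm{Bin}(r_{tot}, v_{exp})$.
`prevalencePosterior()` evaluates that likelihood on the grid
$C \in \{0, 0.01, \dots, 1\}$ and normalizes — a discrete posterior under a
flat prior. The point estimate is the grid argmax (which provably tracks
the closed-form MLE $\min(1, \hat v (p\,CN_T + (1-p)CN_N)/(p\,m))$ within
one grid step); the interval is the central 95% of grid mass, widened if
needed to contain the argmax (relevant at the $C = 0$ boundary, where an
equal-tailed cut could exclude the mode).

Multiplicity: $CN_T \in \{1,2\}$ forces $m = 1$. In gains, every
$m \in [1, CN_T]$ is enumerated and values implying raw prevalence above
$1 + 0.05$ are ruled out (the 0.05 tolerance absorbs binomial noise at the
boundary); exactly one survivor resolves $m$, otherwise the prevalence is
missing. Zero variant reads give $\hat C = 0$ regardless of $m$. Mutations
in $CN_T = 0$ segments (reads in a deleted locus — an inconsistency between
calls) are treated as missing. Regions whose mutations all sit at VAF
$\le 0.02$, or that lack a copy-number profile, are excluded from
prevalence analysis entirely and recorded as exclusions in the report.

## Clustering

Mutations are clustered on their prevalence vectors across analyzed
regions. The primary method is DBSCAN over a radius sweep
(0.02–0.30, step 0.02, `minPts = 4`), gated on at most 20% noise points and
average silhouette $\ge 0.25$, best silhouette winning. Two deliberate
departures from the simplest formulation, both motivated by measured
failure modes on ground-truthed synthetic mice:

* `minPts = 4` rather than 2: with around ten mutations per cluster,
  two-point cores let single stray points chain adjacent clusters together
  and also let chance pairs nucleate spurious clusters.
* a **divisive refinement** pass: the average silhouette is biased toward
  coarse solutions in nested subclonal data, because the dominant gap
  between the clonal cluster (prevalence $\approx 1$ everywhere) and the
  subclonal clusters rewards merging adjacent subclonal groups. After the
  global selection, each cluster is therefore re-swept in isolation and
  split when the local solution is strong (silhouette $\ge 0.45$ — a
  stricter gate than the global 0.25, guarding against chance density gaps
  in small clusters) and the split centers differ by at least 0.10
  prevalence in some region (differences below the posterior's resolution
  do not define distinct subclones).

When no multi-cluster solution passes the gates, a single dense cluster is
accepted if some radius yields one; otherwise affinity propagation
(negative squared Euclidean similarity, median preference, damping 0.9)
is the secondary approach. Noise points are attached to the nearest
centroid at the end. Mutations with missing prevalences are clustered on
the complete regions when some region is complete for all mutations, and
excluded (with `NA` assignment) otherwise.

## Subclone trees

Under the infinite sites assumption, an ancestor's prevalence is at least
its descendant's in every region, and children of one node cannot sum above
their parent in any region. `precedenceTest()` rejects "i may parent j"
when some region shows $\bar C_j - \bar C_i$ exceeding
$z_{0.95}\sqrt{s_i^2 + s_j^2}$ (sds floored at 0.02 so tight clusters do
not make the test vacuous). A root representing the knock-in ancestral cell
(prevalence 1 everywhere — every cancer cell carries the initiating
transgenes) is always added above the data clusters. `enumerateTrees()`
then scores *every* rooted labeled tree — exhaustive enumeration is exact
and tractable at the study's scale of 2–7 clusters (at most $8^7$ parent
assignments, enumerated in C++); more than 8 clusters is refused rather
than approximated. Cost = precedence violations (per edge) + sum-rule
violations (per node and region, with tolerance 0.10 absorbing estimate
noise); all minimal-cost trees are returned in deterministic order and
never silently reduced to one: the per-mouse `topology` is reported only
when all tied trees agree, and `NA` otherwise. A tree is *linear* when no
node has two children; the *synchronous primary* flag is set when the root
has several children and no non-root cluster reaches prevalence 0.5 in
every region — the signature of two independently initiated tumors
colliding.

## The synthetic cohort

`simulateCohort()` generates the study design end to end: 12 mice (half
KPC, half KPTC), 3 regions each, a truth tree of 2–7 clusters per mouse
(linear, branched, or two synchronous primaries), per-region purity,
amplicon read counts at 300$\times$ mean coverage (Poisson depth, binomial
variant reads at the model's $v_{exp}$, 50/50 binomial strand split — no
strand bias model is implied by the data), aCGH probes every 10 kb with
Gaussian noise (sd 0.15 by default), het-SNP counts at 70$\times$ tumor /
100$\times$ normal depth, and qPCR standards. Cluster prevalence vectors
are pairwise separated by at least 0.15 (sup norm), the margin at which
downstream recovery is tested. Mutations get $m = 1$ except in clonally
gained loci, where $m$ is uniform on $[1, CN_T]$, exercising the deduction
logic. A focal homozygous deletion is planted at a fixed locus in a
configurable subset of mice to validate cross-mouse recurrence counting.
The generator does *not* simulate reads (no FASTQ/BAM), sequencing error,
indels, subclonal copy number, or spatially structured sampling — the
regional prevalences are drawn freely subject to the tree, since the
spatial arrangement of subclones across regions is not constrained by the
model. Passing tests therefore demonstrate correctness of the inference
given the generative model, not robustness to artifacts real amplicon data
can contain (strand bias, mapping error, FFPE damage).

## Validation design and problem sizes

The test-suite and acceptance computations use a 4-autosome, 50 Mb/chromosome
genome with 200 genes — every rule under test is interval arithmetic, so
compact coordinates lose no generality while keeping the suite fast.
Specific validation choices worth stating:

* **Error control / power of allelic-imbalance calls** is measured on 20
  null samples $\times$ 200 genes (false-positive rate against the nominal
  5% FDR with a binomial Monte-Carlo allowance) and on genes inside a
  simulated one-copy loss at $p = 0.6$, coverage 70 (detection
  $\ge 90\%$).
* **Clustering agreement** is scored by adjusted Rand index on
  margin-separated clusters with prevalence noise sd 0.03, ten mutations
  per cluster.
* **Tree recovery** is evaluated over 20 mice at 300$\times$ on cluster
  centers and spreads formed per generating cluster — validating the
  precedence/sum-rule search against known truth. Recovering the *number*
  of clusters from scratch is reported separately: a power analysis
  ($\mathrm{sd}(\hat C) \approx (2/p)\sqrt{v(1-v)/r_{tot}}$, i.e. up to
  ~0.06–0.09 per region at realistic purity) shows that at the 0.15 margin
  floor the cluster count is genuinely ambiguous for a fraction of mice at
  300$\times$, so count recovery lands around 70–80% rather than being a
  near-certain event; in practice this ambiguity is the kind an analyst
  resolves by visual inspection of the clustering solutions.

## Known limitations

* Purity correction assumes one dominant clone sets each segment's copy
  number (no subclonal SCNA mixture).
* The prevalence model treats $r_{tot}$ as fixed and ignores
  overdispersion beyond binomial.
* Tree search is cluster-level; mutation-level placement and branch
  lengths/timing are out of scope.
* Affinity propagation's cluster count is governed by the preference
  (median similarity here) and is not tuned per sample.
* The permutation segmentation is a deliberate simplification of full
  circular binary segmentation; with very short alternating segments it is
  more conservative than CBS at defaults.
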