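---
title: "Methods: probe design, normalization and the drought-memory taxonomy"
author: "droughtmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe design, normalization and the drought-memory taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtmem)
```

This vignette documents the models and procedures behind `droughtmem`, the
choices made where the design was genuinely open, and what the package's
tests do and do not establish about real data.

## 1. Probe design

### Coordinates and anchoring

All probe arithmetic is done in *transcript coordinates*: 1-based, with
position 1 at the 5' end, obtained by splicing the exons and
reverse-complementing on the minus strand. The anchor is `stop_end_tx`,
the transcript position of the last base of the stop codon (the CDS is
assumed to include the stop codon; annotations that exclude it can be
accommodated with `stop_codon_included = FALSE`, which extends the CDS end
by 3 bases).

With a full CDS flank and a 3'-UTR of at least 60 nt, the three 60-nt
tiling probes occupy

```
TILE1 = [stop - 59, stop]
TILE2 = [stop - 29, stop + 30]
TILE3 = [stop + 1,  stop + 60]
```

whose union is exactly 120 bases split evenly across the CDS/3'-UTR
boundary. This anchoring is the only reading of "starting 60 bp upstream
of the stop codon, shifting downstream at 30-bp intervals" that yields 60
coding and 60 untranslated bases.

Two degenerate regimes are handled deterministically:

* **Short 3'-UTR** (< 60 nt): the whole three-probe frame shifts upstream
  by the deficit so TILE3 still ends on the transcript. This preserves
  both the probe count and the 30-bp spacing at the cost of covering more
  CDS; the alternative (dropping probes) would bias detection against
  short-UTR genes.
* **Short upstream flank**: probes whose start would fall before position
  1 are omitted rather than truncated, since a sub-60-mer changes
  hybridization behaviour. Transcripts under 60 nt get no probes, with a
  recorded reason.

### Representative isoforms and unique exons

The representative transcript of a gene anchors its tiling probes. No
selection rule is standard here, so the package fixes a deterministic one:
longest total CDS, ties broken by longest spliced sequence, then by
lexicographically smallest transcript id. A 3'-anchored design needs a
well-defined stop codon, which is why CDS length leads.

A *unique exon* is an exon of the representative whose exact genomic
interval (both boundaries) appears in no sibling isoform. Exact boundary
matching was chosen over partial-overlap tests because it is unambiguous
and directly testable; a partially shifted exon still shares most of its
sequence with its siblings and would make a poor discriminating probe
target anyway. Unique-exon probes are centred in the exon and require at
least 60 nt of exon.

### Cross-hybridization screening

A probe is considered cross-hybridizing when its exact 60-mer, or the
reverse complement, occurs in any transcript of a *different* gene;
matches to the probe's own gene's isoforms are expected (the tiling region
is usually shared across isoforms) and exempt. The exact-match criterion
is the simplest reproducible rule; near-match screening (allowing k
mismatches) changes the decision boundary but not the mechanics and can be
layered on the same counting interface.

Dropping is conservative: per tiling trio at most one probe — the one with
the most cross-gene matches, ties resolved against the higher
`start_tx` — is removed, so every transcript keeps at least two probes.
Unique-exon and control probes are dropped on any cross-gene match since
their whole purpose is specificity.

### Controls

Organellar genes and selection markers are supplied as FASTA and receive
three tiling-style probes anchored at the sequence end (they carry no CDS
annotation, so the frame-shift rule with a zero-length 3'-UTR places the
last probe flush with the 3' end). Control sequences are user-supplied
rather than bundled.

## 2. Normalization

The chain is: per-column background subtraction at the 5th percentile with
a positive floor (`offset`, default 1), log2 transform, quantile
normalization. The background quantile, floor and the probe-to-transcript
summary statistic (median over the tiling probes, mean available) are all
configurable.

Quantile normalization replaces each column's values with the
across-column mean of order statistics at their ranks; tie groups receive
the mean of their rank-range targets. Two of its properties matter for
interpretation:

* After normalization every array shares one multiset of values — this is
  asserted exactly in the tests (on tie-free data).
* It *assumes rank stability*: a transcript that occupies the extreme
  ranks of one array but not another is pulled toward the common
  reference, attenuating its measured fold change. Fold-change screens on
  transcripts at the very top or bottom of the intensity distribution are
  therefore conservative. This is inherent to the method, not an
  implementation artifact, and it shaped the synthetic generator defaults
  (section 5).

## 3. Moderated differential statistics

Per transcript, condition means are fitted and the residual variance
$s^2$ (with $d$ residual degrees of freedom, $d = 4$ for the 8-array
design) is shrunk toward a prior:

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d}$$

The hyperparameters are estimated by closed-form moment matching on
$z = \log s^2$: under the scaled-chi-square model,
$\mathrm{Var}(z) = \psi'(d/2) + \psi'(d_0/2)$, so $\psi'(d_0/2)$ is read
off the observed excess spread of $z$ and inverted numerically
(trigamma is monotone), and $s_0^2$ follows from the mean of $z$ with the
digamma bias correction. This is deterministic and needs no iteration.
Degenerate inputs are handled explicitly: when the rows show *no* spread
in $\log s^2$ the prior collapses to the common variance (so shrinkage is
a no-op), and when the spread does not exceed chi-square sampling noise,
$d_0 = \infty$.

The moderated t for contrast $A - B$ is
$t = (\bar x_A - \bar x_B) / (\tilde s \sqrt{1/n_A + 1/n_B})$ on
$d_0 + d$ degrees of freedom, with Benjamini–Hochberg adjustment per
contrast. Two limits are asserted numerically in the tests: $d_0 = 0$
recovers the ordinary linear-model t, and a forced $d_0 = \infty$
recovers the t computed with the pooled (mean) variance. The estimates are
also cross-checked against an independent established empirical-Bayes
implementation on simulated data.

Significance filtering keeps transcripts with adjusted p below `alpha`
(default 0.05) in at least one contrast *and* an absolute log2 level
versus the watered control above `level_cut` (default 1) at at least one
stage. The order of the two gates does not change the result since both
are applied as an intersection.

## 4. The memory taxonomy

Fold-change screens are computed on the linear scale within each
replicate. The thresholds are strict (`> fold`, `< 1/fold`, default
fold = 4), reading "more than fourfold" literally; a ratio of exactly 4 in
either replicate fails. Both replicates must pass (a geometric-mean mode
is available behind `mode = "mean"`).

Memory labels are *gated*: DIMT requires a transcript already classified
DIT, DRMT requires DRT. The ungated alternative (screening DR2 vs DR1
over all transcripts) is available behind `gate = FALSE`, but the gated
reading matches the notion that a memory response modifies an existing
response. Control/organellar rows are never memory-labelled.

Recovery at WT2 is an annotation only: a transcript is flagged recovered
when WT2/WT1 lies within a symmetric 2-fold band in both replicates. The
2-fold tolerance is this package's choice — recovery is descriptive in the
underlying design and never filters labels.

**Detection guard.** Transcripts whose intensity never rises meaningfully
above background have ratios dominated by the background floor: after
background subtraction both numerator and denominator sit near the floor
offset, and tiny fluctuations produce arbitrarily large apparent fold
changes (in practice, spurious "repressed" calls). `classify_response()`
therefore labels a transcript non-responsive unless its linear intensity
reaches `detect_rel` (default 0.05) times the matrix median in at least
one sample. The guard is relative to the median, so classification is
invariant under rescaling all intensities. At the generator's default
settings about 90% of transcripts pass it, in line with the detection
rates typical of this array class.

## 5. The synthetic-data generator

The generator emulates the study design: four states times two
replicates, log-normal intensities with additive background, planted
response and memory structure.

* **Baseline intensities**: log2-normal with mean `log2(231)` and
  standard deviation 2.5. The anchors are the array's printed intensity
  scale — a median of 231 raw units and a maximum around 5.4e5 on a
  ~60,000-row array; a normal tail reaches that maximum at roughly 4.5
  standard deviations, giving the 2.5 default.
* **Planted effects**: the first-drought response adds ±3 log2 in DR1 and
  DR2; memory transcripts gain a further ±3 log2 increment in DR2 only,
  so the DR2/DR1 fold is directly controlled; WT2 returns to baseline.
  Replicate noise is N(0, 0.25) on the log2 scale.
* **Planted baselines**: induced transcripts draw their baselines from
  `baseline_mean - effect` (sd/2), repressed from `baseline_mean +
  effect`. This mirrors the biology being emulated — drought-induced
  stress genes (dehydrins, LEA proteins) sit near basal levels when
  watered, while the repressed classes (photosynthesis, primary
  metabolism) are constitutively high — and it keeps the planted peaks
  inside the bulk dynamic range, where quantile normalization preserves
  ranks (section 2). Drawing strong planted effects from the bulk
  baseline would park them on the extreme order statistics, where any
  rank-based normalization structurally erases fold changes; at a
  60,000-row scale this matters only for a handful of transcripts, but at
  test scale (hundreds of rows) it would dominate.
* **Genome**: genes of 1–4 exons on alternating strands, valid CDS ending
  in TAA, 3'-UTRs of 0–200 nt (deliberately including values below 60 to
  exercise the probe frame-shift rule), and a configurable fraction of
  genes with a second isoform skipping one internal exon — which makes
  that exon a unique exon of the representative.
* **GO annotation**: background terms with uniform random membership plus
  one planted term containing 80% of a designated gene set.
* **Determinism**: every generator derives its RNG stream from the config
  seed plus a fixed per-stage offset; identical configs give byte-identical
  output files.

What passing tests on this generator establish: the classifier, the
enrichment machinery and the network code recover planted structure at the
stated effect sizes and noise under the full normalization chain. What
they do not establish: behaviour under probe-level hybridization physics,
dye or spatial artifacts, heavy-tailed or correlated noise, or
non-normal baseline distributions — none of which the generator models.

## 6. Enrichment: randomization FDR and the score scale

Term p-values are one-sided upper-tail hypergeometric probabilities. The
FDR is estimated by redrawing `R` (default 100) random gene sets of the
query's size from the universe and recomputing all term p-values per
draw:

$$\mathrm{FDR}(T) \;=\; \frac{\tfrac1R\sum_r \#\{T' : p_r(T') \le p_{\mathrm{obs}}(T)\}}
{\#\{T' : p_{\mathrm{obs}}(T') \le p_{\mathrm{obs}}(T)\}} \wedge 1$$

i.e. the expected number of terms reaching a given significance level by
chance, relative to the number observed at that level, capped at one. The
raw ratio is then monotonized in observed p (running minimum from the
largest p downward), so a more significant term never reports a larger
FDR. The estimator choice (mean false-positive count over observed count)
is the standard construction for randomization-based enrichment FDRs;
annotations are taken as given, with no propagation up the GO hierarchy.

Significant FDRs (strictly below the 0.05 cutoff) map linearly onto the
0.5–5 display scale, $\mathrm{score} = 0.5 + 4.5\,(c - \mathrm{fdr})/c$,
negated for repressed classes; non-significant terms score 0. The linear
form is this package's construction: it is the simplest map consistent
with the stated range and with "more enriched closer to 5". Row order in
the combined score matrix comes from average-linkage clustering of the
score profiles and is presentation-only.

## 7. Co-expression

Depth-0 semantics: correlations are computed only among the supplied gene
set, never expanding to outside neighbours. Edges require |r| >= 0.65;
components are maximal connected sets (the graph machinery is delegated to
`igraph`, with a brute-force oracle asserting equivalence in the tests).
Genes with zero variance have undefined correlation and are excluded with
a warning.

Trees use average linkage on the distance $d = 1 - r$, not $1 - |r|$:
anti-correlated genes are kept maximally distant rather than folded onto
their positively correlated partners. A flag switches to $1 - |r|$ where
co-membership regardless of sign is wanted. Newick output preserves
branch lengths and round-trips through standard readers.

Ortholog mapping filters a 12-column tabular alignment at score >= 70
(the bit-score column by default; the column is configurable since score
conventions differ) and keeps one best subject per query, ties broken
lexicographically for determinism.

## 8. Problem sizes and numerical choices

The test-suite simulations use 200–500 transcripts, 8 arrays, 20 seeds
for the recovery study, and 50–100 randomizations for enrichment — sizes
chosen so the planted-truth studies have enough events per label (600
planted response and 200 planted memory transcripts pooled across seeds)
while the whole suite runs in well under a minute. Recovery is reported
as sensitivity and specificity pooled across the seeded runs; per-seed
minima at 10–30 planted genes per label would mostly measure binomial
noise at the strict both-replicate threshold.

Tolerances: exact equality is asserted for quantile multisets, probe
coordinates and label assignments; numerical comparisons against oracles
use tolerances of 1e-10 to 1e-3 depending on whether the oracle is
algebraically identical or an independently estimated quantity (the
empirical-Bayes hyperparameters). Tie-breaks everywhere are
lexicographic, making every output deterministic under a fixed seed.

## 9. Known limitations

* The >4-fold two-replicate screen is a hard threshold; transcripts
  hovering at the boundary flip labels under small noise. The moderated-t
  route exists precisely to complement it, but the taxonomy follows the
  fold rule by design.
* Quantile normalization attenuates fold changes at the distribution
  extremes (section 2); headline counts from any rank-based pipeline are
  conservative for the most extreme responders.
* The randomization FDR is granular at small R (multiples of 1/R); R =
  100 gives a 0.01 grid, adequate for a 0.05 cutoff but not for ranking
  deep in the tail.
* Cross-hybridization screening is exact-match only by default;
  thermodynamic effects (Tm, secondary structure) are out of scope.
* The co-expression module computes networks among the supplied set only;
  building a compendium-scale correlation database to expand against is
  explicitly not attempted.
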