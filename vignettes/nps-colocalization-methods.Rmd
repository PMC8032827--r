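---
title: "Methods: co-localization, enrichment and intermediate classification at natural pausing sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-localization, enrichment and intermediate classification at natural pausing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npscoloc)
```

# The scientific problem

Replication forks slow or stall at natural pausing sites (NPSs) of the
budding-yeast genome: tRNA genes, centromeres (CENs), and the regions where
converging forks meet (replication termination regions, TERs). Several
genome-maintenance factors — the Smc5/6 complex, the Sgs1–Top3–Rmi1 (STR)
helicase–topoisomerase complex, the Mus81–Mms4 resolvase — are recruited to
these sites, and the question of whether their chromatin-binding patterns
*co-localize* genome-wide, beyond what random placement would produce, is a
statistical one. The raw material is a set of "clusters" per protein:
maximal genomic intervals of significant ChIP enrichment, obtained upstream
from tiling arrays and taken here as BED input. This package implements the
downstream statistics: the co-localization score and its null model, fold
enrichment at feature classes, discrete-feature co-occupancy, plus two
companion quantifications used in the same experimental programme —
classification of electron-microscopy (EM) joint molecules from
branch-length records, and ChIP-qPCR percent-input statistics.

# Coordinate conventions

All coordinates are 0-based, half-open (the BED convention), everywhere
internally; a 1-based fully-closed dialect must be declared at the reader
(`read_bed(..., one_based = TRUE)`), which converts `start` to `start - 1`
on read. A single convention prevents off-by-one drift between modules.
Book-ended intervals (end of one equals start of the next) are merged on
cluster-set construction: clusters are maximal runs of enrichment, and
adjacency is an artifact of tiling resolution. Strand is ignored in all
overlap computations. Readers reject out-of-bounds coordinates rather than
clamping them.

# The co-localization statistic

## Score

For two cluster sets $A$ and $B$ on the same genome, the score is the
total number of overlapping bases between their genomic footprints,

$$ S(A, B) \;=\; \lvert \mathrm{union}(A) \cap \mathrm{union}(B) \rvert
\quad \text{(bp)}, $$

computed exactly by `overlap_bases()`. It is symmetric and bounded by
$\min(|A|, |B|)$.

## Monte-Carlo null

`monte_carlo_colocalization()` confronts the observed score with a null
in which one set's clusters are randomly re-placed. The randomization
preserves, per chromosome, the number of clusters and the multiset of
cluster lengths; starts are drawn uniformly from the valid positions and
whole-chromosome proposals are rejection-sampled until the placed
intervals are pairwise disjoint (with at least a 1 bp gap, so that the
merged representation keeps the same interval count). This conserves
`total_bases` exactly — the quantity the score depends on. Placement
constraints of this kind are a design choice of this package: disjointness
matches the observed property of cluster sets, and chromosome preservation
respects per-chromosome density differences. For sets too dense for
disjoint placement, `allow_overlap = TRUE` lets placements collide and
merges them before scoring. By default only the first set is randomized
each iteration (conditioning on the other observed pattern — the cheaper
and more common null); `randomize = "b"` or `"both"` are available and the
choice is recorded in the result.

The empirical p-value uses the add-one estimator

$$ p \;=\; \frac{1 + \#\{S_{\text{null}} \ge S_{\text{obs}}\}}{N + 1}, $$

standard permutation-test practice: ties count as at least as extreme and
$p$ is never 0, so $p \ge 1/(N+1)$. The default is $N = 1000$ iterations;
results are bit-reproducible given the seed.

## Fisher's exact test on base counts

Alongside the empirical p, the one-tailed Fisher's exact test is computed
on the genome-wide base-count table: with $a = |A \cap B|$,
$b = |A| - a$, $c = |B| - a$, $d = G - a - b - c$ (cells summing to the
genome length $G$), the reported p is the exact hypergeometric upper tail
$P(X \ge a)$ with margins fixed, evaluated as
`phyper(a - 1, |A|, G - |A|, |B|, lower.tail = FALSE)`. Treating every
base as an independent trial ignores the strong autocorrelation of
neighbouring bases, which makes this test anti-conservative for long
clusters; it is reported because it is the field's conventional summary,
but the Monte-Carlo empirical p is the recommended headline statistic.
Reports always carry both, labeled, never a single unlabeled "p".

# Enrichment at feature classes

`fold_increase()` measures a protein's enrichment at a feature class
(tRNA, CEN, TER, ARS) as observed overlap divided by the overlap
"expected for random binding". Two expectations are implemented and
labeled, since either reading is defensible:

* **analytic** (default): the independence expectation
  $|A| \cdot |F| / G$;
* **montecarlo**: the mean of the randomization null, which also yields an
  empirical p.

On sparse sets the two agree closely (the suite checks 10% agreement at
1000 iterations). Fold is computed on *bases* by default, matching the
overlap score; a secondary `unit = "features"` mode works on the fraction
of discrete features bound, with a Monte-Carlo expectation. Features enter
as their stated bodies; an optional `flank` parameter (default 0 bp)
extends them symmetrically.

A discrete feature is **bound** when its body overlaps the cluster
footprint by at least `min_overlap_bp` (default 1 bp — the weakest
defensible rule, surfaced as a parameter rather than hidden).
`cooccupancy()` applies this per protein and partitions the features over
all $2^k$ protein combinations (including "none"); percentages are raw
reals over the feature count — display rounding is left to the caller,
since published tables round inconsistently.

# Joint-molecule classification

Psoralen-crosslinked replication intermediates spread for EM are branched
molecules whose geometry identifies them. Expert visual classification is
replaced by explicit, ordered geometric rules on measured branch lengths,
so the tabulation is reproducible and parameterized:

1. no junction, two ends → **linear** (excluded from the tally);
2. one three-way junction → **fork**;
3. two three-way junctions sharing arcs → **bubble**;
4. two four-way junctions on one molecule → **double Holliday junction**
   (junction count alone — no length criterion exists for dHJs);
5. one four-way junction with two branches equal within `rel_tol` (the
   daughter arms) and the shortest remaining branch (the regressed arm) no
   longer than them → **reversed fork**;
6. one four-way junction whose branches pair into two through-going
   filaments of equal total length within `rel_tol` (any of the three
   pairings) — the geometry of two crossed intact duplexes — when rule 5
   fails → **hemicatenane**;
7. otherwise **unclassified**.

`rel_tol` defaults to 5%; the exact thresholds an expert applies are not
published, so the tolerance is a surfaced parameter. All rules are
relative, so classification is invariant to branch permutation and uniform
rescaling — and therefore identical whether lengths are recorded in nm or
bp. The calibration 500 bp per 180 nm (`nm_to_bp()`) converts EM contour
lengths to base pairs. Records are encoded by `(n_junctions, n_branches)`
pairs — (0,2), (1,3), (2,3), (2,4), (1,4) — which disambiguate the
taxonomy before any length rule is consulted. Single-stranded-region
annotation is an image-level call and does not enter classification.

`tabulate_jm()` reports per-genotype category percentages over the
analysed (non-linear) molecule count; they sum to 100 by construction.

# ChIP-qPCR percent input

`percent_input()` implements the dilution-corrected $2^{-\Delta C_t}$
method:

$$ \%\,\text{input} \;=\; 100 \cdot
   2^{\,(C_t^{\text{input}} - \log_2 d) - C_t^{\text{IP}}}, $$

where $d$ is the fraction of chromatin used as input (e.g. 0.01). The
dilution is a required input column because published analyses rarely
print it yet it shifts every value by a constant factor. Group comparison
uses the unpaired two-tailed Student t-test with pooled variance
(`summarize_and_test()`), matching the classical procedure; Welch is
available by flag. SEM is sample sd over $\sqrt{n}$, requiring $n \ge 2$.
No multiple-testing correction is applied: per-locus p-values are
reported raw, as is conventional for targeted qPCR panels.

# The synthetic-data generator

Every input the pipeline consumes can be generated with known structure,
so all stages are testable without external downloads.

* **Genome** (`make_genome()`): 16 chromosomes, 12 Mb total by default,
  using the real *S. cerevisiae* chromosome length profile scaled to the
  requested total, so per-chromosome densities are realistic.
* **Features** (`place_features()`): 71 TERs of 2–8 kb (termination zones
  are broad), one 120 bp CEN per chromosome, 275 tRNA genes of 70–100 bp —
  the annotated pausing-site classes — placed mutually non-overlapping.
  TER lengths are not published as a distribution; 2–8 kb uniform is a
  realistic breadth chosen once.
* **Clusters** (`make_cluster_set()`): lengths are log-normal with median
  1 kb and log-sd 0.5 — a standard heavy-tailed choice for
  enrichment-domain widths, as no cluster-length distribution is
  published. A fraction $f$ of clusters is centered on anchor midpoints
  (feature bodies or a partner protein's clusters) with Gaussian jitter;
  the rest are uniform. Anchoring-by-midpoint creates exactly the
  base-overlap signal the score measures, with one interpretable knob.
  When the anchored count reaches the number of anchors, anchors are
  recycled so each is used at least once — this makes $f = 1$ saturate
  feature binding deterministically.
* **JM records** (`make_jm_records()`): noise-free geometries satisfy
  exactly one rule each, with cross-category length ratios far from the
  tolerance boundary; multiplicative log-normal noise emulates tracing
  error. `jm_profile()` provides category mixes emulating unperturbed
  cells (~1% reversed forks, no dHJs) versus STR/Smc5-6-deficient cells
  (5–8% reversed forks, 7–9% dHJs, elevated hemicatenanes). In the
  reproduction script, tracing noise is set to 2% — realistic for EM
  contour measurement and below the 5% rule tolerance, so tabulated
  percentages reflect the mix rather than tolerance breakage.
* **qPCR tables** (`make_qpcr_table()`): Ct pairs constructed by
  inverting the percent-input formula around a known truth, with optional
  Gaussian Ct noise on both wells.

What the generator does **not** emulate: probe-level tiling-array signal
and the cluster-calling step; GC or chromatin-state biases in cluster
placement; correlated (non-independent) feature classes; EM image
artifacts. Passing tests therefore demonstrate correctness of the
*statistics* under the stated models, not robustness to every property of
real arrays.

# Numerical choices and degenerate inputs

* Interval arithmetic is exact integer arithmetic in doubles (coordinates
  far below $2^{53}$); merge/union/intersection are checked against a
  per-base bitmap oracle and against GenomicRanges in the suite.
* Empty cluster sets are legal: overlap 0, coverage 0, empirical p 1;
  fold against an empty set is an error ("undefined fold") rather than a
  silent NaN.
* An interval covering a whole chromosome randomizes to itself (single
  valid placement).
* Rejection sampling retries 1000 whole-chromosome proposals by default
  before failing with a pointer to `allow_overlap`.
* Fisher p-values use `phyper` directly (no normal approximation at any
  size); negative table cells raise an internal consistency error.
* Report floats are serialized at 6 significant digits identically in TSV
  and JSON.

# Problem sizes used by the test suite

The suite exercises the statistics at sizes chosen for statistical
adequacy of each check: bitmap-oracle equality on 10 kb toy genomes with
up to 50 intervals; null calibration on 200 independent pairs
(two 50 kb chromosomes, 12 clusters of median 1 kb per set, 1000
Monte-Carlo iterations each) — dense enough that the overlap score is
rarely zero, so the p distribution is informatively near-uniform;
enrichment-recovery ladders ($f \in \{0, 0.25, 0.5, 0.75\}$, 25
replicates per rung) on a 1 Mb genome with 20 anchor features; classifier
recovery on 25 records per category. The full-scale 12 Mb configuration
is exercised end to end by the reproduction script
(`scripts/acceptance.R`).

# Known limitations

* The Fisher test on base counts inherits base-level autocorrelation and
  should not be interpreted as a calibrated p-value for long clusters;
  use the empirical p.
* The randomization constraints (chromosome-preserving, disjoint) are this
  package's explicit choices; other nulls (circular shifts, GC-matched
  placement) are out of scope.
* The JM rules codify verbal criteria; near-threshold geometries
  (e.g. symmetric reversed forks vs equal-filament hemicatenanes) are
  resolved by rule order and tolerance, both surfaced.
* Co-occupancy percentages are exact-subset partitions; "bound by at
  least" queries should be computed from the returned boolean matrix.
* No multiple-testing correction across protein pairs or loci is applied
  anywhere; p-values are reported raw.
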