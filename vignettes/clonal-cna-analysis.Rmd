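---
title: "Tracking clonal copy-number evolution from longitudinal SNP arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking clonal copy-number evolution from longitudinal SNP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clonecna` reconstructs the clonal history of a serially passaged cell
population from SNP-array-like copy-number signals taken at a handful of
passages. This vignette describes the models behind each stage, the
tunable parameters and their defaults, the design choices that were
genuinely open, and what the package's validation does and does not show
about real data.

## The simulation model

`simulate_lineage()` runs a discrete per-passage model chosen to mirror
how passaging experiments actually proceed; a continuous-time branching
process would fit cell division more finely but would buy nothing for
per-passage array sampling, and the discrete update keeps an independent
re-implementation of the dynamics (used as a test oracle) trivial.

At every passage, in order:

1. **Mutation.** Every existing clone spawns at most one child carrying
   `k ~ Poisson(event_rate)` new segmental events (the child is only
   created when `k >= 1`). Kinds follow `kind_weights` over gain / loss /
   cn-LOH; sizes are log-uniform over `event_size_range` (default 0.5–50
   Mbp, spanning focal events to arm-scale aberrations); positions are
   uniform, never overlapping the clone's existing events on the same
   haplotype. With probability `wgd_prob` a clone also spawns a
   genome-doubled child. Events are never lost along a lineage (the
   reconstruction stage assumes exactly this events-never-revert model).
2. **Selection.** Discrete replicator update
   `x_i <- x_i w_i / sum_j x_j w_j`. A clone's fitness is the product of
   per-event factors drawn from `Normal(fitness_mean, fitness_sd)`
   (truncated at 0.01), times `aneuploidy_tolerance` if it carries any
   event of at least 1 Mbp, times `wgd_fitness` if genome-doubled.
3. **Drift.** Multinomial resampling of `bottleneck_size` cells (default
   10,000); clones drawn at zero cells are extinct. A newborn clone starts
   at one cell.

The regime presets encode a qualitative contrast between genetic
backgrounds rather than measured rates (no quantitative per-genotype
event rates are available to calibrate against): the wild-type-like
preset produces rare events under mild positive selection, so occasional
clonal replacement remains possible; the RB1-/CDKN2A-like presets give
event carriers `aneuploidy_tolerance = 0.1`, purging aneuploid clones
before they reach detectable size; the TP53-like preset combines a high
event rate, tolerance of aneuploidy and a fitness bonus for genome
doubling, producing saltatory evolution through WGD. These values were
fixed once, from the contrast they must reproduce, and are not tuned per
experiment.

## Array emulation

For a mixture of clones at passage *p*, each clone's haplotype copy
numbers at a position follow from its branch events applied in
acquisition order (gain/loss adjust the affected haplotype, cn-LOH zeroes
one haplotype and doubles the other, WGD doubles both; `complex` regions
are emulated as an unresolvable overlapping stack, +2 on one haplotype
and −1 on the other). Mixture-averaging by clone fraction gives
`(h1, h2)`, and

- `logR = log2((h1 + h2) / 2)` (diploid-centered; a median-centering mode
  re-centers the emitted signal, as many array pipelines do),
- `BAF = copies(B) / (h1 + h2)` at heterozygous probes, where the B
  allele sits on a per-probe random haplotype; homozygous probes emit 0
  or 1.

Noise is independent Gaussian per probe (`sigma_logr = 0.15`,
`sigma_baf = 0.03` — mid-range values for genotyping arrays). Probes are
uniformly spaced (default one per 50 kb, so a 5 Mbp event spans ~100
probes) with 30% heterozygous. The emulator deliberately omits GC waves,
probe-specific biases and genotype-calling artifacts; validation results
therefore speak to the method's statistical behaviour under calibrated
noise, not to platform-specific systematics.

## Segmentation

`segment_signal()` segments each chromosome on **two tracks**: mean
shifts in logR over all probes, and mean shifts in folded BAF
(`|BAF − 0.5|`) over heterozygous probes — the latter is what delimits
copy-neutral LOH, which is invisible in logR. Each track is scanned
recursively; at every step two candidate families are evaluated:

- **edge splits** — the two-sample z statistic at every split position;
- **interior windows** — a geometric ladder of window widths (ratio 1.25,
  stride w/6), scoring window-vs-remainder contrast. A plain left/right
  split statistic dilutes a focal event embedded in a long chromosome to
  invisibility, which is why the window family exists; it is what makes a
  100-probe event detectable inside a 4,000-probe chromosome.

The acceptance threshold for the best candidate is the upper-`alpha`
quantile (default `alpha = 0.01`) of the **null maximum scan statistic**,
estimated once per (length bucket, track) by Monte Carlo simulation of
pure-noise tracks with a Gumbel tail fit, and cached. Analytic Bonferroni
corrections were tried first and were either too lax (decorrelated
candidate counts let minimum-width windows through) or too conservative
(raw counts); simulating the null directly is the same calibration role
that permutation p-values play in circular binary segmentation. Noise is
re-estimated per interval from successive differences, because folded BAF
is heteroscedastic: allelic imbalance widens the folded noise, and a
global estimate overstates significance inside imbalanced regions.

Post-processing: sub-`min_probes` slivers are absorbed into the closer
neighbour; adjacent segments are merged when they are indistinguishable
on **both** tracks (below `merge_tol = 0.04` logR / `merge_tol_baf =
0.02` folded-BAF, or not separable at 3 pooled standard errors — pooling
keeps the test stable when one fragment is tiny); every internal boundary
is then **polished** by the local two-segment contrast combining both
tracks (`z_logR^2 + z_BAF^2`), and the merge is repeated, since polishing
can pull a diluted boundary back onto the true step and thereby make
fragments of one state mergeable. Boundary accuracy matters downstream:
matching events across samples at reciprocal overlap 0.8 needs boundaries
good to a few probes.

## Event calling and MCF estimation

Classification is relative to the ploidy baseline (see WGD below): gain
when adjusted mean logR exceeds `t_gain = 0.04`, loss below
`-t_loss = -0.04`, cn-LOH when the segment is copy-neutral **and** its
mirrored BAF bands split beyond `b_split = 0.06`. The copy-neutrality
test widens with the segment-mean noise (`|logR| <= max(0.02, 3 sem)`): a
fixed cutoff makes cn-LOH calls on shorter segments drop out at random.

The logR thresholds are deliberately lenient — a 10% one-copy loss only
shifts logR by 0.074, so thresholds near 0.1 would silently become the
binding constraint on sensitivity. The intended binding constraint is the
**clone-size detectability floor** (`clone_size_floor = 0.10`): events
whose estimated MCF falls below 10% of cells are not emitted, reflecting
the practical resolution of clonal array analysis.

MCF estimation inverts the single-step mixture identities. On a baseline
of total ploidy `psi` (2 for diploid), with `L` the baseline-adjusted
mean logR, `b`/`bu` the lower/upper mirrored het band:

| call | logR route | BAF route |
|------|------------|-----------|
| loss | `f = psi (1 − 2^L)` | `f = psi (1 − 2b) / (2 (1 − b))` |
| gain | `f = psi (2^L − 1)` | `f = psi (2bu − 1) / (2 (1 − bu))` |
| cn-LOH | — | `f = (psi/2) (1 − 2b)` |

The BAF route is used when the segment holds at least `min_het_probes =
10` het probes (BAF is free of the logR baseline and of ploidy
re-centering errors), otherwise the logR route; results are clipped to
[0, 1]. Bands are estimated as `0.5 ± mean(|BAF − 0.5|)` over het probes;
the folded mean is biased upward when the true split is small relative to
the BAF noise, which errs on the side of calling weak imbalance — at a
true clone fraction of 10% the estimate sits near 12%, which is why
detection at the floor itself is possible at all.

A gain/loss/cn-LOH segment whose BAF- and logR-implied MCFs contradict
each other by more than `complex_tol = 0.35` is re-labelled **complex**:
its allelic structure is not a single one-copy step from the baseline.
Complex events are annotated, carried through matrices, and excluded from
tree placement — their evolutionary trajectory is not decipherable under
the single-step model, and pretending otherwise would corrupt the tree.
Multi-copy states that happen to be internally consistent (e.g. a clonal
two-copy gain) are estimated under the single-step model and clip to 1.

Contiguous same-kind calls with MCFs within `stitch_mcf_tol = 0.15` are
stitched back into one event, and a sub-20%-length sliver is absorbed
into its neighbour regardless of its MCF — interior micro-fragments carry
unreliable estimates.

## WGD detection

`detect_wgd()` scores candidate average ploidies `psi` in [1.5, 5] (step
0.05) by converting every segment's (logR, band) pair to implied
allele-specific copy numbers and measuring the length-weighted squared
distance to non-negative integers. Under **median-centered** logR the
implied total is `psi · 2^logR` and the grid is searched, preferring the
smaller `psi` at near-ties (the conventional resolution of the ploidy
ambiguity — a clean WGD with no segmental events is genuinely
indistinguishable from diploid under median centering; odd-copy segments
break the tie). Under **diploid-centered** logR the total `2 · 2^logR`
is absolute and does not depend on `psi`, so the fitted ploidy is read
directly as the length-weighted mean total snapped to the grid. The
sample is flagged genome-doubled at `psi >= 3`, and the flagged ploidy
re-baselines logR before event classification; the WGD itself is emitted
as a genome-wide event with MCF `(psi − 2)/2`, the genome-doubled cell
fraction implied by average ploidy.

## The event matrix

Events called independently per sample are unified into matrix rows when
they share a kind and overlap reciprocally by `match_overlap = 0.8`,
tested against the best-matching member call (a running intersection
alone shrinks under boundary jitter and makes later samples progressively
harder to match); the reported unified segment is still the intersection.
A consolidation pass then folds together same-kind rows that still
overlap by at least 0.5 but never co-occur in any sample: such pairs are
one alteration whose boundaries were drawn differently in different
samples, since two genuinely distinct co-located same-kind alterations
would have to avoid every shared sample under the events-never-revert
model. The MCF of an event in a sample where it was not called is 0 —
meaning "below the floor", a censoring the tree stage takes seriously.

## Subclone tree reconstruction

Events are clustered by their MCF profiles (complete linkage, cut at
`tau = 0.10`, matching the ~10% resolution of the data) under a
**censoring-aware Chebyshev distance**: the per-sample distance between a
reported 0 and a positive value is the amount by which the positive value
exceeds the floor. Without this, two co-branch events straddling the
floor in one sample (one reported 0.09 → 0, the other 0.11) would be
pushed apart artificially.

The tree is built over cluster consensus profiles (per-sample medians)
under two constraint families, both at tolerance `tau` per sample:
**containment** (a child's MCF never exceeds its parent's) and the
**pigeonhole constraint** (sibling MCFs cannot sum past their parent).
Stem clusters (MCF >= 1 − tau everywhere — alterations carried by every
cell) chain directly under the event-free root in descending-mean order.
Remaining clusters attach greedily in descending-mean order to the
feasible parent minimizing the summed per-sample MCF gap — the *closest*
feasible ancestor — with ties broken by earliest first event in genome
order. A cluster with no feasible parent is reported as unplaced rather
than forced on. The root is always present, so clone-proportion pies
include a wild-type compartment even when a stem is clonal.

Greedy construction is not guaranteed to recover *the* history; the
correctness contract is **oracle membership**: for small instances,
`enumerate_trees()` exhaustively enumerates every rooted arrangement
satisfying both constraint families, and the greedy output must always be
a member of that set. This is asserted over hundreds of seeded random
matrices in the tests. When the data genuinely admit several trees (a
sibling pair whose profiles satisfy one-way containment everywhere is
also consistent with a chain), the greedy rule prefers nesting; only
configurations in which the constraint set is a singleton pin the truth
down, and the recovery experiment (below) conditions on exactly that.

Clone proportions subtract children from parents per sample (clipped at
0 and renormalized, with a warning, when noise pushes sibling sums past a
parent). **Replacement detection** tracks the dominant node (largest own
fraction, ties to the shallower node) across passages and reports the
first sampled passage whose dominant node shares no lineage with the
previous one — a parent giving way to its own descendant is ordinary
succession, not replacement.

## Dynamics and statistics

`fishplot_layout()` re-derives cumulative bands bottom-up from the
clipped, renormalized own fractions, so the layout invariants hold
exactly (own fractions sum to 1; a child band never exceeds its parent);
interpolation between sampled passages is linear only — layout data, not
graphics aesthetics. `count_events()` applies the >= 1 Mbp headline
filter via `size_filter()` (read as inclusive; a whole-genome duplication
counts as one event). `ranksum_test()` computes W as the midrank sum of
the first group and enumerates all `choose(n1+n2, n1)` assignments
exactly when `n1 + n2 <= 12` (with ties handled by enumerating the
observed midranks), falling back to the tie-corrected,
continuity-corrected normal approximation above that; pairwise group
comparisons are Holm-adjusted — conservative, order-free, and requiring
no independence assumptions across the handful of pairs.

## Validation experiments and problem sizes

The experiment helpers run on a compact six-chromosome genome (180–100
Mbp, 850 Mbp total at 50 kb spacing), large enough for realistic
scan-statistic behaviour while keeping hundreds of replicates cheap.

- **Detectability** (`detection_experiment()`): one subclone carrying a
  5 Mbp loss at grid fractions 0.05–0.50 under default noise. Two
  threshold readings are reported: the *switch-on* point (interpolated
  50% crossing, snapped to the grid), which lands on the configured 10%
  floor, and the *reliably detected* point (smallest grid fraction at
  >= 95% detection), one grid step above it at 15%. Both are honest
  summaries of the same curve: at the floor itself roughly half to
  two-thirds of replicates detect the event; one step above, essentially
  all do.
- **Recovery** (`recovery_replicate()`): random clone trees (4–8 clones,
  5 samples), 1–3 globally disjoint events of 3–20 Mbp per clone, clone
  profiles drawn by stick-breaking and **screened for identifiability**
  — the true tree must be the unique member of the enumerated
  constraint-satisfying set at margin 0.15. Without that screen the
  experiment would punish the reconstruction for ambiguities no method
  could resolve from MCFs alone. Under default noise, ancestor–descendant
  precision and recall average above 0.95 and MCF RMSE stays below 0.05
  across 100 replicates.
- **WGD calling** (`wgd_experiment()`): constructed clonal-WGD mixtures
  (plus five segmental events) versus diploid mixtures, 100 replicates
  each; flagged and spared respectively in >= 99% of replicates.

## Known limitations

- Multi-copy and compound states are not decomposed; they are either
  estimated under the single-step model (when internally consistent) or
  flagged complex. MCFs of events acquired *after* a WGD are estimated
  against the re-baselined average ploidy and are biased when the true
  background at the locus differs from it.
- cn-LOH sensitivity is governed by `b_split` as well as the floor; with
  the defaults the effective cn-LOH floor sits nearer 12% than 10%.
- Same-branch event order is not identifiable from MCFs and is never
  reported; cross-branch order is only trustworthy where the constraint
  set is tight.
- The emulator's noise is idealized (independent Gaussian, no GC waves or
  platform artifacts); thresholds may need re-examination on real arrays.
- The clone simulator encodes genotype biology purely as regime
  parameters; it has no mechanistic cell-cycle or checkpoint model and no
  spatial structure.
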