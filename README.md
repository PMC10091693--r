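# clonecna

Clonal evolution analysis of cultured cell populations from longitudinal
SNP-array copy-number data.

When a cell line is passaged for months, subclones carrying copy-number
alterations (CNAs) arise, drift through bottlenecks, and occasionally sweep.
Genotyping arrays observe this as probe-level logR (log2 total copy-number
ratio) and BAF (B-allele frequency) signals per sample. `clonecna`
implements the full chain from signal to clonal history:

- **Simulation** of branching clonal evolution under per-genotype
  chromosomal-instability regimes — per-passage mutation
  (`k ~ Poisson(event_rate)` new gains/losses/cn-LOH per clone, optional
  whole genome duplication), replicator selection
  (`x_i <- x_i w_i / sum_j x_j w_j`), and multinomial drift through a
  passage bottleneck — with full ground truth (tree, branch events,
  per-passage clone fractions).
- **Array emulation**: mixture-averaged haplotype copy numbers per probe,
  `logR = log2((h1 + h2)/2)`, `BAF = copies(B)/(h1 + h2)`, plus Gaussian
  noise.
- **Segmentation and event calling**: two-track (logR + folded BAF)
  multiscale scan segmentation with Monte-Carlo-calibrated critical values,
  classification into gain / loss / cn-LOH / complex, a >= 1 Mbp headline
  size filter, and a 10% clone-size detectability floor.
- **MCF estimation**: every event's mutated cell fraction (the fraction of
  cells carrying it) from the mixture identities, e.g. for a one-copy loss
  carried by a fraction `f` of diploid cells,
  `logR = log2((2 - f)/2)` and the lower het-BAF band sits at
  `b = (1 - f)/(2 - f)`, inverted as `f = 2(1 - 2^logR)` or
  `f = (1 - 2b)/(1 - b)`.
- **WGD detection** by ploidy grid search over implied allele-specific
  integer copy numbers.
- **Subclone phylogeny** reconstruction from the event-by-sample MCF matrix
  under containment (a descendant never exceeds its ancestor's MCF) and the
  pigeonhole constraint (sibling MCFs cannot sum past their parent), with
  an exhaustive oracle for small instances, clone proportions per sample,
  and dominant-clone replacement detection.
- **Clonal dynamics and statistics**: fishplot layout data and exact
  Wilcoxon rank-sum comparisons of per-sample event counts between groups
  (Holm-adjusted).

## Worked example

```r
library(clonecna)

cfg <- read_run_config(system.file("extdata", "demo_config.json",
                                   package = "clonecna"))
res <- run_pipeline(cfg)
res$counts
#>   sample regime n_events n_events_min_len
#> 1    P04     WT        0                0
#> ...
#> 7    P08   TP53        0                0
#> 8    P16   TP53        5                3
#> 9    P24   TP53       14               11
```

The wild-type-like series stays quiet while the TP53-like series
accumulates alterations between passages 8 and 24. The fitted average
ploidy per TP53 sample shows the genome doubling arriving by passage 24:

```r
sapply(res$per_regime$TP53$ploidy, `[[`, "psi_hat")
#> P08 P16 P24
#>   2   2 3.8
```

The reconstructed subclone tree places the `wgd` event on the branch of
the sweeping clone, with per-sample MCF profiles for every node:

```r
res$per_regime$TP53$tree
#> subclone_tree: 7 nodes (+root), 3 samples, 0 unplaced events
round(res$per_regime$TP53$tree$profiles, 2)
#>      P08  P16  P24
#> root   1 1.00 1.00
#> N1     0 0.95 1.00
#> N2     0 0.65 1.00
#> N3     0 0.00 1.00
#> N4     0 0.00 0.88   # <- branch carrying wgd
#> N5     0 0.00 0.79
#> N6     0 0.00 0.27
#> N7     0 0.11 0.00
```

`fishplot_layout()` turns the tree into nested band data
(`plot(fishplot_layout(tree, passages))` renders it), and
`res$comparisons` holds the exact rank-sum comparison of event counts
between the two regimes (here W = 21, p = 0.17 with 6 vs 3 samples).

The same stages are scriptable from a shell through the bundled wrapper:

```sh
Rscript inst/scripts/clonecna run-all \
    --config inst/extdata/demo_config.json --out out/
```

which writes the event-matrix TSV, tree (newick + JSON), fishplot JSON,
per-chromosome gain/loss summary, comparisons TSV and the effective
configuration. Subcommands `simulate`, `emulate`, `call`, `matrix`,
`tree`, `fishplot` and `compare` run the stages separately over files.

## Layout

- `R/` — implementation (genome model, simulator, emulator, calling,
  phylogeny, dynamics/statistics, IO, pipeline, CLI, experiments)
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/clonal-cna-analysis.Rmd` — methods: models, identities,
  parameter choices, limitations
- `inst/extdata/` — synthetic plain-text fixtures and the demo config
- `inst/scripts/clonecna` — command-line wrapper
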