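---
title: "The fragment-ratio method: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fragment-ratio method: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragratio)
```

## The model

The method rests on the copy-number asymmetry of an XX/XY system. A pool
of female DNA carries, per individual, two copies of each autosome, two X
and no Y; a male pool carries two autosomal copies, one X and one Y. If
both pools are sequenced and mapped to a male reference, the expected
female:male depth ratio at a locus is 1 on autosomes, 2 on X and 0 on
unique Y sequence. Residual X–Y homology moves Y loci off zero, because
female reads from the X copy land on the homologous Y stretch; fully
degenerate Y sequence stays at zero.

The unit of comparison is not a window but a *fragment*: a maximal run of
unmasked, non-gap bases in the softmasked male assembly. Splitting at
repeats does two jobs at once — it removes the multi-mapping sequence that
would blur depth ratios, and it yields units small enough that a scaffold
becomes a set of quasi-independent draws for the enrichment test. Runs
shorter than `min_len` (default 200 bp) are discarded as too short for
stable counts.

Per fragment $i$, with female/male mapped-read counts $F_i, M_i$ and
library totals $F_{tot}, M_{tot}$:

$$R_i = F_i / M_i, \qquad \mathrm{norm} = M_{tot}/F_{tot}, \qquad
R_i^{norm} = R_i \cdot \mathrm{norm}.$$

`compute_ratios()` leaves $R_i^{norm}$ undefined when $M_i = 0$ and bands
such fragments, with every fragment below the male depth floor, as
`low_coverage`.

Fragments with $R_i^{norm} < 0.3$ (strict) and $M_i \ge 15$ are
Y-candidates. Per scaffold, `enrich_scaffolds()` computes the upper-tail
hypergeometric probability of the observed candidate count $k$ among its
$M$ fragments given $n$ candidates among $N$ fragments genome-wide, and
calls scaffolds with raw $P < 10^{-5}$ Y-linked. Stringent candidates
($R_i^{norm} < 0.15$) on the called scaffolds are then screened against a
female assembly; any tabular-BLAST hit with e-value $< 10^{-5}$ discards
the fragment, and `export_marker_candidates()` writes the survivors.

## Tail direction of the enrichment test

A lower-tail sum $\sum_{i=0}^{k-1}$ of the hypergeometric pmf approaches 1
for a scaffold overloaded with candidates; it is the *upper* tail
$P(X \ge k)$ that measures enrichment, and it is the upper tail that
reproduces the published per-scaffold P-values this class of analyses
reports (e.g. $P = 8.63 \times 10^{-17}$ for $k=6$ of $M=7$ at
$N = 605{,}448$, $n = 923$). `hypergeom_upper_tail()` therefore computes
$P(X \ge k)$, the complement of the lower-tail sum, and the package
documents this as the intended reading wherever the lower-tail formula
appears in print.

## Numerical choices

* P-values are accumulated in log space (`lchoose` + log-sum-exp), so
  $N \approx 6\times10^5$ with $P$ down past $10^{-75}$ loses no
  precision. Terms are normalized by the log-sum of the full support,
  which cancels shared rounding in the binomial coefficients.
* When the tail exceeds $1/2$ the direct sum is ill-conditioned in
  doubles, so the implementation sums the (short) lower tail instead and
  returns `log1p(-exp(lower))`. Tests hold the agreement with brute-force
  enumeration to $10^{-9}$ relative error in $\log_{10} P$ everywhere the
  magnitude of $\log_{10} P$ exceeds $10^{-12}$, and to $10^{-12}$
  absolute below that (the relative measure is meaningless at
  $P \to 1$).
* Threshold comparisons (`0.3`, `0.15`, the e-value cut, $\alpha$) are all
  strict `<`, matching the method's stated decision rules; boundary values
  are excluded.
* $M_i = 0$ yields an undefined ratio, never $\infty$ or a sentinel; such
  fragments can never be candidates because they also fail the depth
  floor.
* Ties in report ordering break by scaffold id after P-value.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_len` | 200 bp | minimum unmasked run kept as a fragment |
| `y_max` | 0.3 | Y-candidate ceiling on $R_i^{norm}$ |
| `stringent_max` | 0.15 | marker-selection ceiling |
| `min_male_reads` | 15 | male-pool depth floor |
| `alpha` | 1e-5 | raw P-value cut for the scaffold call |
| `evalue_max` | 1e-5 | female-homology discard threshold |
| `totals_mode` | `mapped_reads` | denominator convention for `norm` |

`totals_mode` deserves a note: published pool totals are printed both as
sequenced reads and as mapped reads, and the two give norms differing by
about 5% (0.98795 vs 1.03926 for the study totals). The package defaults
to mapped totals because they are internally consistent with the counts
entering $R_i$ — the same alignments are numerator and denominator — and
exposes `total_reads` with `external_totals` for users who prefer
sequenced library sizes. Under mapped totals the statistic is invariant to
rescaling either pool's depth, which the test suite checks as a property.
Published per-fragment ratio tables are not reproducible to the printed
digit under either convention (their rows are mutually inconsistent), so
those rows are treated as illustrative; the zero rows ($F_i = 0 \Rightarrow
R_i^{norm} = 0$) hold exactly and are asserted.

The X-like ($\ge 1.5$) and autosome-like ($0.6$–$1.4$) band edges are
diagnostic only — nothing downstream depends on them; only the Y threshold
is operational.

## Fragment definition details

Several choices the fragment splitter makes are conventions where the
method's description is silent:

* Runs of `N` (assembly gaps) separate fragments by default
  (`split_on_n = TRUE`), since a gap is not evidence of contiguous unique
  sequence; with `FALSE`, uppercase `N` is treated as ordinary sequence.
* Any masked/gap run of length ≥ 1 splits; there is no merging across
  short masked runs.
* Ordinals are assigned 1-based over *retained* (post-length-filter)
  fragments in scaffold order, and the fragment name is
  `{scaffold}_{ordinal}_{length}`. Indexing before the filter would be
  equally defensible; retained-order matches the observed pattern that low
  ordinals sit near scaffold starts.
* `masked_fraction()` reports lowercase bases over non-gap bases — repeat
  content is conventionally quoted over resolved sequence — and this is
  the convention used when comparing Y scaffolds with the genome.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions the method targets:
50 autosomal, 5 X and 5 Y scaffolds; 25× per pool (the published pools
were 24.68× and 25.08×); 150-bp reads; repeat density 0.17
genome-wide rising to 0.30 on Y, mirroring the published repeat-load
contrast (17.53% vs 30.71%); leakage 0 (fully diverged Y). Scaffold
lengths are uniform on 10–40 kb: a deliberate floor, because a Y scaffold
needs roughly five or more fragments for its hypergeometric P to clear
$10^{-5}$ at these candidate rates, and the published Y scaffolds are in
the 1–140 kb range with the informative ones above 8 kb. Counts are
Poisson with mean $\mathrm{depth} \times \mathrm{copies}/2 \times
L/\mathrm{read\_len}$ per pool and class (copies $(2,2,0)$ female,
$(2,1,1)$ male for A/X/Y), plus an additive female-pool leakage term on Y
emulating X–Y homology; negative-binomial overdispersion is available via
`overdispersion`.

The simulator is count-level by design: the statistic consumes
per-fragment counts, so simulating reads and re-aligning would test the
aligner, not the method. `write_counts_sam()` exists only to exercise the
BAM-counting path. Consequently, passing tests demonstrates correctness of
the statistic, the enrichment test and the decision rules under the
generative model — it does not demonstrate robustness to mappability
artifacts, GC bias, PCR duplicates, collapsed repeats or reference errors,
all of which real pool-seq data carry and which the published workflow
addressed upstream with standard trimming/alignment/dedup tooling. The
published mapping-rate asymmetry between pools (69.0% vs 72.6%) conflates
Y-specific content with library effects; the simulator exposes
`depth_f`/`depth_m` to mimic either but does not decompose them, and the
published genome-wide mean $R^{norm}$ of 0.905 (below the theoretical 1)
is data-dependent and not modeled.

Problem sizes in the shipped tests and the acceptance script are the
defaults above (~1.5 Mb of simulated genome, ~1,300 fragments), which a
laptop core processes in about a second; the exhaustive small-case oracle
sweep for the hypergeometric tail covers every valid $(N \le 60, n, M, k)$.

## Known limitations

* Fixed thresholds, no mixture modeling of the ratio distribution; the
  bands are descriptive.
* No multiple-testing correction by default (the method's operating
  point); `p_adjust = "bonferroni"`/`"BH"` tightens the call if wanted.
* Fragments are treated as exchangeable draws in the enrichment test;
  positional clustering of candidates within a scaffold is ignored.
* The homology filter applies the e-value cut only — no coverage or
  identity floor — so a short high-identity hit can disqualify a fragment.
* Windows users: the CLI wrapper assumes `Rscript` on the PATH.
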