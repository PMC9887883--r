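---
title: "Models and methods: small-RNA classification, enrichment calling and CLIP metagene analysis"
author: "smallRNAtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallRNAtools)
```

## The biological setting

In the *C. elegans* germline, RNA-dependent RNA polymerases synthesise
22-nt secondary siRNAs ("22G-RNAs") antisense to target mRNAs. These are
sorted onto two Argonaute clades with opposite outcomes: WAGO Argonautes
(WAGO-1, WAGO-9/HRDE-1) silence their targets, while CSR-1 licenses and
protects germline transcripts. 21-nt uridine-starting piRNAs guide the
Piwi Argonaute PRG-1, which initiates WAGO 22G-RNA production on
piRNA-recognised transcripts. Perturbing P-granule helicases (the GLH
family) redistributes 22G-RNAs between these pathways — including the
appearance of *ectopic* WAGO-type 22G-RNAs on CSR-1 targets.

All the quantitative procedures this package implements are
threshold-based set calls on per-gene read abundances, plus positional
profiling of CLIP fragments. None involves statistical testing; this
mirrors standard practice for these calls, and the package deliberately
keeps the rules explicit and auditable rather than wrapping them in
inference machinery.

## Read classification

A read record carries its position, strand, length, sequence and mapping
multiplicity. Classification precedence for reads overlapping several
annotation biotypes is piRNA > miRNA > mRNA:

- **22G**: mapping multiplicity 1, length exactly 22 nt, antisense to an
  mRNA gene. The 5'-G check is off by default: the class is defined
  operationally by length, strand and uniqueness, and requiring the G
  would silently change counts on real data where the convention is not
  absolute. It can be enabled (`classifyRules(require5primeG = TRUE)`).
- **piRNA**: sense overlap of an annotated piRNA locus; optional
  21-nt-length and 5'-U checks.
- **miRNA**: overlap of a miRNA locus, with no strand requirement (the
  annotation-overlap rule is deliberately permissive; miRNA handling is
  peripheral here).
- Reads overlapping an mRNA without qualifying as 22G are **other**;
  reads overlapping nothing are **unassigned**. Reads on chromosomes
  absent from the annotation are unassigned, not errors.

Ties between overlapping same-biotype genes go to the larger overlap,
then to the lexicographically smallest gene id — deterministic and
independent of record order. The minimum overlap to assign is 1 nt.

## Quantification and normalisation

Per-gene counts are normalised to reads per million,
$\mathrm{RPM}_g = 10^6 \, c_g / N$. The default denominator $N$ is the
total number of mapped records in the sample ("total read counts of each
sample"), not the counted class; `normMode = "class"` and
`"unique_mapped"` are provided because the composition of the intended
denominator on real data is ambiguous — whether multimappers count is
not derivable from the calling rules themselves, so it is an explicit
option rather than a hidden choice. An empty library yields an all-zero
table with total 0 and no division by zero.

## Threshold rules

The wording of each published rule decides strict versus non-strict
comparison, and the package follows the wording per procedure:

| procedure | rule | comparison |
|---|---|---|
| Argonaute IP enrichment | IP RPM ≥ 1 and IP/input **more than** 2-fold | strict `>` |
| differential 22G | **at least** 2-fold change | non-strict `≥` |
| CLIP targets | tagged RPM ≥ 5 and **at least** 2-fold over untagged | non-strict `≥` |
| IP-MS proteins | **at least** 2-fold over background IP | non-strict `≥` |

The RPM floor is applied on the side where it is meaningful: the IP (or
tagged) sample for enrichment, the test sample for up-calls and the
reference for down-calls — a "2-fold reduction and >5 RPM" rule only
makes sense with the floor on the higher side. Zero-denominator folds
are reported as `+Inf` rather than pseudocounted, so the printed
thresholds are never silently altered; genes absent from both samples
(0/0) are excluded from enrichment sets and fall to `below_floor` in
differential output. A pseudocount display option exists only in the
scatterplot.

Two rules are not fully specified by their sources and are exposed as
options with a documented default:

- **Suppression** of an ectopic gene by a second depletion: the default
  criterion is `double ≤ mutant / fold` (the ectopic signal halves); the
  alternative `"wt"` criterion (returned to within `fold` of wild type)
  is available, and both are reportable.
- Whether the 171-type "increased" call used an extra floor beyond the
  2-fold rule: the default applies no extra floor.

## The ectopic-target composite

`ectopicTargets()` intersects four conditions: membership in the
supplied CSR-1 target list, `up` in the mutant-versus-wild-type
differential, membership in at least one WAGO-family IP enrichment set,
and absence from the CSR-1 IP enrichment set. Each condition is computed
by the rules above, so the composite inherits their thresholds, which
are recorded in every serialized output.

## Metagene profiles

Per-gene coverage (RPM units) over the annotated gene span is oriented
5'→3' (reversed for minus-strand genes) and mapped onto 100 bins of 1%
of the gene length each. Binning is by exact fractional overlap: the
cumulative coverage function is piecewise linear in position, so
evaluating it at fractional bin boundaries and differencing conserves
per-gene mass exactly, for any gene length. Genes are aggregated with
equal weight by default (`mean`), matching "averaged CLIP reads along
each mRNA"; whether the original analysis weighted genes by coverage is
not stated, so `sum` mode is retained and the conservation tests use it.
The gene span is used as the transcript proxy — simulated genes are
unspliced, and exon-aware profiling of real GFF3 annotations is a
possible extension, not implemented.

The profile summary statistic is the centre of mass over bins 1–100; a
positionally unbiased library centres at 50.5.

## The simulator

`buildTruth()` lays the configured genes on one chromosome with
intergenic gaps, draws log-normal baseline abundances, assigns WAGO/CSR-1
target classes, and plants three kinds of structure recorded in a
`GroundTruth` object:

- **condition multipliers** — a genotype multiplies a chosen gene set's
  small-RNA rate (e.g. a glh-1-null-like condition raising 22G-RNAs
  4-fold on 50 CSR-1 targets); a derived condition can reuse another's
  gene set with a subset restored to baseline, emulating suppression by
  a second depletion;
- **IP enrichment factors** — a bait multiplies its planted target set's
  sampling weight by `e` in IP and tagged-CLIP fractions; bait sets can
  add or drop another condition's planted genes (`plusCondition` /
  `minusCondition`), which is how ectopic genes become WAGO-IP-enriched
  but CSR-1-IP-depleted in the demo;
- **CLIP positional bias** — fragment start positions in
  transcript-relative coordinates are drawn as $1 - \mathrm{Beta}(1,
  1+\beta)$: exactly uniform at $\beta = 0$, increasingly 3'-skewed as
  $\beta$ grows, and analytically checkable.

Reads are multinomial: depth is first split across classes by the
configured mixture, then within a class across genes with probability
proportional to abundance × condition multiplier (× `e` where
applicable). Every emitted record's sequence is extracted from the
generated genome FASTA (antisense reads as reverse complements), so the
classifier's sequence checks are honest. 22G reads are drawn from a
per-gene set of designated antisense start sites fixed at truth-build
time; the genome base under each designated 5' position is forced so
that 22G reads begin with G and 21U piRNA reads with U. This respects
both "sequences come from the genome" and the 22G/21U conventions
without rewriting whole strands, and resembles the discrete site usage
of RdRP products. piRNA loci are single 21-nt species; "other" reads
fall in intergenic space, exercising the unassigned path.

Determinism: one master seed; each library's stream is seeded by a
stable hash of (master seed, sample id), so samples are reproducible
individually and independent of simulation order. Identical config and
seed give byte-identical outputs, which the pipeline tests assert at the
file level.

### What the simulator does and does not emulate

It reproduces the *statistical* structure the calling rules assume —
planted abundance ratios, IP enrichment factors, class mixtures,
positional bias, multimapping (a configurable fraction of records with
multiplicity 2) — but not sequencing errors, adapter chimeras, intron
structure, expression-correlated GC effects, or ping-pong piRNA
biogenesis. Passing recovery tests therefore demonstrates that the
analysis correctly inverts the generative model it targets, not that it
is robust to artefacts absent from that model.

### Fixed-depth renormalisation, and the choice of defaults

Because each library has a fixed read depth, multiplying one gene set's
weight deflates every other gene's share. A planted factor $e$ on a set
holding fraction $f$ of its class's weight is observed as a fold of
$e / (1 + (e-1)f)$, not $e$ — with $e = 4$ and $f = 0.5$ the observable
fold is only 1.6, below a 2-fold threshold no matter how deep the
library. The defaults are chosen from this closed form: 1000 mRNAs with
planted sets of 50–150 genes keep $f \approx 0.1$, so a planted 4-fold
effect is observed near 3-fold; abundances use `sdlog = 0.5` (about a
10-fold dynamic range) so at the default depth of $10^5$ reads even
low-abundance genes retain tens of reads and binomial noise does not
straddle the threshold. The demo scenario's baits use $e = 6$ because a
WAGO bait carrying both its 100 normal targets and 50 condition-amplified
ectopic genes runs at higher $f$; at $e = 4$ the ectopic genes would sit
at an observed fold of ~2.25 against a strict >2 rule, i.e. the call
would hinge on noise rather than on the planted effect.

Problem sizes used throughout the tests — 1000-gene universe, $10^5$
reads per library, 20 seeds for recovery rates, 10 seeds per point on
the 3-point $\beta$ grid — are desk-scale choices that keep every
recovery estimate's own sampling error well below the margins being
asserted.

## Numerical and degenerate-input choices

- Duplex annealing scores every ungapped antiparallel register by
  Watson–Crick matches (U ≡ T; G·U wobble only on request, since the
  motivating duplex is perfect Watson–Crick); ties break toward the
  smallest register offset. Zero-match inputs report duplex length 0
  with undefined overhangs.
- Adaptor trimming is exact-substring plus a ≥6-nt adaptor prefix at the
  read's 3' terminus; reads lacking the adaptor are kept (the processing
  rule states only a length floor). No error tolerance — synthetic reads
  are error-free and read-level error models are out of scope.
- Gene universes must match exactly between compared tables; mismatches
  raise an error naming the symmetric difference rather than silently
  intersecting, because silent gene drops are the classic failure mode
  of set pipelines.
- Coordinates are 1-based closed inside R (`GRanges`); the TSV dialects
  are 0-based half-open and GFF3/SAM are 1-based at the boundary.

## Known limitations

Unspliced gene spans as transcript proxies; no crosslink-site or peak
calling; no statistical testing of enrichment (by design, matching the
procedures implemented); the IP-MS module consumes protein-level
quantifications and does not process spectra; alignment itself is out of
scope — the package consumes aligned records and the simulator emits
them pre-assigned.
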