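---
title: "Comparative meta-gene profiling of histone marks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative meta-gene profiling of histone marks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamark)
```

# The analysis problem

`metamark` compares the genomic distribution of a histone modification
between two conditions starting from aligned single-end read positions.
The motivating biology is a methyltransferase (MMSET/NSD2) whose
overexpression both raises the total amount of H3K36me2 several-fold
and dissolves its normal focal patterning: instead of peaks just
upstream of the TSS of expressed genes over a quiet intergenic
background, the mark becomes diffuse, elevated and boundary-less. Two
properties of this situation shape every design choice below:

1. **ChIP-seq measures fractional enrichment.** Read counts are
   normalized within a library, so a condition with 8-fold more total
   methylation does not produce 8-fold more reads. Comparisons must be
   phrased in relative terms and interpreted with that caveat.
2. **Global normalization can fail.** Count-based between-sample
   normalization assumes that most of the genome is unchanged. When a
   mark changes almost everywhere — up in some compartments, down in
   others — no single factor is meaningful. The package therefore (a)
   focuses its primary readout on *ratio curves across gene classes*,
   which are ordinal in the normalization factor, and (b) ships a
   diagnostic that detects when the unchanged-majority assumption is
   violated.

# Pipeline stages and their assumptions

## Duplicate removal

Reads mapping to the same position on the same strand are collapsed to
one, treating exact positional duplicates as amplification artifacts.
This is the conventional rule for unpaired reads; it deliberately also
removes genuine duplicate fragments, which biases dense regions
downward at very high depth. The operation is idempotent and
order-independent.

## Fragment-length estimation

The estimator computes, for every lag $d$ in a search range, the
Pearson correlation between the Watson 5′-frequency vector $f^+(x)$
and the Crick vector $f^-(x+d)$, pooling the aligned overlapping
segments of all chromosomes. A fragment $[s, s+L-1]$ places a Watson
5′ end at $s$ and a Crick 5′ end at $s+L-1$, so the correlation peaks
at lag $L-1$ and the reported length is $\mathrm{argmax}_d + 1$.

Choices made where the method is underdetermined:

* **Pearson correlation** rather than raw covariance, for scale
  invariance between libraries of different depth. Both the statistic
  and the search range are visible in the returned object.
* **Search range 50–500 bp** by default: wide enough for sonicated
  chromatin, with a floor that avoids lag-0/read-length artifacts. No
  special masking of the read-length "phantom" lag is applied; the
  floor handles the common case and the range is configurable.
* **Ties break to the smallest lag**, making the output deterministic.
* Degenerate inputs (a single strand present, or an everywhere-flat
  correlation) raise errors rather than returning a guess.

A caveat that the synthetic experiments make explicit: a sharp
correlation peak requires fragment midpoints that pile up at shared
sites. Punctate, site-structured signal (`simulate_binding_site_reads()`)
yields exact recovery; broad domain-like enrichment (the focal
Gaussian regime with its 1-kb sd) smears the peak, as it does in real
broad-mark data. The estimator is therefore validated on
site-structured reads, and the pipeline accepts a fixed
`fragment_length` when the experimentalist knows the sonication size.

## Tracks and normalization

Shifted 5′ positions ('+' reads moved $+\lfloor L/2 \rfloor$, '−'
reads $-\lfloor L/2 \rfloor$, clamped to the chromosome) give
centered-count tracks; extended fragments give coverage tracks. Every
track value is divided by $N/G_\mathrm{eff}$ — the average read
frequency per base pair of the effective genome size — so the
expectation of the value at any position is 1 and values read as fold
over the genome average. $N$ counts post-deduplication reads;
$G_\mathrm{eff}$ defaults to the mappable human genome size
$2.7\times10^9$ bp and should be set to the genome length for
synthetic genomes (`pipeline_config(g_eff = "genome")`).

Region summaries default to **centered counts**; coverage is available
behind the same interface (`track_kind = "coverage"`). Tracks are dense
per-base vectors, appropriate for the desk-scale genomes the package
targets (tens of Mb); bedGraph export merges equal-value runs and
omits zeros.

## Meta-gene and intergenic binning

Gene bodies are divided evenly into 50 bins regardless of length, so
all genes align at TSS and TES; the immediate 10-kb flanks get 50
fixed 200-bp bins each. Bin $k$ of a length-$L$ body covers fractional
coordinates $[Lk/50, L(k+1)/50)$; integer position $p$ belongs to bin
$\lfloor 50p/L \rfloor$. Genes shorter than 50 bp still produce 50
bins by letting an integer-empty bin read the position containing its
fractional start. Profiles are strand-oriented (index 1 is the most
5′-upstream flank bin); '−'-strand genes are computed left-to-right
and reversed. Flank positions beyond the chromosome are dropped from
their bin's mean, and an entirely out-of-range bin reports 0. Exact
reflection symmetry of the fractional partition holds when $L$ is a
multiple of the bin count (the straddling base otherwise has to fall
on one side); the property suite exercises symmetry on such genes.

Intergenic regions implement the upstream-gap rule: for each gene, the
strand-oriented gap from the nearest annotated gene boundary on the
TSS's 5′ side (chromosome start/end for terminal genes — the only
reading that always yields a well-defined gap) is selected when it
spans ≥ 30 kb, trimmed by 10 kb at both ends (those flanks already
appear in the gene plots), and profiled in 100 equal fractional bins.
Regions are deduplicated by interval, so two genes sharing a gap
contribute it once; both the deduplication and the bin counts are
configurable because conventions differ between published pipelines.

## Expression classification

Probes need at least 4 positive (log-scale > 0; positivity is the
package's reading of an unstated detection rule) values among the
replicates of *both* conditions. Multi-probe genes are represented by
the probe with the highest overall mean — a deliberate, documented
stand-in for an unstated collapse rule. Genes with both condition
means below 3 log units are `not_expressed` (a per-replicate variant
is available); the rest get a two-sample t-test, with `p < 0.002`
split into `up`/`down` by the sign of $t$ and everything else
`no_change`. No multiple-testing correction is applied: the fixed
threshold *is* the classification rule, and its realized size on null
data is one of the package's acceptance checks.

The **Welch** (unequal-variance) test is the default because
"two-sample t-test" is ambiguous and Welch is the safer general
choice; `var_equal = TRUE` reproduces pooled-variance Student
behavior. At 6+6 replicates with equal variances the Welch test is
mildly conservative (realized size ≈ 0.0016 at the 0.002 threshold),
which the null-simulation test band accommodates. A gene with zero
variance on both sides and equal means is `no_change`; with unequal
means it is a degenerate but unambiguous separation (p = 0).

## Ratio curves

For each class, each bin reports
$(\sum_{g \in \mathrm{class}} A_{g} + pc) / (\sum_g B_{g} + pc)$ with
pseudocount $pc = 0.5$. Summed rather than per-gene-averaged mass
mirrors a read-count ratio and weights genes by signal; both the
aggregation and the pseudocount are configurable. Ratios are invariant
to any common rescaling of both conditions, which is exactly why this
readout survives the normalization ambiguity described above.

## Peak comparison

Peaks arrive as intervals with an opaque nonnegative height (whether a
summit count or a fold enrichment does not matter to the statistics).
A gene is peak-bound when any peak overlaps TSS ± 2 kb — a
conventional promoter window, configurable because the upstream
peak-calling tools that produce such lists each have their own rule.
Shared peaks are matched 1:1 by greatest reciprocal overlap (ties to
the smallest coordinate), and matched heights and lengths are compared
by Welch t-tests.

## Normalization diagnostics

Non-overlapping windows (default 10 kb — unstated in the motivating
analysis, so configurable) give
$\log_2((\bar A + pc)/(f \cdot \bar B + pc))$. The factor $f$ applied
to condition B defaults to the **median of the per-window ratio** — a
deliberately simple, stated substitute for tool-derived count
normalization factors; an externally computed factor can be injected.
Bimodality is operationalized by Sarle's coefficient
$b = (g_1^2+1)/(g_2 + 3(n-1)^2/((n-2)(n-3)))$ at the conventional
uniform-distribution threshold 5/9 ≈ 0.555, because the underlying
judgment ("one mode or two?") is visual; the normal distribution gives
$b = 1/3$, well below threshold, and a Hartigan dip test would be a
natural alternative if finer control is wanted. Fewer than 10 windows
or zero variance raise errors.

# The synthetic-data generator

The generator defines the study conditions under which the package is
tested:

* **Genome and annotation.** Two chromosomes (1.6 + 1.2 Mb) carrying
  60 non-overlapping, strand-randomized genes of 5–15 kb, each
  preceded by a gap drawn from a two-point 15 kb / 45 kb mixture
  (default half and half) so the ≥ 30 kb intergenic rule has a crisp
  truth set.
* **Reads.** Fragments are placed by midpoint and emit one read from a
  uniformly chosen end, which pins the Watson/Crick separation at
  exactly $L-1$ ($L$ = 150 bp by default). The *focal* regime mixes a
  uniform background with a Gaussian (sd 1 kb) at the TSS of every
  expressed gene, scaled so the midpoint density at a TSS is 10-fold
  background — the TSS enrichment magnitude is a free parameter of the
  artifact, chosen as a typical active-promoter enrichment, since the
  motivating data constrain only the pattern. The *diffuse* regime is
  uniform with total mass 8-fold the focal background mass, so its
  per-bp density in gene-poor windows is 8× the focal background — 8
  being the documented overall fold change of the modeled mark. The
  focal condition draws exactly `n_fragments` (2×10⁵ by default); the
  diffuse fragment count is `diffuse_fold` × the expected focal
  background count, which is what makes the mass ratio recoverable.
  Fragments overhanging chromosome ends are clipped, not wrapped;
  tests of the expectation-1 property use interior-only placement to
  avoid edge bias.
* **Expression.** 6 replicates per condition; expressed genes at
  baseline 6 log units with noise sd 0.5, planted `up`/`down` genes
  shifted ±2 log units in condition A (an effect giving essentially
  complete power at 6+6, so recovery failures indicate bugs rather
  than bad luck), `not_expressed` genes at baseline 2 (< 3) in both.
  Class fractions default to 15/10/60/15%.
* **Peaks.** One promoter-centered peak per selected gene realizes any
  requested (A-only, common, B-only) Venn structure exactly; common
  peaks in condition A are drawn 2× taller and 1.5× wider, emulating
  shared repressive-complex peaks that grow under the MMSET-high
  condition (magnitudes chosen, not measured).

Determinism: every generator derives its stream from `sim_config`'s
single seed (with fixed per-stage offsets), so identical configs give
bit-identical outputs.

**What passing tests do and do not show.** The generator emulates the
*pattern contrast* (focal vs diffuse, planted expression classes,
controlled Venn structure) with clean Poisson-like sampling noise. It
does not model mappability, GC bias, chromatin-input background,
sequence content, replicate-level biological variability in the
ChIP-seq arm, or probe-level microarray artifacts. Passing tests
therefore demonstrate that the *computations* are correct and that the
method recovers planted truth under its own assumptions — not that
those assumptions hold in any particular real dataset.

# Numerical conventions and problem sizes

* All internal coordinates are 0-based half-open; BED/bedGraph match
  natively, and conversions happen only at format boundaries.
* `floor(L/2)` shifting; deterministic tie-breaks everywhere (smallest
  lag, lexicographic gene ids, smallest coordinates).
* The expectation-1 check holds to 10⁻⁹ (it is exact up to float
  summation); oracle-equivalence checks run at 10⁻¹² relative
  tolerance, except the cross-correlation curve, where two
  algebraically identical formulas differ at machine epsilon and the
  argmax is required to agree exactly.
* Test problem sizes — 10⁴–10⁵ fragments on 1–3.5 Mb genomes, 60-gene
  annotations, 2×10⁴ null genes for the classifier-size check, 100
  random instances for oracle equivalence — were chosen so the full
  suite completes in about two minutes on one core while keeping
  every stochastic band at least 3σ wide.
* The pipeline is a pure function of (inputs, config): reruns produce
  byte-identical output files.

# Known limitations

* No input/control subtraction, GC correction or mappability masking.
* Dense per-base tracks assume desk-scale genomes; a run-length
  backing store behind the same interface would be needed for
  mammalian-scale work.
* The fragment-length estimator is unreliable on purely broad-domain
  signal (by construction of the statistic, not implementation); fix
  the length explicitly in that regime.
* Peak calling itself is out of scope: peak sets are inputs.
* The expression arm assumes data already on a log analysis scale;
  array preprocessing belongs upstream.
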