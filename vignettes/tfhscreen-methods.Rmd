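---
title: "Methods: simulating and analysing in vivo pooled CRISPR screens of Tfh differentiation"
author: "tfhscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing in vivo pooled CRISPR screens of Tfh differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfhscreen)
```

# The screen this package models

Targeted in vivo pooled CRISPR knockout screens of CD4 T cell
differentiation work as follows. A retroviral sgRNA library (4–5 guides
per gene plus non-targeting controls) is transduced into Cas9⁺
TCR-transgenic (SMARTA) CD4 T cells, the pool is expanded in culture,
and about 10⁶ cells are adoptively transferred into each recipient
mouse, which is then infected with acute LCMV. The transferred cells
expand and bifurcate into CXCR5⁺ Tfh and CXCR5⁻SLAM⁺ Th1 populations;
these are sorted per mouse, sgRNA cassettes are PCR-amplified from
genomic DNA, and guide abundance is read out by sequencing. A gene that
promotes Tfh differentiation shows depletion of its guides in the Tfh
gate relative to Th1.

Two features dominate the statistics of such screens and both are
explicit in this package:

* **The engraftment bottleneck.** Adoptive transfer loses roughly 90%
  of cells, so a guide present at 1-in-1000 of a 10⁶-cell pool is
  represented by only ~100 founding cells in vivo. This bottleneck, not
  sequencing depth, sets the detection limit, and is why the assay is
  practical only for pools of ≲1000 guides.
* **The replicate hierarchy.** Each mouse is an independent
  bottleneck-and-expansion experiment. Per-guide log2 fold changes are
  therefore averaged per mouse within experiment and then across
  experiments, never pooled across all samples.

# The forward model

`simulateScreen()` composes six stages, each a standard stochastic
kernel:

1. **Plasmid pool** — log-normal relative abundance with standard
   deviation `plasmidSigma` (default 0.5) on the log scale; cloned
   libraries are never exactly uniform.
2. **Culture** — a guide with in vitro fitness $f$ grows as
   $2^{d(1+f)}$ over $d$ doublings (default 6, a day-6 culture);
   realised counts are Poisson. $f=0$ is neutral, $f=-1$ is stasis.
3. **Transfer and engraftment** — a multinomial draw of
   `transferPoolSize` (default 10⁶) cells, then independent binomial
   thinning at `engraftmentRate` (default 0.10, the ~90% transfer
   loss). No homing heterogeneity is modelled; the binomial is the
   simplest kernel consistent with the stated loss.
4. **In vivo expansion** — deterministic exponential expectation
   $2^{d(1+f_{\mathrm{vivo}})}$ with Poisson realisation per guide
   rather than a per-cell birth–death process; at the cell numbers
   involved the first two moments agree and the computation stays
   desk-scale. The default `invivoDoublings = 8` reflects the massive
   clonal burst of virus-specific CD4 T cells over six days of acute
   infection; the true value is not measurable from the screen data and
   only shifts the effective bottleneck depth, so it is a config
   parameter, chosen once.
5. **Fate choice** — each cell becomes Tfh with probability
   $\mathrm{logit}^{-1}(\beta_0 + \Delta_g)$ where $\beta_0$ is
   `baselineTfhLogit` (default 0, i.e. a 50:50 split — flow data show
   variable splits and no canonical value) and $\Delta_g$ is the
   gene's `tfhLogitShift`. Negative $\Delta_g$ means knockout impairs
   Tfh differentiation. Tfh cells split into GC Tfh at a fixed
   `gcTfhFraction` (default 0.5) because screen results are nearly
   identical in the pre-Tfh-vs-Th1 and GC-Tfh-vs-Th1 readouts; the
   split is not itself modelled as gene-dependent.
6. **Sorting and sequencing** — each gate is sampled at
   `sortCoverage` (default 750) cells per guide; with probability
   `1 - sortPurity` (default purity 0.95) a sorted cell is drawn from
   the pooled complementary gates — impurity is symmetric because only
   the purity level, not its direction, is known. Sequencing is a
   multinomial of `seqDepth` (default 300) reads per guide with
   gamma-distributed PCR weights (`pcrShape`, default 10; larger is
   cleaner). The 750×/300× defaults are the assay's stated coverage
   floor.

A guide-level effect size worth remembering: a shift $\Delta = -2$
moves the Tfh probability from 0.50 to 0.12, which corresponds to an
ideal Tfh-vs-Th1 log2 fold change of $\log_2(0.12/0.88) \approx -2.9$,
attenuated in practice by sort impurity and bottleneck noise to around
$-2.4$ under default conditions.

## What the simulator does and does not emulate

The generator reproduces the sampling structure of the screen —
bottlenecks, coverage, purity, replicate design — with known ground
truth, which is exactly what the statistical pipeline needs to be
validated against. It does not emulate viral titer or infection
kinetics, homing heterogeneity, Tfr cells, clone-level lineage
correlations (sibling cells share no latent state), guide-level
variability in cutting efficiency, or sequence-dependent PCR bias.
Passing tests on simulated screens therefore demonstrate that the
statistics recover truth under the assay's sampling regime, not that
any particular biological hit list is correct.

# Guide quantification

Reads are amplicons containing the cloning cassette
`ggagaaaagccttgtttg-N20-gttttagagctaggatcctagc`. Rather than aligning
with a general-purpose aligner, `countSample()` anchors on the flanks:
it finds the 9-mer `CCTTGTTTG` (the 3′ end of the upstream flank),
takes the next 20 nt, and requires `GTTTTA` (the 5′ end of the tracr
flank) immediately after. For a closed library of known 20-mers this is
equivalent in effect to local alignment, fully specified, and exact.
Assignment is exact-match first; an unmatched spacer is rescued to a
library spacer at Hamming distance 1 only when that assignment is
unique — ambiguous reads stay unmapped, and
`sum(counts) + unmapped = total` holds for every sample. Reads are
searched on the emitted strand only; the simulator writes sense-strand
reads.

Normalisation is counts-per-million mapped reads; the upstream
pipeline's normalisation was not published in detail, and CPM is the
simplest scheme under which downstream ratios are depth-invariant. A
median-of-controls alternative (`method = "medianControls"`) anchors
the scale to non-targeting guides instead, which is preferable if large
fractions of the library change abundance.

# Statistics

**Per-guide L2FC.** $\log_2\frac{c_n + 0.5}{c_d + 0.5}$ on CPM values.
The 0.5-CPM pseudocount bounds the statistic for dropout guides;
guides absent from both members of a pair carry no information and are
flagged and excluded from that replicate. The "Tfh" population in
comparisons is the sum of the preTfh and GCTfh sort gates.

**Hierarchy.** `hierarchicalAverage()` averages mouse values within
experiment, then experiment means, unweighted at both levels, so an
experiment with more mice does not dominate. When mice are pooled
before sorting, the pooled (experiment, day) samples take the mouse
slot in the hierarchy — days act as replicates.

**Gene level.** Mean over guides with SEM on the $n-1$ sample standard
deviation; SEM is reported absent for single-guide genes.

**Z-scores.** Standardised against non-targeting control guides grouped
into pseudo-genes of `guidesPerGene` guides, the controls defining the
null scale. All control pseudo-genes enter the reference, so their own
z-scores have sample mean 0 and sd 1 by construction. With a finite
number of control pseudo-genes (8 under default conditions) the
targeting genes' null z-scores are slightly heavier-tailed than
standard normal (sd ≈ 1.2–1.3), which is inherent to plug-in
standardisation, not a defect. An all-gene reference is available via
`zReference = "all"`.

**α-RRA with permutation FDR.** Guides are ranked by L2FC in the
chosen direction; for a gene with $k$ guides at normalised ranks
$u_{(1)} \le \dots \le u_{(k)}$ the score is
$\min_{j:\,u_{(j)} < \alpha} P\!\left(U_{(j)} \le u_{(j)}\right)$ with
$U_{(j)} \sim \mathrm{Beta}(j, k-j+1)$, i.e. the most surprising order
statistic among guides inside the top-$\alpha$ fraction
($\alpha = 0.25$ by default, matching the FDR < 0.25 display
convention). Genes with no guide in the top fraction score 1. The null
distribution draws size-matched pseudo-genes from the control guides'
observed ranks (10,000 draws, seeded); $p = (1 + \#\{\mathrm{null} \le
\mathrm{obs}\})/(1 + n_{\mathrm{perm}})$, never exactly zero, and FDR
is Benjamini–Hochberg across targeting genes. With few control guides
the permutation floor ties the strongest hits at the same p-value;
the RRA score itself breaks such ties. If a library has fewer controls
than `guidesPerGene` the null falls back to all guides, with a
warning.

**Quadrant classification.** From the two against-culture comparisons:
depleted in both arms (below −1 L2FC by default) means required for
expansion; enriched in both (above +1) means the gene inhibits
expansion; one-armed depletion assigns the fate-specific categories.
The ±1 defaults are display conventions, not inference.

# Power analysis

`titrationPower()` reproduces the spike-in titration in silico: the
target gene's guides are mixed at a known frequency into a neutral
background pool, carried through the full mouse model, and detection is
called when the target's Tfh-vs-Th1 L2FC lies ≥ 2 control-anchored
standard deviations from the background genes (two-sided, so the null
detection rate is the rule's nominal size, ≈ 0.05). The default grid —
frequencies 1/100 to 1/3000 of a 10⁶-cell pool at 10% engraftment —
brackets the regime where the assay's stated 1-in-1000 sensitivity
lives. The spike-in readout in the wet lab was flow cytometry of GFP⁺
fractions; mapping it onto count space is a deliberate modelling
translation, and power at a given frequency is always conditional on
the assumed effect size (reported alongside), since the titration
itself does not estimate one.

Detection power is Monte-Carlo (`nReps` per grid cell with binomial
standard errors); no closed form is attempted.
`minimumDetectableFrequency()` reports the smallest tested frequency
reaching a target power, a grid quantity by design.

# Numerical and design choices

* Spacers in generated libraries are uniform random 20-mers with
  duplicates and homopolymer runs ≥ 6 rejected. Sequence identity is
  irrelevant to the pipeline; only uniqueness matters.
* One master seed fans out to per-stage seeds through a fixed
  multiplicative map, so any stage can be rerun in isolation and whole
  runs are bit-reproducible (`runEndToEnd()` writes md5s of every
  output into `manifest.json`).
* Ties in guide ranking share average ranks; missing guide statistics
  take the worst rank rather than being dropped, so a gene cannot
  improve by losing guides.
* Degenerate inputs are warnings, not errors, when they mirror real
  failure modes: a mouse with zero engrafted cells returns an empty
  sample; an all-zero cell pool sequences to an all-zero column.
* Problem sizes in the shipped tests are the screen's own design
  points: 80 genes × 5 guides + 40 controls, 2 experiments × 5 mice,
  750× sort coverage, 300× depth. Monte-Carlo loops use 10–20
  replicates, enough for the 3-SE bands used in the assertions.

# Known limitations

* The FDR engine is an independent re-implementation of the α-RRA
  idea; it is not byte-compatible with any released screen-analysis
  software, and exact published hit lists are out of scope (the
  original raw screen FASTQ are not public).
* Control-based permutation nulls are granular when control guides are
  few; p-value floors are expected and documented above.
* The quantifier assumes single-end reads containing the full cassette
  on one strand; quality trimming, paired-end merging and UMIs are out
  of scope.
* Whether published Z-scores derived from gene means or from upstream
  software's own fold changes is ambiguous in the source protocols;
  both pathways exist here (`zReference`), neither is asserted as the
  original.

# Session info

```{r}
sessionInfo()
```
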