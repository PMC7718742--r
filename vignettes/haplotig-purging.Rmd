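---
title: "Haplotig purging from k-mer spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotig purging from k-mer spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purgetigs)
```

## The problem

Short-read assemblers working on heterozygous diploid genomes often emit
*haplotigs*: the two alleles of a sufficiently divergent region assemble
into separate scaffolds instead of collapsing into one. The assembly then
carries that region twice, inflating its size and duplicating genes. The
signature is visible without any alignment to a reference: take all
canonical k-mers of the sequencing reads and ask how often each occurs in
the assembly. Collapsed (normal) regions put homozygous-coverage k-mers on
the copy-1 diagonal of the read-multiplicity-by-assembly-copy histogram;
haplotig regions put k-mers with *single-copy read coverage* at *assembly
copy 2*.

`purgetigs` detects and removes such scaffolds in four stages:

1. **Count** canonical k-mers in reads and assembly (`count_kmers()`,
   `spectra_cn()`).
2. **Decompose** the read k-mer spectrum into error, heterozygous and
   homozygous components and derive a homozygous-coverage band
   (`fit_spectrum()`, `homozygous_bounds()`).
3. **Flag** scaffolds whose median assembly k-mer copy number is exactly 2
   and whose median read k-mer multiplicity lies inside the band
   (`profile_scaffolds()`, `flag_haplotigs()`).
4. **Remove** flagged scaffolds contained within a strictly longer
   scaffold at ≥ 75% identity and ≥ 25% query coverage, then verify from
   the before/after copy-number matrices that no single-copy homozygous
   content was lost (`deduplicate()`, `validate_dedup()`).

## The spectrum model

For a diploid genome sequenced at total depth $C$ with reads of length
$L_r$ and per-base error rate $e$, an error-free k-mer from a homozygous
position is expected at multiplicity

$$\lambda_{\mathrm{hom}} = C \cdot \frac{L_r - k + 1}{L_r} \cdot (1-e)^k,$$

while a heterozygous k-mer, covered by only one haplotype, peaks near
$\lambda_{\mathrm{hom}}/2$. Sequencing errors produce a large mass of
near-unique k-mers at the bottom of the spectrum. `fit_spectrum()` models
the histogram of distinct-k-mer counts above the error region as a sum of
Gaussian components,

$$h(m) \approx \sum_j w_j\, \mathcal{N}(m;\, \mu_j, \sigma_j),$$

fitted by bounded Levenberg–Marquardt least squares on the histogram
itself. Histogram-level fitting (rather than per-k-mer mixture EM) is
deterministic, fast at any genome size, and sufficient because only the
component locations, widths and the resulting band matter downstream.

Numerical choices:

* **Error cutoff** — the first local minimum of the histogram scanning up
  from multiplicity 1; if the histogram is monotone decreasing
  (pathological input), multiplicity 3 is used so the fit can still
  proceed.
* **Peak anchoring** — the homozygous component is anchored at the
  histogram mode above the cutoff, *except* when a second local maximum
  near twice the mode carries at least 20% of its height. In that case the
  upper peak anchors the homozygous component: at ~1% heterozygosity the
  half-depth peak can be the global mode, and anchoring on it would swap
  the roles of the two components. Initial means are then half, one, two
  (and three) times the anchor for the 2–4 requested components.
* **Fit window** — multiplicities from the cutoff to four times the
  anchor; mass beyond that is repeat content the 2-component model does
  not describe.
* **Degenerate spectra** — if no mass remains above the cutoff the fit
  aborts with an error advising deeper coverage, rather than returning a
  meaningless band.

### The homozygous band

The band is $\mu_{\mathrm{hom}} \pm 3\sigma_{\mathrm{hom}}$, truncated on
each side where a neighboring component stops being negligible, and never
below the error cutoff. Truncation is by *posterior purity*: the band
keeps only multiplicities where the homozygous component contributes at
least 90% of the fitted density relative to the adjacent component. The
more obvious rule — truncating at the equal-density crossing — is the 50%
special case, and it is not strict enough: at the crossing, half the
k-mers are heterozygous by definition, and the heterozygous peak's upper
tail then leaks into the band. That leakage matters twice. For flagging it
is harmless (scaffold medians sit near peak centers, not edges), but the
post-removal validation counts k-mers in the band that drop to assembly
copy 0, and the removed haplotigs' allele-specific k-mers populate exactly
that heterozygous upper tail. With the purity rule the band edge moves a
few multiplicity units up from the crossing and measures genuine
homozygous loss instead.

A zero-width component (degenerate fit) yields the guard band
$(\mu - 1, \mu + 1)$.

## Flagging

A scaffold is flagged as a putative haplotig when

* its **median assembly k-mer copy number equals 2** — the lower-middle
  median of all its N-free k-mer windows looked up in the assembly's own
  table (lower-middle keeps medians integral, so "equals 2" is an exact
  predicate);
* its **median read k-mer multiplicity lies inside the homozygous band**
  (inclusive at both edges) — i.e. the duplicated content has the read
  coverage of single-copy genome, which is what distinguishes a haplotig
  from a genuine segmental duplication (whose read coverage is doubled);
* it has at least one valid k-mer window (scaffolds shorter than `k` or
  all-N are profiled but never flagged).

An aggressive mode (`copy_at_least = TRUE`) flags median copy ≥ 2 instead;
the default keeps the literal copy-2 predicate.

## Containment and removal

Flagged scaffolds must additionally be *contained* in a strictly longer
scaffold before removal — flagging alone is deliberately not sufficient.
Containment uses canonical minimizer anchors (default `k_a` = 15, window
`w` = 10, expected anchor density $2/(w+1)$), chained per target and
strand by a bounded longest-colinear-subsequence pass (gap difference ≤
200 bp, chain gap ≤ 5 kb, lookback 64), keeping chains of ≥ 3 anchors and
merging chains separated by < 1 kb on both sequences.

* **Query coverage** is the union of chained query intervals over the
  query length. Coverage is measured on the query (the candidate
  haplotig) because the removal rule deletes the query: a short scaffold
  fully contained in a long one should count as covered regardless of how
  little of the *target* it spans.
* **Identity** is exactly matched query bases over the chained span.
  Anchor bases are exact matches by construction; the bases between
  consecutive anchors are compared directly against the target along the
  local diagonal (strand-aware), with length differences between the two
  gap sides counted as mismatches. This estimator stays within a few
  thousandths of the planted substitution rate down to at least 90%
  identity. A pure anchor-coverage ratio, by contrast, collapses at high
  divergence (only $(1-e)^{k_a}$ of windows survive errors) and cannot
  resolve the 75% threshold region; full dynamic-programming alignment
  would be needless cost since haplotigs are typically > 95% identical.
* Reverse-strand containments are handled by strand-consistent chains on
  the target's reverse complement; inversions appear as separate chains.

Removal requires best-hit identity ≥ 0.75 **and** query coverage ≥ 0.25,
both inclusive. Flagged scaffolds are processed in ascending length order;
targets are all strictly longer scaffolds of the input assembly regardless
of their own flagged/removed status (single pass, no cascades, no
recursion), and the assembly k-mer table is not recomputed between
removals. Ties between equally scoring targets break by higher identity,
then lexicographic target id, so runs are fully deterministic.

## Validation

`validate_dedup()` compares the spectra-cn matrices before and after
removal, inside the homozygous band:

* `duplicated_hom` — distinct k-mer mass at assembly copy ≥ 2; removal
  should shrink it (that mass *is* the pathology).
* `lost_single_copy` — the increase of band mass at assembly copy 0;
  content newly absent from the assembly. The pass threshold is 0.5% of
  the band mass.

## The synthetic data generator

`simulation_spec()` describes the study conditions; all outputs are pure
functions of the spec and its mandatory seed (genome at `seed`, assembly
structure at `seed + 1`, reads at `seed + 2`).

* **Genome** — i.i.d. bases at a target GC (default 0.32, typical of
  insect genomes); haplotype B differs by Bernoulli substitutions at
  `het_rate` (default 1%, the heterozygosity regime where short-read
  assemblers start emitting haplotigs).
* **Mock assembly** — the genome is cut into Exponential(50 kb) segments
  truncated to [5 kb, 500 kb]; each segment yields a haplotype-A primary
  contig, and 30% of variant-bearing segments additionally emit a
  haplotype-B copy trimmed to a random 30–90% sub-interval (the planted
  haplotig, always shorter than its partner). Variant-free duplicates are
  never planted: they would be exact repeats, a different pathology the
  flagging predicate does not target.
* **Reads** — single-end 100 bp at total depth 40 (20 per haplotype),
  uniform substitution errors at 0.5%; ids carry the source haplotype and
  position as truth labels.

What the generator does *not* emulate: indels (in heterozygosity or in
read errors), paired ends, quality models, repeat structure,
assembler-specific artifacts (chimeras, gaps, contig graphs). Passing
tests therefore demonstrate the pipeline's behavior under
substitution-dominated heterozygosity on repeat-poor sequence — the core
mechanism — not performance on repeat-rich real genomes, where flagging
precision depends on how well copy-2 repeats are distinguished by read
coverage.

## Problem sizes and tunables

The package defaults are `k` = 27 (counting), `k_a` = 15 / `w` = 10
(anchoring), target copy 2, identity 0.75, query coverage 0.25, spectra-cn
clip 10. `k` is capped at 31 so every k-mer packs into a 64-bit word; it
must be odd so no k-mer is its own reverse complement.

The test suite exercises the full pipeline at the generator's default
scale (5 Mb genome, 2 million reads, three seeds) and the brute-force
oracle comparisons at ≤ 2 kb; spectrum-recovery sweeps use 300 kb genomes
across depths 30/40/60 and heterozygosity 0.2%/1%, sizes at which the
histogram is smooth enough for stable fits while a full sweep stays in the
minutes range on one core.

## Known limitations

* Copy-2 *repeats* with homozygous coverage are indistinguishable from
  haplotigs by the flagging predicate alone; the containment requirement
  is the safeguard, and it resolves tandem or dispersed exact repeats only
  when the repeat copies live on a longer scaffold.
* The Gaussian components have thinner tails than true k-mer multiplicity
  distributions (which are overdispersed); the purity truncation
  compensates at the band edges, but extremely uneven coverage (amplified
  libraries) would call for heavier-tailed components, which the fit does
  not model.
* Identity estimation assumes substitution-dominated divergence; long
  indels fragment chains and depress coverage rather than identity.
* The minimizer index holds sequences and postings in memory; assemblies
  far beyond the gigabase range would need an on-disk index.
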