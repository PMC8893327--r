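---
title: "Methods: calling TE landscapes and quantifying TE eccDNA with telscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling TE landscapes and quantifying TE eccDNA with telscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telscope)
```

# The problem

Transposable elements (TEs) are mobile DNA sequences that can insert at new
genomic loci. In pooled whole-genome sequencing of small groups of animals
(for instance ten flies, i.e. twenty haplotypes), the set of non-reference
insertion loci — the *TE landscape* — can be compared between young and aged
cohorts to ask whether TEs mobilize during aging. Two obstacles dominate
this analysis. First, library-preparation artifacts (chimeric PCR
molecules) masquerade as novel junctions, so a caller needs both a strict
evidence rule and an internal false-positive benchmark. Second, landscapes
from libraries of different depth are not comparable without depth
matching. `telscope` implements the full workflow — insertion calling,
false-positive benchmarking with immobile gene elements, depth-matched
bootstrap comparison, consensus coverage profiling, TE-derived
extrachromosomal circular DNA (eccDNA) quantitation with plasmid
spike-ins, and PCR-based copy-number calculators — together with a seeded
synthetic-data generator, so every stage is testable against a known truth.

# Insertion calling

## Evidence model

Reads are aligned to the combined reference (genome, TE consensus library,
IGE genes, plasmids). Two evidence channels support a putative insertion at
genomic position $p$ of family $f$:

* **Split reads**: a read whose 5' or 3' segment maps uniquely to the
  genome while the clipped remainder (at least 15 bp) maps a TE consensus;
  these carry a base-precise junction coordinate.
* **Discordant pairs**: one mate maps uniquely to the genome, the other to
  a TE consensus or inside an annotated pre-existing TE copy; these bound
  the junction only to an insert-size interval.

The *side* of each piece of evidence records which flank of the insertion
the genomic segment abuts. Evidence near annotated pre-existing TE copies
is excluded, since reference copies produce genuine genome–TE junctions
that are not new insertions.

## Acceptance rule and Coverage Ratio

Evidence of the same family within a clustering window (default: insert
mean + 2 SD) merges into one candidate. A candidate is accepted iff

$$ i = i_L + i_R \ge 4 \quad\text{and}\quad \min(i_L, i_R) \ge 2, $$

the two-sided rule (about two reads on each junction) that suppresses
one-sided artifact junctions. Each accepted call gets a **Coverage Ratio**

$$ \mathrm{CR} = \frac{i}{r + 1}, $$

where $r$ counts concordant read pairs cleanly spanning the junction
window with no TE signal (reference-allele reads) and the $+1$ is a
pseudocount. In a pooled sample CR proxies penetrance: a fully penetrant
insertion leaves no reference-allele reads at the locus ($r \approx 0$,
CR large), a rare insertion is swamped by reference reads (CR small). The
conventional classification cutoff is CR $> 2$ ("deep"), with the boundary
CR $= 2$ classified shallow. Landscapes are normalized to insertions per
million mapped reads.

## IGE false-positive benchmark

One hundred arbitrarily selected protein-coding genes — *immobile gene
elements* (IGEs) — are carried through the entire pipeline exactly like TE
families. Since genes do not transpose, any accepted "IGE insertion" is an
artifact, and

$$ \text{FP rate} = \frac{|\text{IGE calls}|}{|\text{TE calls}| + |\text{IGE calls}|} $$

estimates the artifact fraction of the landscape.

## Parameter defaults

| parameter | default | meaning |
|---|---|---|
| `minTotal` | 4 reads | minimum total junction support |
| `minSide` | 2 reads | per-side floor (the "about two per junction" rule) |
| `window` | insert mean + 2 SD (bp) | evidence clustering window |
| `minClip` | 15 bp | smallest clipped segment considered |
| `crSpan` | read length (bp) | half-width of the reference-read window |
| `crThreshold` | 2 | CR classification cutoff (strictly greater) |

The reference-read window for $r$ is a declared convention (no standard
definition exists); `minSide` reads the per-junction wording as a hard
per-side floor and can be relaxed to 1.

# Depth matching and bootstrap

To compare two libraries, the deeper one is downsampled to the mapped
depth of the shallower: the fraction is `mappedLow / mappedDeep` rounded
*up* at the fourth significant digit (0.572135 becomes 0.5722; this
ceiling reading is configurable to nearest rounding), and read pairs are
kept atomically with that probability. Reproducibility of landscape calls
under resampling is assessed by a seeded bootstrap: for permutation
$k = 1..20$ the library is downsampled at fraction 0.5 with seed $k$
(seeds equal the iteration index, so reruns are bit-identical), re-called,
and summarized by mean, SD and a percentile 95% CI. Twenty permutations at
50% are the settled defaults; both are exposed, including a
100-permutation mode.

Two normalized values are recorded per permutation: the insertions per
million mapped reads of the downsampled library itself, and the same call
count normalized to the parent-library depth equivalent
(`mapped / fraction`). The second is the depth-adjusted estimator of the
full-library value: for well-supported landscapes the call count is
insensitive to halving while the mapped denominator is not, so only the
parent-normalized value is expected to match the full-library figure.

# Landscape comparison

Calls from two depth-matched landscapes match iff same chromosome, same
family, and positions within `matchWindow` (default 100 bp — discordant
evidence is interval-resolved, so exact matching would be too strict;
0 restores exact matching). Matching is greedy nearest-first with each
call used at most once, which guarantees the partition identity
$|\text{common}| + |\text{unique}_X| = |X|$. Family composition tables
lump families below 1% of calls into "Others"; per-family aged/young
ratios use per-million normalized counts, with a +1 pseudocount option for
families absent at one timepoint.

Paired per-family gains are tested with the Wilcoxon signed-rank test and
cohort differences with the rank-sum test. Both use exact null
distributions at small sample sizes, computed by dynamic programming over
the rank generating polynomial in half-rank units — equivalent to full
enumeration of sign patterns / group assignments and exact *including
midranks from ties* (the all-gains-equal case that motivates it). The
exact limit is $n \le 25$ pairs (signed-rank) and combined $n \le 30$
(rank-sum); beyond that a normal approximation with tie and continuity
corrections is used. Fewer than 3 informative family pairs refuses the
test.

# Consensus coverage

Location-independent TE load is profiled by end-to-end (no soft-clip)
mapping against the consensus entries: per family and IGE gene, the read
count, RPM, and mean per-base coverage (`count * readLength / length`;
both the per-base mean and the read-count mean are derivable, since the
two are sometimes conflated). Aged/young coverage ratio tables flag
zero-denominator targets and report Wilcoxon rank-sum p-values separately
across TE families and across IGE genes, the latter serving as the
stability control.

# eccDNA quantitation

eccDNA libraries (circular DNA surviving exonuclease digestion of linear
DNA) are mapped against a *doubled-consensus* index: each TE consensus and
plasmid concatenated head-to-tail with itself, so a read crossing the
circular junction maps contiguously; alignments are canonicalized to
start mod consensus length. Per family, `x` counts all reads and `j` the
circular-junction reads covering the boundary by at least `m = 10` bp on
each side (the detection rule is our concrete realization of
junction-spanning read counting). For uniform sampling of a circle of
length $L$, $j/x \approx (w - 2m + 1)/L$, an analytic check used in the
tests.

Spike-in plasmids calibrate recovery: four post-extraction plasmids
(2.7/3.5/5.2/6.3 kb at a 1, 0.1, 0.01, 0.001 relative-mass dilution
series) and one pre-extraction 7 kb reference added before gDNA
extraction. Because the plasmids share a backbone, a read mapping a region
shared by $k$ plasmids contributes $1/k$ to each (mapping-site
normalization). The spike-in-normalized value per family is

$$ v = \frac{(x / y) \cdot 10^6}{z}, $$

with $y$ the genome-derived aligned reads of the library (plasmid reads
are excluded from the denominator so that spike-in amounts cannot dilute
the sample normalization) and $z$ the aggregate site-normalized
post-extraction spike-in count. Note $v$ is *not* depth-invariant ($z$ is
an absolute count); the meaningful quantity is the between-sample ratio,
and aging ratio tables always emit the RPM-only and spike-in-normalized
ratios side by side, plus a mode normalizing by the pre-extraction
reference plasmid's coverage ratio.

Spike-in QC reports, per sample, each post-extraction plasmid's
plasmid-specific (unique-region) read count relative to the
pre-extraction reference, and the CV of that ratio across samples.
Unique-region counts are used here deliberately: under the 1000-fold
dilution series, backbone reads redistributed $1/k$ from the dominant
plasmid would swamp the rare reference's own signal and mask recovery
shifts. The IGE read total of each eccDNA library is also reported — IGEs
live on linear DNA, so residual IGE reads measure incomplete digestion.

# PCR calculators

Droplet digital PCR wells are summarized by Poisson occupancy:
$\lambda = -\ln((N - N^+)/N)$ copies per droplet, concentration
$d\,\lambda/V$ with a binomial-delta 95% CI pushed through the log (the
standard open-form counterpart of vendor software's propagated Poisson
CI). Wells under 10,000 droplets are rejected; saturated wells are
flagged. TE copies per genome divide by half of the Rp49 (diploid
single-copy) concentration. The droplet volume $V$ is instrument-specific
and therefore a required input with no default. qPCR fold changes use
$2^{-\Delta\Delta C_t}$ with replicate SDs converted to SDs of the mean
($SD/\sqrt{3}$) and propagated in quadrature through both
$\Delta C_t$ terms.

# The synthetic-data generator

The generator emulates the study conditions end to end:

* **Reference bundle**: random genome (at least 100 kb per chromosome),
  TE consensus library with one pre-existing full-length genomic copy per
  family (so consensus mapping is ambiguous in the right way and
  reference-copy junctions exist to be excluded), 100 IGE genes copied
  verbatim from the genome, and the plasmid panel above sharing a 2 kb
  backbone.
* **Pooled sample**: a bag of $2N$ haplotypes; each planted insertion is
  carried by exactly `round(p * 2N)` haplotypes. Penetrance is a haplotype
  frequency — there is no diploid pairing logic, matching pooled-sample
  semantics. Truncated elements keep the consensus 3' end.
* **WGS reads**: error-free by default (errors and chimeras are opt-in so
  tests isolate algorithmic behavior from noise); fragment lengths are
  truncated-normal with lower bound read length; read-pair count is
  `depth * genomeLength / (2 * readLength)`. Chimeric molecules recur at a
  seeded panel of fusion hotspots joining a genomic locus to a TE or IGE
  sequence — recurrence (as in PCR-mediated chimeras) is what lets
  artifact junctions accumulate callable two-sided support, which is
  precisely the failure mode the IGE benchmark measures. The hotspot count
  scales with the chimera rate.
* **eccDNA library**: reads drawn from circular coordinates (positions
  wrap), read share proportional to copies x length; pre-extraction
  material (TE circles, linear background, the pre-extraction plasmid) is
  additionally scaled by an extraction-loss factor while post-extraction
  plasmids are not, making the post/pre ratio a recovery observable.

Default insertion plans keep loci 1 kb apart and 600 bp clear of
annotation; the spacing deliberately exceeds the caller's clustering
window so planted loci remain separable calls.

What the generator does *not* emulate: sequencing quality-score structure,
indels, amplification (MDA) bias, real repeat nesting and truncation
spectra, or heterochromatic satellite structure. Passing tests therefore
demonstrate algorithmic correctness under clean conditions, not
performance on real libraries; with substitution errors enabled, the
bundled exact-match mapper leaves error-bearing reads unmapped, which is
the main idealization relative to a production aligner (the alignment
stage is contract-based, so an external aligner could stand behind the
same interface).

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and in BED output; 1-based
  only in human-readable reports.
* Multi-mapping reads take one best hit; ties break by category priority
  (genome first in junction mode, consensus first in coverage mode), then
  target order, then coordinate — fully deterministic.
* Call positions are the floor of the median split-read junction
  coordinate; residual 1–2 bp scatter reflects genuine junction
  microhomology, which is why locus matching defaults to a window.
* Orientation is the majority consensus-strand vote, `"."` on ties.
* Degenerate inputs error early: empty read sets, all-zero circle plans,
  plans with loci closer than twice the read length, downsampling with
  `mappedLow > mappedDeep`, ddPCR wells under 10,000 droplets.
* Every stochastic step takes an explicit seed and is bit-reproducible;
  bootstrap seeds equal the iteration index by construction.

# Problem sizes used in the test-suite

The shipped tests run the full caller on a 1 Mb genome with 5 TE
families, 100 IGEs and 100 fully penetrant insertions at 20X (75 bp
pairs), the bootstrap on a 200 kb / 20-insertion / 20X fixture with 20
permutations, and eccDNA quantitation on 100 kb bundles with 30–40k read
pairs — sizes chosen so the whole suite exercises every stage end-to-end
in a few minutes on one CPU while keeping per-junction read support in
the same regime as a 30-million-read fly library (about 10–20 reads per
junction side).

# Known limitations

* The exact-match mapper requires a constant read length per library and
  does not model base-call errors in alignment.
* Depletion calls (loss of reference TE copies) are out of scope.
* No breakpoint assembly or target-site-duplication reconstruction;
  insertion orientation comes only from strand votes.
* eccDNA analysis quantifies the provided consensus/plasmid universe; it
  does not discover circles genome-wide, and probabilistic circle-calling
  (realignment scores) is deliberately not reimplemented — an external
  circle caller's table can be supplied to filter families.
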