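---
title: "Pile-based haplotype clustering of pooled long amplicons: models and methods"
author: "pilepool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pile-based haplotype clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilepool)
```

This vignette explains the models implemented in `pilepool`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where the design was genuinely open.

## 1. The clustering model

### Reads as variant profiles

A q30 HiFi amplicon read spans the whole amplicon and differs from the
guide sequence by (i) the true variants of its source haplotype and (ii)
on the order of one residual sequencing error. `alignToGuide()` detects
read orientation by a shared k-mer vote (k = 13, sampled k-mers), runs a
banded global alignment with affine gap penalties (band half-width 24,
widened by the read/guide length difference; match +2, mismatch −4, gap
open −12, gap extend −4), and reduces the alignment to a *variant
profile*: SNVs plus left-aligned, VCF-anchored indels, each annotated
with the guide homopolymer run length at its site. Profiles are exact —
`applyProfile(guide, profile)` reconstructs the oriented read, and the
test suite asserts this round-trip on every simulated read class.

The gap penalties are deliberately stiff. With lenient gaps, a global
alignment of an unrelated random sequence against the guide reaches ~50%
column identity by splicing in gaps; at the chosen penalties it stays
near 40%, so the off-target rule (alignment identity < 0.5 ⇒ excluded
from clustering) separates cleanly. True single-base indels are
unaffected: a length difference forces the gap regardless of its cost,
and its placement within a homopolymer is normalized afterwards by
left-alignment.

### Identity, piles, correction

Read-to-read identity is computed from profiles as
`1 − |A Δ B| / L` (symmetric difference of variant sets over guide
length), not by aligning read pairs. For reads that are each > 99%
identical to the guide the two notions coincide — variants at distinct
sites contribute identically to both — and the cost drops from
quadratic-in-length alignment per pair to a sparse matrix product over
all pairs. The one divergence (two reads carrying *different* alternates
at the *same* site count two profile differences but one alignment
mismatch column) is irrelevant at these densities; the declared
definition is the profile one.

For each focal read, the *pile* is the focal read plus its
`pileSize − 1` highest-identity neighbours, ties broken by lexicographic
read id so results are deterministic. Each focal variant is kept iff its
frequency among pile members is at least `minVarFrequency` (default
0.4). Two asymmetries are intentional:

* **Correction only masks.** A variant common in the pile but absent
  from the focal read is never introduced. Full consensus replacement
  would collapse a rare haplotype into its common neighbour whenever the
  pile is impure; masking at 0.4 keeps a haplotype-specific variant as
  long as piles are at least ~40% pure.
* **Optional homopolymer masking.** With
  `homopolymerMaskLength = n`, variants inside guide homopolymer runs
  longer than `n` bases are always masked (suggested n = 6). Off by
  default: the indel error model is part of what the pile correction is
  supposed to handle, but long homopolymers are the dominant residual
  error mode of the technology, and masking them trades a small loss of
  real variation for robustness.

Reads with identical corrected profiles form one cluster; the consensus
is the guide with the shared profile applied (members are
profile-identical by construction, so no second consensus round exists).
Cluster frequency is read count over the normalized pool read count.

### Pool-design parameters

`derivePoolParameters(nIndividuals, totalReads, pileFactor = 1.25)`
encodes the design rule: expected per-haplotype depth
`d = totalReads / (2 × nIndividuals)`; `minClusterReadCount = ⌈d/2⌉`
(half the expected depth, so a real haplotype present at the design
depth is kept even with 50% read loss to errors);
`minClusterFrequency = minClusterReadCount / totalReads`; and
`pileSize = round(d × pileFactor)` — about a quarter larger than the
expected haplotype read count, large enough to collect the haplotype's
reads, small enough that piles stay mostly within-haplotype. For
(200 individuals, 16,000 reads) this gives (40, 20, 0.00125, 50); for
(150, 5,300) it gives (17.7, 9, 0.0017, 22). `pileFactor` stays
configurable because the depth-to-pile rounding is a judgment call (a
published run at the second design used pile 25 where the 1.25× rule
gives 22); the package default reproduces the rule, not the rounding.

Memory for the all-pairs identity matrix is quadratic in pool reads
(16,000 reads ≈ 2 GB); the intended working range is the normalized
pool sizes above.

## 2. TSR annotation

The gene model maps field-convention codon numbers (1781–2096 of the
ACCase reference protein) to 3-base amplicon intervals. The mapping is
explicit metadata rather than a literal CDS index so that reduced test
geometries can carry canonically numbered codons; in the full-size
default geometry the mapping *is* literal. SNVs inside a TSR codon are
translated strand-aware; an amino-acid change yields an allele name
`{wtAA}{codon}.{codonPos}{newAA}_{altBase}` (alternate base in CDS
orientation), e.g. `Ile1781.1Leu_T`. The name is fully parseable back
into its fields, and the suite round-trips every non-synonymous
single-base change at all seven sites. Synonymous codon changes are
reported separately and never counted as TSR; frameshift indels in the
CDS are flagged disruptive rather than named. Cross-resistance spectra
are a lookup of the published table (Ile1781Leu, Asp2078Gly → FOPs,
DIMs, DENs; Trp2027Cys, Ile2041Asn → FOPs, DENs; any Gly2096
substitution → FOPs); anything else is an empty set flagged
uncharacterized.

`nearestWildtypePairs()` reports, per TSR cluster, the wild-type cluster
at minimal profile distance. Distance 1 — one mutation across the whole
amplicon — marks the wild-type haplotype as the plausible immediate
progenitor, and the report notes whether the wild type outnumbers its
TSR derivative, the pattern expected when resistance arose in the field
from standing variation rather than arriving by gene flow.

## 3. Frequencies and the recovery benchmark

`pooledAlleleFrequencies()` counts, per `(site, alt)`, the fraction of
on-target reads whose profile carries the variant. Reads count equally
and span the full amplicon, so depth equals read count at every site; no
depth weighting is applied. Sites below `minAltFraction` (default 0.005,
the pooled-continuous calling convention) are suppressed, and rows are
biallelic by construction. Because cluster frequencies share the same
denominator, on error-free data the summed frequency of carrier clusters
equals the pooled allele frequency *exactly*; with default error rates
they agree to ~0.01. Pearson correlations (`correlateFrequencies()`) use
the t-distribution on n − 2 df for the two-sided p-value and report
zero-variance input as undefined rather than erroring.

`benchmarkRecovery()` compares unique haplotypes among individually
genotyped plants with pool clusters. A correct pair is an *exact*
sequence match: with same-guide, full-length synthetic amplicons, exact
identity is equivalent to the multiple-alignment uniqueness used on real
data, and terminal-gap tolerance cannot be distinguished here (all
sequences share coordinates). `recoveryByCarrierCount()` stratifies
recovery by 1, 2–3 and ≥ 4 carrier individuals, the strata in which
pool recovery saturates.

## 4. The synthetic-data generator

The generator defines the study conditions; it is not tuned per test.

* **Reference.** `geneModelConfig("default")` builds a 13,249 bp
  amplicon: 585 bp upstream flank, a 12.3 kb gene of 32 exons / 31
  introns whose penultimate exon hosts all seven TSR codons, 364 bp
  downstream. The CDS translates without internal stops and the TSR
  codons carry the canonical wild-type residues, with codon usage chosen
  so the published substitutions are single-base changes. The `"mini"`
  profile (2 kb, 4 exons, one TSR codon) exists for fast runs; every
  algorithmic property exercised on it transfers, since nothing in the
  pipeline depends on amplicon length beyond run time.
* **Haplotypes.** Wild-type haplotypes carry Poisson-distributed
  (mean 8) random SNVs outside the TSR codons — the magnitude of
  haplotype differentiation seen across a gene-scale amplicon in an
  outcrossing grass. TSR haplotypes are their parent plus exactly the
  specified codon change, so parent/child pairs differ by one mutation,
  the hardest case for cluster resolution. Per-pool haplotype counts and
  frequencies are caller-supplied configuration, not asserted defaults:
  field distributions vary too much to hard-code one as realistic.
* **Reads.** Full-length (amplicon sequencing yields full-length reads
  by construction), drawn per read from the pool's haplotype
  frequencies, with substitutions at 5e-4 per base and single-base
  indels at 3e-4 per homopolymer run of ≥ 4 bases — the ~q30 regime in
  which residual errors concentrate in homopolymer contexts. Per-base
  Phred qualities are drawn from a mixture (30/33/37/40) whose implied
  predicted accuracy (~0.9996) sits above the q30 filter, matching
  post-filter inputs. A configurable fraction (default 0.5) of reads is
  reverse-complemented. The true source haplotype and orientation are
  recorded in read headers for test oracles; the pipeline never parses
  them.
* **Not emulated:** polymerase chimeras, barcode hopping, ZMW/subread
  artifacts, coverage bias along the amplicon, and contamination.
  Passing tests therefore demonstrate the algorithm's behaviour under
  its own error model, not robustness to PCR artifacts; on real data
  those failure modes surface as extra low-frequency clusters, which is
  what the cluster-level filters exist to absorb.

Determinism: every generator entry point takes an integer seed, and
identical seeds give byte-identical FASTA/FASTQ output.

## 5. The persistence model

The question is how long a TSR allele persists in a field once
herbicide selection stops, given a fitness cost. `pilepool` implements
the single-locus diploid Wright–Fisher model directly: genotype
fitnesses `w_AA = 1 + s`, `w_Aa = 1 + h·s`, `w_aa = 1`; the
deterministic selection update
`p* = p(p·w_AA + q·w_Aa) / w̄` followed by binomial sampling of 2N
allele copies. For the marginal allele-count process of one pre-existing
biallelic locus this *is* the model a per-individual forward simulator
integrates over: mutation (3.0e-8) and recombination (7.4e-9) rates are
recorded in `WFParams` for provenance but have no measurable effect on
the loss time of an existing allele at one locus, and are not simulated.

Conventions, chosen once: the initial state is generation 0 and loss is
recorded at the first generation the count hits 0; replicate *i* uses
seed `seed + i − 1` (logged, reproducible independently of outer RNG
state); runs are censored at 100,000 generations (only reachable at
s = 0) and censored/fixed replicates are excluded from the mean but
reported, so either inclusion convention is computable from the output.
The 0.95 confidence interval is t-based on replicate loss times —
deterministic, unlike a bootstrap, and indistinguishable from it at 400
replicates.

Defaults follow the field setting: N = 42,000 diploids, 400 replicates,
grid s ∈ {0, −0.1, −0.2, −0.3, −0.4} × h ∈ {0.5, 0.25} × p0 ∈ {0.05,
0.1, 0.4, 0.7}. Two independent oracles check the stochastic engine:
the infinite-population recursion (`deterministicRecursion()`, iterated
until p < 1/(2N)) agrees with stochastic means within 15% for s ≤ −0.2,
and at s = 0 the process is a martingale with fixation probability p0.

## 6. Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; 1-based in VCF export.
* Indels are left-aligned against the guide before any comparison, so
  equivalent indels in a homopolymer always produce the same profile key.
* Ties (pile membership, nearest wild-type cluster) break by
  lexicographic id; cluster ids are assigned by decreasing size then
  profile signature — outputs are invariant to input read order.
* Degenerate inputs: empty read sets filter to empty with a zero-count
  report; pools smaller than the normalization target are excluded (and
  reported), not truncated; a pool with no on-target reads is an error;
  zero-variance vectors make the correlation undefined, not an error;
  `p0 = 0` is loss at generation 0, `p0 = 1` fixation at generation 0.
* `estimateTemplateCopies()` is the standard dsDNA molarity arithmetic
  (6.022e23 / (bp × 1e9 × 650 g/mol)); 50 ng of a 3.56 Gbp genome is
  13,012 template copies, i.e. 32.5 / 43.4 copies per haploid genome for
  pools of 400 / 300 haploid genomes.

## 7. Problem sizes in the shipped tests

The suite exercises the mini geometry with pools of 60–2,000 reads
(the largest being the 200-diploid, 2,000-read recovery benchmark, depth
5, pile 6) and the persistence engine at N = 42,000 with 400 replicates
for the headline scenarios, with toy N (50–500) for the martingale,
coverage and monotonicity properties. These sizes were chosen so the
whole suite documents the method's behaviour in minutes while preserving
every ratio the design rules depend on (reads per haplotype, pile to
depth, threshold to depth); none of the algorithms branch on problem
size.

## 8. Known limitations

* The identity matrix is dense in the number of reads; pools far beyond
  the normalized designs (≳ 20k reads) need blocking that the package
  does not implement.
* Clustering is reference-aided: structural variants that break the
  banded alignment against the guide are excluded as off-target rather
  than assembled.
* Copy-number resistance mechanisms (gene amplification) are invisible
  to any single-locus pool assay, including this one.
* The recovery benchmark treats haplotypes as recovered only on exact
  sequence identity; a consensus wrong in a single base counts as a
  miss.
* The Wright–Fisher model has no seed bank, spatial structure, or
  selfing; all would lengthen persistence, so its estimates are best
  read as lower bounds.
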