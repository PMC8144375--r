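---
title: "Detecting and phasing minor SNVs from noisy long reads"
author: "minorhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and phasing minor SNVs from noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minorhap)
```

## The problem

A pooled or mixed sample — strains in a microbiome, subclones in a culture,
variants in a viral swarm — is sequenced with long reads and aligned to a
single reference. Some genomes in the pool differ from the reference by a
handful of single-nucleotide substitutions and make up only a few percent of
the DNA. The per-base substitution error rate of raw long reads (several
percent to above ten percent) is far larger than the frequency of these
variants, so a locus-by-locus caller cannot separate a 2% variant from a 3%
error process. `minorhap` detects such minor SNVs and phases them into
haplotype contigs with read support.

## Read encoding

Reads are reduced to their differences from the reference. With 0-based
loci, a read base `r != t_k` at locus `k` becomes the integer code
`4k + d`, where `d` is 0/1/2/3 for alternative base A/C/G/T; a matching
base contributes nothing. A read is then a pair `(S, [b, e])`: its code set
and its covering interval. Bases below a quality threshold and deleted
bases stay inside `[b, e]` (they count toward coverage) but contribute
neither a code nor a reference match; this is the package's reading of an
ambiguity in the pileup denominator, and `pileupTable(maskedInDepth =
FALSE)` flips it.

The marginal substitution rate of a code is its carrier count over the
reads covering its locus. For five substitutions with marginal rates below
1% each, observing them *jointly* on 28 of 23,432 covering reads
(`workedExampleFixture()`) is more than one hundred times the
`0.1^5 = 1e-5` expected under independent errors — co-occurrence, not
marginal frequency, is the detectable signal.

## Detection: maximal conditional substitution rate

The detection statistic for a substitution `x_k` is the maximum, over
conditioning sets of other substitutions, of the estimated conditional
probability that a read carries `x_k` given that it carries the set and
covers `k`. For a real SNV conditioned on other SNVs of the same genome,
this approaches the per-read allele recall (about `1 - error rate`); for
an error it stays near the error rate. A substitution is called when the
estimate exceeds `hThreshold = 0.65`.

Three guards control the estimate's variance and bias:

* `vMin = 25`: every accepted conditioning step must keep at least 25
  reads in the denominator. Because denominators only shrink as codes are
  added, a candidate whose single-code denominator is below `vMin` can
  never qualify and is dropped before ranking.
* `hdMin = 15`: conditioning loci must be at least 15 homopolymer runs
  away from the target locus ("homopolymer distance"), because errors at
  nearby loci are not independent. Two loci in the same or adjacent runs
  have distance 0.
* the greedy search ranks candidates by their single-code conditional rate
  (ties: larger denominator, then lower locus, then lower code — fixed for
  reproducibility) and accepts them while the rate strictly increases.

A naive greedy search over the whole window of `t_l + t_r` loci covered
together with `k` almost surely picks a noise locus first: its success
probability is bounded by `rho0^(t_l + t_r - p)`
(`greedySuccessUpperBound()`), which at `rho0 = 0.99`, `t_l = t_r = 2000`,
`p = 1` is about `3.5e-18`. The package therefore restricts the search to
*subspaces*: for each read, the code sets shared with its `w = 100`
most-similar reads (modified Jaccard index, below). A subspace built from
two reads of the same genome contains that genome's SNVs and only a few
coincident errors, so the greedy search inside it faces a handful of
candidates instead of thousands. The final estimate is the maximum over
subspaces; `bruteForceMaxConditional()` is an exhaustive oracle used only
in tests.

Read similarity is a modified Jaccard index: shared codes over all codes of
either read inside the overlapped interval, zero when the overlap is
shorter than `lMinFraction = 0.5` of the first read's length.

### Orphan SNVs and the context error model

A genome distinguished by a single SNV offers nothing to condition on. For
this case the package models the sequencing error rate of each (locus,
alternative) pair from its homopolymer context — the flanking run bases
and lengths plus the current and substituting base, one-hot encoded with
run lengths capped at 20 — with gradient boosting (xgboost; presets
`eta = 0.01, 2000 trees, depth 10` for PacBio and `0.1, 2000, 10` for
ONT). A candidate is called when the binomial likelihood ratio of the
observed carrier count against the predicted error rate exceeds 50 *and*
its marginal rate exceeds 0.1 (PacBio) or 0.2 (ONT). Model accuracy is
reported as the standard cross-validated `R^2 = 1 - SS_res/SS_tot`.
Predictions are clipped to `[1e-6, 0.5]` so likelihood ratios stay
defined. The final detection output is the union of the subspace calls and
these context-corrected single-locus calls, deduplicated by code; the
uncorrected single-locus mode (`mode = "sl"`) exists only for
benchmarking.

For ONT data, loci within five bases of known bacterial methylation motif
occurrences (defaults CCWGG and CGCATC, both strands) are masked before
detection, because methylation-induced miscalls are correlated across
reads and mimic linked variants.

## Phasing

**Local realignment.** Alignment against the reference depresses the
observed rate of true alternatives (reference bias). Each read segment
over a window of 21 homopolymer runs centred on a detected locus is
re-aligned (Smith-Waterman, match 2, mismatch -4, gap open -4, gap extend
-2, N/masked columns 0; a gap of length L costs `-4 - 2(L-1)`) against
four references carrying A/C/G/T at the locus. The best-scoring base
becomes the read's call there; ties involving the reference base
conservatively yield no call, other ties resolve alphabetically.
Realignment windows are never extended past the genome ends, so loci in
terminal runs lose flanking evidence — an edge limitation the simulator's
default placement avoids (below).

**Adaptive-nearest-neighbour clustering.** Reads are restricted to
detected codes. Each read seeds a cluster of its `q = 100` most-similar
reads; the most dissimilar member is discarded (ties by read order) until
every detected locus inside the seed's interval is *homogeneous* — every
alternative's rate among informative cluster reads lies in
`[0, pLim]` or `[1 - pLim, 1]` (`pLim` 0.2 PacBio / 0.3 ONT) — or the
best-covered locus drops below `minCov = 10`, which aborts the seed. The
consensus (alternatives at rate `>= 1 - pLim`) becomes a draft contig;
identical drafts are deduplicated. `q` is a package choice (the
neighbourhood size is not prescribed by the method), set parallel to `w`
and exposed as a parameter. Contigs with no SNV are not emitted: the
reference is not a contig.

**Bayes-factor screening.** The method prescribes a two-step Bayes-factor
filter but not its distributional forms; the package's choices are:

* *SNV frequency* (`bfSnvFrequency`): beta-binomial marginal likelihood
  with a uniform prior restricted to `(p0, 1]` against the point null
  `Binomial(t; n, p0)`, with `p0` the context-predicted error rate (or a
  data-driven genome-wide floor, `estimateErrorRate()`, when no model is
  supplied). The frequency of an SNV *in a contig* is its carrier count
  among the contig's supporting reads over the locus coverage — a contig
  that merely collects the expected errors at a locus is not significant.
* *SNV dependence* (`bfSnvDependence`): the same form with the product of
  dataset-wide marginal rates as the null, applied to the joint carrier
  count; single-SNV contigs count as independent (no co-occurrence
  evidence).
* Step 1 removes a contig only when some SNV frequency is non-significant
  *and* its SNVs test independent; step 2 compares surviving overlapping
  pairs (`bfContigPairDifference`) and removes the redundant member of
  pairs that are not significantly different.

The pairwise test distinguishes three regimes. Identical consensus sets
give BF = 1. For nested sets the deciding counts are deliberately taken
from the *unselected* read population, because clustering discards exactly
the reads that would reveal an artifact: a subset contig must have more
exclusive carriers (all its codes, none of the superset's extras) than
expected from coincident errors plus full allele dropout, and a superset
contig's extra codes must ride above the error rate among carriers of the
shared codes; the weaker claim is the one removed. Genuinely conflicting
sets are contrasted per differing code with a two-binomial marginal
(independent uniform rates versus one common rate), and the
lower-abundance contig is removed when the combined factor is weak. All
factors use the Jeffreys-style threshold `bfThreshold = 10`.

**Assembly.** Draft contigs become vertices of an overlap graph with an
edge `i -> j` when they agree in their overlap, share more than half of
either side's SNVs or half of either side's length, and `end(i) <
end(j)` — the strict ordering makes the graph acyclic by construction.
After transitive reduction (reachability preserved; verified against a
closure oracle in the tests), contigs are concatenated along unambiguous
paths. A path starts at a vertex with in-degree different from 1 *or*
whose unique parent branches — the second clause is the package's
resolution of the path criteria for fork children, so every vertex lands
in exactly one path — and extends through in/out-degree-1 vertices,
stopping before any vertex with several parents. Assembled contigs are
re-screened with the two-step filter, contained near-duplicates (Jaccard
> 0.9) are removed, highly similar overlapping contigs (overlap Jaccard >
0.9) are connected (conflicts resolved toward the higher-abundance
contig), and finally every read is assigned to its best-Jaccard contig
(reference if below 0.5), which defines contig abundance. Divergence
between overlapping contigs — differing SNVs per overlapped base
(`contigDivergence`) — expresses the resolution at which two strains can
be told apart.

## The simulator

`simConfig()` fixes the study conditions: a uniform-random reference
(default 500 bp), `K` haplotypes defined by substitution codes at loci
with pairwise homopolymer distance at least 15 (so detection's
conditioning constraint is satisfiable by construction), relative
abundances 5/3/2% over a reference background, full-length reads at 2000x
depth, and independent per-base substitution errors at rate 0.1 replacing
the base with one of the other three uniformly. These defaults are the
desk-scale analogue of a pooled-strain experiment on raw long reads: minor
lineages at percent-level abundance under an error rate two to five times
larger. Options add context-dependent error rates (a function of flanking
run lengths, used to validate the context model), partial-length reads,
and correlated-error loci that imitate methylation artefacts. SNV loci are
also kept out of the first and last 10 homopolymer runs (`edgeRuns`) so
realignment windows are never clipped — terminal-run variants are a known
blind spot of windowed realignment, not something the simulator should
plant by default.

What the simulator does *not* emulate: indels and homopolymer-length
errors (the dominant long-read error mode; the method only calls
substitutions), chimeric reads, abundance skew along the genome, and
alignment artefacts other than the reference-bias scenario constructed
explicitly in the realignment tests. Passing tests therefore demonstrate
the statistical machinery under the stated error model, not performance on
real instrument data.

Every stochastic operation takes a seed; reads are generated directly in
encoded form, with FASTA/SAM writers (`writeSimFasta`, `writeSimSam`) for
end-to-end tests through the alignment reader.

## Numerical and degenerate-input choices

* Rates with zero denominators are errors or `NA` sentinels, never 0/0;
  subspace candidates with undefined denominators are excluded from
  ranking.
* Likelihood ratios and Bayes factors are computed in log space.
* All tie-breaks (candidate ranking, discard order, read assignment,
  realignment calls) are fixed and documented above, so identical inputs
  give byte-identical outputs.
* Empty inputs (no reads, no calls, empty contig sets) propagate as empty
  results rather than errors, except where a quantity is genuinely
  undefined (TPR with empty truth, divergence without overlap).

## Problem sizes in the test suite

The tests run the full pipeline at the default study conditions (500 bp,
2000x, three haplotypes at 5/3/2%, 10% errors) and exercise individual
operations on smaller instances (80-400 bp, depths 100-800) where
exhaustive oracles are feasible; these sizes are the package's choice of
desk-scale instances on which the brute-force comparisons and seeded
property checks remain exact.

## Known limitations

* Only substitutions are modelled; indels are neither called nor used as
  phasing signal.
* Variants rarer than `vMin / depth` cannot clear the denominator floor;
  at 2000x the practical floor is around 1-2% (deeper data lowers it).
* A genuine sub-haplotype whose exclusive read support is comparable to
  the error-coincidence expectation is indistinguishable from an artifact
  and will be merged by the pairwise screen.
* Contigs cannot extend across regions with no detected SNV; such regions
  disconnect the overlap graph.
* Loci in terminal homopolymer runs lose realignment evidence at the
  genome boundary.
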