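# minorhap

Detection and phasing of minor single-nucleotide variants (SNVs) from
noisy long-read alignments.

## The problem

A mixed sample — bacterial strains in a pool or microbiome, subclones of a
culture, a viral swarm — is sequenced with long reads and aligned to one
reference. Lineages present at only a few percent differ from the
reference by a handful of substitutions, while the raw long reads
themselves mis-call several percent of bases. A per-locus caller cannot
tell a 2% variant from a 3% error process. `minorhap` is for anyone who
needs to find such minor SNVs and reconstruct which of them travel
together on the same genome.

## The method

Each read is encoded as the set of its substitution codes `4k + d`
(alternative base `d` ∈ {A, C, G, T} at 0-based locus `k`) plus its
covering interval. Detection uses the **maximal conditional substitution
rate**

&nbsp;&nbsp;&nbsp;&nbsp;H(x_k) = max over {x_g1, …, x_gp} of
P̂r(X_k = x_k | X_g1 = x_g1, …, X_gp = x_gp),

estimated by a greedy search restricted to *subspaces* C_ij = S_i ∩ S_j
formed from each read and its `w = 100` most-similar reads (modified
Jaccard index) — random subspace maximization. For a real SNV conditioned
on its co-travelling SNVs, H approaches the per-read allele recall; for
independent errors it stays near the error rate. Calls require
H > 0.65 with conditioning denominators ≥ 25 and conditioning loci at
least 15 homopolymer runs from the target. Orphan SNVs (nothing to
condition on) are recovered by a binomial likelihood-ratio test
(threshold 50) against a homopolymer-context gradient-boosting error
model. Phasing then realigns reads locally against base-modified
references, clusters them with adaptive nearest neighbours under a
per-locus homogeneity rule, screens draft contigs with Bayes factors, and
assembles them along unambiguous paths of a transitively reduced overlap
graph. The methods vignette
(`vignettes/minor-snv-detection-and-phasing.Rmd`) describes every stage,
parameter and design choice.

## Worked example

Simulate the default study conditions — three haplotypes at 5/3/2%
abundance with five SNVs each on a 500 bp reference, 2000x coverage, 10%
substitution errors — then detect and phase:

```r
library(minorhap)

cfg <- simConfig(seed = 1)
hp  <- simulateHaplotypes(cfg)
sim <- simulateReads(hp$ref, hp$haplotypes, cfg)

calls <- runDetect(sim$reads, hp$ref, platform = "pacbio")
head(calls[, c("pos", "refBase", "altBase", "rate", "hHat", "nDen", "method")])
#>   pos refBase altBase   rate  hHat nDen method
#> 1  36       A       C 0.0645 0.841   44    RSM
#> 2  66       C       T 0.0695 0.872   78    RSM
#> 3 111       G       T 0.0745 0.872   78    RSM
#> 4 147       C       G 0.0555 0.853   34    RSM
#> 5 179       C       T 0.0850 0.932   73    RSM
#> 6 213       G       A 0.0570 0.917   36    RSM
```

Every call sits at a marginal rate of 5-8% — indistinguishable from the
10% error process by rate alone — but its conditional rate `hHat` is
0.84-0.93, close to the per-read allele recall of a real variant.
Against the planted truth:

```r
unlist(evaluateCalls(calls, unlist(hp$haplotypes)))
#>      tpr      fdr   nCalls   nTruth nCorrect
#>        1        0       15       15       15

ph <- runPhase(sim$reads, hp$ref, calls, platform = "pacbio")
ph$contigs
#> ContigSet with 3 contigs
#>   [1] 0-499  5 SNVs  abundance 99
#>   [2] 0-499  5 SNVs  abundance 69
#>   [3] 0-499  5 SNVs  abundance 51

evaluateContigs(ph$contigs, hp$haplotypes)
#>   contig bestHaplotype jaccard
#> 1      1             1       1
#> 2      2             2       1
#> 3      3             3       1
```

All fifteen planted SNVs are detected with no false positives, and the
three contigs recover the three haplotypes exactly; the abundances
99/69/51 of 2000 reads match the planted 5/3/2% mixture.

A thin command-line wrapper (`inst/scripts/minorhap`) exposes
`simulate`, `detect` and `phase` over FASTA/SAM files.

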