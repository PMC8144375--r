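test_that("locus homogeneity follows the two-sided rate rule", {
  # 10 informative reads at locus 10: vary the alternative count
  mkPhasing <- function(nAlt, nRef = 10L - nAlt) {
    reads <- tinyReads(c(rep(list(41L), nAlt),
                         rep(list(integer()), nRef)))
    buildPhasingData(reads, 41L)
  }
  h1 <- locusHomogeneity(mkPhasing(1L), 1:10, 10L, pLim = 0.2)
  expect_equal(unname(h1$rates["C"]), 0.1)
  expect_true(h1$homogeneous)
  h3 <- locusHomogeneity(mkPhasing(3L), 1:10, 10L, pLim = 0.2)
  expect_false(h3$homogeneous)
  h9 <- locusHomogeneity(mkPhasing(9L), 1:10, 10L, pLim = 0.2)
  expect_equal(unname(h9$rates["C"]), 0.9)
  expect_true(h9$homogeneous)  # 0.9 >= 1 - pLim
  expect_error(locusHomogeneity(mkPhasing(1L), 1:10, 11L), "not a detected")
})

test_that("read restriction keeps only detected SNVs", {
  reads <- tinyReads(list(c(8L, 41L, 100L), c(8L, 55L)))
  r <- restrictReads(reads, c(8L, 100L))
  expect_identical(readSubs(r), list(c(8L, 100L), 8L))
  expect_identical(readStarts(r), readStarts(reads))
})

test_that("clustering a clean single haplotype returns its SNV set", {
  hap <- c(41L, 201L, 362L)
  reads <- tinyReads(rep(list(hap), 50L))
  phasing <- buildPhasingData(reads, hap)
  d <- annCluster(phasing, 7L, phasingParams())
  expect_identical(d$snvs, hap)
  expect_identical(d$start, 0L)
})

test_that("a seed from one haplotype discards the other until homogeneous", {
  hapA <- c(41L, 201L); hapB <- c(86L, 250L)
  reads <- tinyReads(c(rep(list(hapA), 25L), rep(list(hapB), 25L)))
  phasing <- buildPhasingData(reads, c(hapA, hapB))
  d <- annCluster(phasing, 1L, phasingParams())
  expect_identical(d$snvs, hapA)
  # discarding stops at homogeneity, so the cluster is dominated by (but
  # need not consist solely of) the seed's haplotype
  expect_gt(mean(d$support <= 25L), 0.7)
})

test_that("too few reads for the coverage floor yields no contig", {
  hap <- c(41L, 201L)
  reads <- tinyReads(c(rep(list(hap), 5L), rep(list(86L), 5L)))
  phasing <- buildPhasingData(reads, c(hap, 86L))
  expect_null(annCluster(phasing, 1L, phasingParams(minCov = 10L)))
})

test_that("draft contigs satisfy the homogeneity criterion at all covered
           loci", {
  s <- smallSim(seed = 19, refLength = 300L, nSnvs = c(5L, 5L),
                abundance = c(0.15, 0.08), depth = 400L, errorRate = 0.1)
  codes <- sort(unlist(s$haplotypes))
  real <- realignReads(s$reads, s$ref, codes %/% 4L)
  params <- phasingParams("pacbio")
  drafts <- annPhase(real, codes, params)
  expect_gt(length(drafts), 0L)
  phasing <- buildPhasingData(real, codes)
  for (ci in seq_along(drafts)) {
    sup <- contigSupport(drafts)[[ci]]
    loci <- phasing$loci[phasing$loci >= contigStarts(drafts)[ci] &
                           phasing$loci <= contigEnds(drafts)[ci]]
    for (k in loci) {
      h <- locusHomogeneity(phasing, sup, k, params$pLim)
      expect_true(h$homogeneous)
    }
  }
})

test_that("identical draft contigs are deduplicated on clean input", {
  hap <- c(41L, 201L)
  reads <- tinyReads(c(rep(list(hap), 30L), rep(list(integer()), 30L)))
  drafts <- annPhase(reads, hap, phasingParams())
  keys <- vapply(seq_along(drafts), function(i)
    paste(contigStarts(drafts)[i], paste(contigSnvs(drafts)[[i]],
                                         collapse = ","), sep = ":"),
    character(1))
  expect_identical(anyDuplicated(keys), 0L)
  expect_identical(contigSnvs(drafts)[[1]], hap)
})

test_that("reads go to the highest-Jaccard contig or the reference", {
  contigs <- contigSet(start = c(0L, 0L), end = c(99L, 99L),
                       snvs = list(c(41L, 201L), c(86L, 250L)),
                       support = list(1:10, 11:20))
  reads <- tinyReads(list(c(41L, 201L),   # matches contig 1 exactly
                          integer(),      # empty: reference
                          c(86L, 250L),   # matches contig 2
                          c(41L, 86L)))   # 1 of 3 with both: below 0.5
  asg <- assignReads(reads, contigs)
  expect_identical(asg$assignment, c(1L, 0L, 2L, 0L))
  expect_identical(contigAbundance(asg$contigs), c(1L, 1L))
  # tie between identical contigs resolves to the lower index
  dup <- contigSet(start = c(0L, 0L), end = c(99L, 99L),
                   snvs = list(c(41L), c(41L)))
  asg2 <- assignReads(tinyReads(list(41L)), dup)
  expect_identical(asg2$assignment, 1L)
})
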