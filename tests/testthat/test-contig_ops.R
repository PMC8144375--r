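test_that("SNV-frequency Bayes factor favours the null at the error rate", {
  expect_lt(bfSnvFrequency(0, 100, 0.05), 1)
  # monotone in the carrier count
  bf <- vapply(seq(0, 60, by = 5), function(t)
    bfSnvFrequency(t, 500, 0.01, log = TRUE), numeric(1))
  expect_true(all(diff(bf) > 0))
  expect_gt(bfSnvFrequency(250, 500, 0.01, log = TRUE), log(1e6))
  expect_error(bfSnvFrequency(1, 0, 0.1), "undefined")
})

test_that("identical contigs leave a single survivor", {
  reads <- tinyReads(c(rep(list(c(41L, 201L)), 30L),
                       rep(list(integer()), 70L)))
  contigs <- contigSet(start = c(0L, 0L), end = c(99L, 99L),
                       snvs = list(c(41L, 201L), c(41L, 201L)),
                       support = list(1:30, 1:20))
  bf <- bfContigPairDifference(contigs, 1L, 2L, reads, p0 = 0.01)
  expect_equal(as.numeric(bf), 1)
  out <- filterDraftContigs(contigs, reads, p0 = 0.01)
  expect_identical(length(out), 1L)
  expect_identical(contigAbundance(out), 30L)
})

test_that("contigs with well-supported differences are both retained", {
  hapA <- c(41L, 201L, 362L); hapB <- c(86L, 250L, 310L)
  reads <- tinyReads(c(rep(list(hapA), 30L), rep(list(hapB), 25L),
                       rep(list(integer()), 145L)))
  contigs <- contigSet(start = c(0L, 0L), end = c(99L, 99L),
                       snvs = list(hapA, hapB),
                       support = list(1:30, 31:55))
  out <- filterDraftContigs(contigs, reads, p0 = 0.01)
  expect_identical(length(out), 2L)
})

test_that("a contig assembled from independent errors is removed", {
  set.seed(23)
  # two codes occurring independently at ~5% each; a cluster of their rare
  # coincidence carriers is not a haplotype
  m <- 400L
  subs <- lapply(seq_len(m), function(i) {
    s <- integer()
    if (runif(1) < 0.05) s <- c(s, 41L)
    if (runif(1) < 0.05) s <- c(s, 201L)
    s
  })
  reads <- tinyReads(subs)
  sup <- which(vapply(subs, function(s) all(c(41L, 201L) %in% s),
                      logical(1)))
  contigs <- contigSet(start = 0L, end = 99L, snvs = list(c(41L, 201L)),
                       support = list(sup))
  out <- filterDraftContigs(contigs, reads, p0 = 0.05)
  expect_identical(length(out), 0L)
})

test_that("a spurious extra SNV riding at the error rate is filtered", {
  set.seed(24)
  hap <- c(41L, 201L, 362L)
  m <- 300L
  subs <- lapply(seq_len(m), function(i) {
    s <- if (i <= 100) hap else integer()
    if (runif(1) < 0.03) s <- sort(c(s, 130L))  # error code on top
    s
  })
  reads <- tinyReads(subs)
  supA <- 1:100
  supB <- which(vapply(subs, function(s) all(c(hap, 130L) %in% s),
                       logical(1)))
  contigs <- contigSet(start = c(0L, 0L), end = c(99L, 99L),
                       snvs = list(hap, sort(c(hap, 130L))),
                       support = list(supA, supB))
  out <- filterDraftContigs(contigs, reads, p0 = 0.03)
  expect_identical(length(out), 1L)
  expect_identical(contigSnvs(out)[[1]], hap)
})

test_that("overlap-graph edges require identity, sharing and ordered ends", {
  # two overlapping contigs from one haplotype: single edge 1 -> 2
  contigs <- contigSet(start = c(0L, 40L), end = c(99L, 139L),
                       snvs = list(c(41L, 241L), c(241L, 521L)),
                       support = list(1:20, 21:40))
  g <- buildOverlapGraph(contigs)
  expect_identical(unname(graphEdges(g)), matrix(c(1L, 2L), nrow = 1))
  # conflicting SNV in the overlap: no edge
  bad <- contigSet(start = c(0L, 40L), end = c(99L, 139L),
                   snvs = list(c(41L, 241L), c(242L, 521L)),
                   support = list(1:20, 21:40))
  expect_identical(nrow(graphEdges(buildOverlapGraph(bad))), 0L)
  # equal end coordinates: criterion 3 is strict
  eq <- contigSet(start = c(0L, 50L), end = c(99L, 99L),
                  snvs = list(c(241L), c(241L)),
                  support = list(1:20, 21:40))
  expect_identical(nrow(graphEdges(buildOverlapGraph(eq))), 0L)
})

test_that("transitive reduction removes shortcuts and preserves
           reachability", {
  contigs <- contigSet(start = c(0L, 40L, 80L), end = c(99L, 139L, 179L),
                       snvs = list(c(201L), c(201L, 441L), c(441L)),
                       support = list(1:10, 11:20, 21:30))
  g <- new("OverlapGraph", contigs = contigs,
           edges = cbind(from = c(1L, 2L, 1L), to = c(2L, 3L, 3L)))
  r <- transitiveReduce(g)
  expect_identical(unname(graphEdges(r)),
                   matrix(c(1L, 2L, 2L, 3L), nrow = 2, byrow = TRUE))
  # closure oracle: boolean matrix powers give identical reachability
  closure <- function(edges, n) {
    A <- matrix(FALSE, n, n)
    A[edges] <- TRUE
    R <- A
    for (i in seq_len(n)) R <- R | (R %*% A > 0)
    R
  }
  set.seed(25)
  for (rep in 1:10) {
    n <- 8L
    starts <- sort(sample(0:200, n))
    contigsR <- contigSet(start = starts, end = starts + 80L,
                          snvs = rep(list(integer()), n),
                          support = rep(list(1L), n))
    # random consistent SNV layout: one shared backbone code per overlap
    gR <- buildOverlapGraph(contigsR)
    rR <- transitiveReduce(gR)
    expect_identical(closure(graphEdges(gR), n), closure(graphEdges(rR), n))
    expect_lte(nrow(graphEdges(rR)), nrow(graphEdges(gR)))
  }
})

test_that("unambiguous paths concatenate chains and split at forks", {
  chain <- contigSet(start = c(0L, 40L, 80L), end = c(99L, 139L, 179L),
                     snvs = list(c(201L), c(201L, 441L), c(441L)),
                     support = list(1:10, 11:20, 21:30))
  out <- assemblePaths(transitiveReduce(buildOverlapGraph(chain)))
  expect_identical(length(out), 1L)
  expect_identical(contigStarts(out), 0L)
  expect_identical(contigEnds(out), 179L)
  expect_identical(contigSnvs(out)[[1]], c(201L, 441L))
  # fork a -> {b, c}: a alone, then b and c as separate paths
  fork <- new("OverlapGraph",
              contigs = contigSet(start = c(0L, 50L, 50L),
                                  end = c(99L, 149L, 149L),
                                  snvs = list(c(241L), c(241L, 425L),
                                              c(241L, 426L)),
                                  support = list(1:10, 11:20, 21:30)),
              edges = cbind(from = c(1L, 1L), to = c(2L, 3L)))
  outF <- assemblePaths(fork)
  expect_identical(length(outF), 3L)
  # isolated vertex assembles to itself
  iso <- buildOverlapGraph(contigSet(start = 0L, end = 99L,
                                     snvs = list(41L),
                                     support = list(1:5)))
  outI <- assemblePaths(iso)
  expect_identical(length(outI), 1L)
  expect_identical(contigSnvs(outI)[[1]], 41L)
})

test_that("redundant contigs are removed or connected at Jaccard 0.9", {
  # fully contained duplicate haplotype: removed
  contigs <- contigSet(start = c(10L, 0L), end = c(89L, 149L),
                       snvs = list(c(201L, 301L), c(201L, 301L, 521L)),
                       abundance = c(5L, 20L),
                       support = list(1:5, 6:25))
  out <- mergeRedundantContigs(contigs)
  expect_identical(length(out), 1L)
  expect_identical(contigEnds(out), 149L)
  # overlap Jaccard 0.95: one discordant SNV in 20 -> connected
  codes <- 4L * seq(10L, 200L, by = 10L)  # 20 shared loci
  a <- sort(codes)
  b <- sort(c(codes[-1], codes[1] + 1L))  # one conflicting call
  two <- contigSet(start = c(0L, 0L), end = c(249L, 249L),
                   snvs = list(a, b), abundance = c(30L, 10L),
                   support = list(1:30, 31:40))
  expect_equal(length(intersect(a, b)) / length(union(a, b)), 19 / 21,
               tolerance = 1e-9)
  merged <- mergeRedundantContigs(two)
  expect_identical(length(merged), 1L)
  expect_identical(contigSnvs(merged)[[1]], a)  # higher abundance wins
  # overlap Jaccard 0.5: untouched
  half <- contigSet(start = c(0L, 0L), end = c(99L, 99L),
                    snvs = list(c(41L, 201L), c(41L, 330L)),
                    abundance = c(10L, 8L), support = list(1:10, 11:18))
  expect_identical(length(mergeRedundantContigs(half)), 2L)
})

test_that("divergence is differing SNVs per overlapped base", {
  same <- contigSet(start = c(0L, 0L), end = c(9999L, 9999L),
                    snvs = list(c(41L, 201L), c(41L, 201L)),
                    support = list(1L, 2L))
  expect_equal(contigDivergence(same, 1, 2), 0)
  diff2 <- contigSet(start = c(0L, 0L), end = c(9999L, 9999L),
                     snvs = list(c(41L, 201L), c(42L, 202L)),
                     support = list(1L, 2L))
  expect_equal(contigDivergence(diff2, 1, 2), 2 / 10000)
  two <- contigSet(start = c(0L, 0L), end = c(9089L, 9089L),
                   snvs = list(c(41L), integer()),
                   support = list(1L, 2L))
  expect_equal(contigDivergence(two, 1, 2), 1 / 9090)
  apart <- contigSet(start = c(0L, 200L), end = c(99L, 299L),
                     snvs = list(c(41L), c(841L)), support = list(1L, 2L))
  expect_error(contigDivergence(apart, 1, 2), "undefined")
})
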