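test_that("conditional rate counts carriers over covering conditioned reads", {
  # 3 reads carry {x, g}, 1 carries g alone: rate 3/4 with denominator 4
  reads <- readsFromCounts(list(`41,201` = 3L, `201` = 1L, `41` = 2L),
                           m = 10L)
  cr <- conditionalRate(reads, 41L, 201L)
  expect_equal(cr$rate, 0.75)
  expect_identical(cr$den, 4L)
  expect_error(conditionalRate(reads, 41L, integer()), "non-empty")
  none <- conditionalRate(reads, 41L, 999L)
  expect_true(is.na(none$rate))
})

test_that("observed joint rate matches carrier arithmetic", {
  reads <- readsFromCounts(list(`8,41` = 6L, `8` = 4L), m = 100L)
  expect_equal(observedJointRate(reads, c(8L, 41L)), 0.06)
  pu <- pileupTable(reads, alternatingRef(100L))
  expect_equal(observedJointRate(reads, 8L), substitutionRate(pu, 8L))
  expect_equal(independentJointRate(rep(0.1, 5)), 1e-5)
})

test_that("modified Jaccard uses the overlap window and minimal overlap", {
  a <- tinyReads(list(c(8L, 41L, 100L)), e = 49L)
  b <- tinyReads(list(c(8L, 41L, 100L)), e = 49L)
  expect_equal(readJaccard(a, b), 1)
  d <- tinyReads(list(c(12L, 45L)), e = 49L)
  expect_equal(readJaccard(a, d), 0)
  # shares 2 of 4 union codes in the overlap
  e <- tinyReads(list(c(8L, 41L, 104L)), e = 49L)
  expect_equal(readJaccard(a, e), 0.5)
  # overlap shorter than half of read i -> 0 despite shared codes
  short <- encodedReadSet(40L, 49L, list(c(170L, 180L)))
  long <- encodedReadSet(0L, 49L, list(c(8L, 170L, 180L)))
  expect_gt(readJaccard(short, long), 0)      # overlap 10 >= 0.5 * 9
  far <- encodedReadSet(45L, 120L, list(c(190L)))
  wide <- encodedReadSet(0L, 49L, list(c(190L)))
  expect_equal(readJaccard(far, wide, 0.5), 0)  # overlap 5 < 0.5 * 75
})

test_that("subspaces come from top-Jaccard neighbours", {
  s <- c(8L, 41L, 100L)
  reads <- tinyReads(list(s, s, s))
  sub <- buildSubspaces(reads, w = 2L)
  expect_lte(length(sub), 6L)
  expect_true(all(vapply(sub, function(x) identical(x$codes, sort(s)),
                         logical(1))))
  # a read sharing nothing contributes no subspace
  reads2 <- tinyReads(list(s, s, c(13L, 55L)))
  sub2 <- buildSubspaces(reads2, w = 2L)
  expect_false(any(vapply(sub2, function(x) 3L %in% c(x$i, x$j),
                          logical(1))))
})

test_that("greedy search accepts strictly increasing conditional rates", {
  set.seed(21)
  for (rep in 1:20) {
    s <- smallSim(seed = rep, refLength = 120L, nSnvs = c(3L),
                  abundance = 0.2, depth = 120L, errorRate = 0.15,
                  minHd = 0L, edgeRuns = 0L)
    codes <- unique(unlist(readSubs(s$reads)))
    xk <- sample(codes, 1)
    cand <- setdiff(codes, xk)
    cand <- cand[cand %/% 4L != xk %/% 4L]
    if (length(cand) == 0) next
    g <- greedyMaxConditional(s$reads, xk, cand,
                              rsmParams(vMin = 5L, hdMin = 0L))
    if (length(g$rates) > 1)
      expect_true(all(diff(g$rates) > 0))
    if (!is.na(g$h)) {
      expect_gte(g$h, 0)
      expect_lte(g$h, 1)
      expect_gte(g$den, 5L)
    }
  }
})

test_that("single-candidate greedy equals the pairwise conditional rate", {
  reads <- readsFromCounts(list(`41,201` = 30L, `201` = 10L), m = 100L)
  g <- greedyMaxConditional(reads, 41L, 201L, rsmParams(vMin = 5L))
  expect_equal(g$h, 0.75)
  expect_identical(g$chosen, 201L)
})

test_that("pair-dependent SNVs defeat p = 1 conditioning but not the
           unrestricted greedy", {
  # x co-occurs only with the *pair* {g2, g3}; singly, each conditions x
  # at under the detection threshold
  reads <- readsFromCounts(
    list(`17,202,411` = 40L,   # x with both partners
         `202` = 60L, `411` = 60L),
    m = 400L, e = 149L)
  cand <- c(202L, 411L)
  bf1 <- bruteForceMaxConditional(reads, 17L, cand, pMax = 1L, vMin = 25L)
  expect_lt(bf1$h, 0.65)
  bfAll <- bruteForceMaxConditional(reads, 17L, cand, vMin = 25L)
  expect_equal(bfAll$h, 1)
  g <- greedyMaxConditional(reads, 17L, cand, rsmParams(vMin = 25L))
  expect_equal(g$h, bfAll$h)
  expect_setequal(g$chosen, cand)
})

test_that("greedy estimates never exceed the brute-force oracle", {
  set.seed(33)
  for (rep in 1:15) {
    s <- smallSim(seed = 100 + rep, refLength = 80L, nSnvs = c(3L),
                  abundance = 0.25, depth = 150L, errorRate = 0.1,
                  minHd = 0L, edgeRuns = 0L)
    tab <- table(unlist(readSubs(s$reads)))
    codes <- as.integer(names(tab)[tab >= 5])  # keep the instance small
    if (length(codes) > 12) codes <- codes[seq_len(12)]
    for (xk in codes[seq_len(min(4, length(codes)))]) {
      cand <- setdiff(codes, xk)
      cand <- cand[cand %/% 4L != xk %/% 4L]
      if (length(cand) == 0) next
      g <- greedyMaxConditional(s$reads, xk, cand, rsmParams(vMin = 5L))
      bf <- bruteForceMaxConditional(s$reads, xk, cand, vMin = 5L)
      if (!is.na(g$h)) expect_lte(g$h, bf$h + 1e-12)
    }
  }
})

test_that("error-free reads from two haplotypes yield exactly the planted
           SNVs with H = 1", {
  s <- smallSim(seed = 42, refLength = 300L, nSnvs = c(4L, 4L),
                abundance = c(0.3, 0.02), depth = 2000L, errorRate = 0)
  calls <- rsmDetect(s$reads, s$ref, rsmParams())
  expect_setequal(calls$code, unlist(s$haplotypes))
  expect_true(all(calls$hHat == 1))
})

test_that("noisy minor haplotypes are detected without false positives", {
  s <- smallSim(seed = 6, refLength = 300L, nSnvs = c(5L, 5L),
                abundance = c(0.10, 0.05), depth = 800L, errorRate = 0.1)
  calls <- rsmDetect(s$reads, s$ref, rsmParams())
  ev <- evaluateCalls(calls, unlist(s$haplotypes))
  expect_identical(ev$tpr, 1)
  expect_identical(ev$fdr, 0)
  expect_true(all(calls$nDen >= 25L))
})

test_that("detection power does not decrease with depth or abundance", {
  tprAt <- function(depth, ab, seed = 77) {
    s <- smallSim(seed = seed, refLength = 300L, nSnvs = c(5L),
                  abundance = ab, depth = depth, errorRate = 0.1)
    ev <- evaluateCalls(rsmDetect(s$reads, s$ref), unlist(s$haplotypes))
    ev$tpr
  }
  expect_lte(tprAt(150L, 0.05), tprAt(900L, 0.05))
  expect_lte(tprAt(500L, 0.02), tprAt(500L, 0.15))
})

test_that("the naive-greedy failure bound is the stated power", {
  expect_equal(greedySuccessUpperBound(1, 2000, 2000, 1), 1)
  expect_equal(greedySuccessUpperBound(0.7, 10, 10, 20), 1)
  expect_equal(greedySuccessUpperBound(0.5, 3, 2, 1), 0.5^4)
})
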