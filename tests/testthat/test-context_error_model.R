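test_that("context extraction reports the flanking homopolymer runs", {
  ref <- refGenome("AAACGGT")
  ctx <- extractContext(ref, encodeSubstitution("T", "C", 3))
  expect_identical(ctx$upBase, "A")
  expect_identical(ctx$upLen, 3L)
  expect_identical(ctx$downBase, "G")
  expect_identical(ctx$downLen, 2L)
  expect_identical(ctx$curBase, "C")
  expect_identical(ctx$altBase, "T")
  expect_false(ctx$truncated)
  # genome edge -> truncated flag
  edge <- extractContext(ref, encodeSubstitution("T", "A", 0))
  expect_true(edge$truncated)
  # identical flanking structure gives identical features
  ref2 <- refGenome("TTAAACGGTCCAAACGGTAA")
  c1 <- extractContext(ref2, encodeSubstitution("T", "C", 5))
  c2 <- extractContext(ref2, encodeSubstitution("T", "C", 14))
  expect_identical(c1[, -1], c2[, -1])
})

test_that("likelihood ratio behaves as a maximum-likelihood ratio", {
  expect_equal(likelihoodRatio(0, 10, 0.1), 1 / 0.9^10)
  expect_equal(likelihoodRatio(2, 20, 0.1), 1)  # t = n * p0 exactly
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(5:500, 1)
    t <- sample(0:n, 1)
    p0 <- runif(1, 0.01, 0.99)
    expect_gte(likelihoodRatio(t, n, p0), 1)
  }
  # monotone in |t/n - p0| at fixed n
  lr <- vapply(0:20, function(t) likelihoodRatio(t, 100, 0.1), numeric(1))
  expect_true(all(diff(lr[1:10]) < 0))   # approaching t = n*p0 = 10
  expect_true(all(diff(lr[11:21]) > 0))  # moving away again
  expect_error(likelihoodRatio(1, 0, 0.1), "undefined")
})

test_that("context model learns a deterministic context effect", {
  set.seed(7)
  ref <- refGenome(paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                         collapse = ""))
  codes <- vapply(sample(1:2900, 400), function(k) {
    refB <- substr(refSequence(ref), k + 1, k + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refB), 1)
    encodeSubstitution(alt, refB, k)
  }, integer(1))
  ctx <- extractContext(ref, codes)
  rate <- 0.01 + 0.02 * pmin(ctx$upLen, 5) + 0.015 * pmin(ctx$downLen, 5)
  fit <- fitContextModel(ctx, rate, "pacbio", eta = 0.1, nrounds = 300,
                         maxDepth = 6)
  expect_gte(fit@cvR2, 0.95)
  pred <- predictErrorRate(fit, ctx)
  expect_true(all(pred >= 1e-6 & pred <= 0.5))
  # constant target: fit succeeds with R^2 = 0
  cfit <- fitContextModel(ctx, rep(0.05, nrow(ctx)), "pacbio", eta = 0.1,
                          nrounds = 20, maxDepth = 3)
  expect_identical(cfit@cvR2, 0)
})

test_that("platform presets set the published hyperparameters", {
  set.seed(8)
  ref <- refGenome(paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                         collapse = ""))
  codes <- vapply(sample(1:1900, 150), function(k) {
    refB <- substr(refSequence(ref), k + 1, k + 1)
    encodeSubstitution(sample(setdiff(c("A", "C", "G", "T"), refB), 1),
                       refB, k)
  }, integer(1))
  ctx <- extractContext(ref, codes)
  fit <- fitContextModel(ctx, runif(nrow(ctx), 0, 0.1), "pacbio",
                         nrounds = 5)  # small tree count to stay fast
  expect_identical(fit@hyperparams$eta, 0.01)
  expect_identical(fit@hyperparams$maxDepth, 10L)
  fitO <- fitContextModel(ctx, runif(nrow(ctx), 0, 0.1), "ont",
                          nrounds = 5)
  expect_identical(fitO@hyperparams$eta, 0.1)
})

test_that("orphan-SNV detection applies both LR and rate thresholds", {
  set.seed(11)
  ref <- refGenome(paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                         collapse = ""))
  refCh <- strsplit(refSequence(ref), "")[[1]]
  L <- 400L
  n <- 1000L
  # background errors at 2 percent per alternative, one planted SNV at 15%
  k <- 200L
  alt <- setdiff(c("A", "C", "G", "T"), refCh[k + 1])[1]
  planted <- encodeSubstitution(alt, refCh[k + 1], k)
  subs <- lapply(seq_len(n), function(i) {
    errLoci <- which(runif(L) < 0.02) - 1L
    codes <- vapply(errLoci, function(g) {
      a <- sample(setdiff(c("A", "C", "G", "T"), refCh[g + 1]), 1)
      encodeSubstitution(a, refCh[g + 1], g)
    }, integer(1))
    codes <- codes[!(codes %/% 4L == k)]
    if (runif(1) < 0.15) codes <- c(codes, planted)
    sort(codes)
  })
  reads <- tinyReads(subs, b = 0L, e = L - 1L)
  # train the model on a locus-wise rate table from the same error process
  pu <- pileupTable(reads, ref)
  allCodes <- unlist(lapply(0:3, function(d) 4L * pu$locus + d))
  allCodes <- setdiff(allCodes[(allCodes %% 4L + 1L) !=
                                 match(refCh[allCodes %/% 4L + 1L],
                                       c("A", "C", "G", "T"))], planted)
  ctx <- extractContext(ref, allCodes)
  rates <- vapply(allCodes, function(cd) substitutionRate(pu, cd),
                  numeric(1))
  fit <- fitContextModel(ctx, rates, "pacbio", eta = 0.1, nrounds = 100,
                         maxDepth = 4)
  calls <- detectOrphanSnvs(reads, ref, fit, "pacbio")
  expect_true(planted %in% calls$code)
  expect_true(all(calls$rate > 0.1))
  expect_true(all(calls$lr > 50))
  # a 5 percent substitution stays below the PacBio rate floor
  expect_false(any(calls$rate <= 0.1))
  # uncorrected single-locus mode ignores the context model
  sl <- detectOrphanSnvs(reads, ref, platform = "pacbio", mode = "sl")
  expect_true(planted %in% sl$code)
  expect_true(all(is.na(sl$lr)))
})
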