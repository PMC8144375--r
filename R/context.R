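#' Homopolymer sequence context of a substitution
#'
#' The context of a locus is the homopolymer run immediately upstream and
#' the run immediately downstream of the run containing the locus, plus the
#' current (reference) base and the substituting alternative base. Loci
#' whose run touches a genome end get a truncated context (the missing side
#' is reported with base `"N"` and length 0) and `truncated = TRUE`.
#'
#' @param ref a [ReferenceGenome-class].
#' @param code substitution code(s) `4k + d`.
#' @return data.frame with `locus`, `curBase`, `altBase`, `upBase`, `upLen`,
#'   `downBase`, `downLen`, `truncated`.
#' @examples
#' extractContext(refGenome("AAACGGT"), encodeSubstitution("T", "C", 3))
#' @export
extractContext <- function(ref, code) {
  runs <- homopolymerRuns(ref)
  ri <- runIndex(ref)
  L <- refLength(ref)
  code <- as.integer(code)
  k <- code %/% 4L
  if (any(k < 0L | k >= L)) stop("invalid locus: outside reference")
  r <- ri[k + 1L] + 1L  # 1-based run row
  up <- r - 1L
  down <- r + 1L
  hasUp <- up >= 1L
  hasDown <- down <= nrow(runs)
  data.frame(
    locus = k,
    curBase = runs$base[r],
    altBase = BASES[code %% 4L + 1L],
    upBase = ifelse(hasUp, runs$base[pmax(up, 1L)], "N"),
    upLen = ifelse(hasUp, runs$length[pmax(up, 1L)], 0L),
    downBase = ifelse(hasDown, runs$base[pmin(down, nrow(runs))], "N"),
    downLen = ifelse(hasDown, runs$length[pmin(down, nrow(runs))], 0L),
    truncated = !(hasUp & hasDown))
}

# one-hot encode bases + capped run lengths -> numeric feature matrix
contextFeatureMatrix <- function(ctx, lenCap = 20L) {
  oneHot <- function(base, prefix) {
    m <- sapply(BASES, function(b) as.numeric(base == b))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    colnames(m) <- paste0(prefix, BASES)
    m
  }
  cbind(oneHot(ctx$curBase, "cur"), oneHot(ctx$altBase, "alt"),
        oneHot(ctx$upBase, "up"), oneHot(ctx$downBase, "down"),
        upLen = pmin(ctx$upLen, lenCap), downLen = pmin(ctx$downLen, lenCap))
}

#' Fit the homopolymer-context error model
#'
#' Gradient boosting (xgboost) from context features to observed per-code
#' substitution rates. Defaults follow the platform presets: step size,
#' number of trees and maximal tree depth of (0.01, 2000, 10) for PacBio and
#' (0.1, 2000, 10) for ONT. Reports a 5-fold cross-validated R squared
#' (`1 - SS_res / SS_tot`; 0 for a constant target).
#'
#' @param contexts data.frame of context features (from [extractContext()]).
#' @param rates observed substitution rates, one per context row.
#' @param platform `"pacbio"` or `"ont"` (sets default hyperparameters).
#' @param eta,nrounds,maxDepth optional hyperparameter overrides.
#' @param nfold folds for cross-validated R squared.
#' @return A [ContextErrorModel-class].
#' @export
fitContextModel <- function(contexts, rates, platform = c("pacbio", "ont"),
                            eta = NULL, nrounds = NULL, maxDepth = NULL,
                            nfold = 5L) {
  platform <- match.arg(platform)
  defaults <- if (platform == "pacbio") list(eta = 0.01, nrounds = 2000L,
                                             maxDepth = 10L)
              else list(eta = 0.1, nrounds = 2000L, maxDepth = 10L)
  if (is.null(eta)) eta <- defaults$eta
  if (is.null(nrounds)) nrounds <- defaults$nrounds
  if (is.null(maxDepth)) maxDepth <- defaults$maxDepth
  X <- contextFeatureMatrix(contexts)
  y <- as.numeric(rates)
  if (nrow(unique(X)) < 100L)
    stop("need at least 100 distinct contexts to fit the model")
  params <- list(objective = "reg:squarederror", eta = eta,
                 max_depth = maxDepth, nthread = 1L)
  trainOne <- function(rows) {
    xgboost::xgb.train(params = params,
                       data = xgboost::xgb.DMatrix(X[rows, , drop = FALSE],
                                                   label = y[rows]),
                       nrounds = nrounds, verbose = 0)
  }
  # deterministic fold assignment
  fold <- rep_len(seq_len(nfold), length(y))
  pred <- numeric(length(y))
  for (f in seq_len(nfold)) {
    tr <- which(fold != f)
    bst <- trainOne(tr)
    pred[fold == f] <- predict(bst,
      xgboost::xgb.DMatrix(X[fold == f, , drop = FALSE]))
  }
  ssTot <- sum((y - mean(y))^2)
  cvR2 <- if (ssTot == 0) 0 else max(0, 1 - sum((y - pred)^2) / ssTot)
  booster <- trainOne(seq_along(y))
  new("ContextErrorModel", booster = booster, platform = platform,
      hyperparams = list(eta = eta, nrounds = nrounds, maxDepth = maxDepth),
      cvR2 = cvR2, featureNames = colnames(X))
}

#' Predict the context-driven error rate
#'
#' @param model a [ContextErrorModel-class].
#' @param contexts data.frame of context features.
#' @return Predicted substitution error rates, clipped to `[1e-6, 0.5]`.
#' @export
predictErrorRate <- function(model, contexts) {
  X <- contextFeatureMatrix(contexts)
  p <- predict(model@booster, xgboost::xgb.DMatrix(X))
  pmin(pmax(p, 1e-6), 0.5)
}

#' Binomial likelihood ratio of an observed substitution count
#'
#' `Binomial(t; n, t/n) / Binomial(t; n, p0)`, computed in log space. Always
#' at least 1 because `t/n` is the maximum-likelihood rate.
#'
#' @param t carrier count.
#' @param n coverage (positive).
#' @param p0 context-predicted error rate in (0, 1).
#' @param log return the log likelihood ratio.
#' @return The (log) likelihood ratio.
#' @examples
#' likelihoodRatio(0, 10, 0.1)  # 1 / 0.9^10
#' @export
likelihoodRatio <- function(t, n, p0, log = FALSE) {
  if (any(n <= 0)) stop("undefined: n must be positive")
  if (any(t < 0 | t > n)) stop("t must be in [0, n]")
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must be in (0, 1)")
  llr <- dbinom(t, n, t / n, log = TRUE) - dbinom(t, n, p0, log = TRUE)
  if (log) llr else exp(llr)
}

#' Detect SNVs from single-locus rates with context correction
#'
#' The orphan-SNV path: a substitution is reported when its likelihood ratio
#' against the context-predicted error rate exceeds `lrThreshold` (50) and
#' its marginal substitution rate exceeds the platform floor (0.1 for
#' PacBio, 0.2 for ONT). `mode = "sl"` is the uncorrected single-locus
#' baseline (rate threshold only), exposed for benchmarking.
#'
#' @param reads an [EncodedReadSet-class].
#' @param ref a [ReferenceGenome-class].
#' @param model a [ContextErrorModel-class] (required for `mode = "slc"`).
#' @param platform `"pacbio"` or `"ont"`.
#' @param lrThreshold likelihood-ratio threshold.
#' @param rateThreshold marginal-rate floor (platform default if `NULL`).
#' @param maskedLoci 0-based loci excluded from candidates (e.g. methylation
#'   mask).
#' @param mode `"slc"` (context-corrected) or `"sl"` (rate only).
#' @return data.frame of calls: `code`, `locus`, `pos`, `refBase`,
#'   `altBase`, `rate`, `lr`, `p0`, `method`.
#' @export
detectOrphanSnvs <- function(reads, ref, model = NULL,
                             platform = c("pacbio", "ont"),
                             lrThreshold = 50, rateThreshold = NULL,
                             maskedLoci = integer(),
                             mode = c("slc", "sl")) {
  platform <- match.arg(platform)
  mode <- match.arg(mode)
  if (is.null(rateThreshold))
    rateThreshold <- if (platform == "pacbio") 0.1 else 0.2
  pu <- pileupTable(reads, ref)
  cand <- do.call(rbind, lapply(seq_len(4L), function(d) {
    t <- pu[[BASES[d]]]
    keep <- t > 0L & pu$depth > 0L & !(pu$locus %in% maskedLoci)
    data.frame(code = 4L * pu$locus[keep] + (d - 1L), t = t[keep],
               n = pu$depth[keep])
  }))
  empty <- data.frame(code = integer(), locus = integer(), pos = integer(),
                      refBase = character(), altBase = character(),
                      rate = numeric(), lr = numeric(), p0 = numeric(),
                      method = character())
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand$code), , drop = FALSE]
  cand$rate <- cand$t / cand$n
  refSeq <- strsplit(refSequence(ref), "")[[1L]]
  # drop candidates whose alt equals the reference base (cannot be encoded,
  # defensive only) and below the rate floor
  cand <- cand[cand$rate > rateThreshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  if (mode == "slc") {
    if (is.null(model)) stop("mode 'slc' needs a fitted ContextErrorModel")
    ctx <- extractContext(ref, cand$code)
    cand$p0 <- predictErrorRate(model, ctx)
    cand$lr <- likelihoodRatio(cand$t, cand$n, cand$p0)
    cand <- cand[cand$lr > lrThreshold, , drop = FALSE]
  } else {
    cand$p0 <- NA_real_
    cand$lr <- NA_real_
  }
  if (nrow(cand) == 0L) return(empty)
  data.frame(code = cand$code, locus = cand$code %/% 4L,
             pos = cand$code %/% 4L + 1L,
             refBase = refSeq[cand$code %/% 4L + 1L],
             altBase = BASES[cand$code %% 4L + 1L],
             rate = cand$rate, lr = cand$lr, p0 = cand$p0,
             method = toupper(mode), row.names = NULL)
}
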