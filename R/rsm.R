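#' Detection parameters for the random-subspace search
#'
#' @param hThreshold maximal-conditional-rate threshold for calling an SNV
#'   (0.65).
#' @param vMin minimal denominator (reads carrying the conditioning set and
#'   covering the target locus) for every accepted greedy step (25).
#' @param hdMin minimal homopolymer distance between the target locus and
#'   any conditioning locus (15).
#' @param w number of highest-Jaccard neighbours per read used to build
#'   subspaces (100).
#' @param lMinFraction minimal overlap between compared reads as a fraction
#'   of the first read's length (0.5).
#' @return A named list of class `RsmParams`.
#' @export
rsmParams <- function(hThreshold = 0.65, vMin = 25L, hdMin = 15L, w = 100L,
                      lMinFraction = 0.5) {
  stopifnot(hThreshold > 0, hThreshold < 1, vMin >= 1, hdMin >= 0, w >= 1,
            lMinFraction >= 0)
  structure(list(hThreshold = hThreshold, vMin = as.integer(vMin),
                 hdMin = as.integer(hdMin), w = as.integer(w),
                 lMinFraction = lMinFraction), class = "RsmParams")
}

#' Conditional substitution rate
#'
#' Reads carrying the target substitution and every conditioning
#' substitution, over reads carrying the conditioning set and covering the
#' target locus.
#'
#' @param reads an [EncodedReadSet-class].
#' @param xk target substitution code.
#' @param given non-empty integer vector of conditioning codes.
#' @return list with `rate` and `den` (denominator count); `rate` is `NA`
#'   when no read carries the conditioning set over the locus.
#' @export
conditionalRate <- function(reads, xk, given) {
  if (length(given) == 0L) stop("conditioning set must be non-empty")
  k <- xk %/% 4L
  S <- readSubs(reads)
  hasGiven <- vapply(S, function(s) all(given %in% s), logical(1L))
  covers <- readStarts(reads) <= k & readEnds(reads) >= k
  den <- sum(hasGiven & covers)
  if (den == 0L) return(list(rate = NA_real_, den = 0L))
  num <- sum(hasGiven & covers &
               vapply(S, function(s) xk %in% s, logical(1L)))
  list(rate = num / den, den = den)
}

#' Observed joint substitution rate of a code set
#'
#' Reads carrying every code in the set, over reads covering all their loci.
#'
#' @param reads an [EncodedReadSet-class].
#' @param codes one or more substitution codes.
#' @return Rate in `[0, 1]`; `NA` if no read covers all loci.
#' @export
observedJointRate <- function(reads, codes) {
  stopifnot(length(codes) >= 1L)
  loci <- unique(codes %/% 4L)
  covers <- rep(TRUE, length(reads))
  b <- readStarts(reads); e <- readEnds(reads)
  for (k in loci) covers <- covers & b <= k & e >= k
  den <- sum(covers)
  if (den == 0L) return(NA_real_)
  S <- readSubs(reads)
  num <- sum(vapply(which(covers),
                    function(i) all(codes %in% S[[i]]), logical(1L)))
  num / den
}

#' Expected joint rate under error independence
#'
#' The product of per-locus rates: the baseline joint probability when the
#' substitutions are independent sequencing errors.
#'
#' @param rates per-locus substitution rates.
#' @return `prod(rates)`.
#' @examples
#' independentJointRate(rep(0.1, 5))  # 1e-5
#' @export
independentJointRate <- function(rates) prod(rates)

#' Modified Jaccard similarity of two encoded reads
#'
#' Shared substitution codes over all codes of either read inside the code
#' window of the overlapped interval; 0 when the denominator is 0 or when
#' the overlap is shorter than `lMinFraction * (e_i - b_i)` (relative to the
#' first read).
#'
#' @param ri,rj length-1 [EncodedReadSet-class] objects (or a read set plus
#'   indices via `reads[i]`).
#' @param lMinFraction minimal-overlap fraction.
#' @return Similarity in `[0, 1]`.
#' @export
readJaccard <- function(ri, rj, lMinFraction = 0.5) {
  stopifnot(length(ri) == 1L, length(rj) == 1L)
  cpp_read_jaccard(readSubs(ri)[[1L]], readSubs(rj)[[1L]],
                   readStarts(ri), readEnds(ri),
                   readStarts(rj), readEnds(rj), lMinFraction)
}

#' Build read-pair subspaces
#'
#' For each read, the substitution sets shared with its `w` highest-Jaccard
#' neighbours (`C_ij = S_i` intersect `S_j`); empty intersections are
#' dropped. At most `w * m` subspaces for `m` reads.
#'
#' @param reads an [EncodedReadSet-class].
#' @param w neighbours per read.
#' @param lMinFraction minimal-overlap fraction for the Jaccard index.
#' @return List of subspaces, each a list with read indices `i`, `j` and the
#'   shared `codes`.
#' @export
buildSubspaces <- function(reads, w = 100L, lMinFraction = 0.5) {
  nb <- cpp_top_neighbors(readSubs(reads), readStarts(reads),
                          readEnds(reads), as.integer(w), lMinFraction)
  S <- readSubs(reads)
  out <- list()
  for (i in seq_along(nb)) {
    for (j in nb[[i]]) {
      codes <- intersect(S[[i]], S[[j]])
      if (length(codes))
        out[[length(out) + 1L]] <- list(i = i, j = j, codes = sort(codes))
    }
  }
  out
}

#' Greedy estimate of the maximal conditional substitution rate
#'
#' Candidates are ranked by their single-conditioning rate (ties: larger
#' denominator, lower locus, lower code) and accepted one by one while the
#' conditional rate strictly increases and the denominator stays at least
#' `vMin`. Candidate loci closer than `hdMin` homopolymer runs to the target
#' locus (or sharing it) are excluded; the homopolymer distance check needs
#' `ref` and is skipped when `ref` is `NULL`.
#'
#' @param reads an [EncodedReadSet-class].
#' @param xk target substitution code.
#' @param candidates candidate conditioning codes (e.g. one subspace).
#' @param params an [rsmParams()] list.
#' @param ref optional [ReferenceGenome-class] for the homopolymer-distance
#'   constraint.
#' @return list with `h` (estimate; `NA` when no candidate has a valid
#'   denominator), `den`, the accepted `chosen` codes and the accepted-step
#'   `rates`.
#' @export
greedyMaxConditional <- function(reads, xk, candidates, params = rsmParams(),
                                 ref = NULL) {
  if (is.null(ref)) {
    runId <- seq_len(max(readEnds(reads), xk %/% 4L) + 1L) - 1L
    hdMin <- 0L
  } else {
    runId <- runIndex(ref)
    hdMin <- params$hdMin
  }
  cpp_greedy(readSubs(reads), readStarts(reads), readEnds(reads),
             as.integer(xk), as.integer(candidates), as.integer(runId),
             params$vMin, as.integer(hdMin))
}

#' Exhaustive maximal conditional substitution rate (test oracle)
#'
#' Brute-force maximum of the conditional rate over all conditioning subsets
#' of size at most `pMax` whose denominator meets `vMin`. Guarded to at most
#' 15 candidate codes.
#'
#' @param reads an [EncodedReadSet-class].
#' @param xk target substitution code.
#' @param candidates candidate conditioning codes.
#' @param pMax maximal conditioning-set size.
#' @param vMin minimal denominator.
#' @return list with `h` (`NA` if no subset qualifies) and the maximizing
#'   `set`.
#' @export
bruteForceMaxConditional <- function(reads, xk, candidates,
                                     pMax = length(candidates), vMin = 1L) {
  candidates <- setdiff(as.integer(candidates), xk)
  candidates <- candidates[candidates %/% 4L != xk %/% 4L]
  if (length(candidates) > 15L)
    stop("refusing brute force over more than 15 candidates")
  best <- NA_real_
  bestSet <- integer()
  for (p in seq_len(min(pMax, length(candidates)))) {
    idx <- utils::combn(length(candidates), p)
    for (col in seq_len(ncol(idx))) {
      set <- candidates[idx[, col]]
      cr <- conditionalRate(reads, xk, set)
      if (cr$den >= vMin && !is.na(cr$rate) &&
          (is.na(best) || cr$rate > best)) {
        best <- cr$rate
        bestSet <- set
      }
    }
  }
  list(h = best, set = bestSet)
}

#' Detect minor SNVs by random subspace maximization
#'
#' For every substitution present in at least one read-pair subspace, the
#' greedy search is run inside each subspace containing it and the best
#' estimate `H` is kept. A substitution is reported when `H` exceeds
#' `hThreshold` with a denominator of at least `vMin`; conditioning loci
#' must be at least `hdMin` homopolymer runs from the target.
#'
#' @param reads an [EncodedReadSet-class] (QV/methylation masking already
#'   applied).
#' @param ref a [ReferenceGenome-class].
#' @param params an [rsmParams()] list.
#' @param maskedLoci 0-based loci excluded from calls.
#' @return data.frame of calls: `code`, `locus`, `pos` (1-based), `refBase`,
#'   `altBase`, `rate`, `hHat`, `nDen`, `method = "RSM"`, sorted by `code`.
#' @export
rsmDetect <- function(reads, ref, params = rsmParams(),
                      maskedLoci = integer()) {
  empty <- data.frame(code = integer(), locus = integer(), pos = integer(),
                      refBase = character(), altBase = character(),
                      rate = numeric(), hHat = numeric(), nDen = integer(),
                      method = character())
  if (length(reads) == 0L) return(empty)
  scan <- cpp_rsm_scan(readSubs(reads), readStarts(reads), readEnds(reads),
                       runIndex(ref), params$w, params$vMin, params$hdMin,
                       params$lMinFraction)
  if (nrow(scan) == 0L) return(empty)
  keep <- scan$hHat > params$hThreshold & scan$nDen >= params$vMin &
    !(scan$code %/% 4L %in% maskedLoci)
  scan <- scan[keep, , drop = FALSE]
  if (nrow(scan) == 0L) return(empty)
  refSeq <- strsplit(refSequence(ref), "")[[1L]]
  data.frame(code = scan$code, locus = scan$code %/% 4L,
             pos = scan$code %/% 4L + 1L,
             refBase = refSeq[scan$code %/% 4L + 1L],
             altBase = BASES[scan$code %% 4L + 1L],
             rate = scan$t / scan$n, hHat = scan$hHat, nDen = scan$nDen,
             method = "RSM", row.names = NULL)
}

#' Upper bound on the naive greedy algorithm's success probability
#'
#' With signal-to-noise ratio `rho0`, a search window of `tl + tr` loci and
#' `p` true dependent loci, the probability that the unrestricted greedy
#' search recovers the maximal conditional rate is at most
#' `rho0^(tl + tr - p)`. For typical long-read windows this bound is
#' astronomically small, which motivates the subspace restriction.
#'
#' @param rho0 signal-to-noise probability in `[0, 1]`.
#' @param tl,tr window extents left/right of the target locus.
#' @param p number of true dependent loci (`p <= tl + tr`).
#' @return The bound `rho0^(tl + tr - p)`.
#' @examples
#' greedySuccessUpperBound(0.99, 2000, 2000, 1)
#' @export
greedySuccessUpperBound <- function(rho0, tl, tr, p) {
  stopifnot(rho0 >= 0, rho0 <= 1, tl + tr >= p)
  rho0^(tl + tr - p)
}
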