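#' Bayes factor for an SNV frequency exceeding the error rate
#'
#' Marginal likelihood of the carrier count under a uniform prior on the
#' substitution rate restricted to `(p0, 1]`, against the point null
#' `Binomial(t; n, p0)`. Values above the threshold (default 10 in the
#' filters) mean the frequency is significantly higher than the
#' context-predicted error rate.
#'
#' @param t carrier count.
#' @param n coverage (positive).
#' @param p0 error rate in (0, 1).
#' @param log return the log Bayes factor.
#' @return The (log) Bayes factor.
#' @export
bfSnvFrequency <- function(t, n, p0, log = FALSE) {
  if (any(n <= 0)) stop("undefined: n must be positive")
  stopifnot(all(t >= 0 & t <= n), all(p0 > 0 & p0 < 1))
  # integral of Binomial(t; n, p) over p in (p0, 1] equals
  # (1 - pbeta(p0, t+1, n-t+1)) / (n + 1)
  logNum <- pbeta(p0, t + 1, n - t + 1, lower.tail = FALSE, log.p = TRUE) -
    log(n + 1) - log1p(-p0)
  logBF <- logNum - dbinom(t, n, p0, log = TRUE)
  if (log) logBF else exp(logBF)
}

#' Bayes factor for dependence of co-occurring SNVs
#'
#' Tests whether the joint carrier rate of a contig's SNVs exceeds the
#' product of their marginal rates (the expectation under independence).
#' Same restricted-uniform form as [bfSnvFrequency()] with the independence
#' product as the null rate; a small value means the SNVs look independent.
#'
#' @param t joint carrier count.
#' @param n reads covering all loci.
#' @param q product of marginal rates (null).
#' @param log return the log Bayes factor.
#' @return The (log) Bayes factor for dependence.
#' @export
bfSnvDependence <- function(t, n, q, log = FALSE) {
  bfSnvFrequency(t, n, pmin(pmax(q, 1e-12), 1 - 1e-12), log = log)
}

#' Bayes factor for two contigs being distinct haplotypes
#'
#' Evidence that the lower-abundance contig of an overlapping pair is a
#' distinct haplotype rather than an artifact of the higher-abundance one.
#' Three regimes, depending on how the consensus sets relate in the
#' overlap:
#'
#' * identical sets: BF = 1 (the lower contig is redundant);
#' * nested sets: the existence of the smaller haplotype is judged from
#'   *unselected* read counts. When the lower contig's set is contained in
#'   the higher's, its exclusive carriers (reads carrying all its codes but
#'   none of the higher contig's extras) are tested against the
#'   error-coincidence plus allele-dropout expectation; when the lower
#'   contig adds extra codes, each extra code's rate among carriers of the
#'   shared codes is tested against the error rate, and the weakest code
#'   decides. Cluster-selected support is deliberately not used here:
#'   clustering discards exactly the reads that would reveal an artifact;
#' * conflicting sets: per differing code, the carrier counts among the two
#'   support sets are contrasted - independent uniform rates (distinct
#'   haplotypes) against a common uniform rate (one shared haplotype) -
#'   and combined across codes.
#'
#' @param contigs a [ContigSet-class].
#' @param i,j contig indices (must overlap).
#' @param reads restricted [EncodedReadSet-class].
#' @param p0 per-code error rate (named vector keyed by code, or a single
#'   rate).
#' @param log return the log Bayes factor.
#' @return The (log) Bayes factor; above the threshold means significantly
#'   different. Attribute `"suspect"` names the contig index judged
#'   redundant when the evidence is weak (for nested sets the redundant
#'   claim, otherwise the lower-abundance contig).
#' @export
bfContigPairDifference <- function(contigs, i, j, reads, p0 = 0.01,
                                   log = FALSE) {
  s <- contigStarts(contigs); e <- contigEnds(contigs)
  mb <- max(s[i], s[j]); me <- min(e[i], e[j])
  if (me < mb) stop("contigs ", i, " and ", j, " do not overlap")
  p0of <- function(code) {
    if (length(p0) == 1L && is.null(names(p0))) return(rep(as.numeric(p0),
                                                           length(code)))
    v <- as.numeric(p0[as.character(code)])
    v[is.na(v)] <- mean(as.numeric(p0))
    v
  }
  inWin <- function(codes) codes[codes %/% 4L >= mb & codes %/% 4L <= me]
  # order so that `hi` is the higher-abundance contig of the pair
  ab <- contigAbundance(contigs)
  hi <- if (ab[i] >= ab[j]) i else j
  lo <- if (hi == i) j else i
  sh <- inWin(contigSnvs(contigs)[[hi]])
  sl <- inWin(contigSnvs(contigs)[[lo]])
  S <- readSubs(reads); b <- readStarts(reads); ee <- readEnds(reads)
  carriersOf <- function(codes) {
    which(vapply(S, function(x) all(codes %in% x), logical(1L)))
  }
  coversAll <- function(loci) {
    ok <- rep(TRUE, length(S))
    for (k in loci) ok <- ok & b <= k & ee >= k
    which(ok)
  }
  if (setequal(sh, sl)) {
    out <- if (log) 0 else 1
    attr(out, "suspect") <- lo
    return(out)
  }
  logBF <- NULL
  suspect <- lo
  nested <- (length(sl) && all(sl %in% sh)) ||
    (length(sh) && all(sh %in% sl))
  if (nested) {
    subIx <- if (length(sl) && all(sl %in% sh)) lo else hi
    supIx <- if (subIx == lo) hi else lo
    subSet <- inWin(contigSnvs(contigs)[[subIx]])
    extras <- setdiff(inWin(contigSnvs(contigs)[[supIx]]), subSet)
    # is the subset a real standalone lineage? its exclusive carriers
    # (all subset codes, none of the extras) must exceed the coincident
    # error plus full-dropout expectation
    logSub <- NA_real_
    covIx <- coversAll(unique(c(subSet, extras) %/% 4L))
    n <- length(covIx)
    if (n > 0L) {
      excl <- sum(vapply(S[covIx], function(x)
        all(subSet %in% x) && !any(extras %in% x), logical(1L)))
      supSup <- contigSupport(contigs)[[supIx]]
      pDrop <- vapply(extras, function(d) {
        carr <- sum(vapply(S[supSup], function(x) d %in% x, logical(1L)))
        max(1 - carr / max(length(supSup), 1L), 1e-3)
      }, numeric(1L))
      rate0 <- prod(p0of(subSet)) + (length(supSup) / n) * prod(pDrop)
      rate0 <- min(max(rate0, 1e-12), 1 - 1e-9)
      logSub <- bfSnvFrequency(excl, n, rate0, log = TRUE)
    }
    # is the superset real? every extra code must ride above the error
    # rate among unselected carriers of the shared codes
    base <- carriersOf(subSet)
    per <- vapply(extras, function(d) {
      k <- d %/% 4L
      cov <- base[b[base] <= k & ee[base] >= k]
      if (length(cov) == 0L) return(NA_real_)
      t <- sum(vapply(S[cov], function(x) d %in% x, logical(1L)))
      bfSnvFrequency(t, length(cov), p0of(d), log = TRUE)
    }, numeric(1L))
    per <- per[!is.na(per)]
    logSup <- if (length(per)) min(per) else NA_real_
    cand <- c(logSub, logSup)
    who <- c(subIx, supIx)
    ok <- !is.na(cand)
    if (any(ok)) {
      logBF <- min(cand[ok])
      suspect <- who[ok][which.min(cand[ok])]
    }
  }
  if (is.null(logBF)) {
    # conflicting consensus claims: contrast support carrier rates
    diffCodes <- unique(c(setdiff(sh, sl), setdiff(sl, sh)))
    supI <- contigSupport(contigs)[[i]]
    supJ <- contigSupport(contigs)[[j]]
    logBF <- 0
    for (cd in diffCodes) {
      k <- cd %/% 4L
      covI <- supI[b[supI] <= k & ee[supI] >= k]
      covJ <- supJ[b[supJ] <= k & ee[supJ] >= k]
      na <- length(covI); nb <- length(covJ)
      if (na == 0L || nb == 0L) next
      ta <- sum(vapply(S[covI], function(x) cd %in% x, logical(1L)))
      tb <- sum(vapply(S[covJ], function(x) cd %in% x, logical(1L)))
      logDiff <- -log(na + 1) - log(nb + 1)
      logSame <- lchoose(na, ta) + lchoose(nb, tb) +
        lbeta(ta + tb + 1, na + nb - ta - tb + 1)
      logBF <- logBF + (logDiff - logSame)
    }
  }
  out <- if (log) logBF else exp(logBF)
  attr(out, "suspect") <- suspect
  out
}

#' Two-step Bayes-factor screen of draft contigs
#'
#' Step 1 removes a contig when any of its SNV frequencies fails the
#' [bfSnvFrequency()] test against the context-predicted error rate *and*
#' its SNVs test independent ([bfSnvDependence()]). The frequency of an SNV
#' in a contig is its carrier count among the contig's supporting reads over
#' the total coverage of the locus, so a contig whose support merely
#' collects the expected sequencing errors at one locus is not significant;
#' the dependence test uses dataset-wide co-occurrence, so genuinely linked
#' SNVs rescue low-frequency contigs. A single-SNV contig has no
#' co-occurrence evidence and counts as independent. Step 2 compares the
#' survivors pairwise (overlapping pairs only) and drops the lower-abundance
#' member when the pair is not significantly different
#' ([bfContigPairDifference()]).
#'
#' @param contigs a [ContigSet-class] of draft contigs.
#' @param reads restricted [EncodedReadSet-class].
#' @param p0 context-predicted error rate per SNV code: a named numeric
#'   vector (names = codes) or a single rate.
#' @param bfThreshold Bayes-factor threshold (10).
#' @return The filtered [ContigSet-class].
#' @export
filterDraftContigs <- function(contigs, reads, p0, bfThreshold = 10) {
  n <- length(contigs)
  if (n == 0L) return(contigs)
  S <- readSubs(reads); b <- readStarts(reads); e <- readEnds(reads)
  p0of <- function(code) {
    if (length(p0) == 1L && is.null(names(p0))) return(as.numeric(p0))
    v <- p0[as.character(code)]
    if (any(is.na(v))) stop("no p0 supplied for code ", code[is.na(v)][1L])
    as.numeric(v)
  }
  coverCount <- function(k) sum(b <= k & e >= k)
  keep <- rep(TRUE, n)
  for (ci in seq_len(n)) {
    codes <- contigSnvs(contigs)[[ci]]
    sup <- contigSupport(contigs)[[ci]]
    tt <- vapply(codes, function(code)
      sum(vapply(S[sup], function(x) code %in% x, logical(1L))), numeric(1L))
    nn <- vapply(codes %/% 4L, coverCount, numeric(1L))
    ok <- nn > 0
    sig <- rep(FALSE, length(codes))
    sig[ok] <- bfSnvFrequency(tt[ok], nn[ok], p0of(codes[ok]),
                              log = TRUE) > log(bfThreshold)
    independent <- TRUE
    if (length(codes) > 1L) {
      loci <- codes %/% 4L
      covAll <- rep(TRUE, length(S))
      for (k in loci) covAll <- covAll & b <= k & e >= k
      nJoint <- sum(covAll)
      if (nJoint > 0L && all(ok)) {
        tJoint <- sum(vapply(which(covAll),
                             function(ix) all(codes %in% S[[ix]]),
                             logical(1L)))
        tGlob <- vapply(codes, function(code)
          sum(vapply(S, function(x) code %in% x, logical(1L))), numeric(1L))
        q <- prod(tGlob / nn)
        independent <- bfSnvDependence(tJoint, nJoint, q,
                                       log = TRUE) <= log(bfThreshold)
      }
    }
    if (any(!sig) && independent) keep[ci] <- FALSE
  }
  contigs <- contigs[keep]
  n <- length(contigs)
  if (n <= 1L) return(contigs)
  # step 2: pairwise, higher abundance wins ties
  ord <- order(-contigAbundance(contigs), seq_len(n))
  alive <- rep(TRUE, n)
  for (a in seq_len(n - 1L)) {
    for (bIx in (a + 1L):n) {
      ci <- ord[a]; cj <- ord[bIx]
      if (!alive[ci] || !alive[cj]) next
      mb <- max(contigStarts(contigs)[ci], contigStarts(contigs)[cj])
      me <- min(contigEnds(contigs)[ci], contigEnds(contigs)[cj])
      if (me < mb) next
      bf <- bfContigPairDifference(contigs, ci, cj, reads, p0 = p0,
                                   log = TRUE)
      if (as.numeric(bf) <= log(bfThreshold)) {
        suspect <- attr(bf, "suspect")
        if (is.null(suspect)) suspect <- cj
        alive[suspect] <- FALSE
      }
    }
  }
  contigs[alive]
}

# consensus codes of a contig restricted to a locus window
snvsInWindow <- function(codes, mb, me) {
  sort(codes[codes %/% 4L >= mb & codes %/% 4L <= me])
}

#' Build the overlap graph over draft contigs
#'
#' Edge i -> j when (1) the contigs carry identical SNV sets in their
#' overlapped region, (2) the shared SNVs exceed 50% of either contig's SNV
#' count or the overlap exceeds 50% of either contig's length, and (3)
#' `end(i) < end(j)` (strict, which makes the graph acyclic).
#'
#' @param contigs a [ContigSet-class].
#' @return An [OverlapGraph-class].
#' @export
buildOverlapGraph <- function(contigs) {
  n <- length(contigs)
  s <- contigStarts(contigs); e <- contigEnds(contigs)
  snv <- contigSnvs(contigs)
  from <- integer(); to <- integer()
  if (n > 1L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || e[i] >= e[j]) next
        mb <- max(s[i], s[j]); me <- min(e[i], e[j])
        if (me < mb) next
        wi <- snvsInWindow(snv[[i]], mb, me)
        wj <- snvsInWindow(snv[[j]], mb, me)
        if (!identical(wi, wj)) next
        shared <- length(intersect(snv[[i]], snv[[j]]))
        ovLen <- me - mb + 1L
        li <- e[i] - s[i] + 1L; lj <- e[j] - s[j] + 1L
        if (shared > 0.5 * length(snv[[i]]) ||
            shared > 0.5 * length(snv[[j]]) ||
            ovLen > 0.5 * li || ovLen > 0.5 * lj) {
          from <- c(from, i); to <- c(to, j)
        }
      }
    }
  }
  new("OverlapGraph", contigs = contigs,
      edges = cbind(from = from, to = to))
}

# descendant reachability (list of reachable vertex sets) on a DAG
reachableSets <- function(n, edges) {
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(n)))
  memo <- vector("list", n)
  visit <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    memo[[v]] <<- integer()  # cycle guard
    out <- integer()
    for (w in adj[[v]]) out <- union(out, c(w, visit(w)))
    memo[[v]] <<- out
    out
  }
  for (v in seq_len(n)) visit(v)
  memo
}

#' Transitive reduction of the overlap graph
#'
#' Removes every edge whose endpoints stay connected through a longer path;
#' reachability is preserved exactly.
#'
#' @param g an [OverlapGraph-class] (acyclic).
#' @return The reduced [OverlapGraph-class].
#' @export
transitiveReduce <- function(g) {
  n <- length(g@contigs)
  edges <- g@edges
  if (nrow(edges) == 0L) return(g)
  ends <- contigEnds(g@contigs)
  if (any(ends[edges[, 1L]] >= ends[edges[, 2L]]))
    stop("cycle detected: edge against the end-coordinate order")
  reach <- reachableSets(n, edges)
  keep <- rep(TRUE, nrow(edges))
  for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1L]; v <- edges[r, 2L]
    others <- edges[edges[, 1L] == u & edges[, 2L] != v, 2L]
    if (any(vapply(others, function(w) v %in% reach[[w]], logical(1L))))
      keep[r] <- FALSE
  }
  new("OverlapGraph", contigs = g@contigs,
      edges = g@edges[keep, , drop = FALSE])
}

#' Assemble contigs along unambiguous paths
#'
#' A path starts at a vertex whose in-degree is not 1 (or whose unique
#' parent branches) and extends through vertices with in- and out-degree 1,
#' stopping before any vertex with several parents. Draft contigs along a
#' path are concatenated: union interval, union SNV set (consistent by the
#' edge criteria), union support.
#'
#' @param g a transitively reduced [OverlapGraph-class].
#' @return A [ContigSet-class] of assembled contigs.
#' @export
assemblePaths <- function(g) {
  contigs <- g@contigs
  n <- length(contigs)
  if (n == 0L) return(contigs)
  edges <- g@edges
  indeg <- tabulate(edges[, 2L], nbins = n)
  outdeg <- tabulate(edges[, 1L], nbins = n)
  childOf <- function(v) edges[edges[, 1L] == v, 2L]
  parentOf <- function(v) edges[edges[, 2L] == v, 1L]
  starts <- which(indeg != 1L)
  branched <- which(vapply(seq_len(n), function(v)
    indeg[v] == 1L && outdeg[parentOf(v)] > 1L, logical(1L)))
  starts <- sort(union(starts, branched))
  paths <- list()
  for (st in starts) {
    path <- st
    cur <- st
    while (outdeg[cur] == 1L) {
      ch <- childOf(cur)
      if (indeg[ch] != 1L) break
      path <- c(path, ch)
      cur <- ch
    }
    paths[[length(paths) + 1L]] <- path
  }
  contigSet(
    start = vapply(paths, function(p) min(contigStarts(contigs)[p]),
                   integer(1L)),
    end = vapply(paths, function(p) max(contigEnds(contigs)[p]),
                 integer(1L)),
    snvs = lapply(paths, function(p)
      sort(unique(unlist(contigSnvs(contigs)[p])))),
    support = lapply(paths, function(p)
      sort(unique(unlist(contigSupport(contigs)[p])))),
    abundance = vapply(paths, function(p)
      sum(contigAbundance(contigs)[p]), integer(1L)))
}

# Jaccard of two contigs' SNV sets inside a locus window; NA when neither
# carries an SNV there
windowJaccard <- function(ci, cj, mb, me) {
  wi <- snvsInWindow(ci, mb, me)
  wj <- snvsInWindow(cj, mb, me)
  u <- union(wi, wj)
  if (length(u) == 0L) return(NA_real_)
  length(intersect(wi, wj)) / length(u)
}

#' Merge redundant contigs
#'
#' First removes contigs fully contained in a longer contig when their SNV
#' Jaccard in the contained interval exceeds `jaccardMin`; then connects
#' overlapping contigs whose overlap-region Jaccard exceeds `jaccardMin`
#' (union interval; conflicting calls resolved toward the higher-abundance
#' contig).
#'
#' @param contigs a [ContigSet-class].
#' @param jaccardMin similarity threshold (0.9).
#' @return The merged [ContigSet-class].
#' @export
mergeRedundantContigs <- function(contigs, jaccardMin = 0.9) {
  repeat {
    n <- length(contigs)
    if (n <= 1L) return(contigs)
    s <- contigStarts(contigs); e <- contigEnds(contigs)
    snv <- contigSnvs(contigs); ab <- contigAbundance(contigs)
    drop <- NA_integer_
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        contained <- s[j] <= s[i] && e[i] <= e[j] &&
          (e[j] - s[j]) > (e[i] - s[i])
        if (!contained) next
        jc <- windowJaccard(snv[[i]], snv[[j]], s[i], e[i])
        if (!is.na(jc) && jc > jaccardMin) { drop <- i; break }
      }
      if (!is.na(drop)) break
    }
    if (is.na(drop)) break
    contigs <- contigs[-drop]
  }
  repeat {
    n <- length(contigs)
    if (n <= 1L) return(contigs)
    s <- contigStarts(contigs); e <- contigEnds(contigs)
    snv <- contigSnvs(contigs); ab <- contigAbundance(contigs)
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        mb <- max(s[i], s[j]); me <- min(e[i], e[j])
        if (me < mb) next
        jc <- windowJaccard(snv[[i]], snv[[j]], mb, me)
        if (is.na(jc) || jc <= jaccardMin) next
        hi <- if (ab[i] >= ab[j]) i else j
        lo <- if (hi == i) j else i
        keepCodes <- snv[[hi]]
        addCodes <- snv[[lo]][!(snv[[lo]] %/% 4L) %in% (keepCodes %/% 4L)]
        newSnvs <- sort(c(keepCodes, addCodes))
        sup <- sort(unique(c(contigSupport(contigs)[[i]],
                             contigSupport(contigs)[[j]])))
        keep <- setdiff(seq_len(n), c(i, j))
        contigs <- contigSet(
          start = c(s[keep], min(s[i], s[j])),
          end = c(e[keep], max(e[i], e[j])),
          snvs = c(snv[keep], list(newSnvs)),
          abundance = c(ab[keep], ab[i] + ab[j]),
          support = c(contigSupport(contigs)[keep], list(sup)))
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  contigs
}

#' Divergence between two overlapping contigs
#'
#' Number of SNV differences in the overlapped region divided by the
#' overlap length in bases — the resolution at which two strains can be
#' told apart.
#'
#' @param contigs a [ContigSet-class].
#' @param i,j contig indices (must overlap).
#' @return Fraction of differing loci per overlapped base.
#' @export
contigDivergence <- function(contigs, i, j) {
  s <- contigStarts(contigs); e <- contigEnds(contigs)
  mb <- max(s[i], s[j]); me <- min(e[i], e[j])
  if (me < mb) stop("undefined: contigs do not overlap")
  wi <- snvsInWindow(contigSnvs(contigs)[[i]], mb, me)
  wj <- snvsInWindow(contigSnvs(contigs)[[j]], mb, me)
  nDiff <- length(unique(c(setdiff(wi, wj), setdiff(wj, wi)) %/% 4L))
  nDiff / (me - mb + 1L)
}
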