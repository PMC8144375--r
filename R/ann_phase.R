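#' Phasing parameters for adaptive-nearest-neighbour clustering
#'
#' @param platform `"pacbio"` or `"ont"`; sets the default homogeneity
#'   limit `pLim` (0.2 PacBio, 0.3 ONT).
#' @param pLim homogeneity limit: a locus is homogeneous when every
#'   alternative-base rate lies in `[0, pLim]` or `[1 - pLim, 1]`.
#' @param q neighbourhood size: number of most-similar reads clustered with
#'   each seed.
#' @param minCov clustering stops (without a contig) once the best-covered
#'   locus drops below this (10).
#' @param assignJaccardMin reads whose best contig Jaccard is below this are
#'   assigned to the reference (0.5).
#' @return Named list of class `PhasingParams`.
#' @export
phasingParams <- function(platform = c("pacbio", "ont"), pLim = NULL,
                          q = 100L, minCov = 10L, assignJaccardMin = 0.5) {
  platform <- match.arg(platform)
  if (is.null(pLim)) pLim <- if (platform == "pacbio") 0.2 else 0.3
  stopifnot(pLim > 0, pLim < 0.5, minCov >= 1, q >= 1)
  structure(list(platform = platform, pLim = pLim, q = as.integer(q),
                 minCov = as.integer(minCov),
                 assignJaccardMin = assignJaccardMin),
            class = "PhasingParams")
}

#' Restrict reads to detected SNVs
#'
#' Keeps only detected substitution codes in each read's set (the phasing
#' representation); intervals and masks are unchanged.
#'
#' @param reads an [EncodedReadSet-class].
#' @param detectedCodes detected substitution codes.
#' @return An [EncodedReadSet-class] with `S` replaced by
#'   `S` intersect `detectedCodes`.
#' @export
restrictReads <- function(reads, detectedCodes) {
  detectedCodes <- as.integer(detectedCodes)
  encodedReadSet(readStarts(reads), readEnds(reads),
                 lapply(readSubs(reads), intersect, y = detectedCodes),
                 readId = readIds(reads), masked = readMasked(reads),
                 deleted = reads@deleted)
}

#' Build the per-read base record at detected loci
#'
#' Matrix with one row per read and one column per detected locus: the
#' detected alternative-base index (1-4) when the read carries a detected
#' code there, 0 when its base matches the reference, `NA` when the read
#' does not cover the locus, is masked/deleted there, or carries an
#' undetected alternative.
#'
#' @param reads realigned [EncodedReadSet-class] (full substitution sets).
#' @param detectedCodes detected substitution codes.
#' @return list with the restricted `reads`, sorted detected `loci`, and the
#'   base record matrix `mat`.
#' @export
buildPhasingData <- function(reads, detectedCodes) {
  detectedCodes <- sort(unique(as.integer(detectedCodes)))
  loci <- sort(unique(detectedCodes %/% 4L))
  restricted <- restrictReads(reads, detectedCodes)
  m <- length(reads)
  mat <- matrix(NA_integer_, nrow = m, ncol = length(loci))
  b <- readStarts(reads); e <- readEnds(reads)
  S <- readSubs(reads); M <- readMasked(reads); D <- reads@deleted
  Sr <- readSubs(restricted)
  for (i in seq_len(m)) {
    cols <- which(loci >= b[i] & loci <= e[i])
    if (length(cols) == 0L) next
    v <- integer(length(cols))  # default: reference match
    lk <- loci[cols]
    v[lk %in% (S[[i]] %/% 4L)] <- NA_integer_  # some alternative base
    det <- Sr[[i]]
    if (length(det)) {
      hit <- match(det %/% 4L, lk)
      v[hit[!is.na(hit)]] <- det[!is.na(hit)] %% 4L + 1L
    }
    v[lk %in% M[[i]] | lk %in% D[[i]]] <- NA_integer_
    mat[i, cols] <- v
  }
  list(reads = restricted, loci = loci, mat = mat)
}

#' Homogeneity of a detected locus within a read cluster
#'
#' For each alternative base, its rate is its carrier count over the total
#' number of substitution carriers plus reference-matching reads at the
#' locus. The locus is homogeneous when every alternative rate lies in
#' `[0, pLim]` union `[1 - pLim, 1]`.
#'
#' @param phasing output of [buildPhasingData()].
#' @param cluster read indices forming the cluster.
#' @param locus 0-based detected locus.
#' @param pLim homogeneity limit.
#' @return list with per-alternative `rates` (named A/C/G/T) and
#'   `homogeneous`; errors when no cluster read is informative at the locus.
#' @export
locusHomogeneity <- function(phasing, cluster, locus, pLim = 0.2) {
  col <- match(locus, phasing$loci)
  if (is.na(col)) stop("locus ", locus, " is not a detected locus")
  v <- phasing$mat[cluster, col]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("undefined: no informative read at locus ", locus)
  altCounts <- tabulate(v[v > 0L], nbins = 4L)
  den <- sum(altCounts) + sum(v == 0L)
  rates <- setNames(altCounts / den, BASES)
  list(rates = rates,
       homogeneous = all(rates <= pLim | rates >= 1 - pLim))
}

# counts-based homogeneity over a set of loci columns; cnt is 5 x nLoci
# (row 1 = reference matches, rows 2-5 = alternatives A/C/G/T)
allHomogeneous <- function(cnt, pLim) {
  den <- colSums(cnt)
  use <- den > 0
  if (!any(use)) return(TRUE)
  r <- sweep(cnt[-1L, use, drop = FALSE], 2L, den[use], "/")
  all(r <= pLim | r >= 1 - pLim)
}

#' Adaptive-nearest-neighbour clustering around a seed read
#'
#' The seed's `q` most-similar reads (modified Jaccard on the restricted
#' substitution sets) form the initial cluster; the most dissimilar member
#' is discarded until every detected locus covered by the seed is
#' homogeneous, or until the best-covered locus falls below `minCov` (then
#' no contig is produced). On success the consensus (alternatives at rate at
#' least `1 - pLim`) over the seed's interval becomes a draft contig.
#'
#' @param phasing output of [buildPhasingData()].
#' @param seed seed read index.
#' @param params a [phasingParams()] list.
#' @param jaccardRow optional precomputed similarity of the seed to every
#'   read.
#' @return list with `start`, `end`, `snvs`, `support` — or `NULL`.
#' @export
annCluster <- function(phasing, seed, params = phasingParams(),
                       jaccardRow = NULL) {
  reads <- phasing$reads
  if (length(readSubs(reads)[[seed]]) == 0L) return(NULL)
  b <- readStarts(reads); e <- readEnds(reads)
  if (is.null(jaccardRow)) {
    jaccardRow <- vapply(seq_along(b), function(j)
      if (j == seed) NA_real_
      else cpp_read_jaccard(readSubs(reads)[[seed]], readSubs(reads)[[j]],
                            b[seed], e[seed], b[j], e[j], 0.5),
      numeric(1L))
  }
  others <- setdiff(seq_along(b), seed)
  ord <- others[order(-jaccardRow[others], others)]
  cluster <- c(seed, head(ord, params$q))
  cols <- which(phasing$loci >= b[seed] & phasing$loci <= e[seed])
  if (length(cols) == 0L) return(NULL)
  # counts: reference matches + four alternatives per locus
  sub <- phasing$mat[cluster, cols, drop = FALSE]
  cnt <- vapply(seq_along(cols), function(j) {
    v <- sub[, j]
    c(sum(v == 0L, na.rm = TRUE), tabulate(v[!is.na(v) & v > 0L], 4L))
  }, numeric(5L))
  cnt <- matrix(cnt, nrow = 5L)
  covCnt <- vapply(phasing$loci[cols], function(k)
    sum(b[cluster] <= k & e[cluster] >= k), integer(1L))
  repeat {
    if (allHomogeneous(cnt, params$pLim)) break
    if (length(cluster) <= 1L) return(NULL)
    dropId <- cluster[length(cluster)]  # most dissimilar (ties: later read)
    row <- phasing$mat[dropId, cols]
    upd <- which(!is.na(row))
    for (j in upd) cnt[row[j] + 1L, j] <- cnt[row[j] + 1L, j] - 1L
    covK <- phasing$loci[cols] >= b[dropId] & phasing$loci[cols] <= e[dropId]
    covCnt[covK] <- covCnt[covK] - 1L
    cluster <- cluster[-length(cluster)]
    if (max(covCnt) < params$minCov) return(NULL)
  }
  if (max(covCnt) < params$minCov) return(NULL)
  den <- colSums(cnt)
  snvs <- integer()
  for (j in seq_along(cols)) {
    if (den[j] == 0L) next
    r <- cnt[2:5, j] / den[j]
    d <- which(r >= 1 - params$pLim)
    if (length(d))
      snvs <- c(snvs, 4L * phasing$loci[cols[j]] + (d[1L] - 1L))
  }
  if (length(snvs) == 0L) return(NULL)  # no reference-only contigs
  list(start = b[seed], end = e[seed], snvs = sort(snvs), support = cluster)
}

#' Phase reads into draft contigs
#'
#' Runs [annCluster()] with every read as seed and deduplicates identical
#' draft contigs (same interval and SNV set), keeping the highest-abundance
#' instance.
#'
#' @param reads realigned [EncodedReadSet-class].
#' @param detectedCodes detected substitution codes.
#' @param params a [phasingParams()] list.
#' @return A [ContigSet-class] of draft contigs.
#' @export
annPhase <- function(reads, detectedCodes, params = phasingParams()) {
  phasing <- buildPhasingData(reads, detectedCodes)
  restricted <- phasing$reads
  jm <- cpp_jaccard_matrix(readSubs(restricted), readStarts(restricted),
                           readEnds(restricted), 0.5)
  diag(jm) <- NA_real_
  drafts <- list()
  for (seed in seq_along(readSubs(restricted))) {
    d <- annCluster(phasing, seed, params, jaccardRow = jm[seed, ])
    if (!is.null(d)) drafts[[length(drafts) + 1L]] <- d
  }
  if (length(drafts) == 0L) return(contigSet())
  key <- vapply(drafts, function(d)
    paste(d$start, d$end, paste(d$snvs, collapse = ","), sep = ":"),
    character(1L))
  ab <- vapply(drafts, function(d) length(d$support), integer(1L))
  keep <- vapply(split(seq_along(drafts), key), function(ix)
    ix[which.max(ab[ix])], integer(1L))
  keep <- sort(unname(keep))
  contigSet(start = vapply(drafts[keep], `[[`, integer(1L), "start"),
            end = vapply(drafts[keep], `[[`, integer(1L), "end"),
            snvs = lapply(drafts[keep], `[[`, "snvs"),
            support = lapply(drafts[keep], `[[`, "support"))
}

#' Assign reads to contigs
#'
#' Each read goes to the contig with the largest modified Jaccard between
#' the read's restricted substitution set and the contig's consensus set
#' (no minimal-overlap requirement); reads whose best similarity is below
#' `assignJaccardMin` go to the reference (0). Ties pick the lower contig
#' index. Contig abundances are updated to the assigned-read counts.
#'
#' @param reads restricted [EncodedReadSet-class] (e.g.
#'   `buildPhasingData()$reads`).
#' @param contigs a [ContigSet-class].
#' @param assignJaccardMin reference-assignment threshold (0.5).
#' @return list with `assignment` (contig index per read, 0 = reference)
#'   and the updated `contigs`.
#' @export
assignReads <- function(reads, contigs, assignJaccardMin = 0.5) {
  m <- length(reads)
  n <- length(contigs)
  assignment <- integer(m)
  if (n > 0L && m > 0L) {
    b <- readStarts(reads); e <- readEnds(reads); S <- readSubs(reads)
    cs <- contigStarts(contigs); ce <- contigEnds(contigs)
    cv <- contigSnvs(contigs)
    for (i in seq_len(m)) {
      jac <- vapply(seq_len(n), function(cix)
        cpp_read_jaccard(S[[i]], cv[[cix]], b[i], e[i], cs[cix], ce[cix], 0),
        numeric(1L))
      best <- which.max(jac)
      if (length(best) && jac[best] >= assignJaccardMin)
        assignment[i] <- best
    }
  }
  newAb <- tabulate(assignment[assignment > 0L], nbins = n)
  out <- contigs
  out@abundance <- as.integer(newAb)
  out@support <- split(seq_len(m), factor(assignment,
                                          levels = seq_len(n)))
  out@support <- lapply(out@support, as.integer)
  list(assignment = assignment, contigs = out)
}
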