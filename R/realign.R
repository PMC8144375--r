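#' Alignment scoring scheme for local realignment
#'
#' Match 2, mismatch -4, gap open -4, gap extension -2; a column containing
#' an N (ambiguous or QV-masked base) scores 0. A gap of length L costs
#' `gapOpen + (L - 1) * gapExtend`.
#'
#' @param match,mismatch,gapOpen,gapExtend,neutral scores.
#' @return Named list of class `AlignScores`.
#' @export
alignScores <- function(match = 2, mismatch = -4, gapOpen = -4,
                        gapExtend = -2, neutral = 0) {
  stopifnot(match > 0, gapExtend < 0)
  structure(list(match = match, mismatch = mismatch, gapOpen = gapOpen,
                 gapExtend = gapExtend, neutral = neutral),
            class = "AlignScores")
}

#' Smith-Waterman local alignment score
#'
#' Standard local alignment with affine gaps and the neutral-base rule
#' (columns containing N score `neutral`).
#'
#' @param query,target DNA strings.
#' @param scores an [alignScores()] list.
#' @return list with `score` and the 1-based aligned span (`queryStart`,
#'   `queryEnd`, `targetStart`, `targetEnd`).
#' @examples
#' smithWaterman("ACGTT", "ACGTT")$score  # 10
#' @export
smithWaterman <- function(query, target, scores = alignScores()) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  cpp_smith_waterman(toupper(query), toupper(target), scores$match,
                     scores$mismatch, scores$gapOpen, scores$gapExtend,
                     scores$neutral)
}

#' Realignment window around a detected SNV
#'
#' The window spans 21 homopolymer runs centred on the run containing the
#' locus, clipped (asymmetrically) at the genome ends.
#'
#' @param ref a [ReferenceGenome-class].
#' @param k 0-based locus.
#' @param nRuns number of runs in the window (odd).
#' @return list with 0-based `start`, `end` (inclusive) and the reference
#'   `seq` of the window.
#' @export
realignWindow <- function(ref, k, nRuns = 21L) {
  runs <- homopolymerRuns(ref)
  ri <- runIndex(ref)
  if (k < 0L || k >= refLength(ref)) stop("invalid locus: ", k)
  r <- ri[k + 1L] + 1L
  half <- (nRuns - 1L) %/% 2L
  lo <- max(1L, r - half)
  hi <- min(nrow(runs), r + half)
  start <- runs$start[lo]
  end <- runs$start[hi] + runs$length[hi] - 1L
  list(start = start, end = end,
       seq = substr(refSequence(ref), start + 1L, end + 1L))
}

#' Reconstruct read sequences from encoded reads
#'
#' Applies each read's substitution codes to the reference slice; masked and
#' deleted loci become N. Exact for indel-free alignments, which is what the
#' simulator produces.
#'
#' @param reads an [EncodedReadSet-class].
#' @param ref a [ReferenceGenome-class].
#' @return Character vector of read sequences (over each read's `[b, e]`).
#' @export
reconstructReadSeqs <- function(reads, ref) {
  refSeq <- strsplit(refSequence(ref), "")[[1L]]
  b <- readStarts(reads); e <- readEnds(reads)
  S <- readSubs(reads); M <- readMasked(reads); D <- reads@deleted
  vapply(seq_along(b), function(i) {
    ch <- refSeq[(b[i] + 1L):(e[i] + 1L)]
    s <- S[[i]]
    if (length(s)) ch[s %/% 4L - b[i] + 1L] <- BASES[s %% 4L + 1L]
    if (length(M[[i]])) ch[M[[i]] - b[i] + 1L] <- "N"
    if (length(D[[i]])) ch[D[[i]] - b[i] + 1L] <- "N"
    paste(ch, collapse = "")
  }, character(1L))
}

#' Realign one read segment at a detected SNV locus
#'
#' The read segment over the realignment window is aligned to four copies of
#' the window reference, each carrying A, C, G or T at the SNV locus. The
#' modified base of the best-scoring reference becomes the read's call at
#' the locus; a best base equal to the reference (ties resolved in favour of
#' the reference, then alphabetically) yields no code.
#'
#' @param readSeq read bases over `[readStart, readEnd]` (masked bases as
#'   N).
#' @param readStart,readEnd 0-based read interval.
#' @param ref a [ReferenceGenome-class].
#' @param k 0-based detected-SNV locus.
#' @param scores an [alignScores()] list.
#' @param nRuns window size in homopolymer runs.
#' @return Substitution code, or `NA_integer_` for a reference call; `NA`
#'   also when the read does not cover `k`.
#' @export
realignReadAtLocus <- function(readSeq, readStart, readEnd, ref, k,
                               scores = alignScores(), nRuns = 21L) {
  if (readStart > k || readEnd < k) return(NA_integer_)
  win <- realignWindow(ref, k, nRuns)
  segStart <- max(win$start, readStart)
  segEnd <- min(win$end, readEnd)
  if (segStart > segEnd) return(NA_integer_)
  seg <- substr(readSeq, segStart - readStart + 1L, segEnd - readStart + 1L)
  targets <- vapply(BASES, function(bse) {
    s <- win$seq
    substr(s, k - win$start + 1L, k - win$start + 1L) <- bse
    s
  }, character(1L))
  sc <- cpp_sw_batch(seg, targets, scores$match, scores$mismatch,
                     scores$gapOpen, scores$gapExtend, scores$neutral)[1L, ]
  refBase <- substr(refSequence(ref), k + 1L, k + 1L)
  bestBases <- BASES[sc == max(sc)]
  if (refBase %in% bestBases) return(NA_integer_)
  4L * k + (match(bestBases[1L], BASES) - 1L)
}

#' Realign reads at all detected SNV loci
#'
#' Re-evaluates every read's base call at each detected SNV locus it covers
#' by local alignment against the four base-modified references, replacing
#' the original calls at those loci. Calls at other loci and the covering
#' intervals are untouched.
#'
#' @param reads an [EncodedReadSet-class].
#' @param ref a [ReferenceGenome-class].
#' @param detectedLoci 0-based loci of detected SNVs.
#' @param scores an [alignScores()] list.
#' @param readSeqs optional read sequences (reconstructed when `NULL`).
#' @param nRuns window size in homopolymer runs.
#' @return The realigned [EncodedReadSet-class].
#' @export
realignReads <- function(reads, ref, detectedLoci, scores = alignScores(),
                         readSeqs = NULL, nRuns = 21L) {
  if (length(detectedLoci) == 0L) return(reads)
  if (is.null(readSeqs)) readSeqs <- reconstructReadSeqs(reads, ref)
  detectedLoci <- sort(unique(as.integer(detectedLoci)))
  b <- readStarts(reads); e <- readEnds(reads)
  S <- readSubs(reads)
  refSeqCh <- strsplit(refSequence(ref), "")[[1L]]
  newCall <- matrix(NA_integer_, nrow = length(reads),
                    ncol = length(detectedLoci))
  for (li in seq_along(detectedLoci)) {
    k <- detectedLoci[li]
    win <- realignWindow(ref, k, nRuns)
    targets <- vapply(BASES, function(bse) {
      s <- win$seq
      substr(s, k - win$start + 1L, k - win$start + 1L) <- bse
      s
    }, character(1L))
    cov <- which(b <= k & e >= k)
    if (length(cov) == 0L) next
    segs <- vapply(cov, function(i) {
      s0 <- max(win$start, b[i]); s1 <- min(win$end, e[i])
      substr(readSeqs[i], s0 - b[i] + 1L, s1 - b[i] + 1L)
    }, character(1L))
    ok <- nchar(segs) > 0L
    if (!any(ok)) next
    sc <- cpp_sw_batch(segs[ok], targets, scores$match, scores$mismatch,
                       scores$gapOpen, scores$gapExtend, scores$neutral)
    refBase <- refSeqCh[k + 1L]
    refCol <- match(refBase, BASES)
    rows <- cov[ok]
    mx <- apply(sc, 1L, max)
    isRef <- !is.na(refCol) & sc[, refCol] == mx
    bestAlt <- apply(sc, 1L, which.max)  # alphabetical tie-break
    call <- ifelse(isRef, NA_integer_, 4L * k + (bestAlt - 1L))
    newCall[rows, li] <- ifelse(is.na(call), -1L, call)  # -1 = explicit ref
  }
  detSet <- 4L * rep(detectedLoci, each = 4L) + 0:3
  for (i in seq_along(S)) {
    upd <- newCall[i, ]
    touched <- which(!is.na(upd))
    if (length(touched) == 0L) next
    drop <- S[[i]] %/% 4L %in% detectedLoci[touched]
    keep <- S[[i]][!drop]
    add <- upd[touched]
    add <- add[add >= 0L]
    S[[i]] <- sort(c(keep, add))
  }
  encodedReadSet(b, e, S, readId = readIds(reads),
                 masked = readMasked(reads), deleted = reads@deleted)
}
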