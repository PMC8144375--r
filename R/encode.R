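#' Encode a substitution as an integer code
#'
#' A read base differing from the reference base at 0-based locus `k` is
#' encoded as `4k + d` with `d` = 0/1/2/3 for alternative base A/C/G/T.
#' A matching base, an N on either side, or a masked base yields no code
#' (`NA`).
#'
#' @param readBase,refBase single characters in A/C/G/T/N.
#' @param k 0-based locus (non-negative).
#' @return Integer code, or `NA_integer_` for the empty case.
#' @examples
#' encodeSubstitution("A", "C", 7)  # 28
#' encodeSubstitution("G", "G", 5)  # NA
#' @export
encodeSubstitution <- function(readBase, refBase, k) {
  if (any(k < 0)) stop("invalid locus: k must be non-negative")
  readBase <- toupper(readBase)
  refBase <- toupper(refBase)
  d <- match(readBase, BASES) - 1L
  out <- ifelse(!is.na(d) & refBase %in% BASES & readBase != refBase,
                4L * as.integer(k) + d, NA_integer_)
  as.integer(out)
}

#' Decode a substitution code
#'
#' @param code integer code(s) `4k + d`.
#' @return data.frame with 0-based `locus` and `altBase`.
#' @export
decodeSubstitution <- function(code) {
  code <- as.integer(code)
  data.frame(locus = code %/% 4L, altBase = BASES[code %% 4L + 1L])
}

#' Maximal homopolymer runs of a sequence
#'
#' Runs tile the sequence; a base with no identical neighbour is a run of
#' length 1.
#'
#' @param sequence DNA string or a [ReferenceGenome-class].
#' @return data.frame with 0-based `start`, `length` and `base`, one row per
#'   run in sequence order.
#' @examples
#' homopolymerRuns("AAACCGT")  # 4 runs
#' @export
homopolymerRuns <- function(sequence) {
  if (is(sequence, "ReferenceGenome")) sequence <- refSequence(sequence)
  if (nchar(sequence) == 0L)
    return(data.frame(start = integer(), length = integer(),
                      base = character()))
  ch <- strsplit(sequence, "")[[1L]]
  r <- rle(ch)
  len <- r$lengths
  data.frame(start = c(0L, cumsum(len)[-length(len)]),
             length = as.integer(len), base = r$values)
}

# 1-per-locus vector mapping each 0-based locus to its 0-based run index
runIndex <- function(ref) {
  runs <- homopolymerRuns(ref)
  rep.int(seq_len(nrow(runs)) - 1L, runs$length)
}

#' Homopolymer distance between two loci
#'
#' The number of homopolymer runs strictly between the run containing `k`
#' and the run containing `g`; 0 when the loci share a run or sit in
#' adjacent runs. Symmetric.
#'
#' @param ref a [ReferenceGenome-class] (or DNA string).
#' @param k,g 0-based loci.
#' @return Non-negative integer.
#' @examples
#' homopolymerDistance(refGenome("AAACCGGTTA"), 0, 8)  # runs 0 and 3 -> 2
#' @export
homopolymerDistance <- function(ref, k, g) {
  if (is.character(ref)) ref <- refGenome(ref)
  L <- refLength(ref)
  if (any(c(k, g) < 0) || any(c(k, g) >= L))
    stop("invalid locus: outside reference")
  ri <- runIndex(ref)
  max(0L, abs(ri[k + 1L] - ri[g + 1L]) - 1L)
}

# -- alignment parsing ------------------------------------------------------

parseCigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  list(len = as.integer(sub("[MIDNSHP=X]", "", ops)),
       op = sub("\\d+", "", ops))
}

#' Encode aligned reads from a SAM/BAM file
#'
#' One [EncodedReadSet-class] entry per mapped primary alignment. Only
#' aligned-match columns (CIGAR M/=/X) can produce substitution codes;
#' insertions produce nothing; deletions keep the locus inside `[b, e]` but
#' contribute neither a code nor a reference match. Bases with quality value
#' below `qvMaskThreshold` are masked: they count toward coverage only.
#'
#' @param file SAM or BAM file aligned to `ref` (SAM is converted on the
#'   fly).
#' @param ref a [ReferenceGenome-class].
#' @param qvMaskThreshold integer; bases with QV strictly below this are
#'   masked (0 disables masking).
#' @return An [EncodedReadSet-class]; the number of skipped
#'   unmapped/secondary/supplementary records is attached as attribute
#'   `"skipped"`.
#' @export
encodeAlignments <- function(file, ref, qvMaskThreshold = 0L) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file,
                            destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- file
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(rec$qname)
  keep <- !is.na(rec$pos) &
    bitwAnd(rec$flag, 4L) == 0L &      # unmapped
    bitwAnd(rec$flag, 256L) == 0L &    # secondary
    bitwAnd(rec$flag, 2048L) == 0L     # supplementary
  skipped <- sum(!keep)
  refSeq <- strsplit(refSequence(ref), "")[[1L]]
  ids <- character(); bs <- integer(); es <- integer()
  subs <- list(); masked <- list(); deleted <- list()
  for (i in which(keep)) {
    cg <- parseCigar(rec$cigar[i])
    seqc <- strsplit(as.character(rec$seq[[i]]), "")[[1L]]
    qual <- as.integer(charToRaw(as.character(rec$qual[[i]]))) - 33L
    if (sum(cg$len[cg$op %in% c("M", "=", "X", "I", "S")]) != length(seqc))
      stop("malformed record: CIGAR/sequence length mismatch for ",
           rec$qname[i])
    rp <- rec$pos[i] - 1L  # 0-based reference cursor
    qp <- 0L               # 0-based query cursor
    b <- rp
    s <- integer(); mk <- integer(); del <- integer()
    for (t in seq_along(cg$op)) {
      op <- cg$op[t]; len <- cg$len[t]
      if (op %in% c("M", "=", "X")) {
        loci <- rp + seq_len(len) - 1L
        qidx <- qp + seq_len(len)
        rb <- seqc[qidx]
        tb <- refSeq[loci + 1L]
        qv <- qual[qidx]
        low <- qvMaskThreshold > 0L & qv < qvMaskThreshold
        mk <- c(mk, loci[low])
        mism <- !low & rb != tb & rb %in% BASES & tb %in% BASES
        if (any(mism))
          s <- c(s, 4L * loci[mism] + (match(rb[mism], BASES) - 1L))
        rp <- rp + len; qp <- qp + len
      } else if (op == "D" || op == "N") {
        del <- c(del, rp + seq_len(len) - 1L)
        rp <- rp + len
      } else if (op %in% c("I", "S")) {
        qp <- qp + len
      } # H, P consume nothing
    }
    ids <- c(ids, rec$qname[i]); bs <- c(bs, b); es <- c(es, rp - 1L)
    subs <- c(subs, list(s)); masked <- c(masked, list(mk))
    deleted <- c(deleted, list(del))
  }
  out <- encodedReadSet(bs, es, subs, readId = ids, masked = masked,
                        deleted = deleted)
  attr(out, "skipped") <- skipped
  out
}

#' Per-locus pileup summary
#'
#' For every reference locus: coverage `depth`, carrier counts of the four
#' alternative bases, reads matching the reference, masked bases and
#' deletions. Masked and deleted bases count toward `depth` but toward
#' neither the carrier nor the reference tally (flip with
#' `maskedInDepth = FALSE` to drop masked bases from `depth` as well).
#'
#' @param reads an [EncodedReadSet-class].
#' @param ref a [ReferenceGenome-class].
#' @param maskedInDepth logical; keep masked bases in the denominator.
#' @return data.frame with columns `locus` (0-based), `pos` (1-based),
#'   `depth`, `A`, `C`, `G`, `T` (alternative-base carrier counts),
#'   `refCount`, `maskedCount`, `deletedCount`.
#' @export
pileupTable <- function(reads, ref, maskedInDepth = TRUE) {
  L <- refLength(ref)
  cov <- integer(L + 1L)
  b <- pmax(readStarts(reads), 0L)
  e <- pmin(readEnds(reads), L - 1L)
  for (i in seq_along(b)) {
    if (b[i] <= e[i]) {
      cov[b[i] + 1L] <- cov[b[i] + 1L] + 1L
      cov[e[i] + 2L] <- cov[e[i] + 2L] - 1L
    }
  }
  depth <- cumsum(cov)[seq_len(L)]
  allCodes <- unlist(readSubs(reads), use.names = FALSE)
  alt <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  if (length(allCodes)) {
    tb <- table(allCodes)
    codes <- as.integer(names(tb))
    alt[cbind(codes %/% 4L + 1L, codes %% 4L + 1L)] <- as.integer(tb)
  }
  cnt <- function(lst) {
    v <- unlist(lst, use.names = FALSE)
    out <- integer(L)
    if (length(v)) {
      tb <- table(v[v >= 0L & v < L])
      out[as.integer(names(tb)) + 1L] <- as.integer(tb)
    }
    out
  }
  maskedCount <- cnt(readMasked(reads))
  deletedCount <- cnt(reads@deleted)
  if (!maskedInDepth) depth <- depth - maskedCount
  refCount <- depth - rowSums(alt) - maskedCount - deletedCount
  if (!maskedInDepth) refCount <- refCount + maskedCount
  data.frame(locus = seq_len(L) - 1L, pos = seq_len(L), depth = depth,
             A = alt[, 1L], C = alt[, 2L], G = alt[, 3L], T = alt[, 4L],
             refCount = refCount, maskedCount = maskedCount,
             deletedCount = deletedCount)
}

#' Marginal substitution rate of a code
#'
#' Carriers of the substitution divided by the reads covering its locus.
#'
#' @param pileup a pileup table from [pileupTable()].
#' @param code substitution code `4k + d`.
#' @return Rate in `[0, 1]`.
#' @examples
#' # 3 of 30 covering reads carry the alternative base: rate 0.1
#' @export
substitutionRate <- function(pileup, code) {
  k <- code %/% 4L
  row <- pileup[pileup$locus == k, , drop = FALSE]
  if (nrow(row) != 1L) stop("invalid locus: ", k)
  if (row$depth == 0L) stop("undefined rate: no read covers locus ", k)
  unname(row[[BASES[code %% 4L + 1L]]] / row$depth)
}
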