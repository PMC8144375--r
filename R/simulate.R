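#' Simulation configuration
#'
#' Defines the study conditions for synthetic data: a random reference, `K`
#' haplotypes (one per entry of `nSnvs`) at the given relative abundances
#' (the remainder of the pool is unmutated reference), and noisy reads at
#' the given depth and per-base substitution error rate. Defaults emulate a
#' pooled-sample minor-variant experiment: three strains at 5/3/2%
#' abundance, five SNVs each, 2000x coverage and a 10% error rate, the
#' regime of raw long reads.
#'
#' @param seed mandatory seed; all stochastic operations derive from it.
#' @param refLength reference length in bases.
#' @param nSnvs integer vector, SNVs per haplotype.
#' @param abundance relative abundance per haplotype (sum < 1; remainder is
#'   reference).
#' @param depth mean per-locus coverage.
#' @param readLength read length in bases (`NULL` = full-length reads), or
#'   `c(min, max)` for uniform lengths.
#' @param errorRate independent per-base substitution error rate (0-0.3).
#' @param contextEffect optional `function(upLen, downLen)` returning the
#'   per-locus error rate from the flanking homopolymer run lengths.
#' @param correlatedLoci optional list(`loci`, `fraction`): loci where a
#'   fixed alternative base appears in a random `fraction` of reads
#'   regardless of haplotype (methylation-like correlated errors).
#' @param minHd minimal pairwise homopolymer distance between planted SNV
#'   loci (0 disables the constraint).
#' @param edgeRuns SNV loci are kept out of the first and last `edgeRuns`
#'   homopolymer runs of the reference, so realignment windows are never
#'   clipped at a genome end (0 disables).
#' @return Named list of class `SimConfig`.
#' @export
simConfig <- function(seed, refLength = 500L, nSnvs = c(5L, 5L, 5L),
                      abundance = c(0.05, 0.03, 0.02), depth = 2000L,
                      readLength = NULL, errorRate = 0.1,
                      contextEffect = NULL, correlatedLoci = NULL,
                      minHd = 15L, edgeRuns = 10L) {
  stopifnot(length(nSnvs) == length(abundance), sum(abundance) <= 1,
            errorRate >= 0, errorRate <= 0.3)
  structure(list(seed = as.integer(seed), refLength = as.integer(refLength),
                 nSnvs = as.integer(nSnvs), abundance = abundance,
                 depth = as.integer(depth), readLength = readLength,
                 errorRate = errorRate, contextEffect = contextEffect,
                 correlatedLoci = correlatedLoci,
                 minHd = as.integer(minHd),
                 edgeRuns = as.integer(edgeRuns)), class = "SimConfig")
}

#' Simulate a reference and haplotype SNV sets
#'
#' Haplotype SNV loci are distinct and, when `minHd > 0`, pairwise at least
#' `minHd` homopolymer runs apart (across all haplotypes, so conditioning
#' constraints hold in detection). Deterministic under the config seed.
#'
#' @param config a [simConfig()] list.
#' @return list with `ref` (a [ReferenceGenome-class]) and `haplotypes`
#'   (list of substitution-code vectors).
#' @export
simulateHaplotypes <- function(config) {
  set.seed(config$seed)
  L <- config$refLength
  refSeq <- paste(sample(BASES, L, replace = TRUE), collapse = "")
  ref <- refGenome(refSeq, name = "sim")
  ri <- runIndex(ref)
  total <- sum(config$nSnvs)
  eligible0 <- seq_len(L) - 1L
  if (config$edgeRuns > 0L) {
    nRuns <- max(ri) + 1L
    eligible0 <- eligible0[ri[eligible0 + 1L] >= config$edgeRuns &
                             ri[eligible0 + 1L] <=
                               nRuns - 1L - config$edgeRuns]
  }
  chosen <- integer()
  for (attempt in seq_len(50L)) {
    chosen <- integer()
    eligible <- eligible0
    for (t in seq_len(total)) {
      if (length(eligible) == 0L) break
      k <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      chosen <- c(chosen, k)
      if (config$minHd > 0L) {
        eligible <- eligible[abs(ri[eligible + 1L] - ri[k + 1L]) - 1L >=
                               config$minHd]
      } else eligible <- setdiff(eligible, k)
    }
    if (length(chosen) == total) break
  }
  if (length(chosen) != total)
    stop("infeasible placement: cannot satisfy the homopolymer-distance ",
         "constraint")
  refCh <- strsplit(refSeq, "")[[1L]]
  haps <- vector("list", length(config$nSnvs))
  idx <- 1L
  for (h in seq_along(config$nSnvs)) {
    loci <- sort(chosen[idx:(idx + config$nSnvs[h] - 1L)])
    idx <- idx + config$nSnvs[h]
    alt <- vapply(loci, function(k)
      sample(setdiff(BASES, refCh[k + 1L]), 1L), character(1L))
    haps[[h]] <- 4L * loci + (match(alt, BASES) - 1L)
  }
  list(ref = ref, haplotypes = haps)
}

#' Simulate noisy long reads from a haplotype mixture
#'
#' Reads are drawn from the haplotypes by abundance (the remainder from the
#' unmutated reference) and receive independent per-base substitution
#' errors at `errorRate` (or a context-modulated rate), each error
#' replacing the base with one of the other three uniformly. Truth labels
#' are retained. Deterministic under `seed`.
#'
#' @param ref a [ReferenceGenome-class].
#' @param haplotypes list of haplotype substitution-code vectors.
#' @param config a [simConfig()] list.
#' @param seed seed for the read draw (defaults to `config$seed + 1`).
#' @return list with `reads` (an [EncodedReadSet-class]), `truth`
#'   (haplotype index per read, 0 = reference) and `lociRate` (the per-locus
#'   error rate used).
#' @export
simulateReads <- function(ref, haplotypes, config,
                          seed = config$seed + 1L) {
  set.seed(seed)
  L <- refLength(ref)
  refCh <- strsplit(refSequence(ref), "")[[1L]]
  baseIdx <- match(refCh, BASES)
  if (is.null(config$contextEffect)) {
    rate <- rep(config$errorRate, L)
  } else {
    runs <- homopolymerRuns(ref)
    ri <- runIndex(ref) + 1L
    upLen <- ifelse(ri - 1L >= 1L, runs$length[pmax(ri - 1L, 1L)], 0L)
    downLen <- ifelse(ri + 1L <= nrow(runs),
                      runs$length[pmin(ri + 1L, nrow(runs))], 0L)
    rate <- pmin(pmax(config$contextEffect(upLen, downLen), 0), 0.3)
  }
  rl <- config$readLength
  if (is.null(rl)) rl <- L
  meanLen <- mean(rl)
  nReads <- max(1L, round(config$depth * L / meanLen))
  K <- length(haplotypes)
  truth <- sample.int(K + 1L, nReads, replace = TRUE,
                      prob = c(1 - sum(config$abundance),
                               config$abundance)) - 1L
  hapLoci <- lapply(haplotypes, function(h) h %/% 4L)
  hapAlt <- lapply(haplotypes, function(h) h %% 4L + 1L)
  bs <- integer(nReads); es <- integer(nReads)
  subs <- vector("list", nReads)
  for (i in seq_len(nReads)) {
    len <- if (length(rl) == 2L) sample(rl[1L]:rl[2L], 1L) else rl
    len <- min(len, L)
    b <- if (len < L) sample.int(L - len + 1L, 1L) - 1L else 0L
    e <- b + len - 1L
    bases <- baseIdx[(b + 1L):(e + 1L)]
    if (truth[i] > 0L) {
      hl <- hapLoci[[truth[i]]]
      inR <- hl >= b & hl <= e
      bases[hl[inR] - b + 1L] <- hapAlt[[truth[i]]][inR]
    }
    errAt <- which(runif(len) < rate[(b + 1L):(e + 1L)])
    if (length(errAt)) {
      shift <- sample.int(3L, length(errAt), replace = TRUE)
      bases[errAt] <- (bases[errAt] - 1L + shift) %% 4L + 1L
    }
    bs[i] <- b; es[i] <- e
    changed <- which(bases != baseIdx[(b + 1L):(e + 1L)])
    subs[[i]] <- 4L * (b + changed - 1L) + (bases[changed] - 1L)
  }
  if (!is.null(config$correlatedLoci)) {
    cl <- config$correlatedLoci
    for (k in cl$loci) {
      altIdx <- (baseIdx[k + 1L]) %% 4L + 1L  # a fixed non-reference base
      code <- 4L * k + (altIdx - 1L)
      hit <- which(bs <= k & es >= k & runif(nReads) < cl$fraction)
      for (i in hit) {
        s <- subs[[i]][subs[[i]] %/% 4L != k]
        subs[[i]] <- sort(c(s, code))
      }
    }
  }
  list(reads = encodedReadSet(bs, es, subs), truth = truth,
       lociRate = rate)
}

#' Worked-example read fixture
#'
#' A deterministic encoded-read set reproducing the canonical co-occurrence
#' example: `nReads` reads covering five loci, exactly `nJoint` of them
#' carrying all five substitutions, with the remaining carriers arranged so
#' every code reaches its configured marginal count.
#'
#' @param nReads total reads (23432).
#' @param nJoint reads carrying all five substitutions (28).
#' @param marginalCounts total carriers per code; the defaults reproduce
#'   marginal substitution rates of about 0.57-0.96%.
#' @return list with `reads`, the five `codes`, and the implied
#'   `jointRate = nJoint / nReads`.
#' @export
workedExampleFixture <- function(nReads = 23432L, nJoint = 28L,
                                 marginalCounts = c(133L, 198L, 175L,
                                                    225L, 214L)) {
  stopifnot(all(marginalCounts >= nJoint))
  loci <- c(50L, 150L, 250L, 350L, 450L)
  codes <- 4L * loci  # alternative base A at each locus
  L <- 500L
  subs <- rep(list(integer()), nReads)
  for (i in seq_len(nJoint)) subs[[i]] <- codes
  nxt <- nJoint + 1L
  for (ci in seq_along(codes)) {
    extra <- marginalCounts[ci] - nJoint
    if (extra > 0L) {
      for (i in seq_len(extra)) subs[[nxt + i - 1L]] <- codes[ci]
      nxt <- nxt + extra
    }
  }
  stopifnot(nxt <= nReads + 1L)
  reads <- encodedReadSet(rep(0L, nReads), rep(L - 1L, nReads), subs)
  list(reads = reads, codes = codes, jointRate = nJoint / nReads)
}

#' Write a reference to FASTA
#'
#' @param ref a [ReferenceGenome-class].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
writeSimFasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(refSequence(ref))
  names(x) <- refName(ref)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write encoded reads as a SAM file
#'
#' Emits one primary, indel-free alignment per read (full-length match
#' CIGAR), with masked loci written as N. Useful for end-to-end tests of
#' the alignment reader.
#'
#' @param reads an [EncodedReadSet-class].
#' @param ref a [ReferenceGenome-class].
#' @param path output SAM file.
#' @return `path`, invisibly.
#' @export
writeSimSam <- function(reads, ref, path) {
  seqs <- reconstructReadSeqs(reads, ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:", refName(ref), "\tLN:", refLength(ref))),
             con)
  b <- readStarts(reads); e <- readEnds(reads)
  ord <- order(b)
  lines <- vapply(ord, function(i) {
    paste(readIds(reads)[i], 0L, refName(ref), b[i] + 1L, 60L,
          paste0(e[i] - b[i] + 1L, "M"), "*", 0L, 0L, seqs[i],
          strrep("I", e[i] - b[i] + 1L), sep = "\t")
  }, character(1L))
  writeLines(lines, con)
  invisible(path)
}
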