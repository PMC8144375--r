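#' Estimate the genome-wide per-alternative error floor
#'
#' Mean rate of a specific alternative base at loci not in `excludeLoci`:
#' total alternative-base count over three times the total depth. A crude
#' but data-driven stand-in for the context model when none is supplied.
#'
#' @param reads an [EncodedReadSet-class].
#' @param ref a [ReferenceGenome-class].
#' @param excludeLoci 0-based loci excluded (e.g. detected SNVs).
#' @return A single rate.
#' @export
estimateErrorRate <- function(reads, ref, excludeLoci = integer()) {
  pu <- pileupTable(reads, ref)
  keep <- !(pu$locus %in% excludeLoci) & pu$depth > 0L
  totAlt <- sum(pu$A[keep] + pu$C[keep] + pu$G[keep] + pu$T[keep])
  totDepth <- sum(pu$depth[keep])
  max(totAlt / (3 * totDepth), 1e-6)
}

#' Detect minor SNVs (full detection stage)
#'
#' Applies the methylation mask (for ONT), runs the random-subspace search
#' and, when a context model is available, the orphan-SNV likelihood-ratio
#' test, and returns the union of both call sets deduplicated by code.
#'
#' @param reads an [EncodedReadSet-class], or a SAM/BAM path.
#' @param ref a [ReferenceGenome-class], or a FASTA path.
#' @param platform `"pacbio"` or `"ont"`.
#' @param params an [rsmParams()] list.
#' @param contextModel optional [ContextErrorModel-class] enabling the
#'   orphan-SNV path.
#' @param motifs IUPAC methylation motifs to mask (applied for ONT; set
#'   `NULL` to disable).
#' @param qvMaskThreshold QV mask used when `reads` is a file path.
#' @return data.frame of calls sorted by `code`, with a `method` column
#'   (`"RSM"`, `"SLC"` or `"RSM;SLC"`) and stage counts in attribute
#'   `"log"`.
#' @export
runDetect <- function(reads, ref, platform = c("pacbio", "ont"),
                      params = rsmParams(), contextModel = NULL,
                      motifs = c("CCWGG", "CGCATC"),
                      qvMaskThreshold = 0L) {
  platform <- match.arg(platform)
  if (is.character(ref)) ref <- readReference(ref)
  if (is.character(reads)) reads <- encodeAlignments(reads, ref,
                                                     qvMaskThreshold)
  maskedLoci <- integer()
  if (platform == "ont" && !is.null(motifs) && length(motifs))
    maskedLoci <- maskMethylationLoci(motifSites(ref, motifs),
                                      refLength(ref))
  rsm <- rsmDetect(reads, ref, params, maskedLoci = maskedLoci)
  slc <- NULL
  if (!is.null(contextModel))
    slc <- detectOrphanSnvs(reads, ref, contextModel, platform,
                            maskedLoci = maskedLoci, mode = "slc")
  calls <- rsm
  calls$lr <- rep(NA_real_, nrow(calls))
  calls$p0 <- rep(NA_real_, nrow(calls))
  if (!is.null(slc) && nrow(slc)) {
    both <- slc$code %in% calls$code
    if (any(both)) {
      ix <- match(slc$code[both], calls$code)
      calls$lr[ix] <- slc$lr[both]
      calls$p0[ix] <- slc$p0[both]
      calls$method[ix] <- "RSM;SLC"
    }
    if (any(!both)) {
      add <- slc[!both, , drop = FALSE]
      add$hHat <- NA_real_
      add$nDen <- NA_integer_
      calls <- rbind(calls[, c("code", "locus", "pos", "refBase", "altBase",
                               "rate", "hHat", "nDen", "lr", "p0",
                               "method")],
                     add[, c("code", "locus", "pos", "refBase", "altBase",
                             "rate", "hHat", "nDen", "lr", "p0", "method")])
    }
  }
  calls <- calls[order(calls$code), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "log") <- list(nReads = length(reads),
                             nMaskedLoci = length(maskedLoci),
                             nRsm = nrow(rsm),
                             nSlc = if (is.null(slc)) 0L else nrow(slc))
  calls
}

#' Phase detected SNVs into contigs (full phasing stage)
#'
#' Realigns reads at the detected loci, restricts them to detected SNVs,
#' clusters them into draft contigs, applies the two-step Bayes-factor
#' filter, assembles the survivors on the transitively reduced overlap
#' graph, re-filters, merges redundant contigs and assigns every read to a
#' contig or the reference.
#'
#' @param reads an [EncodedReadSet-class], or a SAM/BAM path.
#' @param ref a [ReferenceGenome-class], or a FASTA path.
#' @param snvTable detection output from [runDetect()] (or any data.frame
#'   with a `code` column).
#' @param platform `"pacbio"` or `"ont"` (sets the homogeneity limit).
#' @param contextModel optional [ContextErrorModel-class] for per-SNV error
#'   rates in the filter; without it a genome-wide error floor is estimated
#'   from the data.
#' @param params a [phasingParams()] list (platform default if `NULL`).
#' @param scores an [alignScores()] list for realignment.
#' @param bfThreshold Bayes-factor threshold for the contig filters (10).
#' @param qvMaskThreshold QV mask used when `reads` is a file path.
#' @return list with `contigs` (a [ContigSet-class] with assignment-based
#'   abundances), `assignment` (contig index per read, 0 = reference),
#'   `drafts` (pre-filter draft contigs) and `detectedCodes`.
#' @export
runPhase <- function(reads, ref, snvTable, platform = c("pacbio", "ont"),
                     contextModel = NULL, params = NULL,
                     scores = alignScores(), bfThreshold = 10,
                     qvMaskThreshold = 0L) {
  platform <- match.arg(platform)
  if (is.character(ref)) ref <- readReference(ref)
  if (is.character(reads)) reads <- encodeAlignments(reads, ref,
                                                     qvMaskThreshold)
  if (is.null(params)) params <- phasingParams(platform)
  codes <- sort(unique(as.integer(snvTable$code)))
  if (length(codes) == 0L)
    return(list(contigs = contigSet(), assignment = integer(length(reads)),
                drafts = contigSet(), detectedCodes = integer()))
  loci <- unique(codes %/% 4L)
  if (any(loci < 0L | loci >= refLength(ref)))
    stop("SNV table references loci outside the reference")
  realigned <- realignReads(reads, ref, loci, scores)
  phasing <- buildPhasingData(realigned, codes)
  drafts <- annPhase(realigned, codes, params)
  if (is.null(contextModel)) {
    p0 <- estimateErrorRate(reads, ref, excludeLoci = loci)
  } else {
    p0 <- setNames(predictErrorRate(contextModel,
                                    extractContext(ref, codes)),
                   as.character(codes))
  }
  filtered <- filterDraftContigs(drafts, phasing$reads, p0, bfThreshold)
  g <- transitiveReduce(buildOverlapGraph(filtered))
  assembled <- assemblePaths(g)
  assembled <- filterDraftContigs(assembled, phasing$reads, p0, bfThreshold)
  merged <- mergeRedundantContigs(assembled)
  asg <- assignReads(phasing$reads, merged,
                     assignJaccardMin = params$assignJaccardMin)
  list(contigs = asg$contigs, assignment = asg$assignment, drafts = drafts,
       detectedCodes = codes)
}

#' Evaluate detection calls against simulation truth
#'
#' True positive rate = correctly detected SNVs / real SNVs; false
#' discovery rate = 1 - correct / reported.
#'
#' @param calls detection output (data.frame with `code`) or a code vector.
#' @param truth vector of true SNV codes.
#' @return list with `tpr`, `fdr`, `nCalls`, `nTruth`, `nCorrect`.
#' @export
evaluateCalls <- function(calls, truth) {
  codes <- if (is.data.frame(calls)) calls$code else as.integer(calls)
  truth <- as.integer(truth)
  if (length(truth) == 0L) stop("undefined TPR: empty truth set")
  correct <- length(intersect(codes, truth))
  list(tpr = correct / length(truth),
       fdr = if (length(codes) == 0L) NA_real_
             else 1 - correct / length(codes),
       nCalls = length(codes), nTruth = length(truth),
       nCorrect = correct)
}

#' Evaluate contigs against truth haplotypes
#'
#' Each contig is scored by the Jaccard index between its consensus SNV set
#' and the closest truth haplotype's SNVs restricted to the contig
#' interval.
#'
#' @param contigs a [ContigSet-class].
#' @param truthHaplotypes list of true haplotype code vectors.
#' @return data.frame with `contig`, `bestHaplotype`, `jaccard`.
#' @export
evaluateContigs <- function(contigs, truthHaplotypes) {
  n <- length(contigs)
  if (n == 0L)
    return(data.frame(contig = integer(), bestHaplotype = integer(),
                      jaccard = numeric()))
  out <- data.frame(contig = seq_len(n), bestHaplotype = NA_integer_,
                    jaccard = NA_real_)
  for (i in seq_len(n)) {
    cs <- contigSnvs(contigs)[[i]]
    jac <- vapply(truthHaplotypes, function(h) {
      hw <- snvsInWindow(h, contigStarts(contigs)[i], contigEnds(contigs)[i])
      u <- union(cs, hw)
      if (length(u) == 0L) return(0)
      length(intersect(cs, hw)) / length(u)
    }, numeric(1L))
    out$bestHaplotype[i] <- which.max(jac)
    out$jaccard[i] <- max(jac)
  }
  out
}

#' Write detection calls as a VCF-like TSV
#'
#' @param calls detection output from [runDetect()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCalls <- function(calls, path) {
  out <- calls[, c("pos", "refBase", "altBase", "rate", "hHat", "method")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write contigs as a TSV table
#'
#' 1-based interval, comma-separated SNVs (`pos:alt`), abundance.
#'
#' @param contigs a [ContigSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeContigs <- function(contigs, path) {
  n <- length(contigs)
  snv <- vapply(contigSnvs(contigs), function(s) {
    if (length(s) == 0L) return("")
    paste(sprintf("%d:%s", s %/% 4L + 1L, BASES[s %% 4L + 1L]),
          collapse = ",")
  }, character(1L))
  out <- data.frame(start = contigStarts(contigs) + 1L,
                    end = contigEnds(contigs) + 1L, snvs = snv,
                    abundance = contigAbundance(contigs))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
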