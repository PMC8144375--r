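#' Loci covered by methylation-motif occurrences
#'
#' Scans the reference for every IUPAC motif on both strands (the
#' reverse-complement pattern is searched on the forward sequence) and
#' returns all loci covered by any occurrence. The two default motifs are
#' the known bacterial methylation motifs relevant for nanopore data.
#'
#' @param ref a [ReferenceGenome-class].
#' @param motifs IUPAC patterns (W = A/T etc.).
#' @return Sorted 0-based loci covered by a motif on either strand.
#' @examples
#' motifSites(refGenome("ACCAGGT"), "CCWGG")  # loci 1..5
#' @export
motifSites <- function(ref, motifs = c("CCWGG", "CGCATC")) {
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(unique(strsplit(paste(motifs, collapse = ""), "")[[1L]]),
                 iupac)
  if (length(bad)) stop("invalid IUPAC symbol: ", paste(bad, collapse = ","))
  subject <- Biostrings::DNAString(refSequence(ref))
  loci <- integer()
  for (motif in motifs) {
    pats <- unique(c(motif, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))))
    for (p in pats) {
      hits <- Biostrings::matchPattern(p, subject, fixed = FALSE)
      if (length(hits))
        loci <- c(loci, unlist(lapply(seq_along(hits), function(h)
          (Biostrings::start(hits)[h] - 1L):(Biostrings::end(hits)[h] - 1L))))
    }
  }
  sort(unique(loci))
}

#' Expand motif loci into a detection mask
#'
#' Every locus within `window` bases of a motif-covered locus is masked
#' (clipped to the genome); masked loci are excluded from detection
#' candidates downstream.
#'
#' @param sites 0-based motif-covered loci (from [motifSites()]).
#' @param genomeLength reference length for clipping.
#' @param window flank size in bases (5).
#' @return Sorted 0-based masked loci.
#' @export
maskMethylationLoci <- function(sites, genomeLength, window = 5L) {
  if (length(sites) == 0L) return(integer())
  loci <- unlist(lapply(as.integer(sites), function(s)
    (s - window):(s + window)))
  sort(unique(loci[loci >= 0L & loci < genomeLength]))
}
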