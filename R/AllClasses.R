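#' Reference genome for substitution encoding
#'
#' A single uppercase DNA sequence (A/C/G/T/N) against which reads are
#' encoded. Loci are 0-based throughout the package; tabular output uses
#' 1-based positions.
#'
#' @slot name contig name.
#' @slot sequence uppercase DNA string.
#' @export
setClass("ReferenceGenome",
         representation(name = "character", sequence = "character"),
         validity = function(object) {
           if (length(object@name) != 1L || length(object@sequence) != 1L)
             return("name and sequence must be length 1")
           if (grepl("[^ACGTN]", object@sequence))
             return("sequence must contain only A/C/G/T/N")
           TRUE
         })

#' Construct a ReferenceGenome
#'
#' @param sequence DNA string (case-insensitive; non-ACGT characters other
#'   than N are rejected).
#' @param name contig name.
#' @return A [ReferenceGenome-class] object.
#' @examples
#' ref <- refGenome("AAACGGT")
#' refLength(ref)
#' @export
refGenome <- function(sequence, name = "ref") {
  new("ReferenceGenome", name = name, sequence = toupper(sequence))
}

#' Read a reference genome from a FASTA file
#'
#' The first record of the FASTA file is used.
#'
#' @param path FASTA file.
#' @return A [ReferenceGenome-class] object.
#' @export
readReference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequence in ", path)
  refGenome(as.character(seqs[[1L]]), name = sub("\\s.*", "", names(seqs)[1L]))
}

#' @describeIn ReferenceGenome-class reference length in bases
#' @param x,object a `ReferenceGenome`.
#' @export
refLength <- function(x) nchar(x@sequence)

#' @describeIn ReferenceGenome-class reference sequence as a string
#' @export
refSequence <- function(x) x@sequence

#' @describeIn ReferenceGenome-class reference name
#' @export
refName <- function(x) x@name

setMethod("show", "ReferenceGenome", function(object) {
  cat("ReferenceGenome", object@name, "of", refLength(object), "bp\n")
})

#' Set of reads encoded as substitution codes
#'
#' Each read is stored as its covering interval `[b, e]` (0-based, inclusive)
#' and the set `S` of substitution codes `4k + d` (alternative base
#' `c(A, C, G, T)[d + 1]` at locus `k`). A matching base produces no code.
#' QV-masked loci and deleted loci are kept separately: they count toward
#' coverage but contribute neither a substitution nor a reference match.
#'
#' @slot readId read identifiers.
#' @slot start,end 0-based inclusive covering interval per read.
#' @slot subs list of sorted integer code vectors, one per read.
#' @slot masked list of 0-based QV-masked loci per read.
#' @slot deleted list of 0-based deleted loci per read.
#' @export
setClass("EncodedReadSet",
         representation(readId = "character", start = "integer",
                        end = "integer", subs = "list", masked = "list",
                        deleted = "list"),
         validity = function(object) {
           m <- length(object@readId)
           if (length(object@start) != m || length(object@end) != m ||
               length(object@subs) != m || length(object@masked) != m ||
               length(object@deleted) != m)
             return("slot lengths differ")
           if (m && any(object@start > object@end))
             return("start must be <= end")
           for (i in seq_len(m)) {
             s <- object@subs[[i]]
             if (length(s) == 0L) next
             if (any(s < 4L * object@start[i] | s > 4L * object@end[i] + 3L))
               return("substitution code outside read interval")
             if (anyDuplicated(s %/% 4L))
               return("two codes share a locus in one read")
           }
           TRUE
         })

#' Construct an EncodedReadSet
#'
#' @param start,end 0-based inclusive covering intervals.
#' @param subs list of integer substitution-code vectors (one per read).
#' @param readId read names (generated if missing).
#' @param masked,deleted optional lists of 0-based masked / deleted loci.
#' @return An [EncodedReadSet-class].
#' @examples
#' reads <- encodedReadSet(start = c(0, 0), end = c(9, 9),
#'                         subs = list(c(11L), integer()))
#' readSubs(reads)[[1]]
#' @export
encodedReadSet <- function(start, end, subs, readId = NULL,
                           masked = NULL, deleted = NULL) {
  m <- length(start)
  if (is.null(readId)) readId <- sprintf("read%06d", seq_len(m))
  if (is.null(masked)) masked <- rep(list(integer()), m)
  if (is.null(deleted)) deleted <- rep(list(integer()), m)
  subs <- lapply(subs, function(s) sort(as.integer(s)))
  new("EncodedReadSet", readId = as.character(readId),
      start = as.integer(start), end = as.integer(end), subs = subs,
      masked = lapply(masked, as.integer),
      deleted = lapply(deleted, as.integer))
}

#' @describeIn EncodedReadSet-class read identifiers
#' @param x,object an `EncodedReadSet`.
#' @export
readIds <- function(x) x@readId

#' @describeIn EncodedReadSet-class 0-based start loci
#' @export
readStarts <- function(x) x@start

#' @describeIn EncodedReadSet-class 0-based end loci (inclusive)
#' @export
readEnds <- function(x) x@end

#' @describeIn EncodedReadSet-class list of substitution-code sets
#' @export
readSubs <- function(x) x@subs

#' @describeIn EncodedReadSet-class list of masked loci
#' @export
readMasked <- function(x) x@masked

setMethod("length", "EncodedReadSet", function(x) length(x@readId))

setMethod("show", "EncodedReadSet", function(object) {
  m <- length(object)
  cat("EncodedReadSet with", m, "reads;",
      sum(lengths(object@subs)), "substitutions\n")
  if (m) cat("  interval span:", min(object@start), "-", max(object@end), "\n")
})

setMethod("[", "EncodedReadSet", function(x, i, j, ..., drop = TRUE) {
  new("EncodedReadSet", readId = x@readId[i], start = x@start[i],
      end = x@end[i], subs = x@subs[i], masked = x@masked[i],
      deleted = x@deleted[i])
})

#' Set of (draft) contigs
#'
#' A contig is a consensus substitution set over a genomic interval together
#' with its supporting reads. Draft contigs come from ANN clustering;
#' assembled contigs from overlap-graph path concatenation.
#'
#' @slot start,end 0-based inclusive intervals.
#' @slot snvs list of sorted substitution-code vectors.
#' @slot abundance number of reads assigned to / supporting each contig.
#' @slot support list of supporting read indices.
#' @export
setClass("ContigSet",
         representation(start = "integer", end = "integer", snvs = "list",
                        abundance = "integer", support = "list"),
         validity = function(object) {
           n <- length(object@start)
           if (length(object@end) != n || length(object@snvs) != n ||
               length(object@abundance) != n || length(object@support) != n)
             return("slot lengths differ")
           if (n && any(object@start > object@end))
             return("start must be <= end")
           TRUE
         })

#' Construct a ContigSet
#'
#' @param start,end 0-based inclusive intervals.
#' @param snvs list of substitution-code vectors.
#' @param abundance supporting-read counts (defaults to `lengths(support)`).
#' @param support list of supporting read indices.
#' @return A [ContigSet-class].
#' @export
contigSet <- function(start = integer(), end = integer(), snvs = list(),
                      abundance = NULL, support = NULL) {
  n <- length(start)
  if (is.null(support)) support <- rep(list(integer()), n)
  if (is.null(abundance)) abundance <- lengths(support)
  new("ContigSet", start = as.integer(start), end = as.integer(end),
      snvs = lapply(snvs, function(s) sort(as.integer(s))),
      abundance = as.integer(abundance),
      support = lapply(support, as.integer))
}

#' @describeIn ContigSet-class 0-based start loci
#' @param x,object a `ContigSet`.
#' @export
contigStarts <- function(x) x@start

#' @describeIn ContigSet-class 0-based end loci
#' @export
contigEnds <- function(x) x@end

#' @describeIn ContigSet-class list of consensus substitution codes
#' @export
contigSnvs <- function(x) x@snvs

#' @describeIn ContigSet-class supporting-read counts
#' @export
contigAbundance <- function(x) x@abundance

#' @describeIn ContigSet-class supporting read indices
#' @export
contigSupport <- function(x) x@support

setMethod("length", "ContigSet", function(x) length(x@start))

setMethod("show", "ContigSet", function(object) {
  cat("ContigSet with", length(object), "contigs\n")
  n <- min(length(object), 5L)
  for (i in seq_len(n))
    cat(sprintf("  [%d] %d-%d  %d SNVs  abundance %d\n", i,
                object@start[i], object@end[i], length(object@snvs[[i]]),
                object@abundance[i]))
  if (length(object) > n) cat("  ...\n")
})

setMethod("[", "ContigSet", function(x, i, j, ..., drop = TRUE) {
  new("ContigSet", start = x@start[i], end = x@end[i], snvs = x@snvs[i],
      abundance = x@abundance[i], support = x@support[i])
})

#' Homopolymer-context sequencing-error model
#'
#' A gradient-boosting regressor mapping the homopolymer context of a locus
#' (flanking run bases and lengths, current base, substituting base) to the
#' expected substitution error rate of a specific alternative base.
#' Predictions are clipped to `[1e-6, 0.5]`.
#'
#' @slot booster fitted `xgb.Booster`.
#' @slot platform `"pacbio"` or `"ont"`.
#' @slot hyperparams list with `eta`, `nrounds`, `maxDepth`.
#' @slot cvR2 cross-validated R squared (1 - SS_res/SS_tot).
#' @slot featureNames training feature column names.
#' @export
setClass("ContextErrorModel",
         representation(booster = "ANY", platform = "character",
                        hyperparams = "list", cvR2 = "numeric",
                        featureNames = "character"))

setMethod("show", "ContextErrorModel", function(object) {
  cat("ContextErrorModel (", object@platform, "): eta=",
      object@hyperparams$eta, ", trees=", object@hyperparams$nrounds,
      ", depth=", object@hyperparams$maxDepth,
      sprintf("; CV R^2 = %.3f\n", object@cvR2), sep = "")
})

#' Overlap graph over draft contigs
#'
#' Vertices are draft contigs; a directed edge i -> j is added when the two
#' contigs agree in their overlap, share enough SNVs or length, and
#' `end(i) < end(j)` (which guarantees acyclicity).
#'
#' @slot contigs the vertex [ContigSet-class].
#' @slot edges two-column integer matrix (from, to), 1-based vertex indices.
#' @export
setClass("OverlapGraph",
         representation(contigs = "ContigSet", edges = "matrix"))

setMethod("show", "OverlapGraph", function(object) {
  cat("OverlapGraph:", length(object@contigs), "vertices,",
      nrow(object@edges), "edges\n")
})

#' @describeIn OverlapGraph-class edge matrix (from, to)
#' @param x,object an `OverlapGraph`.
#' @export
graphEdges <- function(x) x@edges

#' @describeIn OverlapGraph-class vertex contigs
#' @export
graphContigs <- function(x) x@contigs
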