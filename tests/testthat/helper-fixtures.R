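# small deterministic fixtures built in code

# reads given as list of code vectors over a common interval
tinyReads <- function(subs, b = 0L, e = 99L) {
  m <- length(subs)
  encodedReadSet(rep(b, m), rep(e, m), subs)
}

# reads realised from carrier counts: `carriers` is a named list mapping a
# comma-separated code-set string to the number of reads carrying exactly
# that set; the remaining reads up to `m` are empty
readsFromCounts <- function(carriers, m, b = 0L, e = 99L) {
  subs <- list()
  for (key in names(carriers)) {
    set <- as.integer(strsplit(key, ",")[[1L]])
    subs <- c(subs, rep(list(set), carriers[[key]]))
  }
  subs <- c(subs, rep(list(integer()), m - length(subs)))
  tinyReads(subs, b, e)
}

# a reference whose bases alternate, so every locus is its own homopolymer
# run and homopolymer distances equal locus distances minus one
alternatingRef <- function(L = 100L) {
  refGenome(paste(rep_len(c("A", "C", "G", "T"), L), collapse = ""))
}

# default small simulated data set shared by several tests
smallSim <- function(seed = 5L, refLength = 300L, nSnvs = c(4L, 4L),
                     abundance = c(0.10, 0.06), depth = 500L,
                     errorRate = 0.1, ...) {
  cfg <- simConfig(seed = seed, refLength = refLength, nSnvs = nSnvs,
                   abundance = abundance, depth = depth,
                   errorRate = errorRate, ...)
  hp <- simulateHaplotypes(cfg)
  sim <- simulateReads(hp$ref, hp$haplotypes, cfg)
  list(cfg = cfg, ref = hp$ref, haplotypes = hp$haplotypes,
       reads = sim$reads, truth = sim$truth)
}
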