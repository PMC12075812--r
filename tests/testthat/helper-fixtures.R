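# Shared synthetic loci (one per chemistry) used across the suite.
fx_blunt <- example_locus("blunt", seed = 7)
fx_stag <- example_locus("staggered", seed = 7)

# error-free mixture for exact truth-recovery checks
mix_clean <- function(n, seed = 1L, ...) {
  outcome_mix(n_reads = n, seed = seed, errors = error_model(0, 0, 0), ...)
}

# Independent brute-force oracle for junction microhomology: count the
# equivalent placements of the junction that reproduce the joined sequence,
# minus one. Kept free of any package internals.
mh_oracle <- function(u, a, d, b) {
  lu <- nchar(u); ld <- nchar(d)
  joined <- paste0(substring(u, 1, a), substring(d, b + 1, ld))
  hits <- 0L
  for (a2 in 0:lu) {
    b2 <- b - (a - a2)
    if (b2 < 0 || b2 > ld) next
    cand <- paste0(substring(u, 1, a2), substring(d, b2 + 1, ld))
    if (identical(cand, joined)) hits <- hits + 1L
  }
  hits - 1L
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
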