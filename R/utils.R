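# Internal string helpers. All public coordinates in this package are
# 0-based, half-open, on the top strand of the reference amplicon.

`%||%` <- function(x, y) if (is.null(x)) y else x

# substring by 0-based half-open interval [a, b)
substr0 <- function(x, a, b) substring(x, a + 1L, b)

.check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(x) > 0L && grepl("[^ACGT]", x)) {
    stop(what, " contains characters other than A/C/G/T", call. = FALSE)
  }
  x
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# set.seed only when a seed is supplied, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Maximal exact-match extension between raw vectors `a` and `b`, starting at
# 1-based indices ai/bi and moving right. An isolated substitution is crossed
# only when the next `probe` bases match exactly, so extensions tolerate
# sequencing substitutions but stop hard at junctions and indels.
.extend_fwd <- function(a, b, ai, bi, probe = 8L) {
  K <- min(length(a) - ai, length(b) - bi) + 1L
  if (K <= 0L) return(list(len = 0L, mis = 0L))
  av <- a[ai:(ai + K - 1L)]
  bv <- b[bi:(bi + K - 1L)]
  d <- which(av != bv)
  if (length(d) == 0L) return(list(len = K, mis = 0L))
  mis <- 0L
  for (p in d) {
    blocked <- p + probe > K || any(d > p & d <= p + probe)
    if (blocked) return(list(len = p - 1L, mis = mis))
    mis <- mis + 1L
  }
  list(len = K, mis = mis)
}

# Mirror of .extend_fwd moving left from ai/bi (inclusive).
.extend_bwd <- function(a, b, ai, bi, probe = 8L) {
  K <- min(ai, bi)
  if (K <= 0L) return(list(len = 0L, mis = 0L))
  av <- a[ai:(ai - K + 1L)]
  bv <- b[bi:(bi - K + 1L)]
  d <- which(av != bv)
  if (length(d) == 0L) return(list(len = K, mis = 0L))
  mis <- 0L
  for (p in d) {
    blocked <- p + probe > K || any(d > p & d <= p + probe)
    if (blocked) return(list(len = p - 1L, mis = mis))
    mis <- mis + 1L
  }
  list(len = K, mis = mis)
}

# shift a deletion interval [s, e) (0-based, on `refraw`) as far left as the
# flanking sequence allows, so junction coordinates are deterministic
.left_align_interval <- function(refraw, s, e) {
  while (s > 0L && refraw[s] == refraw[e]) {
    s <- s - 1L
    e <- e - 1L
  }
  c(s, e)
}
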