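#' HiFi-like sequencing error model
#'
#' Per-base independent substitution, insertion and deletion rates. The
#' defaults total 1e-4 errors per base, the accuracy regime of Q >= 40
#' circular-consensus reads.
#'
#' @param sub,ins,del Per-base rates, each in [0, 0.05].
#' @return Named list of rates.
#' @export
error_model <- function(sub = 6e-5, ins = 2e-5, del = 2e-5) {
  for (r in c(sub, ins, del)) {
    if (r < 0 || r > 0.05) stop("error rates must be in [0, 0.05]", call. = FALSE)
  }
  list(sub = sub, ins = ins, del = del)
}

#' Outcome mixture specification for the read simulator
#'
#' Defines the repair-outcome composition of a simulated read set: one
#' fraction per detailed category group, plus the parameter ranges used to
#' draw each category's molecular event. The default proportions describe a
#' plausible knock-in experiment in which donor-independent repair dominates
#' and perfect HDR is a minority of donor integrations.
#'
#' @param proportions Named numeric vector of category fractions over the
#'   categories `WT`, `deletion_lt50`, `deletion_ge50`, `insertion`,
#'   `complex_indel`, `perfect_HDR`, `blunt`, `asymmetric_HDR`, `imperfect`,
#'   `concatenated`, `complex`. Must sum to 1.
#' @param n_reads Number of reads to simulate.
#' @param seed Integer seed.
#' @param errors An [error_model()]; use `error_model(0, 0, 0)` for
#'   error-free reads.
#' @param deletion List: `size_lt50`, `size_ge50` (size ranges) and
#'   `mh_frac`, the fraction of sub-50 nt deletions anchored on engineered
#'   microhomology, with `mh_min`/`mh_max` the microhomology range (MMEJ
#'   substrates span 2-20 nt).
#' @param insertion List with `size` range of untemplated insertions at the
#'   cut.
#' @param complex_indel List with `del` and `ins` size ranges.
#' @param imperfect List: `trim` range of donor-end trimming, `resect` range
#'   of genomic resection, `untemp` range of untemplated junction bases.
#' @param concatemer List: `copies` range and `inverted` (logical) for
#'   donor multimers.
#' @param complex List with `junk` range of unexplained junction sequence.
#' @param duplicate_overhang For staggered chemistry, ligate blunt captures
#'   with an overhang fill-in duplication instead of joining at the
#'   top-strand cut.
#' @return A list of class `kiseq_mix`.
#' @export
outcome_mix <- function(
    proportions = c(WT = 0.30, deletion_lt50 = 0.20, deletion_ge50 = 0.05,
                    insertion = 0.05, complex_indel = 0.03,
                    perfect_HDR = 0.12, blunt = 0.05, asymmetric_HDR = 0.08,
                    imperfect = 0.07, concatenated = 0.03, complex = 0.02),
    n_reads = 1000L, seed = 1L, errors = error_model(),
    deletion = list(size_lt50 = c(1L, 49L), size_ge50 = c(50L, 120L),
                    mh_frac = 0.3, mh_min = 2L, mh_max = 20L),
    insertion = list(size = c(1L, 15L)),
    complex_indel = list(del = c(5L, 25L), ins = c(5L, 25L)),
    imperfect = list(trim = c(1L, 40L), resect = c(0L, 10L),
                     untemp = c(0L, 6L)),
    concatemer = list(copies = c(2L, 2L), inverted = FALSE),
    complex = list(junk = c(30L, 60L)),
    duplicate_overhang = FALSE) {
  cats <- c("WT", "deletion_lt50", "deletion_ge50", "insertion",
            "complex_indel", "perfect_HDR", "blunt", "asymmetric_HDR",
            "imperfect", "concatenated", "complex")
  if (!setequal(names(proportions), cats)) {
    stop("proportions must be named with exactly the 11 outcome categories",
         call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", sum(proportions), ")",
         call. = FALSE)
  }
  if (any(proportions < 0)) stop("proportions must be nonnegative", call. = FALSE)
  if (n_reads < 1) stop("n_reads must be >= 1", call. = FALSE)
  structure(
    list(proportions = proportions[cats], n_reads = as.integer(n_reads),
         seed = seed, errors = errors, deletion = deletion,
         insertion = insertion, complex_indel = complex_indel,
         imperfect = imperfect, concatemer = concatemer, complex = complex,
         duplicate_overhang = duplicate_overhang),
    class = "kiseq_mix"
  )
}

.runint <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  sample(seq.int(range[1], range[2]), 1L)
}

#' Draw an MMEJ-anchored deletion around the cut
#'
#' Enumerates repeated k-mers (k = `mh_min`) within a window around the cut
#' and deletes the sequence between one repeat copy and the other, so the
#' repaired junction carries microhomology of at least `mh_min` nt, as
#' measured by [junction_mh_length()]. MMEJ substrates in the field span
#' 2-20 nt of microhomology.
#'
#' @param locus A [locus_spec()] object.
#' @param mh_min,mh_max Microhomology length bounds (2 <= mh_min <= mh_max
#'   <= 20).
#' @param window Half-width (nt) of the search window around the cut.
#' @param max_size Largest deletion size returned.
#' @param seed Optional seed.
#' @return A list with `found` (logical); when found, `del_start`, `del_end`
#'   (0-based, half-open, overlapping the cut), `mh` (realized junction
#'   microhomology, >= mh_min) and `mh_seq`. When no repeat pair exists the
#'   list has `found = FALSE` and `reason = "no_site"`.
#' @export
mmej_deletion <- function(locus, mh_min = 2L, mh_max = 20L, window = 60L,
                          max_size = 49L, seed = NULL) {
  stopifnot(inherits(locus, "kiseq_locus"))
  if (!(mh_min >= 2 && mh_min <= mh_max && mh_max <= 20)) {
    stop("need 2 <= mh_min <= mh_max <= 20", call. = FALSE)
  }
  cs <- .cut_set(locus)
  L <- nchar(locus$ref_seq)
  win_lo <- max(0L, cs[1] - as.integer(window))
  win_hi <- min(L, cs[2] + as.integer(window))
  if (win_hi - win_lo < 2L * mh_min) {
    stop("search window (", win_hi - win_lo, " nt) is smaller than twice ",
         "mh_min", call. = FALSE)
  }
  .with_seed(seed, {
    k <- as.integer(mh_min)
    starts <- seq.int(win_lo, win_hi - k)
    kmers <- vapply(starts, function(o) substr0(locus$ref_seq, o, o + k), "")
    cand <- list()
    by_kmer <- split(starts, kmers)
    for (pos in by_kmer) {
      if (length(pos) < 2L) next
      for (ii in seq_len(length(pos) - 1L)) {
        for (jj in (ii + 1L):length(pos)) {
          a <- pos[ii] + k
          b <- pos[jj] + k
          size <- b - a
          if (size < 1L || size > max_size) next
          if (a > cs[2] || b < cs[1]) next   # must overlap the cut window
          cand[[length(cand) + 1L]] <- c(a, b)
        }
      }
    }
    if (length(cand) == 0L) {
      return(list(found = FALSE, reason = "no_site"))
    }
    pick <- cand[[sample.int(length(cand), 1L)]]
    la <- .left_align_interval(charToRaw(locus$ref_seq), pick[1], pick[2])
    mh <- junction_mh_length(locus$ref_seq, la[1], locus$ref_seq, la[2],
                             max_scan = 25L)
    list(found = TRUE, del_start = la[1], del_end = la[2], mh = mh,
         mh_seq = substr0(locus$ref_seq, la[1] - mh_min, la[1]))
  })
}

#' Apply per-base sequencing errors to a sequence
#'
#' Independent per-base substitutions, insertions and deletions at the given
#' rates. Deterministic under a fixed RNG state (pass `seed`, or call within
#' a seeded stream).
#'
#' @param seq A DNA string.
#' @param errors An [error_model()].
#' @param seed Optional seed.
#' @return The mutated sequence.
#' @export
apply_sequencing_errors <- function(seq, errors = error_model(), seed = NULL) {
  .with_seed(seed, {
    if (errors$sub == 0 && errors$ins == 0 && errors$del == 0) return(seq)
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    bases <- c("A", "C", "G", "T")
    u <- stats::runif(n)
    del <- u < errors$del
    sub <- !del & u < errors$del + errors$sub
    out <- ch
    if (any(sub)) {
      out[sub] <- vapply(ch[sub],
                         function(b) sample(setdiff(bases, b), 1L), "")
    }
    ins <- stats::runif(n) < errors$ins
    if (any(ins)) {
      out[ins] <- paste0(out[ins], sample(bases, sum(ins), replace = TRUE))
    }
    out[del] <- ""
    paste(out, collapse = "")
  })
}

# ---- junction construction with rejection sampling -------------------------
# A drawn trim/resection/untemplated-insertion combination occasionally
# produces a molecule whose junction is placement-equivalent to a blunt
# ligation, or whose untemplated bases coincide with a parent flank. Such
# draws are rejected so the truth label always describes the realized
# molecule.

.sim_ctx <- function(locus, donor) {
  list(ref = locus$ref_seq, L = nchar(locus$ref_seq),
       dfull = donor_seq(donor), dlen = nchar(donor_seq(donor)),
       haL = donor$ha_len_left, haR = donor$ha_len_right,
       ilen = nchar(donor$insert_seq),
       P = locus$integration_point, cut = locus$cut_offset_top,
       cs = .cut_set(locus))
}

.char_at <- function(s, i) substring(s, i + 1L, i + 1L)  # 0-based

# run of co-matching bases left of a (ref end, donor start) junction
.comatch_left <- function(ref, gend, dfull, dstart) {
  k <- 0L
  while (gend - k >= 1L && dstart - k >= 1L &&
         .char_at(ref, gend - k - 1L) == .char_at(dfull, dstart - k - 1L)) {
    k <- k + 1L
  }
  k
}

.comatch_right <- function(dfull, dend, ref, gstart) {
  k <- 0L
  while (dend + k < nchar(dfull) && gstart + k < nchar(ref) &&
         .char_at(dfull, dend + k) == .char_at(ref, gstart + k)) {
    k <- k + 1L
  }
  k
}

# build the 5' side of an integration allele: genome prefix, untemplated
# bases, and the donor start coordinate
.sim_end5 <- function(kind, sc, mix) {
  if (kind == "HDR") {
    return(list(left = substr0(sc$ref, 0, sc$P), untemp = "",
                donor_from = sc$haL, trim = NA_integer_, status = "HDR"))
  }
  if (kind == "blunt") {
    return(list(left = substr0(sc$ref, 0, sc$cut), untemp = "",
                donor_from = 0L, trim = 0L, status = "blunt"))
  }
  imp <- mix$imperfect
  trim_hi <- min(imp$trim[2], sc$haL - 5L)
  for (try in 1:100) {
    t5 <- .runint(c(imp$trim[1], trim_hi))
    res <- .runint(imp$resect)
    ulen <- .runint(imp$untemp)
    gend <- sc$cut - res
    if (ulen > 0L) {
      u <- .random_dna(ulen)
      # reject untemplated bases that extend a parent flank
      if (.char_at(u, 0L) == .char_at(sc$ref, gend)) next
      if (substring(u, ulen, ulen) == .char_at(sc$dfull, t5 - 1L)) next
      return(list(left = substr0(sc$ref, 0, gend), untemp = u,
                  donor_from = t5, trim = t5, status = "imperfect"))
    }
    # reject junctions placement-equivalent to a blunt ligation
    kL <- .comatch_left(sc$ref, gend, sc$dfull, t5)
    if (kL >= t5 && (gend - t5) >= sc$cs[1] && (gend - t5) <= sc$cs[2]) next
    return(list(left = substr0(sc$ref, 0, gend), untemp = "",
                donor_from = t5, trim = t5, status = "imperfect"))
  }
  stop("could not draw a consistent imperfect 5' junction", call. = FALSE)
}

.sim_end3 <- function(kind, sc, mix) {
  if (kind == "HDR") {
    return(list(right = substr0(sc$ref, sc$P, sc$L), untemp = "",
                donor_to = sc$haL + sc$ilen, trim = NA_integer_,
                status = "HDR"))
  }
  if (kind == "blunt") {
    return(list(right = substr0(sc$ref, sc$cut, sc$L), untemp = "",
                donor_to = sc$dlen, trim = 0L, status = "blunt"))
  }
  imp <- mix$imperfect
  trim_hi <- min(imp$trim[2], sc$haR - 5L)
  for (try in 1:100) {
    t3 <- .runint(c(imp$trim[1], trim_hi))
    res <- .runint(imp$resect)
    ulen <- .runint(imp$untemp)
    gstart <- sc$cut + res
    dto <- sc$dlen - t3
    if (ulen > 0L) {
      u <- .random_dna(ulen)
      if (.char_at(u, 0L) == .char_at(sc$dfull, dto)) next
      if (substring(u, ulen, ulen) == .char_at(sc$ref, gstart - 1L)) next
      return(list(right = substr0(sc$ref, gstart, sc$L), untemp = u,
                  donor_to = dto, trim = t3, status = "imperfect"))
    }
    kR <- .comatch_right(sc$dfull, dto, sc$ref, gstart)
    if (kR >= t3 && (gstart + t3) >= sc$cs[1] && (gstart + t3) <= sc$cs[2]) next
    return(list(right = substr0(sc$ref, gstart, sc$L), untemp = "",
                donor_to = dto, trim = t3, status = "imperfect"))
  }
  stop("could not draw a consistent imperfect 3' junction", call. = FALSE)
}

.truth_row <- function(category_detailed, del_start = NA_integer_,
                       del_end = NA_integer_, trim5 = NA_integer_,
                       trim3 = NA_integer_, mh5 = NA_integer_,
                       mh3 = NA_integer_, donor_copies = 0L) {
  tibble::tibble(
    category_detailed = category_detailed,
    category_broad = regroup_outcome(category_detailed),
    del_start = as.integer(del_start), del_end = as.integer(del_end),
    trim5 = as.integer(trim5), trim3 = as.integer(trim3),
    mh5 = as.integer(mh5), mh3 = as.integer(mh3),
    donor_copies = as.integer(donor_copies)
  )
}

#' Simulate one repair-outcome allele
#'
#' Constructs the allele for one repair outcome by explicit string surgery
#' at the cut, together with a ground-truth record describing the surgery.
#' Donor-dependent categories: blunt ligates the full donor (homology arms
#' included) directly at the cut; asymmetric HDR integrates one donor end
#' precisely via its homology arm and the other bluntly or with trimming;
#' imperfect trims at least one donor end; concatenated inserts multiple
#' donor copies; complex adds a long unexplained junction sequence.
#'
#' @param locus A [locus_spec()] object.
#' @param donor A [donor_spec()] object.
#' @param category One of the 11 outcome categories (see [outcome_mix()]).
#' @param mix An [outcome_mix()] carrying the per-category parameter ranges.
#' @param detailed Optional detailed label (e.g. `"5' HDR, 3' imperfect"`)
#'   to pin the end combination of asymmetric/imperfect draws.
#' @return A list with `seq` (allele sequence) and `truth` (one-row tibble).
#' @export
simulate_allele <- function(locus, donor, category, mix = outcome_mix(),
                            detailed = NULL) {
  sc <- .sim_ctx(locus, donor)
  cut <- sc$cut

  if (category == "WT") {
    return(list(seq = sc$ref, truth = .truth_row("WT")))
  }

  if (category %in% c("deletion_lt50", "deletion_ge50")) {
    use_mmej <- category == "deletion_lt50" &&
      stats::runif(1) < (mix$deletion$mh_frac %||% 0)
    if (use_mmej) {
      m <- mmej_deletion(locus, mh_min = mix$deletion$mh_min,
                         mh_max = mix$deletion$mh_max)
      if (m$found) {
        seq <- paste0(substr0(sc$ref, 0, m$del_start),
                      substr0(sc$ref, m$del_end, sc$L))
        return(list(seq = seq,
                    truth = .truth_row(category, del_start = m$del_start,
                                       del_end = m$del_end, mh5 = m$mh)))
      }
    }
    rng <- if (category == "deletion_lt50") mix$deletion$size_lt50
           else mix$deletion$size_ge50
    size <- .runint(rng)
    off <- .runint(c(0L, size))
    a <- max(30L, cut - off)
    b <- min(sc$L - 30L, a + size)
    a <- b - size
    la <- .left_align_interval(charToRaw(sc$ref), a, b)
    mh <- junction_mh_length(sc$ref, la[1], sc$ref, la[2])
    seq <- paste0(substr0(sc$ref, 0, la[1]), substr0(sc$ref, la[2], sc$L))
    return(list(seq = seq, truth = .truth_row(category, del_start = la[1],
                                              del_end = la[2], mh5 = mh)))
  }

  if (category == "insertion") {
    size <- .runint(mix$insertion$size)
    seq <- paste0(substr0(sc$ref, 0, cut), .random_dna(size),
                  substr0(sc$ref, cut, sc$L))
    return(list(seq = seq, truth = .truth_row("insertion")))
  }

  if (category == "complex_indel") {
    for (try in 1:100) {
      d <- .runint(mix$complex_indel$del)
      j <- .runint(mix$complex_indel$ins)
      off <- .runint(c(0L, d))
      a <- cut - off
      b <- a + d
      junk <- .random_dna(j)
      s1 <- .comatch_right(junk, 0L, sc$ref, a)
      s2 <- 0L
      while (s2 < j && b - s2 >= 1L &&
             .char_at(junk, j - s2 - 1L) == .char_at(sc$ref, b - s2 - 1L)) {
        s2 <- s2 + 1L
      }
      if (d - s1 - s2 < 2L || j - s1 - s2 < 2L) next
      seq <- paste0(substr0(sc$ref, 0, a), junk, substr0(sc$ref, b, sc$L))
      return(list(seq = seq, truth = .truth_row("complex_indel",
                                                del_start = a, del_end = b)))
    }
    stop("could not draw a consistent complex indel", call. = FALSE)
  }

  if (category == "perfect_HDR") {
    pa <- build_perfect_hdr_allele(locus, donor)
    return(list(seq = pa$seq,
                truth = .truth_row("5' HDR, 3' HDR", trim5 = NA, trim3 = NA)))
  }

  if (category == "blunt") {
    if (isTRUE(mix$duplicate_overhang) && locus$chemistry == "staggered") {
      seq <- paste0(substr0(sc$ref, 0, sc$cs[2]), sc$dfull,
                    substr0(sc$ref, sc$cs[1], sc$L))
    } else {
      seq <- paste0(substr0(sc$ref, 0, cut), sc$dfull,
                    substr0(sc$ref, cut, sc$L))
    }
    mh5 <- junction_mh_length(sc$ref, cut, sc$dfull, 0L)
    mh3 <- junction_mh_length(sc$dfull, sc$dlen, sc$ref, cut)
    return(list(seq = seq,
                truth = .truth_row("5' blunt, 3' blunt", trim5 = 0L,
                                   trim3 = 0L, mh5 = mh5, mh3 = mh3,
                                   donor_copies = 1L)))
  }

  if (category %in% c("asymmetric_HDR", "imperfect")) {
    combos <- if (category == "asymmetric_HDR") {
      list(c("HDR", "blunt"), c("blunt", "HDR"),
           c("HDR", "imperfect"), c("imperfect", "HDR"))
    } else {
      list(c("blunt", "imperfect"), c("imperfect", "blunt"),
           c("imperfect", "imperfect"))
    }
    if (!is.null(detailed)) {
      m <- regmatches(detailed,
                      regexec("^5' (\\w+), 3' (\\w+)$", detailed))[[1]]
      combo <- c(m[2], m[3])
    } else {
      combo <- combos[[sample.int(length(combos), 1L)]]
    }
    e5 <- .sim_end5(combo[1], sc, mix)
    e3 <- .sim_end3(combo[2], sc, mix)
    seq <- paste0(e5$left, e5$untemp,
                  substr0(sc$dfull, e5$donor_from, e3$donor_to),
                  e3$untemp, e3$right)
    mh5 <- if (e5$status == "HDR") NA_integer_
           else if (nzchar(e5$untemp)) 0L
           else junction_mh_length(sc$ref, nchar(e5$left), sc$dfull,
                                   e5$donor_from)
    mh3 <- if (e3$status == "HDR") NA_integer_
           else if (nzchar(e3$untemp)) 0L
           else junction_mh_length(sc$dfull, e3$donor_to, sc$ref,
                                   sc$L - nchar(e3$right))
    lab <- sprintf("5' %s, 3' %s", e5$status, e3$status)
    return(list(seq = seq,
                truth = .truth_row(lab, trim5 = e5$trim, trim3 = e3$trim,
                                   mh5 = mh5, mh3 = mh3, donor_copies = 1L)))
  }

  if (category == "concatenated") {
    copies <- .runint(mix$concatemer$copies)
    units <- rep(sc$dfull, copies)
    if (isTRUE(mix$concatemer$inverted) && copies >= 2L) {
      units[2] <- revcomp(sc$dfull)
    }
    seq <- paste0(substr0(sc$ref, 0, cut), paste(units, collapse = ""),
                  substr0(sc$ref, cut, sc$L))
    return(list(seq = seq, truth = .truth_row("concatenated",
                                              donor_copies = copies)))
  }

  if (category == "complex") {
    for (try in 1:100) {
      junk <- .random_dna(.runint(mix$complex$junk))
      if (.char_at(junk, 0L) == .char_at(sc$ref, cut)) next
      seq <- paste0(substr0(sc$ref, 0, cut), junk, sc$dfull,
                    substr0(sc$ref, cut, sc$L))
      return(list(seq = seq, truth = .truth_row("complex", donor_copies = 1L)))
    }
    stop("could not draw a consistent complex junction", call. = FALSE)
  }

  stop("unknown category: ", category, call. = FALSE)
}

#' Simulate a ground-truth-labelled read set
#'
#' Draws read categories from the mixture proportions, builds each allele by
#' [simulate_allele()], reverse-complements a random half of the reads, and
#' applies the sequencing error model. The result is fully reproducible from
#' the seed.
#'
#' @inheritParams simulate_allele
#' @param mix An [outcome_mix()].
#' @param seed Seed; defaults to the seed stored in `mix`.
#' @return A tibble with one row per read: `read_id`, `seq` (the read as
#'   sequenced, i.e. possibly reverse-complemented), `orientation`, and the
#'   truth columns `category_detailed`, `category_broad`, `del_start`,
#'   `del_end`, `trim5`, `trim3`, `mh5`, `mh3`, `donor_copies`.
#' @export
simulate_reads <- function(locus, donor, mix = outcome_mix(),
                           seed = mix$seed) {
  stopifnot(inherits(locus, "kiseq_locus"), inherits(donor, "kiseq_donor"),
            inherits(mix, "kiseq_mix"))
  .with_seed(seed, {
    n <- mix$n_reads
    cats <- sample(names(mix$proportions), n, replace = TRUE,
                   prob = mix$proportions)
    sims <- lapply(cats, function(cat) simulate_allele(locus, donor, cat, mix))
    truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
    alleles <- vapply(sims, `[[`, "", "seq")
    flip <- stats::runif(n) < 0.5
    reads <- ifelse(flip, vapply(alleles, revcomp, "", USE.NAMES = FALSE),
                    alleles)
    reads <- vapply(reads, apply_sequencing_errors, "", errors = mix$errors,
                    USE.NAMES = FALSE)
    dplyr::bind_cols(
      tibble::tibble(read_id = sprintf("read%06d", seq_len(n)), seq = reads,
                     orientation = ifelse(flip, "-", "+")),
      truth
    )
  })
}

#' Simulate a read set and write it to disk
#'
#' Writes the reads as FASTQ (constant Q40 qualities; gzip if the path ends
#' in `.gz`) and the truth table as TSV.
#'
#' @inheritParams simulate_reads
#' @param fastq Output FASTQ path.
#' @param truth Output truth-table TSV path.
#' @return The simulated tibble, invisibly.
#' @export
simulate_dataset <- function(locus, donor, mix = outcome_mix(),
                             fastq, truth, seed = mix$seed) {
  sim <- simulate_reads(locus, donor, mix, seed = seed)
  write_fastq(sim, fastq)
  cols <- c("read_id", "category_detailed", "category_broad", "del_start",
            "del_end", "trim5", "trim3", "mh5", "mh3", "donor_copies",
            "orientation")
  utils::write.table(sim[, cols], truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sim)
}
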