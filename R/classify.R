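#' Classifier parameters
#'
#' Tunable thresholds for read classification. Defaults suit HiFi-like
#' amplicon reads (per-base error around 1e-4, the quality regime of
#' Q >= 40 circular-consensus reads).
#'
#' @param min_read_len Reads shorter than this are reported unalignable.
#' @param min_seg_len Minimum alignment segment length (nt).
#' @param min_identity Minimum percent identity for a segment.
#' @param max_mismatch Mismatches tolerated (with zero indels) across a
#'   homology-arm window when calling an HDR end.
#' @param margin Bases of context beyond the homology arm on each side of
#'   the HDR window.
#' @param min_unexplained Read span matching neither reference nor donor at
#'   which a read is labelled complex (possible genomic insertion).
#' @param cut_pad Positions around the cut window within which an indel is
#'   treated as cut-derived; indels further away are attributed to
#'   sequencing noise.
#' @param max_scan Maximum microhomology scan length.
#' @param probe Exact-match look-ahead used to cross an isolated
#'   substitution during segment extension.
#' @return A named list of class `kiseq_params`.
#' @export
classifier_params <- function(min_read_len = 100L, min_seg_len = 20L,
                              min_identity = 90, max_mismatch = 2L,
                              margin = 20L, min_unexplained = 20L,
                              cut_pad = 5L, max_scan = 25L, probe = 8L) {
  structure(
    list(min_read_len = as.integer(min_read_len),
         min_seg_len = as.integer(min_seg_len),
         min_identity = min_identity,
         max_mismatch = as.integer(max_mismatch),
         margin = as.integer(margin),
         min_unexplained = as.integer(min_unexplained),
         cut_pad = as.integer(cut_pad),
         max_scan = as.integer(max_scan),
         probe = as.integer(probe)),
    class = "kiseq_params"
  )
}

# closed vocabulary of detailed labels
.detailed_vocab <- function() {
  ends <- c("HDR", "blunt", "imperfect")
  pairs <- as.vector(outer(ends, ends,
                           function(a, b) sprintf("5' %s, 3' %s", a, b)))
  c("WT", "deletion_lt50", "deletion_ge50", "insertion", "complex_indel",
    pairs, "concatenated", "complex", "unalignable")
}

#' Regroup a detailed outcome label into its broad category
#'
#' Detailed donor-end labels are collapsed the way the field reports them:
#' both ends HDR is perfect HDR; both ends blunt is a blunt integration; an
#' HDR end paired with a blunt or imperfect end is asymmetric HDR; the
#' remaining blunt/imperfect pairings are imperfect integrations.
#' Donor-independent labels, `concatenated` and `complex` map to themselves.
#'
#' @param category_detailed Character vector of detailed labels.
#' @return Character vector of broad categories.
#' @export
regroup_outcome <- function(category_detailed) {
  map <- c(
    "WT" = "WT", "deletion_lt50" = "deletion_lt50",
    "deletion_ge50" = "deletion_ge50", "insertion" = "insertion",
    "complex_indel" = "complex_indel",
    "5' HDR, 3' HDR" = "perfect_HDR",
    "5' blunt, 3' blunt" = "blunt",
    "5' HDR, 3' blunt" = "asymmetric_HDR",
    "5' blunt, 3' HDR" = "asymmetric_HDR",
    "5' HDR, 3' imperfect" = "asymmetric_HDR",
    "5' imperfect, 3' HDR" = "asymmetric_HDR",
    "5' blunt, 3' imperfect" = "imperfect",
    "5' imperfect, 3' blunt" = "imperfect",
    "5' imperfect, 3' imperfect" = "imperfect",
    "concatenated" = "concatenated", "complex" = "complex",
    "unalignable" = "unalignable",
    # broad labels map to themselves, so regrouping is idempotent
    "perfect_HDR" = "perfect_HDR", "blunt" = "blunt",
    "asymmetric_HDR" = "asymmetric_HDR", "imperfect" = "imperfect"
  )
  unknown <- setdiff(unique(category_detailed), names(map))
  if (length(unknown)) {
    stop("unknown detailed category label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(map[category_detailed])
}

# Precomputed classification context for one locus/donor pair.
.ki_context <- function(locus, donor, params) {
  ref <- locus$ref_seq
  L <- nchar(ref)
  dfull <- donor_seq(donor)
  pa <- build_perfect_hdr_allele(locus, donor)
  P <- pa$integration_point
  ilen <- nchar(donor$insert_seq)
  haL <- donor$ha_len_left
  haR <- donor$ha_len_right
  core_len <- min(30L, ilen)
  core_from <- (ilen - core_len) %/% 2L
  core <- substr0(donor$insert_seq, core_from, core_from + core_len)
  core_off <- haL + core_from
  palen <- nchar(pa$seq)
  win5 <- substr0(pa$seq, max(0L, P - haL - params$margin),
                  min(palen, P + params$margin))
  win3 <- substr0(pa$seq, max(0L, P + ilen - params$margin),
                  min(palen, P + ilen + haR + params$margin))
  cs <- .cut_set(locus)
  probe_ref <- seq(0L, L - 20L, by = 50L)
  probe_ins <- if (ilen >= 20L) haL + seq(0L, ilen - 20L, by = 20L) else integer()
  probes <- c(vapply(probe_ref, function(o) substr0(ref, o, o + 20L), ""),
              vapply(probe_ins, function(o) substr0(dfull, o, o + 20L), ""))
  list(
    locus = locus, donor = donor, ref = ref, refraw = charToRaw(ref), L = L,
    dfull = dfull, draw = charToRaw(dfull), dlen = nchar(dfull),
    pa = pa, P = P, ilen = ilen, haL = haL, haR = haR,
    core = core, core_off = core_off, core_len = core_len,
    win5 = win5, win3 = win3, minc = cs[1], maxc = cs[2],
    pdict = Biostrings::PDict(Biostrings::DNAStringSet(probes))
  )
}

# cluster 1-based hit starts that are within `w` of each other
.cluster_starts <- function(starts, w) {
  if (length(starts) == 0L) return(integer())
  starts <- sort(starts)
  keep <- c(TRUE, diff(starts) > w)
  starts[keep]
}

#' Classify reads into repair-outcome categories
#'
#' Each read is oriented, decomposed into reference and donor alignment
#' segments, and assigned a detailed and a broad repair-outcome category.
#' Donor-free reads are classified as WT, deletions below/at-or-above 50 nt,
#' insertions or complex indels from the indel content of their alignment to
#' the reference around the cut window. Donor-bearing reads get a 5' and 3'
#' end status (HDR, blunt or imperfect, with precedence HDR > blunt >
#' imperfect), are called concatenated when two or more donor copies are
#' present, and complex when a large read span matches neither parent.
#' Genome-donor junction records (coordinates, untemplated insertion,
#' microhomology length) are attached for downstream microhomology analysis.
#'
#' @param reads A data frame with columns `read_id` and `seq`, a character
#'   vector of sequences, a `Biostrings::DNAStringSet`, or a path to a
#'   FASTA/FASTQ file.
#' @param locus A [locus_spec()] object.
#' @param donor A [donor_spec()] object.
#' @param params A [classifier_params()] list.
#' @return A tibble with one row per read: `read_id`, `orientation`,
#'   `category_detailed`, `category_broad`, `end5`, `end3`, `donor_copies`,
#'   `del_start`, `del_end`, `del_intervals` (list), `ins_len`,
#'   `unexplained_len`, `junctions` (list of junction tibbles), `flag`.
#' @export
classify_reads <- function(reads, locus, donor, params = classifier_params()) {
  reads <- .as_reads_tibble(reads)
  stopifnot(inherits(locus, "kiseq_locus"), inherits(donor, "kiseq_donor"))
  ctx <- .ki_context(locus, donor, params)
  n_read <- nchar(reads$seq)

  seqs <- Biostrings::DNAStringSet(reads$seq)
  rcs <- Biostrings::reverseComplement(seqs)
  vf <- colSums(Biostrings::vcountPDict(ctx$pdict, seqs))
  vr <- colSums(Biostrings::vcountPDict(ctx$pdict, rcs))
  orientation <- ifelse(vr > vf, "-", "+")
  oseq <- as.character(seqs)
  oseq[orientation == "-"] <- as.character(rcs)[orientation == "-"]
  oset <- Biostrings::DNAStringSet(oseq)

  core_mm <- min(2L, max(0L, ctx$core_len %/% 12L))
  hits_f <- Biostrings::vmatchPattern(ctx$core, oset, max.mismatch = core_mm)
  hits_r <- Biostrings::vmatchPattern(revcomp(ctx$core), oset,
                                      max.mismatch = core_mm)
  hdr5 <- Biostrings::vcountPattern(ctx$win5, oset,
                                    max.mismatch = params$max_mismatch) > 0
  hdr3 <- Biostrings::vcountPattern(ctx$win3, oset,
                                    max.mismatch = params$max_mismatch) > 0

  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    if (n_read[i] < params$min_read_len || (vf[i] + vr[i]) == 0L) {
      out[[i]] <- .call_row(category_detailed = "unalignable",
                            flag = "unalignable")
      next
    }
    sf <- .cluster_starts(BiocGenerics::start(hits_f[[i]]), ctx$core_len)
    sr <- .cluster_starts(BiocGenerics::start(hits_r[[i]]), ctx$core_len)
    copies <- length(sf) + length(sr)
    if (copies == 0L) {
      out[[i]] <- .classify_free(oseq[i], ctx, params)
    } else if (copies >= 2L) {
      out[[i]] <- .call_row(category_detailed = "concatenated",
                            donor_copies = copies)
    } else if (length(sf) == 0L) {
      out[[i]] <- .call_row(category_detailed = "complex", donor_copies = 1L,
                            flag = "reverse_oriented_donor")
    } else {
      out[[i]] <- .classify_donor(oseq[i], ctx, params, sf[1],
                                  hdr5[i], hdr3[i])
    }
  }
  res <- dplyr::bind_rows(out)
  res$read_id <- reads$read_id
  res$orientation <- orientation
  res$category_broad <- regroup_outcome(res$category_detailed)
  dplyr::relocate(res, "read_id", "orientation", "category_detailed",
                  "category_broad")
}

#' Classify a single read
#'
#' @param read A single sequence (character).
#' @inheritParams classify_reads
#' @return A one-row call tibble; see [classify_reads()].
#' @export
classify_read <- function(read, locus, donor, params = classifier_params()) {
  classify_reads(tibble::tibble(read_id = "read", seq = toupper(read)),
                 locus, donor, params)
}

# template for one call row
.call_row <- function(category_detailed, end5 = NA_character_,
                      end3 = NA_character_, donor_copies = 0L,
                      del_start = NA_integer_, del_end = NA_integer_,
                      del_intervals = list(NULL), ins_len = NA_integer_,
                      unexplained_len = 0L, junctions = list(NULL),
                      flag = NA_character_) {
  tibble::tibble(
    category_detailed = category_detailed, end5 = end5, end3 = end3,
    donor_copies = as.integer(donor_copies),
    del_start = as.integer(del_start), del_end = as.integer(del_end),
    del_intervals = del_intervals, ins_len = as.integer(ins_len),
    unexplained_len = as.integer(unexplained_len),
    junctions = junctions, flag = flag
  )
}

.jn_row <- function(side, up_parent, up_pos, down_parent, down_pos,
                    untemplated, mh, end_status) {
  tibble::tibble(side = side, up_parent = up_parent,
                 up_pos = as.integer(up_pos), down_parent = down_parent,
                 down_pos = as.integer(down_pos), untemplated = untemplated,
                 mh = as.integer(mh), end_status = end_status)
}

# does the placement-ambiguity span of interval [a, b) (run extends right by
# `run`) overlap the padded cut window?
.overlaps_cut <- function(a, b, run, ctx, params) {
  a <= ctx$maxc + params$cut_pad && (b + run) >= ctx$minc - params$cut_pad
}

# ---- donor-free classification -------------------------------------------

.classify_free <- function(s, ctx, params) {
  sraw <- charToRaw(s)
  n <- length(sraw)
  L <- ctx$L
  x <- .extend_fwd(sraw, ctx$refraw, 1L, 1L, params$probe)$len
  y <- .extend_bwd(sraw, ctx$refraw, n, L, params$probe)$len

  if (n == L && x + y >= n) return(.call_row("WT"))

  if (L > n && x + y >= n) {
    del <- L - n
    de_ <- L - y
    ds_ <- de_ - del
    la <- .left_align_interval(ctx$refraw, ds_, de_)
    run <- junction_mh_length(ctx$ref, la[1], ctx$ref, la[2], params$max_scan)
    if (.overlaps_cut(la[1], la[2], run, ctx, params)) {
      lab <- if (del < 50) "deletion_lt50" else "deletion_ge50"
      return(.call_row(lab, del_start = la[1], del_end = la[2],
                       del_intervals = list(matrix(la, ncol = 2))))
    }
    return(.call_row("WT"))
  }

  if (n > L && x + y >= L) {
    ins <- n - L
    p0 <- L - y
    if (p0 <= ctx$maxc + params$cut_pad && x >= ctx$minc - params$cut_pad) {
      return(.call_row("insertion", ins_len = ins))
    }
    return(.call_row("WT"))
  }

  dr <- L - x - y
  dq <- n - x - y
  if (dr >= 2L && dq >= 2L &&
      .overlaps_cut(x, L - y, 0L, ctx, params)) {
    return(.call_row("complex_indel", del_start = x, del_end = L - y,
                     del_intervals = list(matrix(c(x, L - y), ncol = 2)),
                     ins_len = dq, unexplained_len = dq))
  }
  .classify_free_fallback(s, ctx, params)
}

# Full dynamic-programming alignment fallback for donor-free reads the fast
# path cannot explain (typically reads carrying sequencing indels). Indels of
# <= 1 nt outside the cut window are attributed to sequencing noise.
.classify_free_fallback <- function(s, ctx, params) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -6,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s), Biostrings::DNAString(ctx$ref),
    type = "global", substitutionMatrix = sm,
    gapOpening = 4, gapExtension = 1
  )
  ops <- .alignment_indels(aln, ctx$refraw)
  noise <- (ops$width <= 1L) &
    !(ops$ref_start <= ctx$maxc + params$cut_pad &
        ops$ref_end >= ctx$minc - params$cut_pad)
  ops <- ops[!noise, , drop = FALSE]
  dels <- ops[ops$type == "del", , drop = FALSE]
  inss <- ops[ops$type == "ins", , drop = FALSE]
  in_win <- function(o) {
    o[o$ref_start <= ctx$maxc + params$cut_pad &
        o$ref_end >= ctx$minc - params$cut_pad, , drop = FALSE]
  }
  dw <- in_win(dels)
  iw <- in_win(inss)
  if (nrow(dw) > 0 && nrow(iw) > 0) {
    return(.call_row("complex_indel",
                     del_start = dw$ref_start[1], del_end = dw$ref_end[1],
                     del_intervals = list(cbind(dw$ref_start, dw$ref_end)),
                     ins_len = sum(iw$width)))
  }
  if (nrow(dw) >= 2) {
    return(.call_row("complex_indel",
                     del_start = dw$ref_start[1], del_end = dw$ref_end[1],
                     del_intervals = list(cbind(dw$ref_start, dw$ref_end))))
  }
  if (nrow(dw) == 1) {
    lab <- if (dw$width[1] < 50) "deletion_lt50" else "deletion_ge50"
    return(.call_row(lab, del_start = dw$ref_start[1], del_end = dw$ref_end[1],
                     del_intervals = list(cbind(dw$ref_start, dw$ref_end))))
  }
  if (nrow(iw) >= 1) {
    return(.call_row("insertion", ins_len = sum(iw$width)))
  }
  .call_row("WT")
}

# Extract indels (ref coordinates, 0-based half-open, deletions left-aligned)
# from a global pairwiseAlignment.
.alignment_indels <- function(aln, refraw) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  refpos <- 0L
  res <- list()
  i <- 1L
  m <- length(p)
  while (i <= m) {
    if (p[i] == "-") {                      # gap in read: deletion of ref
      j <- i
      while (j <= m && p[j] == "-") j <- j + 1L
      w <- j - i
      la <- .left_align_interval(refraw, refpos, refpos + w)
      res[[length(res) + 1L]] <- data.frame(
        type = "del", ref_start = la[1], ref_end = la[2], width = w)
      refpos <- refpos + w
      i <- j
    } else if (s[i] == "-") {               # gap in ref: insertion in read
      j <- i
      while (j <= m && s[j] == "-") j <- j + 1L
      w <- j - i
      res[[length(res) + 1L]] <- data.frame(
        type = "ins", ref_start = refpos, ref_end = refpos, width = w)
      i <- j
    } else {
      refpos <- refpos + 1L
      i <- i + 1L
    }
  }
  if (length(res) == 0L) {
    return(data.frame(type = character(), ref_start = integer(),
                      ref_end = integer(), width = integer()))
  }
  do.call(rbind, res)
}

# ---- donor-bearing classification ----------------------------------------

# Decompose a single-donor-copy read around the core anchor and analyze both
# genome-donor junctions.
.donor_decompose <- function(s, ctx, params, r0) {
  sraw <- charToRaw(s)
  n <- length(sraw)
  d0 <- ctx$core_off + 1L
  eb <- .extend_bwd(sraw, ctx$draw, r0, d0, params$probe)
  ef <- .extend_fwd(sraw, ctx$draw, r0, d0, params$probe)
  q5 <- r0 - eb$len            # 0-based read start of donor segment
  ds <- d0 - eb$len            # 0-based donor start coordinate
  qe <- (r0 - 1L) + ef$len     # 0-based read end (exclusive) of donor segment
  de <- (d0 - 1L) + ef$len     # 0-based donor end coordinate (exclusive)
  x <- .extend_fwd(sraw, ctx$refraw, 1L, 1L, params$probe)$len
  y <- .extend_bwd(sraw, ctx$refraw, n, ctx$L, params$probe)$len
  list(n = n, q5 = q5, ds = ds, qe = qe, de = de, x = x, y = y,
       g5 = q5 - x, g3 = (n - y) - qe, s = s)
}

.donor_junction5 <- function(dec, ctx, params, hdr5) {
  status <- if (hdr5) {
    "HDR"
  } else if (dec$g5 <= 0L && dec$ds == 0L &&
             dec$q5 >= ctx$minc && dec$q5 <= ctx$maxc) {
    "blunt"
  } else {
    "imperfect"
  }
  jn <- if (status == "HDR") NULL else if (dec$g5 > 0L) {
    .jn_row("5prime", "reference", dec$x, "donor", dec$ds,
            substr0(dec$s, dec$x, dec$q5), 0L, status)
  } else {
    .jn_row("5prime", "reference", dec$q5, "donor", dec$ds, "",
            junction_mh_length(ctx$ref, dec$q5, ctx$dfull, dec$ds,
                               params$max_scan),
            status)
  }
  list(status = status, jn = jn)
}

.donor_junction3 <- function(dec, ctx, params, hdr3) {
  ov <- dec$qe - (dec$n - dec$y)          # junction placement overlap
  ref_resume_right <- (ctx$L - dec$y) + ov
  status <- if (hdr3) {
    "HDR"
  } else if (dec$g3 <= 0L && dec$de == ctx$dlen &&
             ref_resume_right >= ctx$minc && ref_resume_right <= ctx$maxc) {
    "blunt"
  } else {
    "imperfect"
  }
  jn <- if (status == "HDR") NULL else if (dec$g3 > 0L) {
    .jn_row("3prime", "donor", dec$de, "reference", ctx$L - dec$y,
            substr0(dec$s, dec$qe, dec$n - dec$y), 0L, status)
  } else {
    a3 <- dec$de - ov
    b3 <- ctx$L - dec$y
    .jn_row("3prime", "donor", a3, "reference", b3, "",
            junction_mh_length(ctx$dfull, a3, ctx$ref, b3, params$max_scan),
            status)
  }
  list(status = status, jn = jn)
}

.classify_donor <- function(s, ctx, params, r0, hdr5, hdr3) {
  dec <- .donor_decompose(s, ctx, params, r0)
  unexp <- max(dec$g5, 0L) + max(dec$g3, 0L)
  if (dec$g5 >= params$min_unexplained || dec$g3 >= params$min_unexplained) {
    return(.call_row("complex", donor_copies = 1L, unexplained_len = unexp,
                     flag = "possible_genomic_insertion"))
  }
  if (dec$x < params$min_seg_len || dec$y < params$min_seg_len) {
    return(.call_row("complex", donor_copies = 1L, unexplained_len = unexp,
                     flag = "missing_genomic_arm"))
  }
  j5 <- .donor_junction5(dec, ctx, params, hdr5)
  j3 <- .donor_junction3(dec, ctx, params, hdr3)
  jn <- dplyr::bind_rows(j5$jn, j3$jn)
  .call_row(sprintf("5' %s, 3' %s", j5$status, j3$status),
            end5 = j5$status, end3 = j3$status, donor_copies = 1L,
            unexplained_len = unexp,
            junctions = if (nrow(jn) > 0) list(jn) else list(NULL))
}

#' End status of a donor-bearing read at one junction
#'
#' Calls the 5' or 3' genome-donor junction of a read as HDR (the read
#' matches the perfect-HDR allele contiguously across the homology-arm
#' window), blunt (the donor terminal base is retained, the genomic end sits
#' at an accepted cut position and no untemplated bases intervene) or
#' imperfect (anything else: donor trimming, genomic resection or junction
#' insertion). Precedence is HDR > blunt > imperfect.
#'
#' @param read A single read sequence (character, already genome-oriented).
#' @param side `"5prime"` or `"3prime"`.
#' @inheritParams classify_reads
#' @return A list with `status` and `junction` (a one-row junction tibble,
#'   or NULL for an HDR end).
#' @export
call_end_status <- function(read, side = c("5prime", "3prime"),
                            locus, donor, params = classifier_params()) {
  side <- match.arg(side)
  ctx <- .ki_context(locus, donor, params)
  oset <- Biostrings::DNAStringSet(toupper(read))
  core_mm <- min(2L, max(0L, ctx$core_len %/% 12L))
  hit <- Biostrings::matchPattern(ctx$core, oset[[1]], max.mismatch = core_mm)
  if (length(hit) == 0L) {
    stop("read carries no donor segment; end status is not applicable",
         call. = FALSE)
  }
  hdr5 <- Biostrings::countPattern(ctx$win5, oset[[1]],
                                   max.mismatch = params$max_mismatch) > 0
  hdr3 <- Biostrings::countPattern(ctx$win3, oset[[1]],
                                   max.mismatch = params$max_mismatch) > 0
  dec <- .donor_decompose(toupper(read), ctx, params,
                          BiocGenerics::start(hit)[1])
  j <- if (side == "5prime") {
    .donor_junction5(dec, ctx, params, hdr5)
  } else {
    .donor_junction3(dec, ctx, params, hdr3)
  }
  list(status = j$status, junction = j$jn)
}

#' Decompose a read into reference/donor alignment segments
#'
#' Tries both orientations and returns the chain of maximal exact-extension
#' segments (reference prefix/suffix, donor segments anchored on the insert)
#' that explains the read, ordered and non-overlapping in read coordinates.
#' Overlapping candidate segments are trimmed left-first so junction
#' coordinates are deterministic (junction ambiguity from microhomology is
#' resolved to the leftmost placement).
#'
#' @param read A single read sequence.
#' @inheritParams classify_reads
#' @return A tibble of segments: `read_start`, `read_end` (0-based,
#'   half-open), `target` (`"reference"`/`"donor"`), `target_start`,
#'   `target_end`, `orientation`, `pident`. Zero rows if the read is
#'   unalignable.
#' @export
align_read <- function(read, locus, donor, params = classifier_params()) {
  read <- toupper(read)
  ctx <- .ki_context(locus, donor, params)
  empty <- tibble::tibble(read_start = integer(), read_end = integer(),
                          target = character(), target_start = integer(),
                          target_end = integer(), orientation = character(),
                          pident = numeric())
  if (nchar(read) < params$min_read_len) return(empty)
  seqs <- Biostrings::DNAStringSet(read)
  rcs <- Biostrings::reverseComplement(seqs)
  vf <- sum(Biostrings::vcountPDict(ctx$pdict, seqs))
  vr <- sum(Biostrings::vcountPDict(ctx$pdict, rcs))
  if (vf + vr == 0L) return(empty)
  orientation <- if (vr > vf) "-" else "+"
  s <- if (orientation == "-") as.character(rcs[[1]]) else read
  sraw <- charToRaw(s)
  n <- length(sraw)

  segs <- list()
  add <- function(rs, re, target, ts, te, mis) {
    if (re - rs <= 0L) return()
    len <- re - rs
    segs[[length(segs) + 1L]] <<- tibble::tibble(
      read_start = rs, read_end = re, target = target,
      target_start = ts, target_end = te, orientation = orientation,
      pident = 100 * (len - mis) / len)
  }
  ex <- .extend_fwd(sraw, ctx$refraw, 1L, 1L, params$probe)
  if (ex$len > 0L) add(0L, ex$len, "reference", 0L, ex$len, ex$mis)
  ey <- .extend_bwd(sraw, ctx$refraw, n, ctx$L, params$probe)
  if (ey$len > 0L && ey$len < n) {
    add(n - ey$len, n, "reference", ctx$L - ey$len, ctx$L, ey$mis)
  }
  core_mm <- min(2L, max(0L, ctx$core_len %/% 12L))
  hits <- .cluster_starts(
    BiocGenerics::start(Biostrings::matchPattern(ctx$core, seqs[[1]],
                                                 max.mismatch = core_mm)),
    ctx$core_len)
  if (orientation == "-") {
    hits <- .cluster_starts(
      BiocGenerics::start(Biostrings::matchPattern(ctx$core, rcs[[1]],
                                                   max.mismatch = core_mm)),
      ctx$core_len)
  }
  for (r0 in hits) {
    dec <- .donor_decompose(s, ctx, params, r0)
    add(dec$q5, dec$qe, "donor", dec$ds, dec$de, 0L)
  }
  if (length(segs) == 0L) return(empty)
  segs <- dplyr::arrange(dplyr::bind_rows(segs), .data$read_start,
                         .data$read_end)
  # junction-placement ambiguity resolved leftmost: trim the upstream
  # segment back to the start of the downstream one
  if (nrow(segs) > 1L) {
    for (i in 2:nrow(segs)) {
      prev_end <- segs$read_end[i - 1L]
      if (segs$read_start[i] < prev_end) {
        shift <- prev_end - segs$read_start[i]
        segs$read_end[i - 1L] <- segs$read_end[i - 1L] - shift
        segs$target_end[i - 1L] <- segs$target_end[i - 1L] - shift
      }
    }
  }
  segs <- dplyr::filter(segs, .data$read_end - .data$read_start > 0)
  keep <- (segs$read_end - segs$read_start >= params$min_seg_len) &
    segs$pident >= params$min_identity
  if (any(keep)) segs <- segs[keep, , drop = FALSE]
  segs
}

# normalize the various accepted read inputs to a tibble(read_id, seq)
.as_reads_tibble <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    return(tibble::tibble(read_id = as.character(reads$read_id),
                          seq = toupper(reads$seq)))
  }
  if (methods::is(reads, "DNAStringSet")) {
    ids <- names(reads) %||% as.character(seq_along(reads))
    return(tibble::tibble(read_id = ids, seq = as.character(reads)))
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    return(read_sequences(reads)[, c("read_id", "seq")])
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read%05d", seq_along(reads))
    return(tibble::tibble(read_id = ids, seq = toupper(reads)))
  }
  stop("unsupported `reads` input", call. = FALSE)
}
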