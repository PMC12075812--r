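#' Describe a target locus and its nuclease cut geometry
#'
#' A locus is the reference amplicon together with the protospacer position
#' and the end chemistry of the nuclease that cuts it. Cas9-class nucleases
#' leave blunt ends (the two strands are cut at the same position); Cas12a
#' (Cpf1)-class nucleases leave staggered ends with a 5' overhang, cutting
#' distal to the PAM. All coordinates are 0-based, half-open offsets into
#' `ref_seq` on the top strand.
#'
#' @param name Label for the locus.
#' @param ref_seq Reference amplicon sequence (uppercase A/C/G/T).
#' @param protospacer_start,protospacer_end 0-based half-open protospacer
#'   interval in `ref_seq`.
#' @param chemistry `"blunt"` (Cas9-like) or `"staggered"` (Cas12a-like).
#' @param cut_offset_top,cut_offset_bottom Cut positions of the top and
#'   bottom strand, as offsets into `ref_seq`. Equal for blunt chemistry;
#'   their absolute difference is the overhang length for staggered
#'   chemistry.
#' @param pam_side Which side of the protospacer carries the PAM
#'   (`"3prime"` for Cas9, `"5prime"` for Cas12a).
#' @param strand Strand of the protospacer (`"+"` or `"-"`).
#' @param integration_point Reference position where the donor insert is
#'   placed by perfect HDR. Defaults to the top-strand cut.
#'
#' @return An object of class `kiseq_locus`.
#' @export
locus_spec <- function(name, ref_seq, protospacer_start, protospacer_end,
                       chemistry = c("blunt", "staggered"),
                       cut_offset_top, cut_offset_bottom = cut_offset_top,
                       pam_side = c("3prime", "5prime"), strand = c("+", "-"),
                       integration_point = NULL) {
  chemistry <- match.arg(chemistry)
  pam_side <- match.arg(pam_side)
  strand <- match.arg(strand)
  .check_dna(ref_seq, "ref_seq")
  L <- nchar(ref_seq)
  if (!(protospacer_start >= 0 && protospacer_start < protospacer_end &&
        protospacer_end <= L)) {
    stop("protospacer interval [", protospacer_start, ", ", protospacer_end,
         ") is not a valid interval within ref_seq (length ", L, ")",
         call. = FALSE)
  }
  if (cut_offset_top < 0 || cut_offset_top > L ||
      cut_offset_bottom < 0 || cut_offset_bottom > L) {
    stop("cut offsets must lie within [0, ", L, "]", call. = FALSE)
  }
  if (chemistry == "blunt" && cut_offset_top != cut_offset_bottom) {
    stop("chemistry is 'blunt' but cut_offset_top (", cut_offset_top,
         ") != cut_offset_bottom (", cut_offset_bottom, ")", call. = FALSE)
  }
  if (chemistry == "staggered" && cut_offset_top == cut_offset_bottom) {
    stop("chemistry is 'staggered' but cut_offset_top == cut_offset_bottom; ",
         "a staggered cut needs a nonzero overhang", call. = FALSE)
  }
  ip <- as.integer(integration_point %||% cut_offset_top)
  if (ip < 0 || ip > L) stop("integration_point outside ref_seq", call. = FALSE)
  structure(
    list(
      name = name, ref_seq = ref_seq,
      protospacer_start = as.integer(protospacer_start),
      protospacer_end = as.integer(protospacer_end),
      pam_side = pam_side, strand = strand, chemistry = chemistry,
      cut_offset_top = as.integer(cut_offset_top),
      cut_offset_bottom = as.integer(cut_offset_bottom),
      integration_point = ip
    ),
    class = "kiseq_locus"
  )
}

#' @export
print.kiseq_locus <- function(x, ...) {
  cat("<kiseq_locus> ", x$name, "\n", sep = "")
  cat("  reference: ", nchar(x$ref_seq), " nt; protospacer [",
      x$protospacer_start, ", ", x$protospacer_end, ") on ", x$strand,
      "\n", sep = "")
  cat("  chemistry: ", x$chemistry, "; cuts top/bottom ", x$cut_offset_top,
      "/", x$cut_offset_bottom, "; integration point ", x$integration_point,
      "\n", sep = "")
  invisible(x)
}

#' Cut positions on the two strands
#'
#' @param locus A [locus_spec()] object.
#' @return Named integer vector `c(top = ..., bottom = ...)`. For blunt
#'   chemistry the two values are equal; for staggered chemistry the
#'   half-open interval from `min` to `max` is the overhang span.
#' @export
cut_positions <- function(locus) {
  stopifnot(inherits(locus, "kiseq_locus"))
  c(top = locus$cut_offset_top, bottom = locus$cut_offset_bottom)
}

# interval [min, max] of strand cut positions accepted as "zero resection"
.cut_set <- function(locus) {
  range(c(locus$cut_offset_top, locus$cut_offset_bottom))
}

#' Describe a knock-in donor
#'
#' A donor is an insert (e.g. a fluorescent-protein coding sequence) flanked
#' by left and right homology arms copied from the sequence around the
#' integration point.
#'
#' @param insert_seq Insert sequence.
#' @param ha_left,ha_right Homology arm sequences (5' and 3' of the insert).
#' @return An object of class `kiseq_donor`.
#' @export
donor_spec <- function(insert_seq, ha_left, ha_right) {
  .check_dna(insert_seq, "insert_seq")
  .check_dna(ha_left, "ha_left")
  .check_dna(ha_right, "ha_right")
  if (nchar(ha_left) < 1 || nchar(ha_right) < 1) {
    stop("homology arms must have length >= 1", call. = FALSE)
  }
  structure(
    list(insert_seq = insert_seq, ha_left = ha_left, ha_right = ha_right,
         ha_len_left = nchar(ha_left), ha_len_right = nchar(ha_right)),
    class = "kiseq_donor"
  )
}

#' @export
print.kiseq_donor <- function(x, ...) {
  cat("<kiseq_donor> insert ", nchar(x$insert_seq), " nt; HAs ",
      x$ha_len_left, "/", x$ha_len_right, " nt\n", sep = "")
  invisible(x)
}

#' Full donor sequence (left arm + insert + right arm)
#' @param donor A [donor_spec()] object.
#' @return Character string.
#' @export
donor_seq <- function(donor) {
  stopifnot(inherits(donor, "kiseq_donor"))
  paste0(donor$ha_left, donor$insert_seq, donor$ha_right)
}

#' Check that donor homology arms match the reference flanks
#'
#' The left arm must equal the reference substring ending at the integration
#' point and the right arm the substring starting there.
#'
#' @param locus A [locus_spec()] object.
#' @param donor A [donor_spec()] object.
#' @param integration_point 0-based reference position; defaults to the
#'   locus integration point.
#' @return A list with `ok` (logical) and `mismatches`, a tibble of reference
#'   positions where an arm disagrees with the reference.
#' @export
validate_donor_homology <- function(locus, donor,
                                    integration_point = locus$integration_point) {
  stopifnot(inherits(locus, "kiseq_locus"), inherits(donor, "kiseq_donor"))
  P <- as.integer(integration_point)
  L <- nchar(locus$ref_seq)
  if (P < 0 || P > L) stop("integration_point outside ref_seq", call. = FALSE)
  if (P - donor$ha_len_left < 0) {
    stop("integration_point ", P, " leaves insufficient 5' flank for a ",
         donor$ha_len_left, " nt left homology arm", call. = FALSE)
  }
  if (P + donor$ha_len_right > L) {
    stop("integration_point ", P, " leaves insufficient 3' flank for a ",
         donor$ha_len_right, " nt right homology arm", call. = FALSE)
  }
  flank_l <- substr0(locus$ref_seq, P - donor$ha_len_left, P)
  flank_r <- substr0(locus$ref_seq, P, P + donor$ha_len_right)
  mm <- function(arm, flank, ref_offset) {
    a <- charToRaw(arm); b <- charToRaw(flank)
    idx <- which(a != b)
    tibble::tibble(arm_pos = idx - 1L, ref_pos = ref_offset + idx - 1L,
                   arm_base = if (length(idx)) substring(arm, idx, idx) else character(),
                   ref_base = if (length(idx)) substring(flank, idx, idx) else character())
  }
  mml <- mm(donor$ha_left, flank_l, P - donor$ha_len_left)
  mmr <- mm(donor$ha_right, flank_r, P)
  mismatches <- dplyr::bind_rows(
    dplyr::mutate(mml, arm = "ha_left", .before = 1),
    dplyr::mutate(mmr, arm = "ha_right", .before = 1)
  )
  list(ok = nrow(mismatches) == 0L, mismatches = mismatches)
}

#' Construct the expected perfect-HDR allele
#'
#' Perfect HDR is the seamless incorporation of the donor insert at the
#' integration point: the product is the reference with the insert spliced
#' in and nothing else changed.
#'
#' @inheritParams validate_donor_homology
#' @return An object of class `kiseq_perfect_allele` with fields `seq`,
#'   `insert_start`, `insert_end` (0-based, half-open in allele coordinates).
#' @export
build_perfect_hdr_allele <- function(locus, donor,
                                     integration_point = locus$integration_point) {
  v <- validate_donor_homology(locus, donor, integration_point)
  if (!v$ok) {
    stop("donor homology arms do not match the reference flanks (",
         nrow(v$mismatches), " mismatching position(s)); see ",
         "validate_donor_homology() for the report", call. = FALSE)
  }
  P <- as.integer(integration_point)
  seq <- paste0(substr0(locus$ref_seq, 0, P), donor$insert_seq,
                substr0(locus$ref_seq, P, nchar(locus$ref_seq)))
  structure(
    list(seq = seq, insert_start = P, insert_end = P + nchar(donor$insert_seq),
         integration_point = P),
    class = "kiseq_perfect_allele"
  )
}

#' @export
print.kiseq_perfect_allele <- function(x, ...) {
  cat("<kiseq_perfect_allele> ", nchar(x$seq), " nt; insert at [",
      x$insert_start, ", ", x$insert_end, ")\n", sep = "")
  invisible(x)
}

#' Read a locus + donor configuration file
#'
#' One structured YAML or JSON file describes the locus and donor. Keys:
#' `name`, `ref_seq` (or `ref_fasta`), `protospacer` (`start`, `end`,
#' `strand`), `pam_side`, `chemistry`, `cut_offset_top`,
#' `cut_offset_bottom`, `integration_point`, and `donor` (`insert_seq`,
#' `ha_left`, `ha_right`, each either literal or a FASTA path).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `locus` and `donor`.
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  get_seq <- function(x) {
    if (is.null(x)) return(NULL)
    if (file.exists(x) && grepl("\\.(fa|fasta|fa\\.gz|fasta\\.gz)$", x,
                                ignore.case = TRUE)) {
      as.character(Biostrings::readDNAStringSet(x)[[1]])
    } else toupper(x)
  }
  ref <- get_seq(cfg$ref_seq %||% cfg$ref_fasta)
  if (is.null(ref)) stop("config must provide ref_seq or ref_fasta", call. = FALSE)
  locus <- locus_spec(
    name = cfg$name %||% "locus",
    ref_seq = ref,
    protospacer_start = cfg$protospacer$start,
    protospacer_end = cfg$protospacer$end,
    chemistry = cfg$chemistry %||% "blunt",
    cut_offset_top = cfg$cut_offset_top,
    cut_offset_bottom = cfg$cut_offset_bottom %||% cfg$cut_offset_top,
    pam_side = cfg$pam_side %||% "3prime",
    strand = cfg$protospacer$strand %||% "+",
    integration_point = cfg$integration_point
  )
  donor <- donor_spec(
    insert_seq = get_seq(cfg$donor$insert_seq),
    ha_left = get_seq(cfg$donor$ha_left),
    ha_right = get_seq(cfg$donor$ha_right)
  )
  list(locus = locus, donor = donor)
}

#' Generate a synthetic example locus and matching donor
#'
#' Builds a random reference amplicon with a central protospacer and a donor
#' whose homology arms are copied from the reference around the cut, using
#' the conventional cut geometry for each chemistry: a blunt cut 3 nt 5' of
#' the PAM (Cas9 convention) or a staggered cut with a 5 nt 5' overhang
#' distal to the PAM (Cas12a convention). Used throughout the test-suite and
#' by the read simulator as a stand-in for a real tagged locus.
#'
#' @param chemistry `"blunt"` or `"staggered"`.
#' @param ref_len Reference amplicon length.
#' @param ha_len Homology arm length (the tagging donors emulated here carry
#'   90 nt arms).
#' @param insert_len Insert length.
#' @param seed Optional integer seed for reproducibility.
#' @return List with elements `locus` and `donor`.
#' @export
example_locus <- function(chemistry = c("blunt", "staggered"),
                          ref_len = 420L, ha_len = 90L, insert_len = 60L,
                          seed = NULL) {
  chemistry <- match.arg(chemistry)
  .with_seed(seed, {
    ref <- .random_dna(ref_len)
    ps <- as.integer(ref_len / 2) - 10L
    pe <- ps + 20L
    if (chemistry == "blunt") {
      cut_top <- pe - 3L
      cut_bot <- cut_top
      pam_side <- "3prime"
    } else {
      cut_top <- ps + 18L
      cut_bot <- ps + 23L
      pam_side <- "5prime"
    }
    locus <- locus_spec(
      name = paste0("synthetic_", chemistry), ref_seq = ref,
      protospacer_start = ps, protospacer_end = pe, chemistry = chemistry,
      cut_offset_top = cut_top, cut_offset_bottom = cut_bot,
      pam_side = pam_side
    )
    P <- locus$integration_point
    donor <- donor_spec(
      insert_seq = .random_dna(insert_len),
      ha_left = substr0(ref, P - ha_len, P),
      ha_right = substr0(ref, P, P + ha_len)
    )
    list(locus = locus, donor = donor)
  })
}
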