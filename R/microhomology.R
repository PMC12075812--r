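#' Microhomology length at a junction between two parent sequences
#'
#' A junction joins the prefix `U[0, a)` of an upstream parent to the suffix
#' `D[b, len)` of a downstream parent. Its microhomology length is the number
#' of flanking bases attributable to either parent: the maximal `kL` with
#' `U[a-kL, a) == D[b-kL, b)` plus the maximal `kR` with
#' `U[a, a+kR) == D[b, b+kR)`. Equivalently it is the number of equivalent
#' placements of the junction that produce the identical joined sequence,
#' minus one. Microhomology of 2 nt or more at a deletion or donor junction
#' is the classic signature of annealing-mediated (MMEJ-type) repair.
#'
#' @param u_seq Upstream parent sequence.
#' @param a 0-based junction coordinate in `u_seq` (bases `[0, a)` retained).
#' @param d_seq Downstream parent sequence.
#' @param b 0-based junction coordinate in `d_seq` (bases `[b, len)` retained).
#' @param max_scan Maximum bases scanned on each side (default 25, which
#'   comfortably covers the 2-20 nt range of MMEJ substrates).
#' @return Integer microhomology length (>= 0).
#' @export
#' @examples
#' junction_mh_length("GGGGCAT", 7, "CATAAAA", 3) # 3
junction_mh_length <- function(u_seq, a, d_seq, b, max_scan = 25L) {
  stopifnot(a >= 0, a <= nchar(u_seq), b >= 0, b <= nchar(d_seq))
  u <- charToRaw(u_seq)
  d <- charToRaw(d_seq)
  kL <- 0L
  while (kL < max_scan && a - kL >= 1L && b - kL >= 1L &&
         u[a - kL] == d[b - kL]) {
    kL <- kL + 1L
  }
  kR <- 0L
  while (kR < max_scan && a + kR + 1L <= length(u) && b + kR + 1L <= length(d) &&
         u[a + kR + 1L] == d[b + kR + 1L]) {
    kR <- kR + 1L
  }
  kL + kR
}

#' Microhomology length distribution over genome-donor junctions
#'
#' Tabulates junction microhomology lengths over the eligible junction set of
#' a classified call table: the junction at the non-HDR end of each
#' asymmetric-HDR read whose non-HDR end is imperfect, plus both genome-donor
#' junctions of each imperfect (both ends non-HDR) read. Each frequency is
#' the percentage of eligible junctions with that microhomology length.
#' Junctions carrying an untemplated insertion have no placement ambiguity;
#' they enter the denominator with length 0 unless
#' `include_untemplated = FALSE`.
#'
#' @param calls A call tibble from [classify_reads()].
#' @param include_untemplated Keep junctions with untemplated insertions in
#'   the denominator (default TRUE).
#' @return A tibble of class `kiseq_mh_distribution` with columns
#'   `mh_length`, `count`, `percent`, and attributes `total_junctions` and
#'   `freq_mh_ge2` (percentage of junctions with microhomology >= 2 nt).
#' @export
mh_distribution <- function(calls, include_untemplated = TRUE) {
  stopifnot(is.data.frame(calls))
  jn <- eligible_junctions(calls)
  if (!include_untemplated && nrow(jn) > 0) {
    jn <- dplyr::filter(jn, !nzchar(.data$untemplated))
  }
  if (nrow(jn) == 0L) {
    out <- tibble::tibble(mh_length = integer(), count = integer(),
                          percent = numeric())
    attr(out, "total_junctions") <- 0L
    attr(out, "freq_mh_ge2") <- NA_real_
    class(out) <- c("kiseq_mh_distribution", class(out))
    return(out)
  }
  out <- jn |>
    dplyr::count(mh_length = .data$mh, name = "count") |>
    dplyr::arrange(.data$mh_length) |>
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count))
  attr(out, "total_junctions") <- nrow(jn)
  attr(out, "freq_mh_ge2") <- 100 * sum(jn$mh >= 2) / nrow(jn)
  class(out) <- c("kiseq_mh_distribution", class(out))
  out
}

#' Junctions eligible for microhomology analysis
#'
#' @param calls A call tibble from [classify_reads()].
#' @return Tibble of junction records (one row per eligible junction) with
#'   the originating `read_id` and `category_broad`.
#' @export
eligible_junctions <- function(calls) {
  stopifnot(is.data.frame(calls), "junctions" %in% names(calls))
  keep <- calls$category_broad %in% c("asymmetric_HDR", "imperfect")
  if (!any(keep)) {
    return(tibble::tibble(read_id = character(), category_broad = character(),
                          side = character(), mh = integer(),
                          untemplated = character()))
  }
  sub <- calls[keep, , drop = FALSE]
  jn <- purrr::map2_dfr(sub$junctions, seq_len(nrow(sub)), function(j, i) {
    if (is.null(j) || nrow(j) == 0L) return(NULL)
    j$read_id <- sub$read_id[i]
    j$category_broad <- sub$category_broad[i]
    j
  })
  if (nrow(jn) == 0L) {
    return(tibble::tibble(read_id = character(), category_broad = character(),
                          side = character(), mh = integer(),
                          untemplated = character()))
  }
  dplyr::filter(
    jn,
    (.data$category_broad == "asymmetric_HDR" & .data$end_status == "imperfect") |
      (.data$category_broad == "imperfect" & .data$end_status != "HDR")
  )
}

#' @export
print.kiseq_mh_distribution <- function(x, ...) {
  cat("<kiseq_mh_distribution> ", attr(x, "total_junctions"),
      " genome-donor junctions", sep = "")
  if (!is.na(attr(x, "freq_mh_ge2"))) {
    cat("; MH >= 2 nt: ", sprintf("%.2f%%", attr(x, "freq_mh_ge2")), sep = "")
  }
  cat("\n")
  NextMethod()
}

#' @rdname mh_distribution
#' @param object A `kiseq_mh_distribution`.
#' @param ... Unused.
#' @method autoplot kiseq_mh_distribution
#' @export
autoplot.kiseq_mh_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mh_length, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Microhomology length (nt)",
                  y = "% of genome-donor junctions",
                  title = "Microhomology at genome-donor junctions") +
    ggplot2::theme_classic()
}
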