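#' Per-position deletion percentage profile
#'
#' For reads of the analyzed class (by default sub-50 nt deletions, the
#' class positional deletion spectra are reported for), computes at each
#' reference position the percentage of analyzed reads whose deletion
#' interval covers that position. Deletions are counted at their
#' left-aligned placement only, so profiles are deterministic. A read with
#' several deletion intervals contributes once per covered position.
#'
#' @param calls A call tibble from [classify_reads()].
#' @param locus The [locus_spec()] the calls were made against (supplies the
#'   reference length and cut positions for plotting).
#' @param categories Classes analyzed (default `"deletion_lt50"`).
#' @param denominator `"class"` (reads in the analyzed class, the
#'   convention used for positional deletion spectra) or `"all"` (all
#'   classified reads).
#' @return A tibble of class `kiseq_deletion_profile` with columns
#'   `position` (0-based) and `percent`, and attributes `n_reads`,
#'   `categories` and `cuts`.
#' @export
deletion_profile <- function(calls, locus, categories = "deletion_lt50",
                             denominator = c("class", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(calls), inherits(locus, "kiseq_locus"))
  L <- nchar(locus$ref_seq)
  sel <- dplyr::filter(calls, .data$category_broad %in% categories)
  if (nrow(sel) == 0L) {
    stop("no reads in class ", paste(categories, collapse = "/"),
         "; classify reads (or relax `categories`) before profiling",
         call. = FALSE)
  }
  denom <- if (denominator == "class") nrow(sel) else {
    sum(calls$category_broad != "unalignable")
  }
  cov <- integer(L)
  for (iv in sel$del_intervals) {
    if (is.null(iv)) next
    covered <- logical(L)
    for (r in seq_len(nrow(iv))) {
      a <- max(0L, iv[r, 1]); b <- min(L, iv[r, 2])
      if (b > a) covered[(a + 1L):b] <- TRUE
    }
    cov <- cov + covered
  }
  out <- tibble::tibble(position = 0:(L - 1L), percent = 100 * cov / denom)
  attr(out, "n_reads") <- nrow(sel)
  attr(out, "denominator") <- denom
  attr(out, "categories") <- categories
  attr(out, "cuts") <- cut_positions(locus)
  class(out) <- c("kiseq_deletion_profile", class(out))
  out
}

#' @export
print.kiseq_deletion_profile <- function(x, ...) {
  cat("<kiseq_deletion_profile> ", attr(x, "n_reads"), " reads (",
      paste(attr(x, "categories"), collapse = "/"), ")\n", sep = "")
  NextMethod()
}

#' @rdname deletion_profile
#' @param object A `kiseq_deletion_profile`.
#' @param ... Unused.
#' @method autoplot kiseq_deletion_profile
#' @export
autoplot.kiseq_deletion_profile <- function(object, ...) {
  cuts <- attr(object, "cuts")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$percent)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = unname(cuts), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "Reference position (nt)", y = "% reads with deletion",
                  title = "Positional distribution of deletions") +
    ggplot2::theme_classic()
}

#' Write a deletion-profile plot to file
#'
#' @param profile A [deletion_profile()] result.
#' @param path Output image path (format from extension, e.g. `.png`).
#' @param width,height Plot size in inches.
#' @return The path, invisibly; if the profile has no analyzed reads an
#'   explicit message is emitted and no file is written.
#' @export
profile_plot <- function(profile, path, width = 7, height = 3.5) {
  stopifnot(inherits(profile, "kiseq_deletion_profile"))
  if (attr(profile, "n_reads") == 0L || nrow(profile) == 0L) {
    message("deletion profile is empty; no plot written")
    return(invisible(NULL))
  }
  ggplot2::ggsave(path, autoplot(profile), width = width, height = height,
                  dpi = 150)
  invisible(path)
}
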