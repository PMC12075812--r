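#' Summarize classified reads by outcome category
#'
#' Counts and percentages per broad category over all classified reads, plus
#' percentages within donor-integration events (any donor-bearing category)
#' and within single-donor integration events (perfect HDR, blunt,
#' asymmetric HDR, imperfect) — the denominators the field reports
#' integration spectra against. Unalignable reads are excluded from all
#' denominators and reported in `glance()`.
#'
#' @param calls A call tibble from [classify_reads()].
#' @return An object of class `kiseq_summary`. `tidy()` returns the
#'   per-category tibble (`category`, `n`, `pct_total`, `pct_integration`,
#'   `pct_single_donor`); `glance()` a one-row overview.
#' @export
summarize_outcomes <- function(calls) {
  stopifnot(is.data.frame(calls))
  usable <- dplyr::filter(calls, .data$category_broad != "unalignable")
  if (nrow(usable) == 0L) {
    stop("no classified reads to summarize", call. = FALSE)
  }
  integration_cats <- c("perfect_HDR", "blunt", "asymmetric_HDR", "imperfect",
                        "concatenated", "complex")
  single_donor_cats <- c("perfect_HDR", "blunt", "asymmetric_HDR", "imperfect")
  lvls <- c("WT", "deletion_lt50", "deletion_ge50", "insertion",
            "complex_indel", integration_cats)
  n_total <- nrow(usable)
  n_int <- sum(usable$category_broad %in% integration_cats)
  n_sd <- sum(usable$category_broad %in% single_donor_cats)
  tab <- usable |>
    dplyr::count(category = factor(.data$category_broad, levels = lvls),
                 name = "n", .drop = FALSE) |>
    dplyr::mutate(
      category = as.character(.data$category),
      pct_total = 100 * .data$n / n_total,
      pct_integration = dplyr::if_else(
        .data$category %in% integration_cats & n_int > 0,
        100 * .data$n / n_int, NA_real_),
      pct_single_donor = dplyr::if_else(
        .data$category %in% single_donor_cats & n_sd > 0,
        100 * .data$n / n_sd, NA_real_)
    )
  structure(
    list(by_category = tab,
         totals = tibble::tibble(
           n_reads = nrow(calls), n_classified = n_total,
           n_unalignable = nrow(calls) - n_total,
           n_integration = n_int, n_single_donor = n_sd,
           pct_integration = 100 * n_int / n_total,
           pct_perfect_hdr = 100 * sum(usable$category_broad == "perfect_HDR") /
             n_total)),
    class = "kiseq_summary"
  )
}

#' @export
print.kiseq_summary <- function(x, ...) {
  cat("<kiseq_summary> ", x$totals$n_classified, " classified reads (",
      x$totals$n_unalignable, " unalignable); integration events: ",
      x$totals$n_integration, "\n", sep = "")
  print(x$by_category)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname summarize_outcomes
#' @param x A `kiseq_summary` object.
#' @param ... Unused.
#' @method tidy kiseq_summary
#' @export
tidy.kiseq_summary <- function(x, ...) x$by_category

#' @rdname summarize_outcomes
#' @method glance kiseq_summary
#' @export
glance.kiseq_summary <- function(x, ...) x$totals

#' Compare calls against a simulation truth table
#'
#' @param calls A call tibble from [classify_reads()].
#' @param truth A truth tibble from [simulate_reads()] (or the TSV written
#'   by [simulate_dataset()], read back in).
#' @return A list with `accuracy_detailed`, `accuracy_broad` (percentages
#'   over all truth reads) and `confusion`, a tibble of truth-by-called
#'   broad-category counts.
#' @export
evaluate_calls <- function(calls, truth) {
  stopifnot(is.data.frame(calls), is.data.frame(truth))
  j <- dplyr::inner_join(
    dplyr::select(truth, "read_id", truth_detailed = "category_detailed",
                  truth_broad = "category_broad"),
    dplyr::select(calls, "read_id", called_detailed = "category_detailed",
                  called_broad = "category_broad"),
    by = "read_id"
  )
  if (nrow(j) == 0L) stop("no shared read_ids between calls and truth",
                          call. = FALSE)
  list(
    accuracy_detailed = 100 * mean(j$truth_detailed == j$called_detailed),
    accuracy_broad = 100 * mean(j$truth_broad == j$called_broad),
    confusion = dplyr::count(j, .data$truth_broad, .data$called_broad,
                             name = "n"),
    n = nrow(j)
  )
}
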