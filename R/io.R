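#' Read sequences from FASTA or FASTQ
#'
#' Format is sniffed from content (not the file name); gzip is handled
#' transparently. Duplicate read IDs are suffixed and reported.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @return A tibble with `read_id`, `seq` and `qual` (NA for FASTA input).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "r")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0L) stop("empty sequence file: ", path, call. = FALSE)
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("cannot determine format of ", path,
                   " (first line is neither '>' nor '@')", call. = FALSE)
  if (fmt == "fasta") {
    x <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    qual <- rep(NA_character_, length(x))
  } else {
    x <- tryCatch({
      y <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
      stopifnot(length(y) > 0)
      qual <- unname(as.character(Biostrings::quality(y)))
      y
    }, error = function(e) {
      stop("malformed FASTQ in ", path, " (possibly a truncated record): ",
           conditionMessage(e), call. = FALSE)
    })
  }
  if (length(x) == 0L) stop("no records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    message(sum(duplicated(ids)), " duplicate read ID(s) in ", path,
            "; suffixing")
    ids <- make.unique(ids, sep = "_dup")
  }
  tibble::tibble(read_id = ids, seq = unname(as.character(x)), qual = qual)
}

#' Write reads as FASTQ
#'
#' Constant Q40 quality characters are emitted, matching the quality floor
#' used to select HiFi reads. Gzip compression if `path` ends in `.gz`.
#'
#' @param reads Tibble with `read_id` and `seq` (e.g. from
#'   [simulate_reads()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  dss <- Biostrings::DNAStringSet(reads$seq)
  names(dss) <- reads$read_id
  q <- Biostrings::PhredQuality(strrep("I", nchar(reads$seq)))
  x <- Biostrings::QualityScaledDNAStringSet(dss, q)
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write / read a call table as TSV
#'
#' List columns (junction records, deletion intervals) are serialized as
#' JSON strings so the table round-trips.
#'
#' @param calls Call tibble from [classify_reads()].
#' @param path TSV path.
#' @return `write_calls()` returns the path invisibly; `read_calls()` the
#'   call tibble.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  out$junctions <- vapply(calls$junctions, function(j) {
    if (is.null(j)) "[]" else as.character(jsonlite::toJSON(j))
  }, "")
  out$del_intervals <- vapply(calls$del_intervals, function(iv) {
    if (is.null(iv)) "[]" else as.character(jsonlite::toJSON(unclass(iv)))
  }, "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         comment.char = "", stringsAsFactors = FALSE,
                         na.strings = "NA",
                         colClasses = c(junctions = "character",
                                        del_intervals = "character"))
  x <- tibble::as_tibble(x)
  x$junctions <- lapply(x$junctions, function(s) {
    if (is.na(s) || s == "[]") NULL else tibble::as_tibble(jsonlite::fromJSON(s))
  })
  x$del_intervals <- lapply(x$del_intervals, function(s) {
    if (is.na(s) || s == "[]") NULL else {
      m <- jsonlite::fromJSON(s)
      if (is.null(dim(m))) matrix(m, ncol = 2) else m
    }
  })
  x
}

#' Run the full analysis pipeline
#'
#' Classify -> summarize -> microhomology distribution -> deletion profile,
#' writing one TSV per stage plus a JSON run manifest. Reads either come
#' from a file (`config$reads`) or are simulated (`config$simulate = TRUE`),
#' in which case the truth table is written too. Identical configuration and
#' inputs give byte-identical TSV outputs.
#'
#' @param config A list (or path to a YAML/JSON file) with: a locus/donor
#'   description (inline, as accepted by [read_locus_config()], or
#'   `locus_file`), and optionally `reads` (FASTA/FASTQ path), `simulate`
#'   (logical), `mix` (arguments to [outcome_mix()]), `params` (arguments
#'   to [classifier_params()]), `out_dir`, `seed`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed used for simulation (overridden by `config$seed`).
#' @return A list with the stage results (`calls`, `summary`, `mh`,
#'   `profile`, paths), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    cfg_path <- config
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  } else cfg_path <- NA_character_
  out_dir <- out_dir %||% config$out_dir %||% "."
  seed <- seed %||% config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ld <- if (!is.null(config$locus_file)) {
    read_locus_config(config$locus_file)
  } else if (inherits(config$locus, "kiseq_locus")) {
    list(locus = config$locus, donor = config$donor)
  } else {
    cfgl <- config[c("name", "ref_seq", "ref_fasta", "protospacer",
                     "chemistry", "cut_offset_top", "cut_offset_bottom",
                     "pam_side", "integration_point", "donor")]
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfgl[!vapply(cfgl, is.null, TRUE)], tmp)
    on.exit(unlink(tmp), add = TRUE)
    read_locus_config(tmp)
  }
  params <- do.call(classifier_params, as.list(config$params %||% list()))

  truth <- NULL
  if (isTRUE(config$simulate) || is.null(config$reads)) {
    mix <- do.call(outcome_mix, as.list(config$mix %||% list()))
    message("simulating ", mix$n_reads, " reads (seed ", seed, ")")
    sim <- simulate_reads(ld$locus, ld$donor, mix, seed = seed)
    reads <- sim[, c("read_id", "seq")]
    truth <- sim
    cols <- c("read_id", "category_detailed", "category_broad", "del_start",
              "del_end", "trim5", "trim3", "mh5", "mh3", "donor_copies",
              "orientation")
    utils::write.table(sim[, cols], file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_fastq(sim, file.path(out_dir, "reads.fastq"))
  } else {
    message("reading ", config$reads)
    reads <- read_sequences(config$reads)
  }

  message("classifying ", nrow(reads), " reads")
  calls <- classify_reads(reads, ld$locus, ld$donor, params)
  write_calls(calls, file.path(out_dir, "calls.tsv"))

  summ <- summarize_outcomes(calls)
  utils::write.table(tidy(summ), file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")

  mh <- mh_distribution(calls)
  mh_out <- as.data.frame(mh)
  utils::write.table(mh_out, file.path(out_dir, "mh.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  profile <- tryCatch(deletion_profile(calls, ld$locus),
                      error = function(e) {
                        message("deletion profile skipped: ",
                                conditionMessage(e))
                        NULL
                      })
  if (!is.null(profile)) {
    utils::write.table(as.data.frame(profile),
                       file.path(out_dir, "profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "kiseq",
    version = as.character(utils::packageVersion("kiseq")),
    seed = seed,
    config_file = cfg_path,
    locus = ld$locus$name,
    n_reads = nrow(reads),
    params = params[],
    params_hash = rlang::hash(params),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(calls = calls, summary = summ, mh = mh, profile = profile,
                 truth = truth, out_dir = out_dir))
}
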