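test_that("regrouping map collapses detailed end pairs as the field reports them", {
  expect_identical(regroup_outcome("5' HDR, 3' HDR"), "perfect_HDR")
  expect_identical(regroup_outcome("5' blunt, 3' blunt"), "blunt")
  for (lab in c("5' HDR, 3' blunt", "5' blunt, 3' HDR",
                "5' HDR, 3' imperfect", "5' imperfect, 3' HDR")) {
    expect_identical(regroup_outcome(lab), "asymmetric_HDR")
  }
  for (lab in c("5' blunt, 3' imperfect", "5' imperfect, 3' blunt",
                "5' imperfect, 3' imperfect")) {
    expect_identical(regroup_outcome(lab), "imperfect")
  }
  expect_identical(regroup_outcome("concatenated"), "concatenated")
  expect_error(regroup_outcome("5' odd, 3' HDR"), "unknown")

  # total and idempotent over the closed vocabulary
  vocab <- c("WT", "deletion_lt50", "deletion_ge50", "insertion",
             "complex_indel", "concatenated", "complex",
             as.vector(outer(c("HDR", "blunt", "imperfect"),
                             c("HDR", "blunt", "imperfect"),
                             function(a, b) sprintf("5' %s, 3' %s", a, b))))
  broad <- regroup_outcome(vocab)
  expect_identical(regroup_outcome(broad), broad)
})

test_that("self-alignments produce single full-identity segments", {
  ld <- fx_blunt
  seg_ref <- align_read(ld$locus$ref_seq, ld$locus, ld$donor)
  expect_identical(nrow(seg_ref), 1L)
  expect_identical(seg_ref$target, "reference")
  expect_identical(seg_ref$read_start, 0L)
  expect_identical(seg_ref$read_end, nchar(ld$locus$ref_seq))
  expect_equal(seg_ref$pident, 100)

  seg_don <- align_read(donor_seq(ld$donor), ld$locus, ld$donor)
  expect_identical(seg_don$target, "donor")
  expect_identical(seg_don$read_start, 0L)
  expect_identical(seg_don$read_end, nchar(donor_seq(ld$donor)))
})

test_that("a blunt-integration read decomposes into a ref/donor/ref chain", {
  ld <- fx_blunt
  cut <- ld$locus$cut_offset_top
  read <- paste0(substring(ld$locus$ref_seq, 1, cut), donor_seq(ld$donor),
                 substring(ld$locus$ref_seq, cut + 1))
  segs <- align_read(read, ld$locus, ld$donor)
  expect_identical(segs$target, c("reference", "donor", "reference"))
  # chain is ordered and non-overlapping in read coordinates
  expect_true(all(segs$read_start[-1] >= segs$read_end[-nrow(segs)]))
  # every segment reproduces the read from its target, base for base
  tgt <- function(i) {
    src <- if (segs$target[i] == "reference") ld$locus$ref_seq
           else donor_seq(ld$donor)
    substring(src, segs$target_start[i] + 1, segs$target_end[i])
  }
  for (i in seq_len(nrow(segs))) {
    expect_identical(substring(read, segs$read_start[i] + 1, segs$read_end[i]),
                     tgt(i))
  }
  # segments jointly cover the read
  expect_identical(sum(segs$read_end - segs$read_start), nchar(read))
  # junction coordinates agree with a full dynamic-programming alignment of
  # the flanks: the 5' junction sits at the cut modulo placement ambiguity
  mh5 <- junction_mh_length(ld$locus$ref_seq, cut, donor_seq(ld$donor), 0)
  expect_lte(abs(segs$read_end[1] - cut), mh5)
})

test_that("reads match their truth label across categories and chemistries", {
  for (fx in list(fx_blunt, fx_stag)) {
    mix <- mix_clean(250, seed = 17)
    sim <- simulate_reads(fx$locus, fx$donor, mix)
    calls <- classify_reads(sim, fx$locus, fx$donor)
    ev <- evaluate_calls(calls, sim)
    expect_equal(ev$accuracy_detailed, 100)
  }
})

test_that("classification is invariant to reverse complementation", {
  ld <- fx_stag
  mix <- mix_clean(60, seed = 19)
  sim <- simulate_reads(ld$locus, ld$donor, mix)
  fwd <- classify_reads(sim, ld$locus, ld$donor)
  flipped <- dplyr::mutate(sim, seq = vapply(seq, rc, ""))
  rev <- classify_reads(flipped, ld$locus, ld$donor)
  expect_identical(fwd$category_detailed, rev$category_detailed)
  expect_identical(fwd$end5, rev$end5)
  expect_true(all(fwd$orientation != rev$orientation))
})

test_that("end status calls honor the HDR > blunt > imperfect precedence", {
  ld <- fx_blunt
  locus <- ld$locus; donor <- ld$donor
  cut <- locus$cut_offset_top
  pa <- build_perfect_hdr_allele(locus, donor)

  e5 <- call_end_status(pa$seq, "5prime", locus, donor)
  expect_identical(e5$status, "HDR")
  expect_null(e5$junction)

  blunt_read <- paste0(substring(locus$ref_seq, 1, cut), donor_seq(donor),
                       substring(locus$ref_seq, cut + 1))
  for (side in c("5prime", "3prime")) {
    st <- call_end_status(blunt_read, side, locus, donor)
    expect_identical(st$status, "blunt")
  }

  # donor 3' terminus trimmed by 4 nt: 3' imperfect
  dtrim <- substring(donor_seq(donor), 1, nchar(donor_seq(donor)) - 4)
  trim_read <- paste0(substring(locus$ref_seq, 1, cut), dtrim,
                      substring(locus$ref_seq, cut + 1))
  expect_identical(call_end_status(trim_read, "3prime", locus, donor)$status,
                   "imperfect")
  cc <- classify_read(trim_read, locus, donor)
  expect_identical(cc$category_detailed, "5' blunt, 3' imperfect")
  expect_identical(cc$category_broad, "imperfect")

  expect_error(call_end_status(locus$ref_seq, "5prime", locus, donor),
               "no donor")
})

test_that("unalignable and short reads are reported, not classified", {
  ld <- fx_blunt
  reads <- tibble::tibble(
    read_id = c("junk", "short", "good"),
    seq = c(random_dna(400), substring(ld$locus$ref_seq, 1, 50),
            ld$locus$ref_seq)
  )
  calls <- classify_reads(reads, ld$locus, ld$donor)
  expect_identical(calls$category_detailed,
                   c("unalignable", "unalignable", "WT"))
  s <- summarize_outcomes(calls)
  expect_identical(glance(s)$n_unalignable, 2L)
  expect_identical(glance(s)$n_classified, 1L)
})

test_that("summary percentages normalize over the right denominators", {
  calls <- tibble::tibble(
    read_id = sprintf("r%d", 1:4),
    category_broad = c("perfect_HDR", "perfect_HDR", "blunt", "WT"),
    category_detailed = c("5' HDR, 3' HDR", "5' HDR, 3' HDR",
                          "5' blunt, 3' blunt", "WT"),
    junctions = list(NULL, NULL, NULL, NULL)
  )
  s <- summarize_outcomes(calls)
  tab <- tidy(s)
  expect_equal(sum(tab$pct_total), 100, tolerance = 1e-9)
  expect_equal(tab$pct_total[tab$category == "perfect_HDR"], 50)
  expect_equal(tab$pct_integration[tab$category == "perfect_HDR"], 200 / 3,
               tolerance = 1e-9)
  expect_equal(sum(tab$pct_integration, na.rm = TRUE), 100, tolerance = 1e-9)
  expect_equal(sum(tab$pct_single_donor, na.rm = TRUE), 100, tolerance = 1e-9)

  # degenerate all-WT input: integration denominator undefined
  wt <- tibble::tibble(read_id = sprintf("w%d", 1:10),
                       category_broad = "WT", category_detailed = "WT",
                       junctions = replicate(10, NULL))
  swt <- summarize_outcomes(wt)
  expect_equal(tidy(swt)$pct_total[tidy(swt)$category == "WT"], 100)
  expect_true(all(is.na(tidy(swt)$pct_integration)))
  expect_error(summarize_outcomes(calls[0, ]), "no classified reads")
})
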