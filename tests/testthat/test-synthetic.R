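test_that("allele surgery matches each category's molecular definition", {
  ld <- fx_blunt
  locus <- ld$locus; donor <- ld$donor
  cut <- locus$cut_offset_top
  L <- nchar(locus$ref_seq)
  mix <- mix_clean(1)

  set.seed(5)
  wt <- simulate_allele(locus, donor, "WT", mix)
  expect_identical(wt$seq, locus$ref_seq)
  expect_identical(wt$truth$category_broad, "WT")

  del <- simulate_allele(locus, donor, "deletion_lt50", mix)
  sz <- del$truth$del_end - del$truth$del_start
  expect_identical(nchar(del$seq), L - sz)
  expect_true(sz >= 1 && sz < 50)
  expect_identical(del$truth$category_broad, "deletion_lt50")

  big <- simulate_allele(locus, donor, "deletion_ge50", mix)
  expect_gte(big$truth$del_end - big$truth$del_start, 50)

  # blunt ligation: full donor, homology arms included, joined at the cut
  bl <- simulate_allele(locus, donor, "blunt", mix)
  expect_identical(
    bl$seq,
    paste0(substring(locus$ref_seq, 1, cut), donor_seq(donor),
           substring(locus$ref_seq, cut + 1))
  )
  expect_identical(bl$truth$category_detailed, "5' blunt, 3' blunt")
  expect_identical(c(bl$truth$trim5, bl$truth$trim3), c(0L, 0L))

  pf <- simulate_allele(locus, donor, "perfect_HDR", mix)
  expect_identical(pf$seq, build_perfect_hdr_allele(locus, donor)$seq)

  cc <- simulate_allele(locus, donor, "concatenated", mix)
  expect_identical(cc$truth$donor_copies, 2L)
  expect_identical(nchar(cc$seq), L + 2L * nchar(donor_seq(donor)))
})

test_that("mmej deletions carry at least the requested junction microhomology", {
  # reference engineered with a repeated TTTTT on both sides of the cut
  set.seed(8)
  left <- random_dna(180); right <- random_dna(180)
  ref <- paste0(left, "TTTTT", random_dna(20), "TTTTT", right)
  cut <- 195L  # inside the intervening segment
  locus <- locus_spec("mmej", ref, 175, 195, "blunt", cut_offset_top = cut)
  m <- mmej_deletion(locus, mh_min = 5, window = 40, seed = 2)
  expect_true(m$found)
  expect_gte(m$mh, 5)
  expect_gte(
    junction_mh_length(ref, m$del_start, ref, m$del_end, max_scan = 100L), 5)

  # a window with no duplicated k-mer of the requested size yields no site
  ref2 <- paste0(strrep("A", 150), "ACGTACGGTCAGTCCATGAC", strrep("C", 150))
  locus2 <- locus_spec("nosite", ref2, 150, 170, "blunt", cut_offset_top = 160)
  m2 <- mmej_deletion(locus2, mh_min = 8, window = 9, seed = 2)
  expect_false(m2$found)
  expect_identical(m2$reason, "no_site")

  expect_error(mmej_deletion(locus, mh_min = 20, window = 2), "window")
})

test_that("mmej draws always satisfy the measured microhomology bound", {
  locus <- fx_blunt$locus
  set.seed(21)
  for (k in c(2L, 3L)) {
    for (i in 1:50) {
      m <- mmej_deletion(locus, mh_min = k)
      if (!m$found) next
      expect_gte(junction_mh_length(locus$ref_seq, m$del_start,
                                    locus$ref_seq, m$del_end), k)
    }
  }
})

test_that("sequencing error model is unbiased and seed-deterministic", {
  s <- random_dna(500)
  expect_identical(apply_sequencing_errors(s, error_model(0, 0, 0)), s)

  a <- apply_sequencing_errors(s, error_model(0.01, 0.005, 0.005), seed = 99)
  b <- apply_sequencing_errors(s, error_model(0.01, 0.005, 0.005), seed = 99)
  expect_identical(a, b)

  # Monte-Carlo edit count against the binomial expectation
  # (1 kb template, 0.003 total error, 300 replicates)
  template <- random_dna(1000)
  em <- error_model(0.001, 0.001, 0.001)
  set.seed(123)
  edits <- replicate(300, {
    as.integer(utils::adist(apply_sequencing_errors(template, em), template))
  })
  expected <- 1000 * 0.003
  se <- sqrt(1000 * 0.003 * (1 - 0.003)) / sqrt(300)
  expect_lt(abs(mean(edits) - expected), 3 * se)

  expect_error(error_model(sub = 0.2), "rates")
})

test_that("simulated datasets are reproducible and follow the mixture", {
  ld <- fx_stag
  mix <- mix_clean(100, seed = 77)
  s1 <- simulate_reads(ld$locus, ld$donor, mix)
  s2 <- simulate_reads(ld$locus, ld$donor, mix)
  expect_identical(s1, s2)

  only_wt <- mix_clean(60, seed = 3,
                       proportions = c(WT = 1, deletion_lt50 = 0,
                                       deletion_ge50 = 0, insertion = 0,
                                       complex_indel = 0, perfect_HDR = 0,
                                       blunt = 0, asymmetric_HDR = 0,
                                       imperfect = 0, concatenated = 0,
                                       complex = 0))
  sw <- simulate_reads(ld$locus, ld$donor, only_wt)
  expect_identical(nrow(sw), 60L)
  expect_true(all(sw$category_detailed == "WT"))
  # reads are emitted in random orientation
  expect_true(all(c("+", "-") %in% sw$orientation))

  # multinomial sampling bound on category counts (n = 4000)
  mixn <- mix_clean(4000, seed = 11)
  sn <- simulate_reads(ld$locus, ld$donor, mixn)
  counts <- table(factor(sn$category_broad, levels = names(mixn$proportions)))
  n <- mixn$n_reads
  for (cat in names(mixn$proportions)) {
    p <- mixn$proportions[[cat]]
    expect_lte(abs(counts[[cat]] - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("mixture proportion validation rejects inconsistent specs", {
  pr <- c(WT = 0.5, deletion_lt50 = 0.4, deletion_ge50 = 0, insertion = 0,
          complex_indel = 0, perfect_HDR = 0, blunt = 0, asymmetric_HDR = 0,
          imperfect = 0, concatenated = 0, complex = 0)
  expect_error(outcome_mix(proportions = pr), "sum to 1")
  expect_error(outcome_mix(n_reads = 0), "n_reads")
  expect_error(outcome_mix(proportions = c(WT = 1)), "11 outcome categories")
})

test_that("fastq + truth table round-trip through disk", {
  ld <- fx_blunt
  mix <- mix_clean(25, seed = 5)
  fq <- tempfile(fileext = ".fastq.gz")
  tt <- tempfile(fileext = ".tsv")
  sim <- simulate_dataset(ld$locus, ld$donor, mix, fastq = fq, truth = tt)
  back <- read_sequences(fq)
  expect_identical(back$read_id, sim$read_id)
  expect_identical(back$seq, sim$seq)
  expect_true(all(unique(strsplit(back$qual[1], "")[[1]]) == "I"))  # Q40
  truth <- utils::read.table(tt, header = TRUE, sep = "\t", quote = "")
  expect_identical(truth$category_detailed, sim$category_detailed)
  unlink(c(fq, tt))
})
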