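test_that("cut geometry is validated and reported per chemistry", {
  ref <- strrep("ACGT", 60)
  blunt <- locus_spec("b", ref, 100, 120, "blunt", cut_offset_top = 117)
  expect_equal(unname(cut_positions(blunt)), c(117, 117))

  stag <- locus_spec("s", ref, 100, 120, "staggered",
                     cut_offset_top = 118, cut_offset_bottom = 123,
                     pam_side = "5prime")
  cp <- cut_positions(stag)
  expect_equal(unname(cp), c(118, 123))
  expect_equal(abs(unname(diff(cp))), 5)        # conventional Cas12a 5-nt overhang

  expect_error(
    locus_spec("bad", ref, 100, 120, "blunt", cut_offset_top = 117,
               cut_offset_bottom = 119),
    "cut_offset_top"
  )
  expect_error(
    locus_spec("bad", ref, 100, 120, "staggered", cut_offset_top = 117,
               cut_offset_bottom = 117),
    "staggered"
  )
  expect_error(locus_spec("bad", "ACGTN", 0, 2, "blunt", cut_offset_top = 1),
               "A/C/G/T")
  expect_error(locus_spec("bad", ref, 120, 100, "blunt", cut_offset_top = 10),
               "protospacer")
})

test_that("donor homology validation matches direct substring comparison", {
  locus <- fx_blunt$locus
  donor <- fx_blunt$donor
  v <- validate_donor_homology(locus, donor)
  expect_true(v$ok)
  expect_equal(nrow(v$mismatches), 0)

  # one substituted base in the left arm is pinpointed
  arm <- donor$ha_left
  pos <- 41L
  base <- substring(arm, pos, pos)
  sub <- chartr("ACGT", "CAGT", base)
  if (sub == base) sub <- chartr("ACGT", "GGTA", base)
  bad <- donor_spec(donor$insert_seq,
                    paste0(substring(arm, 1, pos - 1), sub,
                           substring(arm, pos + 1)),
                    donor$ha_right)
  v2 <- validate_donor_homology(locus, bad)
  expect_false(v2$ok)
  expect_equal(nrow(v2$mismatches), 1)
  expect_equal(v2$mismatches$arm_pos, pos - 1L)

  expect_error(validate_donor_homology(locus, donor, integration_point = 0),
               "flank")
})

test_that("perfect-HDR allele is the reference with the insert spliced in", {
  ref <- random_dna(60)
  locus <- locus_spec("toy", ref, 20, 40, "blunt", cut_offset_top = 30)
  donor <- donor_spec(insert_seq = random_dna(12),
                      ha_left = substring(ref, 21, 30),
                      ha_right = substring(ref, 31, 40))
  pa <- build_perfect_hdr_allele(locus, donor, integration_point = 30)
  expect_equal(nchar(pa$seq), 72)
  expect_equal(pa$insert_start, 30)
  expect_equal(pa$insert_end, 42)
  # removing the insert restores the reference byte-identically
  expect_identical(paste0(substring(pa$seq, 1, 30), substring(pa$seq, 43)),
                   ref)

  empty <- donor_spec("", substring(ref, 21, 30), substring(ref, 31, 40))
  expect_identical(build_perfect_hdr_allele(locus, empty, 30)$seq, ref)

  expect_error(build_perfect_hdr_allele(locus,
                                        donor_spec(random_dna(10), "AAAA",
                                                   substring(ref, 31, 40)),
                                        30),
               "homology")
})

test_that("insert removal round trip holds over random loci and donors", {
  set.seed(42)
  for (i in 1:20) {
    L <- sample(120:300, 1)
    ref <- random_dna(L)
    P <- sample(50:(L - 50), 1)
    hl <- sample(10:30, 1); hr <- sample(10:30, 1)
    locus <- locus_spec("r", ref, P - 10, P + 10, "blunt", cut_offset_top = P)
    donor <- donor_spec(random_dna(sample(5:40, 1)),
                        substring(ref, P - hl + 1, P),
                        substring(ref, P + 1, P + hr))
    pa <- build_perfect_hdr_allele(locus, donor)
    rebuilt <- paste0(substring(pa$seq, 1, pa$insert_start),
                      substring(pa$seq, pa$insert_end + 1))
    expect_identical(rebuilt, ref)
  }
})

test_that("locus/donor config files round-trip through YAML and JSON", {
  ld <- fx_stag
  cfg <- list(
    name = ld$locus$name, ref_seq = ld$locus$ref_seq,
    protospacer = list(start = ld$locus$protospacer_start,
                       end = ld$locus$protospacer_end, strand = "+"),
    chemistry = "staggered", pam_side = "5prime",
    cut_offset_top = ld$locus$cut_offset_top,
    cut_offset_bottom = ld$locus$cut_offset_bottom,
    donor = list(insert_seq = ld$donor$insert_seq,
                 ha_left = ld$donor$ha_left, ha_right = ld$donor$ha_right)
  )
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    if (ext == ".yaml") yaml::write_yaml(cfg, path)
    else jsonlite::write_json(cfg, path, auto_unbox = TRUE)
    got <- read_locus_config(path)
    expect_identical(got$locus$ref_seq, ld$locus$ref_seq)
    expect_identical(got$locus$chemistry, "staggered")
    expect_identical(cut_positions(got$locus), cut_positions(ld$locus))
    expect_identical(donor_seq(got$donor), donor_seq(ld$donor))
    unlink(path)
  }
})
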