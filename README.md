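# kiseq

Repair-outcome analysis of CRISPR knock-in experiments from long-read
amplicon sequencing.

When a CRISPR nuclease cuts a locus in the presence of a tagging donor
(an insert such as a fluorescent-protein sequence flanked by homology
arms), the double-strand break is resolved by competing repair pathways,
and only a fraction of products are the intended seamless integration
("perfect HDR"). Long amplicon reads spanning the locus expose the full
spectrum: wild-type rejoining, small (< 50 nt) and large deletions —
including microhomology-anchored deletions characteristic of MMEJ —
untemplated insertions, blunt ligation of the entire donor, asymmetric HDR
(one end precise, one not), trimmed imperfect integrations, donor
concatemers, and complex events.

`kiseq` is for groups running such tagging experiments on PacBio-class
long-read amplicons. It provides:

* **Per-read classification** (`classify_reads()`): each read is aligned to
  the reference amplicon and donor, its 5′ and 3′ genome–donor junctions are
  called **HDR**, **blunt**, or **imperfect** (precedence HDR > blunt >
  imperfect), and the detailed label `"5' X, 3' Y"` is regrouped into broad
  categories: both HDR → `perfect_HDR`; both blunt → `blunt`; HDR with
  blunt/imperfect → `asymmetric_HDR`; other blunt/imperfect pairs →
  `imperfect`; ≥ 2 donor copies → `concatenated`; large unexplained spans →
  `complex`. Donor-free reads become `WT`, `deletion_lt50`,
  `deletion_ge50`, `insertion`, or `complex_indel`.
* **Junction microhomology** (`mh_distribution()`): the microhomology
  length at a junction joining U[0, a) to D[b, ) is kL + kR, the shared
  flanking blocks on each side — equivalently the number of equivalent
  junction placements minus one. The distribution is tabulated over the
  non-HDR-end junctions of asymmetric reads and both junctions of imperfect
  reads, with the ≥ 2 nt frequency (the MMEJ signature) reported.
* **Positional deletion profiles** (`deletion_profile()`): percentage of
  sub-50 nt-deletion reads deleted at each reference position.
* **A bi-allelic dual-color model** (`p_double_positive()`,
  `simulate_cells()`): under independent allele editing at probability p,
  the double-positive fraction is p² · 2q(1−q) — proportional to p², the
  basis for enriching accurate knock-in by dual-color selection.
* **A ground-truth-labelled read simulator** (`simulate_reads()`) covering
  all 11 outcome categories under blunt (Cas9-like) and staggered
  (Cas12a-like) cut geometry with HiFi-like error rates, so the entire
  pipeline is testable without sequencing data.

Everything is tibble-in/tibble-out and pipe-friendly; results have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(kiseq)

# a synthetic locus + 90-nt-arm donor, and 2,000 simulated reads
ld   <- example_locus("blunt", seed = 7)
mix  <- outcome_mix(n_reads = 2000, seed = 1)
sim  <- simulate_reads(ld$locus, ld$donor, mix)

calls <- classify_reads(sim, ld$locus, ld$donor)
tidy(summarize_outcomes(calls))
```

```
# A tibble: 11 × 5
   category           n pct_total pct_integration pct_single_donor
   <chr>          <int>     <dbl>           <dbl>            <dbl>
 1 WT               610     30.5            NA                NA
 2 deletion_lt50    420     21              NA                NA
 3 deletion_ge50    101      5.05           NA                NA
 4 insertion         87      4.35           NA                NA
 5 complex_indel     84      4.2            NA                NA
 6 perfect_HDR      201     10.0            28.8              34.4
 7 blunt             89      4.45           12.8              15.2
 8 asymmetric_HDR   148      7.4            21.2              25.3
 9 imperfect        146      7.3            20.9              25
10 concatenated      67      3.35            9.60             NA
11 complex           47      2.35            6.73             NA
```

`pct_total` is the share of all classified reads; `pct_integration`
renormalizes over donor-bearing reads; `pct_single_donor` over single-donor
events (perfect HDR, blunt, asymmetric HDR, imperfect) — the denominators
such spectra are reported against. Downstream statistics chain off the same
call table:

```r
mh_distribution(calls)
```

```
<kiseq_mh_distribution> 366 genome-donor junctions; MH >= 2 nt: 2.73%
# A tibble: 4 × 3
  mh_length count percent
      <int> <int>   <dbl>
1         0   338  92.3
2         1    18   4.92
3         2     7   1.91
4         3     3   0.820
```

```r
prof <- deletion_profile(calls, ld$locus)   # percent deleted per position
autoplot(prof)                              # area plot, cut sites marked

evaluate_calls(calls, sim)$accuracy_broad   # truth recovery on this set
#> [1] 98.5
```

At these HiFi-like error rates (1e-4/base) 98.5% of reads recover their
true broad category; with the error model switched off recovery is exact.

A thin command-line front end wraps the same functions
(`system.file("cli/kiseq.R", package = "kiseq")`) with subcommands
`simulate`, `classify`, `summarize`, `mh-dist`, `del-profile`, `biallelic`,
`evaluate` and `run`; `run_pipeline()` executes the whole chain from one
YAML/JSON config and writes a seeded, hash-stamped run manifest.

## Documentation

The methods vignette (`vignettes/knockin-outcomes.Rmd`) describes the
classification rules and their precedence, the junction-microhomology
definition, the simulator's category semantics and error model, the
bi-allelic model's assumptions, and every tunable threshold with its
default and rationale.
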