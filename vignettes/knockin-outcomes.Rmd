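---
title: "Classifying knock-in repair outcomes from long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying knock-in repair outcomes from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kiseq)
```

## The problem

CRISPR-mediated endogenous tagging introduces a double-strand break (DSB) at
a target locus and supplies a donor carrying an insert (typically a
fluorescent-protein sequence) flanked by homology arms (HAs). The desired
product — *perfect HDR* — is the seamless, homology-templated incorporation
of the insert. But a DSB can be resolved by several competing repair
pathways, and long amplicon reads spanning the locus reveal a whole spectrum
of other products: seamless wild-type rejoining, small and large deletions
(including microhomology-anchored deletions characteristic of MMEJ),
untemplated insertions, blunt ligation of the entire donor including its
arms, asymmetric HDR in which only one donor end recombined precisely,
trimmed ("imperfect") integrations, donor concatemers, and complex
rearrangements.

`kiseq` turns one long-read amplicon sample into a per-read outcome table
and the three derived statistics this kind of study reports: the outcome
category spectrum, the microhomology-length distribution at genome–donor
junctions, and the per-position deletion profile. A synthetic-read generator
with exact ground-truth labels replaces sequencing data for development and
validation, and a small probability model captures why dual-color
(bi-allelic) selection enriches accurate knock-in.

## Locus and donor model

A locus is the reference amplicon plus cut geometry. All coordinates are
0-based, half-open, on the top strand — the package's convention throughout.
Two end chemistries are supported:

* **blunt** (Cas9-like): both strands cut at the same offset; by convention
  the default cut sits 3 nt 5′ of the PAM;
* **staggered** (Cas12a-like): the two strands are cut at different offsets,
  leaving a 5′ overhang (5 nt by default, distal to the PAM).

Cut offsets are explicit configuration, not inferences: different guides,
nucleases and loci vary, so `locus_spec()` records `cut_offset_top` and
`cut_offset_bottom` and validates them against the chemistry. The
*integration point* (where the insert lands in a perfect-HDR product)
defaults to the top-strand cut, matching tagging donors whose arms abut the
cut. Donor orientation is stored 5′→3′ on the top strand.

`build_perfect_hdr_allele()` splices the insert into the reference at the
integration point after `validate_donor_homology()` has confirmed that each
arm is byte-identical to its reference flank; removing the insert from the
product restores the reference exactly, and the package tests this round
trip property on random loci.

## Classification

Each read is first oriented by exact 20-mer votes against the reference and
donor, then decomposed into maximal exact-match segments. Segment extension
crosses an isolated substitution only when the next 8 bases match exactly,
so extensions tolerate the substitution errors expected of high-accuracy
consensus reads but stop hard at junctions and at indels. Where a junction
is ambiguous because flanking bases are shared by both parents
(microhomology), the ambiguity is resolved to the *leftmost placement*, so
all reported junction and deletion coordinates are deterministic.

**Donor-free reads** are classified from their reference alignment:

* `WT` — no indel within ±5 nt (`cut_pad`) of the cut window; substitutions
  anywhere are tolerated as sequencing noise, because wild type here means
  seamless rejoining;
* `deletion_lt50` / `deletion_ge50` — a net deletion of 1–49 nt or ≥ 50 nt
  whose placement-ambiguity span overlaps the cut window (the size boundary
  follows the convention of reporting sub-50 nt deletions as their own
  class);
* `insertion` — net inserted bases at the cut with the reference fully
  explained;
* `complex_indel` — deletion and insertion together, or multiple disjoint
  indels at the cut.

Reads the fast segment decomposition cannot explain (typically reads
carrying a sequencing indel) fall back to a full dynamic-programming
alignment (`Biostrings::pairwiseAlignment`, match 2, mismatch −6, gap open
4, gap extend 1 — mismatch dearer than gaps so junction insertions become
gaps rather than mismatch runs); indels of ≤ 1 nt outside the cut window are
attributed to sequencing noise and dropped before re-classification.

**Donor-bearing reads** (detected by the insert core, a central 30-mer
matched with ≤ 2 mismatches) get a 5′ and a 3′ end status with fixed
precedence **HDR > blunt > imperfect**:

* **HDR** — the read contains the perfect-HDR allele's junction window (the
  whole homology arm plus `margin` = 20 nt of context on each side)
  contiguously, with ≤ `max_mismatch` = 2 substitutions and zero indels;
* **blunt** — the donor terminal base is retained (trim 0), the genomic end
  sits at an accepted cut position, and no untemplated bases intervene. For
  staggered chemistry any position within the overhang span counts as "zero
  resection", since either strand's end may ligate — and by the same logic
  both fill-in and exact-overhang ligation products are accepted;
* **imperfect** — anything else: donor trimming, genomic resection, or
  junction insertion.

The detailed label `"5' X, 3' Y"` is regrouped into broad categories by the
fixed map: both ends HDR → `perfect_HDR`; both blunt → `blunt`; HDR paired
with blunt or imperfect → `asymmetric_HDR`; remaining blunt/imperfect
pairings → `imperfect`. Two or more donor copies (counted as disjoint insert
occurrences in either orientation) → `concatenated`. A read span of ≥
`min_unexplained` = 20 nt matching neither parent → `complex`, flagged as a
possible genomic insertion; resolving such captures against a whole genome
is out of scope. A single donor copy in reverse orientation relative to the
genomic arms is also labelled `complex` and flagged. Ties between
equal-scoring interpretations are broken by precedence (donor-bearing over
donor-free; `complex` is a fallback, never preferred).

Margin 20 with ≤ 2 mismatches makes an accidental HDR window hit in a
blunt or trimmed junction astronomically unlikely (≥ 18 of 20 flanking
bases would have to match by chance) while a true HDR window (~130 nt)
tolerates the expected substitution load comfortably.

## Junction microhomology

The microhomology length of a junction joining `U[0, a)` to `D[b, )` is
`kL + kR`: the longest shared block left of the junction plus the longest
shared block right of it — equivalently, the number of equivalent junction
placements producing the identical joined molecule, minus one. This
placement-ambiguity definition is the standard MMEJ-junction convention;
the package verifies it against a brute-force placement-enumeration oracle.
It is placement-invariant, so left-aligning junctions does not change the
measured length. The scan is capped at `max_scan` = 25 nt, comfortably
above the 2–20 nt range of MMEJ substrates.

The distribution (`mh_distribution()`) is computed over the junction set
used for this statistic in the field: the non-HDR-end junction of each
asymmetric-HDR read whose non-HDR end is imperfect, plus both genome–donor
junctions of each imperfect read. Each frequency is 100 × (junctions with
that length) / (total eligible junctions). Junctions carrying untemplated
insertions have no placement ambiguity; they are included in the
denominator with length 0 by default (`include_untemplated = FALSE`
excludes them — the choice is a documented switch because either convention
is defensible).

## Deletion profile

`deletion_profile()` reports, for each reference position, the percentage
of analyzed reads whose deletion covers that position — by default over
reads in the `deletion_lt50` class, matching how positional deletion
spectra are reported (a `denominator = "all"` switch is available).
Deletions are counted at their left-aligned placement only; spreading mass
over equivalent placements would be equally defensible but
non-deterministic across implementations. The profile conserves mass: the
summed per-position fractions times the read count equals the total number
of deleted bases. Pooled inputs equal the read-count-weighted average of
partition profiles, so replicate pooling (the default) and averaging are
both available to callers.

## The synthetic-read generator

Every outcome category is generated by explicit string surgery at the cut,
so each read carries an exact truth record (`SimTruthRecord` columns in the
output tibble). Category semantics:

| category | construction |
|---|---|
| `WT` | reference unchanged |
| `deletion_lt50` / `ge50` | remove `[a, b)` overlapping the cut; sizes 1–49 / 50–120 nt; 30% of sub-50 deletions are anchored on engineered microhomology via `mmej_deletion()` (k-mer repeat pairs within ±60 nt of the cut, microhomology ≥ 2 nt) |
| `insertion` | 1–15 random nt at the cut |
| `complex_indel` | 5–25 nt removed and 5–25 random nt inserted |
| `perfect_HDR` | the perfect-HDR allele |
| `blunt` | full donor (arms included) ligated at the top-strand cut; for staggered chemistry an overhang fill-in duplication is available (`duplicate_overhang`) |
| `asymmetric_HDR` | one junction copied from the perfect allele, the other blunt or trimmed |
| `imperfect` | donor trimmed 1–40 nt at one or both ends, genomic resection 0–10 nt, untemplated junction bases 0–6 nt |
| `concatenated` | two head-to-tail donor copies (count and inverted-copy option configurable) |
| `complex` | 30–60 random nt interposed at a donor junction |

Half of the reads are reverse-complemented (recorded), and the error model
applies independent per-base substitutions/insertions/deletions. The
default rates (6e-5 / 2e-5 / 2e-5, 1e-4 total) represent the accuracy
regime of Q ≥ 40 circular-consensus reads, the quality floor such studies
filter at.

Two generator details matter for correctness of the truth labels. First,
**rejection sampling**: a drawn trim/resection combination is occasionally
placement-equivalent to a blunt ligation (the trimmed bases are regenerated
by microhomology slippage), and untemplated bases can coincide with a
parent flank; such draws are redrawn so the label always describes the
realized molecule. Second, deletions are placed to overlap the inter-cut
window, where real cut-site deletions concentrate.

What the generator does **not** emulate: realistic PacBio error/quality
profiles (qualities are constant Q40), chimeric library artifacts, captures
of unrelated genomic sequence, and donor-orientation biases. Passing tests
therefore demonstrate the correctness of the classification logic and
statistics under idealized HiFi-like noise, not robustness to every
artifact of a real library. The "complex" class of real data is molecularly
heterogeneous; the generator's junk-at-junction construction is one
reasonable instantiation, chosen because it exercises the unexplained-span
rule directly.

The default mixture (30% WT, 20% sub-50 deletions, 5% large deletions, 5%
insertions, 3% complex indels, 12% perfect HDR, 5% blunt, 8% asymmetric
HDR, 7% imperfect, 3% concatemers, 2% complex) is a plausible knock-in
experiment in which donor-independent repair dominates and perfect HDR is a
minority of integrations; it is a package choice, not a measured spectrum.

## The bi-allelic dual-color model

With two donors carrying different fluorophores delivered together, a cell
is double-positive when both alleles are edited *and* carry different
colors. Under independent allele editing with per-allele probability *p*
and independent color assignment (probability *q* for color A):

* P(any positive) = 1 − (1 − p)²
* P(double positive) = p² · 2q(1 − q) = p²/2 at q = ½

— exactly proportional to p², which is why double-positive selection
enriches accurate knock-in so sharply at low editing rates. Allele
independence and equal-probability color assignment are modeling
assumptions, exposed as parameters; cells whose two edited alleles carry
the same color count as single-color positives, matching dual-color flow
gating. Fitting *p* from measured cytometry percentages is out of scope
(copy number, delivery and viability effects are unmodeled).
`simulate_cells()` provides a seeded Monte-Carlo check of the closed forms.

```{r biallelic}
p_any_positive(0.17)
p_double_positive(0.17)
simulate_cells(0.17, n_cells = 1e5, seed = 1)
```

## Numerical and design choices

* Coordinates 0-based half-open on the top strand everywhere; junctions and
  deletions left-aligned. These conventions are not dictated by the
  biology; they are fixed here for determinism.
* Extension look-ahead `probe` = 8: crossing a junction by chance requires
  8 consecutive coincidental matches (probability 4⁻⁸ per junction).
* Identical inputs give byte-identical outputs: classification is
  deterministic, and all simulation is seeded (`run_pipeline()` writes a
  manifest with the seed and a parameter hash).
* Degenerate inputs: empty call sets error in `summarize_outcomes()` and
  `deletion_profile()` with instructions; an all-HDR call set yields an
  empty microhomology distribution with total 0 (reported, not an error);
  unalignable and sub-`min_read_len` reads are reported and excluded from
  all denominators.
* Validation sizes: the test-suite exercises 2,000 error-free and 2,000
  noisy reads across both chemistries (exact and ≥ 95% truth recovery
  respectively), a 10,000-read mixture-recovery check against multinomial
  sampling bounds, 1,000 junction-microhomology oracle comparisons, 500
  MMEJ draws, and 10⁶-cell Monte-Carlo checks of the bi-allelic closed
  forms. The mixture-recovery check runs error-free so that its tolerance
  is purely the multinomial sampling bound; classifier robustness to noise
  is measured separately by the noisy-recovery check.

## Known limitations

* The classifier is template-directed: it explains reads against one locus
  and one donor. Reads from other loci, vector backbones or chimeras are
  reported as `complex`/`unalignable` rather than resolved.
* Single-copy donors in reverse orientation are flagged `complex`, not
  given end statuses.
* Indel sequencing errors inside a homology-arm window can demote a true
  HDR end to imperfect; at HiFi-like rates this costs about 1% broad
  accuracy.
* The per-end mismatch/indel tolerances are explicit parameters of this
  package, not claims about any other tool's internals.
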