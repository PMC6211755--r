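---
title: "Characterizing Bt isolates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing Bt isolates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btchar)
```

`btchar` implements the computational half of a classical *Bacillus
thuringiensis* characterization workflow: screening a strain collection for
*vip3* genes by (in-silico) PCR with degenerate primers, inferring the Cry
protein content of parasporal crystals from mass-spectrometry search-engine
output via unique tryptic peptides, quantifying insecticidal potency with
probit dose-response models, and characterizing the purified protein itself
(ORF, mass, residue differences, native oligomeric state by size-exclusion
chromatography). This vignette explains the models behind each stage, the
parameters that matter, the synthetic-data generators used in testing, and
the design decisions taken where the underlying conventions are genuinely
open.

## In-silico PCR

A degenerate primer is a short IUPAC string; code *R* matches A or G, *Y*
matches C or T, *K* G or T, *S* C or G, and so on down to *N* matching any
base. `find_primer_sites()` scans both strands: a plus-strand hit is a
left-to-right match of the primer, a minus-strand hit a match of the
primer's reverse complement, reported by the leftmost plus-strand base of
the site. A mismatch is counted only where the template base falls outside
the primer base's expansion set; `max_mismatch` defaults to 0 because the
stringency of a real thermocycler cannot be mapped onto a mismatch count
with any confidence — raising it only ever adds hits (monotonicity is a
tested invariant).

`predict_amplicons()` pairs forward plus-strand hits with reverse
minus-strand hits to the right. Coordinates are 1-based and inclusive at
both ends, so `length = end - start + 1`; this is the convention forced by
the reference spans of the shipped vip3 primer set (`vip3_primers()`),
where a forward site starting at 78 and a reverse site ending at 1472 give
the published 1395 bp screening product, and the typing products are
1060/1052/1027 bp. Default size limits of 50–5000 bp suppress spurious
pairings on large templates.

`screen_collection()` calls an isolate positive when at least one amplicon
is predicted, and reports the positive percentage rounded half away from
zero — base R's banker's rounding would report 18/80 as 22% instead of the
conventional 23%. `type_vip3()` runs one shared forward primer against a
set of type-discriminating reverse primers and assigns the unique type that
yields a product; several products is an error rather than a priority list,
because a real typing PCR with two bands would be re-run, not ranked.

`merge_contigs()` joins the sequenced N-terminal and C-terminal partial
amplicons by the longest exact suffix–prefix overlap above `min_overlap`.
With exact matching the maximal overlap length is unique, so no ambiguity
branch is needed; mismatch-tolerant merging is out of scope.
`percent_identity()` is a deliberately minimal BLAST surrogate: an
ends-free global alignment (match +1, mismatch −1, gap −2 per base, via
`Biostrings::pairwiseAlignment(type = "overlap")`), identity over aligned
columns, and query cover as the aligned fraction of the query. It is meant
for comparing a merged amplicon against a user-supplied reference, not for
searching public databases.

## Unique-peptide protein inference

Cry1 and Cry2 family proteins are so similar that a peptide observed in a
crystal digest typically matches several family members; only peptides
occurring in exactly one reference protein ("unique peptides") can
discriminate them. The pipeline mirrors the standard manual procedure
applied to search-engine output:

1. **Protein-level gate.** Proteins with an unused score of 2 or less are
   excluded (`excluded_low_score`); above 2 the engine's protein-level
   confidence exceeds 99%.
2. **Peptide filters** (`filter_peptides()`): length 6–20 residues,
   contribution score strictly greater than 2, no modifications; repeated
   peptide strings collapse to one representative. The collapse keeps the
   highest-contribution row — the choice is arbitrary in the source
   procedure, and downstream only the peptide string matters.
3. **Uniqueness** (`build_uniqueness_index()`, `classify_peptides()`): a
   peptide is unique when it occurs as an exact substring of exactly one
   family member's full sequence. Substring matching (rather than
   digest-set equality) means peptides with missed cleavages still classify
   correctly. An `equate_IL` switch treats isoleucine and leucine as
   identical — mass spectrometry cannot tell them apart — but defaults to
   off, matching alignment-based practice.
4. **Call** (`identify_proteins()`): a protein is a *positive
   identification* when supported by at least two unique peptides.
   One unique peptide is suggestive, not conclusive (`not_positive`).

Digestion (`digest()`) follows trypsin specificity with the Keil rule:
cleave after K or R unless the next residue is P. Coverage is the
percentage of residue positions lying under at least one occurrence of a
retained peptide, computed on the *filtered* set; whether published
coverage figures predate or postdate filtering is generally unstated, so
the package picks the post-filter convention and documents it.

## Probit dose-response

Mortality is modeled as `P(dead | dose) = pnorm(a + b * log10(dose))`,
fitted to pooled dose groups by maximum likelihood (Fisher scoring with
step halving; convergence at a relative log-likelihood change below 1e-10
or 100 iterations). Base-10 logs keep the slope on the scale familiar from
bioassay tables (roughly 0.5–2.5 probits per decade), and the historical
"+5" probit offset is dropped. The LC50 is `10^(-a/b)`.

The 95% fiducial limits come from Fieller's theorem: the limits for
`m = -a/b` on the log scale are the roots of
`(a + b m)^2 = crit^2 (v11 + 2 m v12 + m^2 v22)`. When the Pearson
goodness-of-fit chi-square over dose groups exceeds its degrees of freedom
(`groups - 2`), the covariance is inflated by the heterogeneity factor
`chisq/df` and the critical value switches from the standard normal to the
t distribution on those degrees of freedom — the convention of the classic
Polo bioassay software. When `g = crit^2 v22 / b^2 >= 1` the interval is
undefined (the slope is not significantly positive) and an error is raised
rather than an arbitrary wide band.

Two LC50s are declared significantly different exactly when their fiducial
intervals do not overlap (touching endpoints overlap). This rule is
conservative relative to a ratio test, but it is the rule used in the
comparative bioassay literature this package accompanies, and
`compare_lc50()` accepts plain `c(lo, hi)` intervals so published limits
can be compared directly. Control mortality can be removed beforehand with
`abbott_correct()`; a natural-response parameter is *not* estimated inside
the likelihood because the motivating assays showed at most ~3% control
mortality. Groups at 0% or 100% mortality enter the likelihood untouched —
no empirical-probit transform is needed under ML.

## Protein characterization

`translate_orf()` performs standard-code translation, consuming a single
terminal stop, so a 2370 bp ORF yields 789 residues. `molecular_mass()`
sums average residue masses plus one water; average (not monoisotopic)
masses are the right convention for comparing with SDS-PAGE and
gel-filtration estimates of an ~88.5 kDa protein.
`residue_differences()` compares equal-length sequences position by
position — the comparison behind published variant-difference tables — and
refuses unequal lengths rather than aligning silently.

Size-exclusion chromatography is calibrated as a straight line of the
partition coefficient `Kav = (Ve - V0)/(Vc - V0)` on `log10(mass)`
(`fit_calibration()`), inverted by `apparent_mw()`. The oligomer order is
the nearest integer to apparent/monomer mass, floored at 1: a 346 kDa
native species of an 88.5 kDa monomer is a tetramer (ratio 3.9), and an
80.3 kDa species is a monomer. Shape corrections (the protein is assumed
globular, as the calibration standards are) are out of scope.

## Synthetic data

Each generator is seeded (one master seed, deterministic per-generator
streams) and emits its ground truth, so every analysis stage can be tested
for exact truth recovery on noiseless data:

- `make_reference_family()` derives members from one random base protein by
  a fixed number of point substitutions. Substitutions avoid K/R positions
  and never introduce K, R or P, so all members share one cleavage pattern
  and a peptide is discriminating exactly when it overlaps a position where
  members differ — which makes the expected unique/shared partition
  computable by construction.
- `make_isolate_genomes()` plants one concrete expansion of each screening
  primer (reverse primer as reverse complement) at the reference
  coordinates in carrier genomes, plus the typing sites for an assigned
  type; non-carriers are uniform random sequence. Defaults are an
  80-isolate collection with 18 carriers.
- `make_psm_table()` draws peptide rows from the true proteins' digests,
  gives true proteins unused scores far above the 2 cutoff and absent
  family members scores below it, and injects at least one row violating
  each individual filter (short, long, low-contribution, modified,
  duplicate) so the cascade is always exercised. Contribution scores are a
  shifted exponential above the cutoff — the actual engine score
  distribution is opaque, and only the >2 threshold matters downstream.
- `make_bioassay()` draws binomial kills from the probit model on a
  geometric dose series centered on the true LC50, with control mortality
  applied as `p = c + (1 - c) p_model` (the inverse of the Abbott
  correction). The default design is the motivating study's: 5 threefold
  dilutions, 16 larvae per dose, 3 replicates, slope 1.05, LC50 48 ng/cm²,
  zero control mortality (the study's untreated controls showed none worth
  modeling).
- `make_calibration()` generates standard elution volumes from a stated
  Kav line plus Gaussian noise, resampling volumes that leave the physical
  column range.

What the generators do **not** emulate: raw spectra or chromatograms,
search-engine scoring behavior, real sequence homology structure (genomes
are uniform random), or between-replicate overdispersion in bioassays.
Passing tests therefore demonstrate correctness of the *procedures*, not
robustness to every pathology of real instrument output.

## Numerical choices and test scale

Simulation-based checks use fixed seeds and modest sizes chosen to make the
whole suite run in well under a minute of CPU: oracle equivalence on
hundreds of random instances per operation, parameter recovery with 200
replicates of the default bioassay design pooled to 48 larvae per dose
(median recovered LC50 within 15% of truth), and interval coverage with 500
replicates (observed coverage ~96% at nominal 95%, within the 93–97% band
expected of Fieller limits with heterogeneity correction at this design
size). Large-sample consistency is spot-checked at 10⁵ larvae per dose.

## Known limitations

- Percent identity is a surrogate for BLAST; identities against external
  database sequences will not match BLAST output digit for digit.
- The uniqueness index treats the supplied family as the whole universe of
  candidate proteins; peptides shared with proteins outside the family are
  invisible to it (the same is true of the manual procedure it mirrors).
- Proteins within a subgroup that share all valid-length peptides (as real
  Cry2A members do) are inherently not distinguishable by this method.
- The probit module fits a single assay; mixed-effects extensions across
  replicates or time-to-death models are out of scope.
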