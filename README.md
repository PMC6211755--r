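# btchar

Computational characterization of *Bacillus thuringiensis* isolates by
their insecticidal toxin complement.

*Bt* strain collections are screened for strains worth developing into
bioinsecticides. The characterization workflow has four computational
pillars, and `btchar` implements all of them as tested, reusable R
functions:

1. **vip3 gene screening and typing by in-silico PCR.** Degenerate IUPAC
   primers (R = A/G, Y = C/T, K = G/T, S = C/G, …) are matched against
   genomes on both strands; amplicons are predicted from forward/reverse
   site pairs with 1-based inclusive coordinates (`length = end − start +
   1`). A shared forward primer with type-discriminating reverse primers
   assigns *vip3Aa* / *vip3Af* / *vip3Ag* by product size (1060 / 1052 /
   1027 bp). Sequenced partial amplicons are merged by exact overlap and
   compared to references by ends-free alignment percent identity.

2. **Cry protein inference from unique tryptic peptides.** Crystal
   proteins within the Cry1 or Cry2 families are too similar for naive
   database matching, so proteins are called from search-engine
   peptide-spectrum-match tables by the unique-peptide rule: keep proteins
   with unused score > 2, keep peptides of 6–20 residues with contribution
   score > 2 and no modifications, deduplicate, classify each peptide as
   *unique* (substring of exactly one family member) or *shared*, and call
   a protein **positive** only when it has ≥ 2 unique peptides.

3. **Probit dose-response analysis.** Mortality is
   `Φ(a + b·log₁₀ dose)` fitted by maximum likelihood;
   `LC50 = 10^(−a/b)` with 95% fiducial limits by Fieller's theorem,
   inflating the covariance by the heterogeneity factor χ²/df (and
   switching z → t critical values) when the Pearson fit statistic
   overshoots its degrees of freedom. Two LC50s differ significantly
   exactly when their fiducial intervals do not overlap. Abbott control
   correction and percent-mortality summaries included.

4. **Protein-level characterization.** ORF translation (2370 bp → 789
   residues), average molecular mass (+ water; an 88.5 kDa protein),
   position-by-position residue differences between variants, and native
   oligomeric state from size-exclusion chromatography via
   `Kav = (Ve − V0)/(Vc − V0)` calibrated against `log₁₀(mass)` —
   a 346 kDa native peak of an 88.5 kDa monomer is a tetramer.

A seeded synthetic-data module (`make_reference_family`,
`make_isolate_genomes`, `make_psm_table`, `make_bioassay`,
`make_calibration`) generates inputs with the exact statistical structure
each stage assumes, each with a ground-truth record, so the whole pipeline
runs and is testable offline.

## Worked example

```r
library(btchar)

cfg <- synthetic_config(seed = 2024)   # 80 isolates, 18 vip3 carriers
res <- run_pipeline(cfg)

res$screen$n_positive        # 18
res$screen$percent_positive  # 23
table(res$typing$assigned_type)
#> vip3Aa vip3Af vip3Ag
#>      6      6      6

res$identification
#>   protein_id unused_score n_peptides n_unique n_shared coverage_pct             status
#> 1         M1   200.697205         15        6        9        56.33           positive
#> 2         M2    21.625551         15        7        8        56.33           positive
#> 3         M3     1.659982          0        0        0         0.00 excluded_low_score

res$doseresponse
#> Probit dose-response fit (log10 dose)
#>   slope: 1.080 +/- 0.152   intercept: -1.904
#>   LC50: 57.91   FL95: 28.9 - 123.4
#>   chisq: 3.452 on 3 df (heterogeneity 1.151)

res$gelfiltration$apparent_mass   # 354 kDa from a 11.8 ml elution
res$gelfiltration$oligomer_order  # 4 (tetramer of the 88.5 kDa monomer)
```

Reading the output: the collection screen recovers the planted 18/80
carriers (23%); the two true crystal proteins are positively identified
(≥ 2 unique peptides each) while the third family member is excluded by
the unused-score gate; the probit fit of the synthetic bioassay (true
slope 1.05, true LC50 48 ng/cm²) estimates LC50 ≈ 58 ng/cm² with fiducial
limits bracketing the truth; and the synthetic gel-filtration peak is
called a tetramer.

Published fiducial limits can be compared directly:

```r
compare_lc50(c(30, 74), c(9, 24))$significant   # TRUE  (disjoint)
compare_lc50(c(30, 74), c(26, 92))$significant  # FALSE (overlap)
```

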