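# tmtpa

Quantitative proteomics of skeletal muscle asks a deceptively simple
question — which proteins track a person's habitual physical activity? —
through a long chain of arithmetic: six-plex tandem-mass-tag (TMT)
reporter ions quantify six samples per spectrum, and getting from raw
reporter intensities to per-protein activity associations requires
isotopic-purity unmixing, identification-quality filtering, within-set
median normalization, spectrum-to-protein roll-up, sample-loading
correction, questionnaire scoring, and a per-protein linear mixed model.
`tmtpa` implements that pipeline end to end for analysts working with
PSM-level TMT exports and activity-questionnaire metadata, together with
a seeded synthetic-cohort generator (with ground truth) that makes every
stage testable without any deposited raw data.

## The model

For protein $p$ and donor $i$ in TMT set $b(i)$, the per-protein model is

$$
y_{p,i} = \alpha_p + \beta_p\,\mathrm{PA}_i
 + \gamma_1\,\mathrm{age}_i + \boldsymbol{\gamma}_2\,\mathrm{race}_i
 + \gamma_3\,\mathrm{BMI}_i + \gamma_4\,\mathrm{fiber}_i
 + u_{b(i)} + \epsilon_{p,i},
 \qquad u_b \sim N(0, \tau_p^2),
$$

where $y_{p,i}$ is the normalized log2 relative abundance,
$\mathrm{PA}_i \in \{0,1,2,3\}$ is the ordinal activity code scored from
a two-week recall questionnaire (weekly MVPA minutes = frequency ×
duration / 2; `<30` → 0, `[30,75)` → 1, `[75,150)` → 2, `≥150` → 3),
$\mathrm{fiber}_i$ is the myosin fiber-type ratio
$2^{a_{MYH7}} / (2^{a_{MYH1}} + 2^{a_{MYH2}} + 2^{a_{MYH4}})$, and the
TMT set enters as a random intercept. Fits are REML via lme4 with
Satterthwaite p-values (lmerTest); Benjamini–Hochberg q-values are
reported alongside raw p, and proteins are called up/down at raw
p < 0.05 by the sign of $\beta_p$ (log2 units per activity point).

## Worked example

```r
library(tmtpa)

cfg    <- cohortConfig(n_donors = 20, n_proteins = 40, seed = 42)
cohort <- simulateCohort(cfg)

flt <- filterPSM(applyPurityCorrection(cohort$psm, cfg@purity_matrix),
                 cohort$samples)
flt$report
#> FilterReport: 779 records in, 653 retained
#>   decoy                        -    15  (779 -> 764)
#>   contaminant                  -     8  (764 -> 756)
#>   peptide_fdr                  -     0  (756 -> 756)
#>   protein_fdr                  -     0  (756 -> 756)
#>   shared_protein               -    28  (756 -> 728)
#>   incomplete_channels          -    16  (728 -> 712)
#>   peptide_coverage             -    59  (712 -> 653)
#>   single_peptide_unconfirmed   -     0  (653 -> 653)
#>   proteins: 63 -> 39

pqm  <- quantifyProteins(flt$psm, cohort$samples)
pqm
#> ProteinQuantMatrix: 39 proteins x 20 samples; loading-corrected

covs <- buildCovariates(cohort$samples, pqm)
res  <- fitAllProteins(pqm, covs)
head(as.data.frame(res[order(res$p_value), c("beta","se","p_value","q_value","direction")]), 5)
#>           beta      se  p_value q_value direction
#> P0008  0.14491 0.02894 0.000240 0.00936        up
#> P0036 -0.13697 0.03366 0.001762 0.03436      down
#> P0032 -0.08527 0.02723 0.008035 0.07464      down
#> P0020 -0.04562 0.01495 0.011339 0.07464      down
#> P0013  0.10945 0.03791 0.012786 0.07464        up
```

The filter report shows each retention rule's toll (decoys, contaminants,
FDR thresholds, shared spectra, incomplete channels, peptide coverage,
single-peptide confirmation), telescoping from 779 records to 653. The
result table gives each protein's activity slope in log2 units per
activity-code point. The generator's ground truth in `cohort$truth` makes
checks routine: the top hits P0008, P0036 and P0013 are genuinely
regulated (true slopes 0.186, −0.099, 0.148), while P0032 and P0020 are
true nulls that reached raw p < 0.05 in this deliberately small 20-donor
cohort — exactly the false positives the reported q-values temper.

A command-line wrapper over the same functions ships in
`inst/cli/tmtpa.R` (`simulate | process | quantify | covariates | fit |
summarize | run | demo`); `demo` runs a bundled small configuration end
to end, including a synthetic annotation table, and writes
`category_summary.tsv` with per-category up/down counts.

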