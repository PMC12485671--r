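# qcmatch

Scan-quality control for structural MRI group studies by propensity-score
matching on automated image-quality metrics.

## The problem

Clinical populations (autism, schizophrenia, older adults) move more in the
scanner than controls. Motion blurs tissue boundaries and systematically
lowers apparent gray-matter volume, so scan quality becomes a
group-correlated confound: voxel-based morphometry (VBM) can report "group
differences" that are really noise. Excluding low-quality scans (the common
fix, e.g. dropping everything below a 70% image quality rating)
preferentially removes the most clinically affected participants.
`qcmatch` implements the alternative: **balance scan quality between groups
by 1:1 optimal propensity-score matching** on automated quality metrics —
the overall image quality rating (IQR, %), the mean surface Euler number,
and the topological defect size (%) — and lets you compare all three
quality-control protocols (full inclusion, threshold exclusion, matching)
end to end through harmonization, smoothing, and permutation-corrected VBM.

At its core:

* propensity score `e = P(treated | IQR, Euler, defect)` by logistic
  regression; matching minimizes total |logit-score| distance, solved
  exactly as a minimum-cost bipartite assignment, with caliper / exact /
  common-support / tiered variants;
* balance assessed by standardized mean differences,
  `SMD = (mean_t - mean_c) / sd_pooled`, with the conventional
  `|SMD| < 0.1` criterion and Love-plot export;
* site harmonization by the empirical-Bayes location/scale batch model,
  protecting group, age, and sex;
* VBM: mask-normalized 8 mm FWHM Gaussian smoothing, per-voxel GLM with
  TIV/age/sex covariates, voxel-level FWE by permutation maxT
  (Freedman–Lane), cluster tables with the 8 mm distinct-peak rule and
  Cohen's d;
* a synthetic motion-confounded cohort generator with full ground truth,
  so every claim above is testable without external imaging data.

## Worked example

```r
library(qcmatch)

cfg <- synth_config(n_treated = 60, n_control = 80, seed = 42)
g <- generate_cohort(cfg)              # patients move more; quality suffers
g$cohort
#> cohort_table 'synthetic': 140 subjects (60 patient / 80 control), 1 site(s)

model  <- fit_propensity(g$cohort)     # logistic model on IQR/Euler/defect
scores <- compute_scores(model, g$cohort)
res <- optimal_match(scores, g$cohort$group,
                     match_spec(caliper_sd = 0.2, discard_unmatchable = TRUE),
                     g$cohort)
res
#> match_result: 29 pairs, total distance 1.88012 ; 31 discarded

balance_report(g$cohort, res, c("iqr_pct", "euler", "defect_pct"), scores)
#> balance_report (|SMD| threshold 0.1 ):
#>    covariate smd_pre smd_post ... balanced_pre balanced_post
#> 1    iqr_pct  -1.272  0.02324 ...        FALSE          TRUE
#> 2      euler   1.399  0.09081 ...        FALSE          TRUE
#> 3 defect_pct   1.206 -0.07692 ...        FALSE          TRUE
#> 4   distance   1.499  0.02051 ...        FALSE          TRUE
```

Before matching the patients' quality is far worse (`smd_pre` above 1 in
magnitude on every metric); after caliper matching every metric — and the
propensity distance itself — is balanced below the 0.1 criterion. The
group difference in scan quality disappears accordingly:

```r
quality_comparison(g$cohort, "iqr_pct")            # full inclusion
#>    metric ... t_stat       df  pearson_r      p_value
#> 1 iqr_pct ... -7.244 95.98556 -0.5945281 1.090427e-10
quality_comparison(apply_match(g$cohort, res), "iqr_pct")   # matched
#>    metric ... t_stat      df  pearson_r   p_value
#> 1 iqr_pct ... 0.1181 55.3497 0.01587889 0.9063768
```

The full pipeline — harmonize (if multi-site), smooth, apply each
protocol, run the permutation-corrected VBM — is one call:

```r
rep <- run_protocol_comparison(pipeline_config(
  synth = synth_config(n_treated = 40, n_control = 40),
  n_perm = 200, seed = 11))
rep
#> comparison_report (seed 11 ):
#>   full_inclusion  n=40/40  significant voxels=483  clusters=1
#>   exclusion       n=28/37  significant voxels=452  clusters=1
#>   matching        n=16/16  significant voxels=39   clusters=1
summarize_voxel_overlap(rep, "full_inclusion", "matching")$percent_difference
#> [1] -91.92547
```

Here the generator injected a motion artifact plus one true effect blob:
full inclusion declares most of the mask significant (the artifact),
while the matched protocol retains essentially the true effect — a ~92%
reduction in significant voxels.

A command-line interface wrapping these functions (subcommands `simulate`,
`propensity`, `match`, `balance`, `protocol`, `harmonize`, `vbm`,
`compare`) is installed at `system.file("cli", "qcmatch", package = "qcmatch")`.

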