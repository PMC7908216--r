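# rspi

Scoring left-ventricular mechanical dyssynchrony from segmental
longitudinal-strain curves, for predicting response to cardiac
resynchronization therapy (CRT).

About a third of CRT recipients do not remodel favourably. The **Regional
Strain Pattern Index (RSPI)** quantifies the dyssynchronous contraction
morphology of left bundle branch block on speckle-tracking strain curves: in
each apical view (4-, 2-, 3-chamber) four components are scored one point
each on the basal/mid segments of the opposing walls —

1. early contraction of the early-activated wall (an evident negative strain
   peak during ejection),
2. prestretch (early-systolic positive strain) of the late-activated wall,
3. the early peak falling within the first 70% of the systolic ejection
   phase,
4. peak contraction of the late-activated wall after aortic valve closure —

so RSPI ∈ 0–12, and patients with **RSPI ≥ 7** form the high-score group.
The package implements the scorer, the binary classical/heterogeneous strain
pattern classifier (all four components in at least one view ⇒ classical),
the classical time-to-peak dyssynchrony indexes (Yu index, IVMD, SPWMD,
LVDFT/RR, maximal time delays), the volumetric responder rule (ΔLVESV ≥
15%), and the cohort evaluation pipeline (2×2 diagnostics with Wald OR CI,
empirical ROC with Youden-optimal cutoff, univariate logistic regression,
nonparametric group tests). A seeded synthetic waveform/cohort generator
makes everything testable without patient data; JSON and long-format CSV
readers/writers and a small CLI (`inst/cli/rspi.R`) bind it together.

## Worked example

```r
library(rspi)

# a 4-chamber view: mid-septal peak just past 70% of ejection, lateral
# prestretch +2.5%, lateral peak contraction 60 ms after AVC
v4 <- make_view("4CH", c(1, 1, 0, 1), prestretch_amp = 2.5,
                early_peak_fraction = 0.75)
score_view(v4)
#> <4CH components> (c1,c2,c3,c4) = (1,1,0,1), 3 point(s)

# a 49-patient cohort with exact responder-by-high-RSPI cell counts
coh <- make_cohort(tp = 18, fp = 1, fn = 18, tn = 12, seed = 7)
res <- run_pipeline(coh)
res$diagnostics
#> sensitivity 50.0%, specificity 92.3%, PPV 94.7%, NPV 40.0%
#> odds ratio 12 (95% CI 1.41-102)
res$roc
#> ROC: AUC 0.714 (36 positives, 13 negatives); optimal cutoff >= 7 (Youden J 0.423)
```

The view scores 3 points: components 1, 2 and 4 are present but the early
peak misses the 70% window. The cohort run shows that a high RSPI is a
strongly specific (92.3%) but only moderately sensitive (50%) marker of
reverse remodelling, with a diagnostic odds ratio of 12, and that 7 points
is the Youden-optimal threshold on this cohort structure.

Command-line use:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/rspi.R", package = "rspi"))')
Rscript $CLI simulate --tp 18 --fp 1 --fn 18 --tn 12 --seed 7 --out traces.json
Rscript $CLI evaluate --input traces.json --out diagnostics.json
```

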