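# psnstrat

Stratify an inpatient cohort into phenotype subgroups from symptom-coded
electronic medical records, and characterize what distinguishes — and what
improves in — each subgroup.

Given one row per hospitalization (chief-complaint symptoms, history-of-
present-illness symptoms, tongue and pulse findings, diagnoses, prescribed
herbs, discharge symptoms) and a term-normalization dictionary, the
package:

1. **curates** the records — dictionary normalization to canonical term
   sets, ICD rollup (`I50.903`, `I50.905` → `I50.9`), exclusion of
   incomplete records, one most-complete admission per patient;
2. **builds a patient similarity network (PSN)** — Jaccard similarity
   $J(A,B) = |A\cap B|/|A\cup B|$ over main symptoms thresholded at
   $J \ge 0.8$, overlapped with the general-symptom network whose
   similarities become the edge weights;
3. **detects subgroups** — weighted Louvain modularity maximization
   (from scratch, seeded, multi-restart), or an overlapping
   cluster-affiliation model (`bigclam()`) where subgroup boundaries are
   not expected to be crisp;
4. **characterizes each module** by relative risk
   $RR = (C_{ij}/C_i)\,/\,((C_j - C_{ij})/(N - C_i))$ with a Pearson
   chi-square screen ($RR > 1$, $p < 0.05$, no continuity correction)
   across five feature classes: symptoms, tongue, pulse, diagnoses, herbs;
5. **scores symptom resolution** — the fraction of patients per module
   whose admission symptom is absent at discharge — and bundles each
   module's enriched features and resolution ranking into a JSON profile.

A synthetic-cohort generator with planted subgroups, herb signatures,
treatment-response probabilities, synonym noise, duplicate admissions and
missing records makes every stage testable without hospital data.

## Worked example

```r
library(psnstrat)

gen <- generate_cohort(generator_config())   # n = 1000, K = 3, seed = 7
cur <- curate(gen$records, gen$dictionary, policy = "strict")
cur$report
#> Curation report
#>   records in:            1053
#>   excluded (incomplete): 29
#>   excluded (duplicate):  53
#>   included:              971

net <- build_psn(cur$records)                # threshold 0.8, overlap-weighted
net
#> Patient similarity network: 469 nodes, 4500 edges
#>   weight range: [0.143, 1.000]

part <- louvain(net, seed = 7)
part
#> Partition: 469 nodes, 16 modules, Q = 0.6590
head(module_size_table(part), 4)
#>   module size share
#> 1      0  168  35.8
#> 2      1  141  30.1
#> 3      2  133  28.4
#> 4      3    3   0.6

enr <- enrich(cur$records, part, "symptom")
head(enr[enr$significant, c("module","feature","C_ij","C_i","rr","p_value")], 3)
#>   module    feature C_ij C_i   rr  p_value
#> 1      0 msym.s1.02  152 168 45.4 3.61e-84
#> 2      0 msym.s1.04  153 168 27.4 1.31e-81
#> 3      0 msym.s1.03  152 168 27.2 9.26e-81

head(symptom_resolution(cur$records, part)[1:3, ])
#>   module    symptom n_admission n_resolved resolution_rate
#> 1      0 msym.s1.02         152        142       0.9342105
#> 2      0 msym.s1.01         155        141       0.9096774
#> 3      0 msym.s1.05         158        141       0.8924051
```

Reading this: 1,053 raw admissions curate down to 971 patients; 469 of
them share a near-identical chief complaint with someone else and enter
the network. Louvain recovers three dominant modules (plus small satellite
fragments) matching the three planted subgroups — adjusted Rand index 0.91
against the planted labels. Module 0's top enriched symptoms are exactly
subgroup 1's planted signature (`msym.s1.*`, relative risks 27–45), and
those symptoms resolve by discharge in ~90% of carriers, matching the
generating resolution probability 0.9 for signature symptoms treated with
the subgroup's herb signature.

The same stages run end to end with a manifest of artifact digests:

```r
run_pipeline(list(input = list(synthetic = list(n_patients = 1000)),
                  seed = 7),
             out_dir = "out")
```

or from the command line (`simulate`, `curate`, `build-psn`, `detect`,
`run-all`, ... — see `inst/cli/psnstrat.R`):

```sh
Rscript inst/cli/psnstrat.R run-all --config config.json --out out
```

Real cohorts are read with `read_records()` (CSV with `|`-delimited list
fields, or JSON-lines) plus `read_term_dictionary()` (3-column TSV); see
`?read_records` for the exact column contract.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model and
its assumptions, every tunable that matters with units and defaults, what
the synthetic generator does and does not emulate, numerical and
degenerate-input choices, and known limitations.
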