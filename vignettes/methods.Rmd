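---
title: "Methods: stratifying an inpatient cohort with a shared-symptom patient similarity network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying an inpatient cohort with a shared-symptom patient similarity network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnstrat)
```

## The problem and the model

Inpatients sharing one diagnosis (the motivating case is chronic atrophic
gastritis in a traditional-Chinese-medicine hospital) are clinically
heterogeneous: different chief complaints, different accompanying symptoms,
different prescriptions, different trajectories. psnstrat stratifies such a
cohort into data-driven subgroups using only the coded phenotype of each
hospitalization, then characterizes each subgroup and scores how its
symptoms changed between admission and discharge.

The pipeline has five modeling stages.

**1. Curation.** Free-text clinical vocabulary is heterogeneous
("gastric distension" may be recorded under several synonymous surface
forms). Every multi-valued field is mapped through a user-supplied
dictionary `raw term -> (canonical term, feature class)` and de-duplicated
into a set. ICD codes are rolled up to their category plus one
post-decimal character (`I50.903`, `I50.905` → `I50.9`), generalizing the
single published example of that collapse. Records lacking a patient id,
all diagnostic information, or any discharge information are excluded;
when a patient has several admissions, the one with the highest
completeness score — the count of populated fields among the seven
clinical set-fields plus outcome, age and sex (0–10) — is retained, ties
broken by latest admission date, then lexicographically greatest admission
id. Both tie-break layers were open design choices; "latest state" was
preferred for consistency with keeping the most informative record.

**2. The patient similarity network (PSN).** For patients $u,v$ with
symptom sets $A,B$, similarity is the Jaccard coefficient
$J(A,B) = |A \cap B| / |A \cup B|$. The network is built in three steps:
an all-pairs network over *main* symptoms (chief complaint) thresholded at
$J \ge 0.8$ — keeping only pairs with nearly identical predominant
symptoms; an unthresholded network over *general* symptoms (history of
present illness); and the overlap of the two edge sets, each surviving
edge weighted by the general-symptom similarity. Three numerical choices
deserve note: the 0.8 threshold is *inclusive* (so the boundary case
$4/5$ survives); a pair with disjoint general symptoms forms *no* edge
rather than a zero-weight edge (a zero-weight edge carries no similarity
information and would distort weighted modularity); and patients with an
empty symptom field are dropped from that network rather than raising an
error. Nodes left without any qualifying edge drop out of the final
network, which is why the networked cohort is smaller than the curated
one.

**3. Community detection.** The default partitioner is a from-scratch
weighted Louvain: repeated passes of greedy local moves maximizing the
gain in Newman–Girvan modularity

$$Q = \sum_c \left[ \frac{W_c}{m} - \gamma\left(\frac{S_c}{2m}\right)^2 \right],$$

with $W_c$ the intra-community edge weight, $S_c$ the community strength,
$m$ the total edge weight and resolution $\gamma = 1$ by default, followed
by aggregation of communities into supernodes, iterated until the
between-level gain falls below `tolerance` (default `1e-7`). Node visit
order is a seeded random permutation per pass and ties in the gain break
toward the lowest module id, so results are deterministic given the seed.
Because single-start greedy ascent can lock into a suboptimum (we observed
this on random graphs as small as 7 nodes), `louvain()` runs 10 seeded
restarts by default and returns the best-Q partition; on every graph of at
most 8 nodes in the test battery this attains the exhaustive-search
optimum. Edge weights are used throughout: the overlap weights are the
only information the final PSN carries beyond topology, and discarding
them was judged indefensible. The reported $Q$ is always recomputed from
the final assignment by an independent code path.

An overlapping alternative, `bigclam()`, fits the cluster-affiliation
model $P(u \sim v) = 1 - \exp(-F_u \cdot F_v)$ with nonnegative
affiliations $F \in \mathbb{R}_{\ge 0}^{N \times k}$ by per-node projected
gradient ascent with backtracking, so the log-likelihood never decreases
on accepted steps. Memberships are thresholded at
$\varepsilon = \sqrt{-\log(1 - 1/N)}$, the strength at which the modeled
edge probability equals the $1/N$ background rate — the conventional rule;
the model itself ignores edge weights (it is a model of the unweighted
topology). The exclusive partitioner is the pipeline default since patient
subgroups with clear boundaries are the analysis target; the overlapping
cover is provided for comorbidity-style questions.

**4. Enrichment.** A module $i$ is characterized against each feature $j$
(symptoms, tongue, pulse, diagnoses, herbs) by relative risk over the
*networked* cohort of size $N$:

$$RR = \frac{C_{ij}/C_i}{(C_j - C_{ij})/(N - C_i)},$$

prevalence inside the module over prevalence outside it, screened by a
Pearson chi-square test on the 2×2 module-by-feature table with one degree
of freedom and **no** continuity correction (at cohort scale the
correction is immaterial; the choice is configurable). A pair is flagged
significant when $RR > 1$ *and* $p < \alpha$ (default 0.05, uncorrected;
Benjamini–Hochberg is available but off by default). Strict $RR > 1$ is
used: $RR = 1$ carries no enrichment signal. $RR$ is $+\infty$ when a
feature occurs only inside the module; such values are serialized as the
string `"inf"`, never clipped. Using the networked patients (not the full
curated cohort) as the universe is a deliberate choice: modules are
defined only over networked patients, so their complement must be too.

**5. Efficacy.** A symptom is *resolved* for a patient when present at
admission (main ∪ general symptoms — both fields describe admission
state) and absent from the discharge set of the same hospitalization.
Per-module resolution rates are reported for symptoms with at least
`min_support = 5` admission carriers, below which rates are dominated by
binomial noise. Patients whose discharge record was never filed (missing,
as opposed to observed-empty, which legitimately means "all symptoms
resolved") are excluded from denominators. Herb–symptom association is
reported as co-occurrence of significant herbs and resolved symptoms
within a module; no causal model is fitted.

## The synthetic world

`generate_cohort()` emulates the *structure* of the motivating EMR
extract, not its marginals. Defaults, fixed once:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 1000 | desk-scale cohort with stable module statistics |
| `n_subgroups` | 3 | mirrors the three analyzed subgroups |
| signature main / general symptoms | 5 / 8 per subgroup, disjoint | identifiable planted structure |
| `p_signature` | 0.85 | strong but noisy signatures |
| background pool / `p_background` | 40 / 0.05 | nonspecific complaints |
| signature herbs / `p_herb_signature` | 5 / 0.9 | subgroup-linked prescriptions |
| resolution (signature + herb / background) | 0.9 / 0.4 | treatment-responsive vs baseline |
| `synonym_rate` | 0.1 | dictionary-resolvable surface variation |
| `duplicate_admission_rate` | 0.05 | re-hospitalizations, degraded copies |
| `missingness_rate` | 0.03 | unfiled discharge records |
| age, sex | 59.27 ± 11.44, 52.6% male | published elderly-gastritis demographics |

Subgroup-linked tongue/pulse/syndrome channels (one signature feature
each at rates 0.8/0.8/0.9, plus a common feature) are emitted so all five
enrichment classes and the inclusion rules are exercisable; they are not
part of the planted-recovery metrics. Under these defaults roughly half
the cohort survives into the network: two same-subgroup patients share a
0.8-Jaccard main-symptom pair only when their noisy signature draws nearly
coincide. That attrition is intentional — it reproduces the qualitative
gap between curated and networked cohort sizes seen in practice.

What a green recovery test establishes: on cohorts with disjoint planted
signatures and this noise level, the pipeline's curation, network,
partitioning, enrichment and resolution stages compose correctly
(ARI ≥ 0.8 against planted labels, every planted signature flagged in its
own mapped module and no other, signature-channel resolution within 0.05
of the generating 0.9). What it does not establish: performance under
overlapping subgroup signatures, correlated symptoms, informative
missingness, or real clinical vocabulary drift — none of which the
generator models.

Subgroups are mapped to detected modules by plurality before scoring
signature recall. Louvain routinely shaves small satellite fragments
(3–5 near-identical patients disconnected from their subgroup's main
component); treating those fragments as "foreign" modules would misread
fragmentation as leakage, so specificity is assessed across the three
*mapped* modules. Background-symptom resolution rates are checked as a
pooled binomial property rather than per-row: at prevalence 0.05 a
(module, symptom) row holds only ~5–10 carriers and its rate is noise.

## Numerical and degenerate-input choices

- Jaccard of two empty sets is an error (undefined), not 0 or 1; callers
  exclude empty-field patients first.
- Edges are stored once, endpoints in lexicographic order, rows sorted —
  serializations are byte-reproducible and digest-comparable.
- All randomness (generator, Louvain visit order, BigClam initialization)
  flows through per-call seeds and restores the caller's RNG state.
- A feature present in every networked patient is reported with
  $RR = 1$, $\chi^2 = 0$, $p = 1$ (the degenerate-marginal chi-square is
  skipped); a feature class absent from the cohort yields an empty table
  with a warning.
- Two arithmetic discrepancies in reference material surfaced during
  validation and are resolved in favor of the mathematics: a published
  worked chi-square example is internally inconsistent with its own 2×2
  table (the table gives 4.762, p = 0.029, confirmed by
  `chisq.test(correct = FALSE)` and the closed-form identity), and a
  published 52.60% share is 0.01 off the value its own printed counts
  produce (52.59%). Tests assert the recomputed values.

## Limitations

- The pipeline starts from coded lists; it performs no free-text NLP, and
  the dictionary is an input, not a learned object.
- No ICD-10↔ICD-11 cross-mapping; rollup is purely lexical truncation.
- BigClam's community count $k$ is user-supplied; no automatic selection
  is performed.
- Enrichment p-values are uncorrected by default by design; with
  thousands of (module, feature) pairs the expected false-flag count is
  material, and users wanting control should switch `p_adjust = "BH"`.
- Resolution compares presence/absence only; symptom severity is not
  modeled.
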